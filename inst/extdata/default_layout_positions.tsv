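block_row	block_col	row	col	analyte	role
0	0	0	0	REF	reference
0	0	0	1	NA	empty
0	0	0	2	CYT01	analyte
0	0	0	3	CYT01	analyte
0	0	0	4	CYT02	analyte
0	0	0	5	CYT02	analyte
0	0	0	6	CYT03	analyte
0	0	0	7	CYT03	analyte
0	0	0	8	CYT04	analyte
0	0	0	9	CYT04	analyte
0	0	1	0	CYT05	analyte
0	0	1	1	CYT05	analyte
0	0	1	2	CYT06	analyte
0	0	1	3	CYT06	analyte
0	0	1	4	CYT07	analyte
0	0	1	5	CYT07	analyte
0	0	1	6	CYT08	analyte
0	0	1	7	CYT08	analyte
0	0	1	8	CYT09	analyte
0	0	1	9	CYT09	analyte
0	0	2	0	CYT10	analyte
0	0	2	1	CYT10	analyte
0	0	2	2	CYT11	analyte
0	0	2	3	CYT11	analyte
0	0	2	4	CYT12	analyte
0	0	2	5	CYT12	analyte
0	0	2	6	CYT13	analyte
0	0	2	7	CYT13	analyte
0	0	2	8	NA	empty
0	0	2	9	NA	empty
0	0	3	0	NA	empty
0	0	3	1	NA	empty
0	0	3	2	NA	empty
0	0	3	3	NA	empty
0	0	3	4	NA	empty
0	0	3	5	NA	empty
0	0	3	6	NA	empty
0	0	3	7	NA	empty
0	0	3	8	NA	empty
0	0	3	9	NA	empty
0	0	4	0	NA	empty
0	0	4	1	NA	empty
0	0	4	2	NA	empty
0	0	4	3	NA	empty
0	0	4	4	NA	empty
0	0	4	5	NA	empty
0	0	4	6	NA	empty
0	0	4	7	NA	empty
0	0	4	8	NA	empty
0	0	4	9	NA	empty
0	0	5	0	NA	empty
0	0	5	1	NA	empty
0	0	5	2	NA	empty
0	0	5	3	NA	empty
0	0	5	4	NA	empty
0	0	5	5	NA	empty
0	0	5	6	NA	empty
0	0	5	7	NA	empty
0	0	5	8	NA	empty
0	0	5	9	NA	empty
0	0	6	0	NA	empty
0	0	6	1	NA	empty
0	0	6	2	NA	empty
0	0	6	3	NA	empty
0	0	6	4	NA	empty
0	0	6	5	NA	empty
0	0	6	6	NA	empty
0	0	6	7	NA	empty
0	0	6	8	NA	empty
0	0	6	9	NA	empty
0	0	7	0	NA	empty
0	0	7	1	NA	empty
0	0	7	2	NA	empty
0	0	7	3	NA	empty
0	0	7	4	NA	empty
0	0	7	5	NA	empty
0	0	7	6	NA	empty
0	0	7	7	NA	empty
0	0	7	8	NA	empty
0	0	7	9	NA	empty
0	0	8	0	NA	empty
0	0	8	1	NA	empty
0	0	8	2	NA	empty
0	0	8	3	NA	empty
0	0	8	4	NA	empty
0	0	8	5	NA	empty
0	0	8	6	NA	empty
0	0	8	7	NA	empty
0	0	8	8	NA	empty
0	0	8	9	NA	empty
0	0	9	0	NA	empty
0	0	9	1	NA	empty
0	0	9	2	NA	empty
0	0	9	3	NA	empty
0	0	9	4	NA	empty
0	0	9	5	NA	empty
0	0	9	6	NA	empty
0	0	9	7	NA	empty
0	0	9	8	NA	empty
0	0	9	9	NEG	negative
0	1	0	0	CYT14	analyte
0	1	0	1	CYT14	analyte
0	1	0	2	CYT15	analyte
0	1	0	3	CYT15	analyte
0	1	0	4	CYT16	analyte
0	1	0	5	CYT16	analyte
0	1	0	6	CYT17	analyte
0	1	0	7	CYT17	analyte
0	1	0	8	NA	empty
0	1	0	9	REF	reference
0	1	1	0	CYT18	analyte
0	1	1	1	CYT18	analyte
0	1	1	2	CYT19	analyte
0	1	1	3	CYT19	analyte
0	1	1	4	CYT20	analyte
0	1	1	5	CYT20	analyte
0	1	1	6	CYT21	analyte
0	1	1	7	CYT21	analyte
0	1	1	8	CYT22	analyte
0	1	1	9	CYT22	analyte
0	1	2	0	CYT23	analyte
0	1	2	1	CYT23	analyte
0	1	2	2	CYT24	analyte
0	1	2	3	CYT24	analyte
0	1	2	4	CYT25	analyte
0	1	2	5	CYT25	analyte
0	1	2	6	CYT26	analyte
0	1	2	7	CYT26	analyte
0	1	2	8	NA	empty
0	1	2	9	NA	empty
0	1	3	0	NA	empty
0	1	3	1	NA	empty
0	1	3	2	NA	empty
0	1	3	3	NA	empty
0	1	3	4	NA	empty
0	1	3	5	NA	empty
0	1	3	6	NA	empty
0	1	3	7	NA	empty
0	1	3	8	NA	empty
0	1	3	9	NA	empty
0	1	4	0	NA	empty
0	1	4	1	NA	empty
0	1	4	2	NA	empty
0	1	4	3	NA	empty
0	1	4	4	NA	empty
0	1	4	5	NA	empty
0	1	4	6	NA	empty
0	1	4	7	NA	empty
0	1	4	8	NA	empty
0	1	4	9	NA	empty
0	1	5	0	NA	empty
0	1	5	1	NA	empty
0	1	5	2	NA	empty
0	1	5	3	NA	empty
0	1	5	4	NA	empty
0	1	5	5	NA	empty
0	1	5	6	NA	empty
0	1	5	7	NA	empty
0	1	5	8	NA	empty
0	1	5	9	NA	empty
0	1	6	0	NA	empty
0	1	6	1	NA	empty
0	1	6	2	NA	empty
0	1	6	3	NA	empty
0	1	6	4	NA	empty
0	1	6	5	NA	empty
0	1	6	6	NA	empty
0	1	6	7	NA	empty
0	1	6	8	NA	empty
0	1	6	9	NA	empty
0	1	7	0	NA	empty
0	1	7	1	NA	empty
0	1	7	2	NA	empty
0	1	7	3	NA	empty
0	1	7	4	NA	empty
0	1	7	5	NA	empty
0	1	7	6	NA	empty
0	1	7	7	NA	empty
0	1	7	8	NA	empty
0	1	7	9	NA	empty
0	1	8	0	NA	empty
0	1	8	1	NA	empty
0	1	8	2	NA	empty
0	1	8	3	NA	empty
0	1	8	4	NA	empty
0	1	8	5	NA	empty
0	1	8	6	NA	empty
0	1	8	7	NA	empty
0	1	8	8	NA	empty
0	1	8	9	NA	empty
0	1	9	0	NEG	negative
0	1	9	1	NA	empty
0	1	9	2	NA	empty
0	1	9	3	NA	empty
0	1	9	4	NA	empty
0	1	9	5	NA	empty
0	1	9	6	NA	empty
0	1	9	7	NA	empty
0	1	9	8	NA	empty
0	1	9	9	NA	empty
1	0	0	0	CYT27	analyte
1	0	0	1	CYT27	analyte
1	0	0	2	CYT28	analyte
1	0	0	3	CYT28	analyte
1	0	0	4	CYT29	analyte
1	0	0	5	CYT29	analyte
1	0	0	6	CYT30	analyte
1	0	0	7	CYT30	analyte
1	0	0	8	NA	empty
1	0	0	9	NEG	negative
1	0	1	0	CYT31	analyte
1	0	1	1	CYT31	analyte
1	0	1	2	CYT32	analyte
1	0	1	3	CYT32	analyte
1	0	1	4	CYT33	analyte
1	0	1	5	CYT33	analyte
1	0	1	6	CYT34	analyte
1	0	1	7	CYT34	analyte
1	0	1	8	CYT35	analyte
1	0	1	9	CYT35	analyte
1	0	2	0	CYT36	analyte
1	0	2	1	CYT36	analyte
1	0	2	2	CYT37	analyte
1	0	2	3	CYT37	analyte
1	0	2	4	CYT38	analyte
1	0	2	5	CYT38	analyte
1	0	2	6	NA	empty
1	0	2	7	NA	empty
1	0	2	8	NA	empty
1	0	2	9	NA	empty
1	0	3	0	NA	empty
1	0	3	1	NA	empty
1	0	3	2	NA	empty
1	0	3	3	NA	empty
1	0	3	4	NA	empty
1	0	3	5	NA	empty
1	0	3	6	NA	empty
1	0	3	7	NA	empty
1	0	3	8	NA	empty
1	0	3	9	NA	empty
1	0	4	0	NA	empty
1	0	4	1	NA	empty
1	0	4	2	NA	empty
1	0	4	3	NA	empty
1	0	4	4	NA	empty
1	0	4	5	NA	empty
1	0	4	6	NA	empty
1	0	4	7	NA	empty
1	0	4	8	NA	empty
1	0	4	9	NA	empty
1	0	5	0	NA	empty
1	0	5	1	NA	empty
1	0	5	2	NA	empty
1	0	5	3	NA	empty
1	0	5	4	NA	empty
1	0	5	5	NA	empty
1	0	5	6	NA	empty
1	0	5	7	NA	empty
1	0	5	8	NA	empty
1	0	5	9	NA	empty
1	0	6	0	NA	empty
1	0	6	1	NA	empty
1	0	6	2	NA	empty
1	0	6	3	NA	empty
1	0	6	4	NA	empty
1	0	6	5	NA	empty
1	0	6	6	NA	empty
1	0	6	7	NA	empty
1	0	6	8	NA	empty
1	0	6	9	NA	empty
1	0	7	0	NA	empty
1	0	7	1	NA	empty
1	0	7	2	NA	empty
1	0	7	3	NA	empty
1	0	7	4	NA	empty
1	0	7	5	NA	empty
1	0	7	6	NA	empty
1	0	7	7	NA	empty
1	0	7	8	NA	empty
1	0	7	9	NA	empty
1	0	8	0	NA	empty
1	0	8	1	NA	empty
1	0	8	2	NA	empty
1	0	8	3	NA	empty
1	0	8	4	NA	empty
1	0	8	5	NA	empty
1	0	8	6	NA	empty
1	0	8	7	NA	empty
1	0	8	8	NA	empty
1	0	8	9	NA	empty
1	0	9	0	REF	reference
1	0	9	1	NA	empty
1	0	9	2	NA	empty
1	0	9	3	NA	empty
1	0	9	4	NA	empty
1	0	9	5	NA	empty
1	0	9	6	NA	empty
1	0	9	7	NA	empty
1	0	9	8	NA	empty
1	0	9	9	NA	empty
1	1	0	0	NEG	negative
1	1	0	1	NA	empty
1	1	0	2	CYT39	analyte
1	1	0	3	CYT39	analyte
1	1	0	4	CYT40	analyte
1	1	0	5	CYT40	analyte
1	1	0	6	CYT41	analyte
1	1	0	7	CYT41	analyte
1	1	0	8	CYT42	analyte
1	1	0	9	CYT42	analyte
1	1	1	0	CYT43	analyte
1	1	1	1	CYT43	analyte
1	1	1	2	CYT44	analyte
1	1	1	3	CYT44	analyte
1	1	1	4	CYT45	analyte
1	1	1	5	CYT45	analyte
1	1	1	6	CYT46	analyte
1	1	1	7	CYT46	analyte
1	1	1	8	CYT47	analyte
1	1	1	9	CYT47	analyte
1	1	2	0	CYT48	analyte
1	1	2	1	CYT48	analyte
1	1	2	2	CYT49	analyte
1	1	2	3	CYT49	analyte
1	1	2	4	CYT50	analyte
1	1	2	5	CYT50	analyte
1	1	2	6	NA	empty
1	1	2	7	NA	empty
1	1	2	8	NA	empty
1	1	2	9	NA	empty
1	1	3	0	NA	empty
1	1	3	1	NA	empty
1	1	3	2	NA	empty
1	1	3	3	NA	empty
1	1	3	4	NA	empty
1	1	3	5	NA	empty
1	1	3	6	NA	empty
1	1	3	7	NA	empty
1	1	3	8	NA	empty
1	1	3	9	NA	empty
1	1	4	0	NA	empty
1	1	4	1	NA	empty
1	1	4	2	NA	empty
1	1	4	3	NA	empty
1	1	4	4	NA	empty
1	1	4	5	NA	empty
1	1	4	6	NA	empty
1	1	4	7	NA	empty
1	1	4	8	NA	empty
1	1	4	9	NA	empty
1	1	5	0	NA	empty
1	1	5	1	NA	empty
1	1	5	2	NA	empty
1	1	5	3	NA	empty
1	1	5	4	NA	empty
1	1	5	5	NA	empty
1	1	5	6	NA	empty
1	1	5	7	NA	empty
1	1	5	8	NA	empty
1	1	5	9	NA	empty
1	1	6	0	NA	empty
1	1	6	1	NA	empty
1	1	6	2	NA	empty
1	1	6	3	NA	empty
1	1	6	4	NA	empty
1	1	6	5	NA	empty
1	1	6	6	NA	empty
1	1	6	7	NA	empty
1	1	6	8	NA	empty
1	1	6	9	NA	empty
1	1	7	0	NA	empty
1	1	7	1	NA	empty
1	1	7	2	NA	empty
1	1	7	3	NA	empty
1	1	7	4	NA	empty
1	1	7	5	NA	empty
1	1	7	6	NA	empty
1	1	7	7	NA	empty
1	1	7	8	NA	empty
1	1	7	9	NA	empty
1	1	8	0	NA	empty
1	1	8	1	NA	empty
1	1	8	2	NA	empty
1	1	8	3	NA	empty
1	1	8	4	NA	empty
1	1	8	5	NA	empty
1	1	8	6	NA	empty
1	1	8	7	NA	empty
1	1	8	8	NA	empty
1	1	8	9	NA	empty
1	1	9	0	NA	empty
1	1	9	1	NA	empty
1	1	9	2	NA	empty
1	1	9	3	NA	empty
1	1	9	4	NA	empty
1	1	9	5	NA	empty
1	1	9	6	NA	empty
1	1	9	7	NA	empty
1	1	9	8	NA	empty
1	1	9	9	REF	reference
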