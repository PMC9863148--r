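{
  "name": "synthetic_default",
  "n_block_rows": 2,
  "n_block_cols": 2,
  "rows_per_block": 10,
  "cols_per_block": 10,
  "pitch": 16,
  "alley_row": 2,
  "alley_col": 2,
  "spot_radius": 5,
  "n_duplicates": 2,
  "positions_tsv": "default_layout_positions.tsv"
}
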