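male_tab <- function() load_marker_table(extdata("markers_male_series12.tsv"))
female_tab <- function() load_marker_table(extdata("markers_female_series12.tsv"))
series3_tab <- function() load_marker_table(extdata("markers_series3.tsv"))

test_that("cross-series consensus on the male kidney-array calls is IL10 up, MME down", {
  tab <- male_tab()
  s1 <- table_calls(tab, "CKD_M_ExpSeries1", series = 1, gender = "M")
  s2 <- table_calls(tab, "CKD_M_ExpSeries2", series = 2, gender = "M")
  panel <- consensus_across_series(s1, s2)
  expect_identical(panel$members$analyte, c("IL10", "MME"))
  expect_identical(panel$members$direction, c("up", "down"))
  # series-discordant markers are reported, not dropped
  expect_identical(panel$discordant$analyte, c("CLU", "MMP9", "RBP4", "VEGF"))
  # symmetry and idempotence
  rev <- consensus_across_series(s2, s1)
  expect_identical(rev$members, panel$members)
  self <- consensus_across_series(s1, s1)
  expect_identical(self$members$analyte, sort(s1$analyte))
})

test_that("cross-series consensus on the female calls matches the published panel", {
  tab <- female_tab()
  panel <- consensus_across_series(
    table_calls(tab, "CKD_F_ExpSeries1", 1, "F"),
    table_calls(tab, "CKD_F_ExpSeries2", 2, "F"))
  members <- setNames(panel$members$direction, panel$members$analyte)
  expect_identical(members,
                   c(AGER = "down", CLU = "up", EGFR = "down",
                     RETN = "up", VEGF = "down"))
})

test_that("gender overlap on the XL-array calls reproduces the published sets", {
  tab <- series3_tab()
  panel <- gender_overlap(table_calls(tab, "CKD_M_ExpSeries3", 3, "M"),
                          table_calls(tab, "CKD_F_ExpSeries3", 3, "F"))
  up <- sort(panel$members$analyte[panel$members$direction == "up"])
  down <- sort(panel$members$analyte[panel$members$direction == "down"])
  expect_identical(up, sort(c("APOA1", "ANGPT2", "C5", "CFD", "GH1", "ICAM1",
                              "IGFBP2", "IL8", "KLK4", "MMP9", "SPP1")))
  expect_identical(down, sort(c("FLT3LG", "CSF1", "PDGFA", "RETN", "VEGFA")))
  # panel members always exist in both inputs (subset property)
  expect_true(all(panel$members$analyte %in% tab$cytokine[!is.na(tab$CKD_M_ExpSeries3)]))
  expect_true(all(panel$members$analyte %in% tab$cytokine[!is.na(tab$CKD_F_ExpSeries3)]))
})

test_that("disjoint or conflicting call sets produce empty overlaps and discordant reports", {
  a <- marker_calls(data.frame(analyte = c("X", "Y"), direction = c("up", "down")), 1, "M")
  b <- marker_calls(data.frame(analyte = c("Z"), direction = "up"), 1, "F")
  panel <- gender_overlap(a, b)
  expect_identical(nrow(panel$members), 0L)
  expect_identical(panel$specific$male$analyte, c("X", "Y"))
  expect_identical(panel$specific$female$analyte, "Z")
  cc <- gender_overlap(a, marker_calls(data.frame(analyte = "X", direction = "down"), 1, "F"))
  expect_identical(nrow(cc$members), 0L)
  expect_identical(cc$discordant$analyte, "X")
})

test_that("the digitized mean column equals the gender overlap plus single-gender-supported calls", {
  tab <- series3_tab()
  overlap <- gender_overlap(table_calls(tab, "CKD_M_ExpSeries3", 3, "M"),
                            table_calls(tab, "CKD_F_ExpSeries3", 3, "F"))
  mean_calls <- table_calls(tab, "CKD_mean_M_F_ExpSeries3", 3, "mean")
  ov <- setNames(overlap$members$direction, overlap$members$analyte)
  mc <- setNames(mean_calls$direction, mean_calls$analyte)
  # every overlap member is in the mean column with the same direction
  expect_identical(mc[names(ov)], ov)
  extra <- mc[setdiff(names(mc), names(ov))]
  expect_identical(extra[c("CHI3L1", "MPO", "PTX3", "SERPINE1")],
                   c(CHI3L1 = "up", MPO = "up", PTX3 = "up", SERPINE1 = "up"))
  expect_identical(extra[c("CD3", "CRP", "CSF2")],
                   c(CD3 = "down", CRP = "down", CSF2 = "down"))
})

test_that("averaging male and female CKD values recomputes the calls", {
  set.seed(19)
  base <- 2^rnorm(30, 8, 0.5)
  noise <- function(eps = 0.04) 2^matrix(rnorm(60, 0, eps), 30, 2)
  fold_m <- rep(1, 30); fold_m[1] <- 2.0
  fold_f <- rep(1, 30); fold_f[1] <- 1.2
  vals <- cbind(base * fold_m * noise(), base * fold_f * noise(), base * noise())
  dimnames(vals) <- list(paste0("a", 1:30),
                         c("km.d1", "km.d2", "kf.d1", "kf.d2", "c.d1", "c.d2"))
  samples <- data.frame(sample_id = colnames(vals),
                        series = 3,
                        gender = c("M", "M", "F", "F", "M", "M"),
                        group = rep(c("CKD", "CKD", "control"), each = 2),
                        replicate = rep(1:2, 3))
  em <- expression_matrix(vals, samples, scale = "normalized")
  det <- data.frame(analyte = rownames(vals), detect_p_ckd_m = 0.01,
                    detect_p_ckd_f = 0.01, detect_p_control = 0.01)
  res <- mean_gender_calls(em, det, de_criteria(), series = 3)
  # mean-based ratio ~ (2.0 + 1.2)/2 = 1.6 > 1.5: eligible for an up call
  expect_equal(res$de$ratio[res$de$analyte == "a1"], 1.6, tolerance = 0.1)
  expect_identical(res$calls$direction[res$calls$analyte == "a1"], "up")
  expect_identical(unique(res$calls$gender), "mean")
  # equal genders reduce to the single-gender contrast
  vals2 <- vals; vals2[, 3:4] <- vals[, 1:2]
  em2 <- expression_matrix(vals2, samples, scale = "normalized")
  res2 <- mean_gender_calls(em2, det, de_criteria(), series = 3)
  de_single <- call_differential(vals2[, c(1, 2, 5, 6)], data.frame(
    analyte = rownames(vals), detect_p_ckd = 0.01, detect_p_control = 0.01),
    de_criteria(), groups = c("CKD", "CKD", "control", "control"))
  expect_equal(res2$de$ratio, de_single$ratio, tolerance = 1e-12)
  expect_identical(res2$de$call, de_single$call)
})

test_that("correlation dendrograms join duplicated samples first", {
  set.seed(20)
  a <- rnorm(40); b <- rnorm(40)
  m <- cbind(A = a + rnorm(40, 0, 0.01), A2 = a + rnorm(40, 0, 0.01),
             B = b + rnorm(40, 0, 0.01), B2 = b + rnorm(40, 0, 0.01))
  dend <- correlation_dendrogram(m)
  p2 <- cutree_partition(dend$hclust, 2)
  expect_true(same_partition(p2, list(c(1, 2), c(3, 4))))
  expect_error(correlation_dendrogram(cbind(m, Z = rep(1, 40))),
               "zero-variance.*Z")
})

test_that("clustering matches the brute-force complete-linkage oracle", {
  set.seed(21)
  for (r in 1:30) {
    n <- sample(5:8, 1)
    m <- matrix(rnorm(20 * n), 20, n,
                dimnames = list(NULL, paste0("s", seq_len(n))))
    dend <- correlation_dendrogram(m)
    oracle <- complete_linkage_brute(m)
    expect_equal(dend$height, oracle$heights, tolerance = 1e-12)
    for (k in seq_along(oracle$partitions)) {
      expect_true(same_partition(cutree_partition(dend$hclust, n - k),
                                 oracle$partitions[[k]]))
    }
  }
})

test_that("newick export encodes all leaves", {
  skip_if_not_installed("ape")
  set.seed(22)
  m <- matrix(rnorm(100), 20, 5, dimnames = list(NULL, paste0("s", 1:5)))
  nwk <- write_newick(correlation_dendrogram(m))
  tr <- ape::read.tree(text = nwk)
  expect_setequal(tr$tip.label, paste0("s", 1:5))
})

test_that("heatmap export restricts to called markers in dendrogram order", {
  set.seed(23)
  m <- matrix(2^rnorm(80, 8, 1), 20, 4,
              dimnames = list(paste0("a", 1:20), paste0("s", 1:4)))
  calls <- data.frame(analyte = c("a3", "a7", "a11"),
                      direction = c("up", "down", "up"))
  out <- export_heatmap_table(m, calls)
  expect_setequal(rownames(out$matrix), calls$analyte)
  expect_identical(rownames(out$matrix), out$row_order)
  dir <- withr::local_tempdir()
  res <- export_heatmap_table(m, calls, file = file.path(dir, "hm"))
  back <- as.matrix(utils::read.csv(file.path(dir, "hm.csv"), row.names = 1))
  expect_equal(unname(back), unname(res$matrix), tolerance = 1e-6)
  expect_identical(readLines(file.path(dir, "hm_rows.txt")), res$row_order)
  expect_warning(none <- export_heatmap_table(m, calls[0, ]), "no called markers")
  expect_identical(nrow(none$matrix), 0L)
})
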