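test_that("corner detection assigns rectangle maxima to the right corners", {
  m <- maxima_set(data.frame(x = c(10, 90, 10, 90), y = c(10, 10, 70, 70),
                             intensity = c(5, 6, 7, 8)))
  co <- detect_corners(m, image_shape = c(80, 100))
  expect_equal(unname(co$tl), c(10, 10))
  expect_equal(unname(co$tr), c(90, 10))
  expect_equal(unname(co$bl), c(10, 70))
  expect_equal(unname(co$br), c(90, 70))
})

test_that("an empty quadrant is a corner-detection error naming the quadrant", {
  m <- maxima_set(data.frame(x = c(10, 90, 10), y = c(10, 10, 70),
                             intensity = c(5, 6, 7)))
  expect_error(detect_corners(m, image_shape = c(80, 100)),
               "no maximum in quadrant BR")
})

square_corners <- list(tl = c(0, 0), tr = c(30, 0), bl = c(0, 30), br = c(30, 30))

test_that("grid interpolation on an axis-aligned square reproduces the pitch lattice", {
  pos <- expand.grid(col = 0:3, row = 0:3)
  lay <- array_layout("one", 1, 1, 4, 4, pitch = 10, spot_radius = 2,
                      positions = data.frame(block_row = 0, block_col = 0,
                                             row = pos$row, col = pos$col,
                                             analyte = sprintf("A%02d", seq_len(16)),
                                             role = "analyte"),
                      n_duplicates = 1)
  g <- interpolate_grid(square_corners, lay)
  expect_identical(nrow(g), 16L)
  expect_true(all(g$provenance == "interpolated"))
  k <- g$row == 1 & g$col == 2
  expect_equal(c(g$x[k], g$y[k]), c(20, 10))
  # corners map exactly onto the extreme positions
  expect_equal(c(g$x[g$row == 0 & g$col == 0], g$y[g$row == 0 & g$col == 0]), c(0, 0))
  expect_equal(c(g$x[g$row == 3 & g$col == 3], g$y[g$row == 3 & g$col == 3]), c(30, 30))
})

alley_layout <- function() {
  pos <- expand.grid(col = 0:1, row = 0:1, block_col = 0:1, block_row = 0:1)
  array_layout("blocks", 2, 2, 2, 2, pitch = 10, alley_row = 1, alley_col = 1,
               spot_radius = 2,
               positions = data.frame(block_row = pos$block_row,
                                      block_col = pos$block_col,
                                      row = pos$row, col = pos$col,
                                      analyte = sprintf("A%02d", seq_len(16)),
                                      role = "analyte"),
               n_duplicates = 1)
}

test_that("alleyways widen the cross-block step to (1 + alley) pitch units", {
  g <- interpolate_grid(square_corners, alley_layout())
  xs <- sort(unique(g$x))
  # unit lattice 0,1,3,4 scaled onto the 30 px span
  expect_equal(xs, c(0, 1, 3, 4) / 4 * 30)
  intra <- xs[2] - xs[1]
  gap <- xs[3] - xs[2]
  expect_equal(gap, 2 * intra)
  expect_equal(sort(unique(g$y)), c(0, 1, 3, 4) / 4 * 30)
})

test_that("sheared corners give parallel rows matching a brute-force bilinear oracle", {
  corners <- list(tl = c(5, 3), tr = c(65, 13), bl = c(15, 83), br = c(75, 93))
  lay <- alley_layout()
  g <- interpolate_grid(corners, lay)
  # independent bilinear evaluation at hand-computed (u, v) fractions
  units <- c(0, 1, 3, 4) / 4
  P <- rbind(corners$tl, corners$tr, corners$bl, corners$br)
  for (k in seq_len(nrow(g))) {
    u <- units[g$block_col[k] * 2 + g$col[k] + 1]
    v <- units[g$block_row[k] * 2 + g$row[k] + 1]
    exp_xy <- (1 - u) * (1 - v) * P[1, ] + u * (1 - v) * P[2, ] +
      (1 - u) * v * P[3, ] + u * v * P[4, ]
    expect_equal(c(g$x[k], g$y[k]), unname(exp_xy), tolerance = 1e-12)
  }
  # parallelogram rows stay parallel
  row0 <- g[g$block_row == 0 & g$row == 0, ]
  row1 <- g[g$block_row == 1 & g$row == 1, ]
  slope0 <- diff(range(row0$y)) / diff(range(row0$x))
  slope1 <- diff(range(row1$y)) / diff(range(row1$x))
  expect_equal(slope0, slope1, tolerance = 1e-12)
})

test_that("degenerate collinear corners are a geometry error", {
  bad <- list(tl = c(0, 0), tr = c(10, 10), bl = c(20, 20), br = c(30, 30))
  expect_error(interpolate_grid(bad, alley_layout()), "collinear")
})

test_that("grid interpolation is equivariant under translation and scaling", {
  lay <- alley_layout()
  g0 <- interpolate_grid(square_corners, lay)
  shift <- lapply(square_corners, function(p) 3 * p + c(11, -4))
  g1 <- interpolate_grid(shift, lay)
  expect_equal(g1$x, 3 * g0$x + 11, tolerance = 1e-12)
  expect_equal(g1$y, 3 * g0$y - 4, tolerance = 1e-12)
})

test_that("snapping moves entries to nearby maxima one-to-one and is idempotent", {
  lay <- alley_layout()
  g <- interpolate_grid(square_corners, lay)
  # maxima exactly at the interpolated positions: all snapped, unchanged
  m_exact <- maxima_set(data.frame(x = g$x, y = g$y, intensity = 1))
  s <- snap_to_maxima(g, m_exact, snap_radius = 4)
  expect_true(all(s$provenance == "snapped"))
  expect_equal(s$x, g$x)
  # empty maxima set: everything stays interpolated
  s0 <- snap_to_maxima(g, maxima_set(NULL), snap_radius = 4)
  expect_true(all(s0$provenance == "interpolated"))
  expect_equal(s0$x, g$x)
  # one bright maximum near two entries serves only the nearest entry
  m1 <- maxima_set(data.frame(x = 0.5, y = 0, intensity = 10))
  s1 <- snap_to_maxima(g, m1, snap_radius = 6)
  expect_identical(sum(s1$provenance == "snapped"), 1L)
  expect_equal(s1$x[s1$provenance == "snapped"], 0.5)
  # idempotence
  m2 <- maxima_set(data.frame(x = g$x + 0.4, y = g$y, intensity = 1))
  once <- snap_to_maxima(g, m2, snap_radius = 2)
  twice <- snap_to_maxima(once, m2, snap_radius = 2)
  expect_equal(as.data.frame(once), as.data.frame(twice))
  expect_error(snap_to_maxima(g, m2, snap_radius = 0), "snap_radius")
})

test_that("grids serialize to TSV and back", {
  g <- interpolate_grid(square_corners, alley_layout())
  dir <- withr::local_tempdir()
  path <- file.path(dir, "grid.tsv")
  write_grid_tsv(g, path)
  back <- read_grid_tsv(path)
  expect_equal(back$x, g$x)
  expect_identical(back$provenance, g$provenance)
})

test_that("simulated membranes are recovered within tight pixel tolerances", {
  cfg <- simulation_config(seed = 5)
  sim <- simulate_membrane(cfg, list(series = 1, gender = "M", group = "CKD"),
                           seed = 5)
  fit <- fit_spot_grid(sim$image, cfg$layout)
  tr <- sim$truth$centers
  d <- sqrt((fit$grid$x - tr$x_true)^2 + (fit$grid$y - tr$y_true)^2)
  # corners recovered at the planted reference anchors
  refs <- tr$role == "reference"
  expect_lt(max(d[refs]), 1)
  # present spots snap close to their planted centers
  snapped <- fit$grid$provenance == "snapped"
  expect_gt(mean(snapped[tr$rendered]), 0.6)
  expect_lt(stats::quantile(d[snapped], 0.99), 1)
  # absent analyte duplicates keep interpolated provenance
  absent <- tr$role == "analyte" & !tr$rendered
  expect_true(all(fit$grid$provenance[absent] == "interpolated"))
})
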