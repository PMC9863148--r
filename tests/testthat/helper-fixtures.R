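# small layouts, synthetic rasters and independent brute-force oracles
# shared across the test files

tiny_layout <- function(pitch = 10, spot_radius = 3) {
  array_layout(
    name = "tiny", n_block_rows = 1, n_block_cols = 1,
    rows_per_block = 2, cols_per_block = 2, pitch = pitch,
    spot_radius = spot_radius,
    positions = data.frame(
      block_row = 0L, block_col = 0L,
      row = c(0L, 0L, 1L, 1L), col = c(0L, 1L, 0L, 1L),
      analyte = c("A", "A", "B", "B"), role = "analyte"),
    n_duplicates = 2)
}

# render Gaussian spots on a constant background, no noise
gauss_image <- function(height, width, centers, sigma = 2, background = 0) {
  px <- matrix(background, height, width)
  for (k in seq_len(nrow(centers))) {
    cx <- centers$x[k]; cy <- centers$y[k]; a <- centers$amp[k]
    js <- 0:(width - 1); is <- 0:(height - 1)
    px <- px + a * outer(exp(-(is - cy)^2 / (2 * sigma^2)),
                         exp(-(js - cx)^2 / (2 * sigma^2)))
  }
  membrane_image(px)
}

# exhaustive 8-neighbour strict local maxima scan (oracle for maxima counts)
brute_maxima_count <- function(px) {
  h <- nrow(px); w <- ncol(px)
  cnt <- 0L
  for (i in 2:(h - 1)) for (j in 2:(w - 1)) {
    nb <- px[(i - 1):(i + 1), (j - 1):(j + 1)]
    if (px[i, j] > max(nb[-5])) cnt <- cnt + 1L
  }
  cnt
}

# O(n^2) brute-force Benjamini-Hochberg step-up oracle
bh_brute <- function(p) {
  n <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(n)
  for (i in seq_len(n)) {
    best <- 1
    for (j in i:n) best <- min(best, ps[j] * n / j)
    q[i] <- best
  }
  out <- numeric(n)
  out[ord] <- q
  out
}

# O(n^3) brute-force agglomeration with complete linkage on 1 - Pearson r;
# returns merge heights (ascending) and the partition after each merge
complete_linkage_brute <- function(m) {
  d <- 1 - stats::cor(m)
  n <- ncol(m)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1) {
    best <- c(NA, NA); bestd <- Inf
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (a >= b) next
      dd <- max(d[clusters[[a]], clusters[[b]]])
      if (dd < bestd) { bestd <- dd; best <- c(a, b) }
    }
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
    heights <- c(heights, bestd)
    partitions[[length(partitions) + 1]] <-
      lapply(clusters, function(x) sort(x))
  }
  list(heights = heights, partitions = partitions)
}

# partition of 1..n induced by cutting an hclust at k clusters, as a
# canonical list of sorted index sets
cutree_partition <- function(hc, k) {
  ct <- stats::cutree(hc, k = k)
  unname(lapply(split(seq_along(ct), ct), sort))
}

same_partition <- function(a, b) {
  key <- function(p) sort(vapply(p, function(x) paste(x, collapse = ","), ""))
  identical(key(a), key(b))
}

extdata <- function(name) system.file("extdata", name, package = "blotgrid")
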