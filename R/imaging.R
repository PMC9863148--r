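#' Construct a membrane image
#'
#' Wraps a 2D non-negative intensity raster.  Rows of the matrix run down the
#' image (y), columns run right (x); pixel \code{[i, j]} has its center at the
#' 0-based real coordinates \code{(x = j - 1, y = i - 1)}.  Images are stored
#' in \code{signal_high} polarity (spots brighter than background); a
#' \code{signal_low} raster is inverted as \code{max(pixels) - pixels} on
#' construction.
#'
#' @param pixels numeric matrix of intensities, all finite and >= 0, at least
#'   16 x 16.
#' @param polarity \code{"signal_high"} or \code{"signal_low"}.
#' @return Object of class \code{membrane_image} with fields \code{pixels},
#'   \code{height}, \code{width}, \code{polarity}; a raster with no contrast
#'   carries the attribute \code{constant = TRUE} (flagged, not an error).
#' @export
membrane_image <- function(pixels, polarity = c("signal_high", "signal_low")) {
  polarity <- match.arg(polarity)
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("pixels must be a numeric matrix")
  if (nrow(pixels) < 16 || ncol(pixels) < 16)
    stop("image must be at least 16x16 pixels")
  if (any(!is.finite(pixels)))
    stop("all intensities must be finite")
  if (any(pixels < 0))
    stop("all intensities must be >= 0")
  constant <- diff(range(pixels)) == 0
  if (polarity == "signal_low")
    pixels <- max(pixels) - pixels
  structure(list(pixels = pixels, height = nrow(pixels), width = ncol(pixels),
                 polarity = "signal_high"),
            constant = constant, class = "membrane_image")
}

#' @export
print.membrane_image <- function(x, ...) {
  cat(sprintf("membrane_image %dx%d px (height x width), range [%.6g, %.6g]\n",
              x$height, x$width, min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Read a scanned membrane image
#'
#' Reads an 8- or 16-bit grayscale TIFF or PNG (RGB inputs are converted by
#' channel-averaged luminance).  TIFF intensities are kept on their native
#' integer scale; PNG intensities (decoded to [0, 1]) are rescaled to the
#' 8-bit range, the depth [write_image()] produces for PNG.  A
#' \code{signal_low} scan (dark spots on bright background, as in
#' transmissive film scans) is inverted to \code{signal_high}.
#'
#' @param path image path, extension \code{.tif}/\code{.tiff} or \code{.png}.
#' @param polarity polarity of the stored file.
#' @return A \code{membrane_image}.
#' @export
read_image <- function(path, polarity = c("signal_high", "signal_low")) {
  polarity <- match.arg(polarity)
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    tif = , tiff = tryCatch(tiff::readTIFF(path, as.is = TRUE),
                            error = function(e) stop("cannot read TIFF '", path,
                                                     "': ", conditionMessage(e))),
    png = tryCatch(png::readPNG(path) * 255,
                   error = function(e) stop("cannot read PNG '", path, "': ",
                                            conditionMessage(e))),
    stop("unsupported image format '", ext, "' (use TIFF or PNG)")
  )
  if (length(dim(px)) == 3)  # RGB(A): luminance average over color channels
    px <- apply(px[, , seq_len(min(3, dim(px)[3])), drop = FALSE], c(1, 2), mean)
  img <- membrane_image(px, polarity = polarity)
  if (isTRUE(attr(img, "constant")))
    warning("image '", path, "' has no contrast (all pixels equal)")
  img
}

#' Write a membrane image
#'
#' Intensities are rounded to integers and clamped to the bit depth, so a
#' write-then-read round trip is pixel-identical for integer-valued rasters.
#' PNG output is always 8-bit (the format backend writes no deeper); use
#' TIFF for 16-bit rasters.
#'
#' @param image a \code{membrane_image}.
#' @param path output path (\code{.tif}/\code{.tiff} or \code{.png}).
#' @param bits bit depth, 8 or 16 (TIFF only; PNG is written at 8).
#' @return Invisibly, \code{path}.
#' @export
write_image <- function(image, path, bits = 16) {
  stopifnot(inherits(image, "membrane_image"), bits %in% c(8, 16))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png" && bits != 8) {
    warning("PNG is written at 8-bit depth")
    bits <- 8
  }
  top <- 2^bits - 1
  px <- pmin(pmax(round(image$pixels), 0), top) / top
  switch(ext,
    tif = , tiff = tiff::writeTIFF(px, path, bits.per.sample = bits),
    png = png::writePNG(px, path),
    stop("unsupported image format '", ext, "' (use TIFF or PNG)"))
  invisible(path)
}

# reflect an out-of-range 1-based index back into 1..n (symmetric padding,
# edge pixel repeated: 0 -> 1, -1 -> 2, n+1 -> n)
.reflect_index <- function(j, n) {
  while (any(bad <- j < 1 | j > n)) {
    j[j < 1] <- 1 - j[j < 1]
    j[j > n] <- 2 * n + 1 - j[j > n]
  }
  j
}

# n x n convolution matrix for a symmetric 1D kernel with reflective boundary
.conv_band <- function(n, kernel, radius) {
  B <- matrix(0, n, n)
  for (off in -radius:radius) {
    i <- seq_len(n)
    j <- .reflect_index(i + off, n)
    idx <- cbind(i, j)
    B[idx] <- B[idx] + kernel[off + radius + 1]
  }
  B
}

#' Gaussian blur
#'
#' Separable Gaussian convolution with reflective boundary handling.  The
#' kernel is truncated at 6 standard deviations and renormalized, so total
#' intensity is conserved and the semigroup property
#' \code{blur(s1) o blur(s2) = blur(sqrt(s1^2 + s2^2))} holds to high
#' accuracy on interior pixels.
#'
#' @param image a \code{membrane_image}.
#' @param sigma Gaussian standard deviation in pixels (default 4, the
#'   preprocessing width used ahead of maxima finding).
#' @return Blurred \code{membrane_image}.
#' @export
gaussian_blur <- function(image, sigma = 4) {
  stopifnot(inherits(image, "membrane_image"))
  if (!is.numeric(sigma) || length(sigma) != 1 || !is.finite(sigma) || sigma <= 0)
    stop("sigma must be a positive number")
  r <- max(1L, ceiling(6 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  h <- image$height; w <- image$width
  out <- .conv_band(h, k, r) %*% image$pixels %*% t(.conv_band(w, k, r))
  out[out < 0] <- 0  # guard tiny negative round-off
  membrane_image(out)
}

#' Construct a set of detected maxima
#'
#' @param points data frame with numeric columns \code{x}, \code{y},
#'   \code{intensity} (0-based pixel coordinates).
#' @param prominence the prominence threshold that produced the set.
#' @param min_separation the minimum point separation in pixels.
#' @return Object of class \code{maxima_set} (a data frame).
#' @export
maxima_set <- function(points, prominence = NA_real_, min_separation = NA_real_) {
  points <- as.data.frame(points)
  if (nrow(points) && !all(c("x", "y", "intensity") %in% names(points)))
    stop("points must have columns x, y, intensity")
  if (!nrow(points))
    points <- data.frame(x = numeric(0), y = numeric(0), intensity = numeric(0))
  structure(points[c("x", "y", "intensity")],
            prominence = prominence, min_separation = min_separation,
            class = c("maxima_set", "data.frame"))
}

#' Find prominent local maxima
#'
#' Detects all strict local maxima of the raster that stand out from their
#' surroundings by at least \code{prominence}: a candidate peak is rejected
#' when a path to strictly higher ground exists that never descends more than
#' \code{prominence} below the peak (the peak-minus-highest-connecting-saddle
#' noise-tolerance definition); the global maximum is measured against the
#' image minimum.  Accepted peaks are at least \code{min_separation} pixels
#' apart (ties resolved in favour of the higher peak, then by (y, x) order)
#' and are refined to sub-pixel position by a 3-point parabolic fit.
#' Typically run on the blurred image; densities are then measured on the
#' original raster at these positions.
#'
#' @param image a \code{membrane_image} (blur first; see [gaussian_blur()]).
#' @param prominence minimum peak prominence in intensity units; default 10%
#'   of the image dynamic range.
#' @param min_separation minimum Euclidean distance between reported maxima,
#'   in pixels (default 5; use pitch/2 when a layout is at hand).
#' @param refine logical; sub-pixel refinement of peak coordinates.
#' @return A [maxima_set()] sorted by descending peak intensity.
#' @export
find_local_maxima <- function(image, prominence = NULL, min_separation = 5,
                              refine = TRUE) {
  stopifnot(inherits(image, "membrane_image"))
  px <- image$pixels
  h <- nrow(px); w <- ncol(px)
  if (is.null(prominence)) prominence <- 0.1 * diff(range(px))
  if (prominence < 0) stop("prominence must be >= 0")
  if (min_separation <= 0) stop("min_separation must be > 0")
  glob_min <- min(px)
  if (max(px) == glob_min)  # no contrast: no maxima
    return(maxima_set(NULL, prominence, min_separation))

  # window max/min via separable shifted-pmax/pmin passes (Chebyshev radius)
  rr <- max(1L, ceiling(min_separation))
  shift_rows <- function(m, off, fill) {
    if (off > 0) rbind(matrix(fill, off, ncol(m)), m[seq_len(nrow(m) - off), , drop = FALSE])
    else if (off < 0) rbind(m[(1 - off):nrow(m), , drop = FALSE], matrix(fill, -off, ncol(m)))
    else m
  }
  run_extreme <- function(m, f, fill) {
    w <- m
    for (off in seq_len(rr))
      w <- f(w, shift_rows(m, off, fill), shift_rows(m, -off, fill))
    w
  }
  winmax <- t(run_extreme(t(run_extreme(px, pmax, -Inf)), pmax, -Inf))
  winmin <- t(run_extreme(t(run_extreme(px, pmin, Inf)), pmin, Inf))

  # candidates: at the top of a non-flat window; small plateaus (such as
  # spots centered exactly between pixels, or saturated spot tops) keep all
  # their pixels as candidates here and are reduced to one representative by
  # the min-separation sweep below
  cand <- which(px == winmax & winmax > winmin)
  if (!length(cand))
    return(maxima_set(NULL, prominence, min_separation))

  ci <- (cand - 1) %% h + 1      # matrix row (y + 1)
  cj <- (cand - 1) %/% h + 1     # matrix col (x + 1)
  val <- px[cand]
  ord <- order(-val, ci, cj)
  ci <- ci[ord]; cj <- cj[ord]; val <- val[ord]; cand <- cand[ord]

  # cheap sea-level cull: a peak can never be more prominent than its height
  # above the image minimum
  keepable <- (val - glob_min) >= prominence
  ci <- ci[keepable]; cj <- cj[keepable]; val <- val[keepable]
  cand <- cand[keepable]

  acc_i <- integer(0); acc_j <- integer(0); acc_v <- numeric(0)
  stamp <- integer(h * w)  # flood bookkeeping, one shared array
  queue <- integer(4096)
  for (s in seq_along(cand)) {
    peak <- val[s]
    if (length(acc_i)) {
      d2 <- (acc_i - ci[s])^2 + (acc_j - cj[s])^2
      if (any(d2 < min_separation^2)) next
    }
    thr <- peak - prominence
    # flood the connected region above thr; reject on reaching higher ground
    ok <- TRUE
    qh <- 1L; qt <- 1L
    queue[1L] <- cand[s]
    stamp[cand[s]] <- s
    while (qh <= qt) {
      p <- queue[qh]; qh <- qh + 1L
      pi <- (p - 1L) %% h + 1L
      pj <- (p - 1L) %/% h + 1L
      nbr <- c(if (pi > 1L) p - 1L, if (pi < h) p + 1L,
               if (pj > 1L) p - h, if (pj < w) p + h)
      for (q in nbr) {
        if (stamp[q] == s) next
        vq <- px[q]
        if (vq > peak) { ok <- FALSE; break }
        if (vq > thr) {
          stamp[q] <- s
          qt <- qt + 1L
          if (qt > length(queue)) queue <- c(queue, integer(length(queue)))
          queue[qt] <- q
        }
      }
      if (!ok) break
    }
    if (ok) {
      acc_i <- c(acc_i, ci[s]); acc_j <- c(acc_j, cj[s]); acc_v <- c(acc_v, peak)
    }
  }
  if (!length(acc_i))
    return(maxima_set(NULL, prominence, min_separation))

  x <- acc_j - 1; y <- acc_i - 1
  if (refine) {
    refine1 <- function(lo, mid, hi) {
      den <- lo - 2 * mid + hi
      if (den < 0) return(max(-0.5, min(0.5, 0.5 * (lo - hi) / den)))
      if (hi == mid && lo < mid) return(0.5)   # 2-wide plateau to the right
      if (lo == mid && hi < mid) return(-0.5)  # 2-wide plateau to the left
      0
    }
    for (m in seq_along(acc_i)) {
      i <- acc_i[m]; j <- acc_j[m]
      if (j > 1 && j < w)
        x[m] <- x[m] + refine1(px[i, j - 1], px[i, j], px[i, j + 1])
      if (i > 1 && i < h)
        y[m] <- y[m] + refine1(px[i - 1, j], px[i, j], px[i + 1, j])
    }
  }
  maxima_set(data.frame(x = x, y = y, intensity = acc_v),
             prominence, min_separation)
}

#' Write / read a maxima CSV
#'
#' Lossless round trip of detected maxima as CSV with header columns
#' \code{x}, \code{y}, \code{intensity} (coordinates kept to full precision).
#'
#' @param maxima a \code{maxima_set}.
#' @param path CSV path.
#' @return Invisibly, \code{path}.
#' @export
write_maxima_csv <- function(maxima, path) {
  stopifnot(inherits(maxima, "maxima_set"))
  df <- as.data.frame(maxima)
  df$x <- format(df$x, digits = 15, trim = TRUE, scientific = FALSE)
  df$y <- format(df$y, digits = 15, trim = TRUE, scientific = FALSE)
  df$intensity <- format(df$intensity, digits = 15, trim = TRUE, scientific = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_maxima_csv
#' @param image optional \code{membrane_image}; when supplied, coordinates are
#'   validated against its bounds.
#' @export
read_maxima_csv <- function(path, image = NULL) {
  if (!file.exists(path)) stop("maxima file not found: ", path)
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop("cannot parse maxima CSV '", path,
                                          "': ", conditionMessage(e)))
  need <- c("x", "y", "intensity")
  if (!all(need %in% names(df)))
    stop("maxima CSV must have header columns x, y, intensity (", path, ")")
  for (cc in need) {
    df[[cc]] <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(!is.finite(df[[cc]]))
    if (length(bad))
      stop(sprintf("maxima CSV '%s': non-numeric %s at data line %d",
                   path, cc, bad[1]))
  }
  if (!is.null(image)) {
    oob <- df$x < 0 | df$x > image$width - 1 | df$y < 0 | df$y > image$height - 1
    if (any(oob))
      stop(sprintf("maxima CSV '%s': point (%g, %g) outside %dx%d image bounds",
                   path, df$x[which(oob)[1]], df$y[which(oob)[1]],
                   image$width, image$height))
  }
  maxima_set(df)
}
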