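#' Detect the four grid corners among maxima
#'
#' Membrane arrays carry bright reference spots in the corner positions of
#' the printed grid; this picks, for each image quadrant, the
#' maximum-intensity point among the \code{k} detected maxima nearest that
#' image corner (ties resolved in favour of the point nearest the corner).
#' Corner assignment (TL/TR/BL/BR) follows the image coordinate convention
#' (x right, y down).
#'
#' @param maxima a [maxima_set()].
#' @param image_shape integer vector \code{c(height, width)} of the image the
#'   maxima came from.
#' @param k how many nearest-to-corner maxima to consider per quadrant.
#' @return Named list \code{tl}, \code{tr}, \code{bl}, \code{br}, each a
#'   numeric \code{c(x, y)}.
#' @export
detect_corners <- function(maxima, image_shape, k = 3) {
  stopifnot(inherits(maxima, "maxima_set"), length(image_shape) == 2)
  h <- image_shape[1]; w <- image_shape[2]
  pts <- as.data.frame(maxima)
  if (nrow(pts) < 1) stop("corner detection needs at least one maximum")
  corners <- list(tl = c(0, 0), tr = c(w - 1, 0),
                  bl = c(0, h - 1), br = c(w - 1, h - 1))
  quads <- list(tl = pts$x < w / 2 & pts$y < h / 2,
                tr = pts$x >= w / 2 & pts$y < h / 2,
                bl = pts$x < w / 2 & pts$y >= h / 2,
                br = pts$x >= w / 2 & pts$y >= h / 2)
  out <- list()
  for (nm in names(corners)) {
    sel <- pts[quads[[nm]], , drop = FALSE]
    if (!nrow(sel))
      stop("no maximum in quadrant ", toupper(nm))
    cc <- corners[[nm]]
    d <- sqrt((sel$x - cc[1])^2 + (sel$y - cc[2])^2)
    near <- order(d)[seq_len(min(k, nrow(sel)))]
    sel <- sel[near, , drop = FALSE]
    d <- d[near]
    best <- which(sel$intensity == max(sel$intensity))
    if (length(best) > 1) best <- best[which.min(d[best])]
    out[[nm]] <- c(x = sel$x[best], y = sel$y[best])
  }
  out
}

# fractional (u, v) grid coordinates for all layout positions, in pitch
# units: spots within a block sit one unit apart, and the step between the
# last column of one block and the first of the next is (1 + alley) units
# (alley is the extra gap on top of the regular pitch)
.grid_uv <- function(layout) {
  pos <- layout$positions
  cu <- pos$block_col * (layout$cols_per_block + layout$alley_col) + pos$col
  tu <- layout$n_block_cols * layout$cols_per_block - 1 +
    (layout$n_block_cols - 1) * layout$alley_col
  rv <- pos$block_row * (layout$rows_per_block + layout$alley_row) + pos$row
  tv <- layout$n_block_rows * layout$rows_per_block - 1 +
    (layout$n_block_rows - 1) * layout$alley_row
  list(u = if (tu > 0) cu / tu else rep(0, nrow(pos)),
       v = if (tv > 0) rv / tv else rep(0, nrow(pos)),
       total_u = tu, total_v = tv)
}

#' Interpolate the full spot grid between four corners
#'
#' Bilinear interpolation of the corner anchor points at the fractional grid
#' coordinates of every layout position.  The fractional column coordinate is
#' \code{u = (block_col * (cols_per_block + alley_col) + col) /
#' total_col_units} with \code{total_col_units = n_block_cols *
#' cols_per_block - 1 + (n_block_cols - 1) * alley_col}, and symmetrically
#' for rows: spots within a block sit one pitch unit apart, the step across
#' a block boundary is \code{1 + alley} units (the alley is the extra gap on
#' top of the regular pitch), and the four corner anchors map exactly onto
#' the four extreme positions.
#'
#' @param corners named list \code{tl}, \code{tr}, \code{bl}, \code{br} of
#'   \code{c(x, y)} anchor points (a convex quadrilateral).
#' @param layout an \code{array_layout}.
#' @return A \code{spot_grid}: data frame with one row per layout position
#'   (\code{block_row}, \code{block_col}, \code{row}, \code{col},
#'   \code{analyte}, \code{role}, \code{x}, \code{y}, \code{provenance}),
#'   all entries \code{provenance = "interpolated"}; the anchor points are
#'   kept in the \code{"corners"} attribute.
#' @export
interpolate_grid <- function(corners, layout) {
  stopifnot(all(c("tl", "tr", "bl", "br") %in% names(corners)))
  P <- do.call(rbind, lapply(corners[c("tl", "tr", "bl", "br")], as.numeric))
  if (any(!is.finite(P))) stop("corner coordinates must be finite")
  # degenerate geometry: quadrilateral area ~ 0 relative to its extent
  area2 <- abs((P[2, 1] - P[1, 1]) * (P[3, 2] - P[1, 2]) -
               (P[3, 1] - P[1, 1]) * (P[2, 2] - P[1, 2])) +
    abs((P[2, 1] - P[4, 1]) * (P[3, 2] - P[4, 2]) -
        (P[3, 1] - P[4, 1]) * (P[2, 2] - P[4, 2]))
  scale2 <- max(dist(P))^2
  if (scale2 == 0 || area2 < 1e-9 * scale2)
    stop("degenerate (collinear) corners: cannot interpolate a grid")
  uv <- .grid_uv(layout)
  u <- uv$u; v <- uv$v
  x <- (1 - u) * (1 - v) * P[1, 1] + u * (1 - v) * P[2, 1] +
    (1 - u) * v * P[3, 1] + u * v * P[4, 1]
  y <- (1 - u) * (1 - v) * P[1, 2] + u * (1 - v) * P[2, 2] +
    (1 - u) * v * P[3, 2] + u * v * P[4, 2]
  g <- layout$positions
  g$x <- x
  g$y <- y
  g$provenance <- "interpolated"
  structure(g, corners = corners, pitch = layout$pitch,
            class = c("spot_grid", "data.frame"))
}

#' Snap interpolated grid positions to detected maxima
#'
#' Moves each grid entry to the nearest detected maximum within
#' \code{snap_radius}; entries with no maximum in range keep their
#' interpolated coordinates.  Matching is one-to-one and greedy by ascending
#' distance, so two grid entries can never collapse onto the same bright
#' maximum; unresolved entries stay interpolated.  The operation is
#' idempotent.
#'
#' @param grid a \code{spot_grid} (from [interpolate_grid()]).
#' @param maxima a [maxima_set()] from the same image.
#' @param snap_radius maximum snap distance in pixels; defaults to 0.4 times
#'   the layout pitch recorded on the grid.
#' @return The grid with snapped entries marked \code{provenance = "snapped"}.
#' @export
snap_to_maxima <- function(grid, maxima, snap_radius = NULL) {
  stopifnot(inherits(grid, "spot_grid"), inherits(maxima, "maxima_set"))
  if (is.null(snap_radius)) {
    pitch <- attr(grid, "pitch")
    if (is.null(pitch)) stop("snap_radius not given and grid carries no pitch")
    snap_radius <- 0.4 * pitch
  }
  if (!is.numeric(snap_radius) || snap_radius <= 0)
    stop("snap_radius must be > 0")
  pts <- as.data.frame(maxima)
  grid$provenance <- "interpolated"
  if (!nrow(pts)) return(grid)
  dx <- outer(grid$x, pts$x, "-")
  dy <- outer(grid$y, pts$y, "-")
  d <- sqrt(dx^2 + dy^2)
  cand <- which(d <= snap_radius, arr.ind = TRUE)
  if (!nrow(cand)) return(grid)
  cand <- cand[order(d[cand]), , drop = FALSE]
  used_entry <- logical(nrow(grid))
  used_max <- logical(nrow(pts))
  for (i in seq_len(nrow(cand))) {
    e <- cand[i, 1]; m <- cand[i, 2]
    if (used_entry[e] || used_max[m]) next
    used_entry[e] <- TRUE
    used_max[m] <- TRUE
    grid$x[e] <- pts$x[m]
    grid$y[e] <- pts$y[m]
    grid$provenance[e] <- "snapped"
  }
  grid
}

#' Infer the spot grid of a membrane image
#'
#' Convenience wrapper chaining the semi-automatic grid pipeline: Gaussian
#' blur, prominent-maxima detection, quadrant corner detection, bilinear grid
#' interpolation with alleyways, and one-to-one snapping to maxima.
#'
#' @param image a \code{membrane_image} (original, un-blurred).
#' @param layout an \code{array_layout}.
#' @param blur_sigma preprocessing blur width in pixels.
#' @param prominence maxima prominence (noise tolerance); default 1% of the
#'   blurred dynamic range.  The dynamic range of a membrane is dominated by
#'   the brightest control/analyte spots, so a small fraction of it sits
#'   well above the blurred read noise while keeping dim spots detectable;
#'   spots dimmer than this fall back to interpolated grid positions.
#' @param min_separation minimum maxima separation; default \code{pitch / 2}.
#' @param snap_radius snap distance; default \code{0.4 * pitch}.
#' @return List with elements \code{grid} (a \code{spot_grid}),
#'   \code{maxima}, \code{corners} and \code{blurred}.
#' @export
fit_spot_grid <- function(image, layout, blur_sigma = 4, prominence = NULL,
                          min_separation = NULL, snap_radius = NULL) {
  if (is.null(min_separation)) min_separation <- layout$pitch / 2
  if (is.null(snap_radius)) snap_radius <- 0.4 * layout$pitch
  blurred <- gaussian_blur(image, blur_sigma)
  if (is.null(prominence)) prominence <- 0.01 * diff(range(blurred$pixels))
  maxima <- find_local_maxima(blurred, prominence = prominence,
                              min_separation = min_separation)
  corners <- detect_corners(maxima, c(image$height, image$width))
  grid <- interpolate_grid(corners, layout)
  grid <- snap_to_maxima(grid, maxima, snap_radius)
  list(grid = grid, maxima = maxima, corners = corners, blurred = blurred)
}

#' Write / read a spot grid as TSV
#'
#' Columns: \code{block_row}, \code{block_col}, \code{row}, \code{col},
#' \code{analyte}, \code{role}, \code{x}, \code{y}, \code{provenance}.
#'
#' @param grid a \code{spot_grid}.
#' @param path TSV path.
#' @return Invisibly, \code{path}.
#' @export
write_grid_tsv <- function(grid, path) {
  utils::write.table(as.data.frame(grid), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_grid_tsv
#' @export
read_grid_tsv <- function(path) {
  if (!file.exists(path)) stop("grid file not found: ", path)
  g <- utils::read.delim(path, stringsAsFactors = FALSE)
  structure(g, class = c("spot_grid", "data.frame"))
}
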