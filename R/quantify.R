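#' Integrated spot densities
#'
#' Measures, for every grid position, the integrated density: the sum of the
#' original (un-blurred) pixel intensities over all pixels whose center lies
#' within \code{spot_radius} of the spot coordinates.  Densities are measured
#' on the original image because blurring is used for localization only;
#' summing raw pixels conserves signal mass and makes the measurement
#' additive and homogeneous in the image.
#'
#' @param image the original \code{membrane_image}.
#' @param grid a \code{spot_grid}.
#' @param layout the \code{array_layout} (provides \code{spot_radius}).
#' @param sample optional named list of membrane annotations
#'   (\code{sample_id}, \code{series}, \code{gender}, \code{group}), attached
#'   to the table.
#' @return A \code{density_table}: one row per layout position with columns
#'   \code{density} (sum of intensities, \code{NA} when the aperture lies
#'   fully outside the image), \code{area} (pixels in the aperture) and
#'   \code{clipped} (aperture truncated by the image border).
#' @export
integrated_density <- function(image, grid, layout, sample = list()) {
  stopifnot(inherits(image, "membrane_image"), inherits(grid, "spot_grid"))
  r <- layout$spot_radius
  px <- image$pixels
  h <- image$height; w <- image$width
  n <- nrow(grid)
  density <- numeric(n); area <- integer(n); clipped <- logical(n)
  for (k in seq_len(n)) {
    cx <- grid$x[k]; cy <- grid$y[k]
    # pixel centers at 0-based integers; matrix indices are center + 1
    js <- max(0, ceiling(cx - r)):min(w - 1, floor(cx + r))
    is <- max(0, ceiling(cy - r)):min(h - 1, floor(cy + r))
    clipped[k] <- cx - r < 0 || cx + r > w - 1 || cy - r < 0 || cy + r > h - 1
    if (cx + r < 0 || cx - r > w - 1 || cy + r < 0 || cy - r > h - 1) {
      density[k] <- NA_real_; area[k] <- 0L; clipped[k] <- TRUE
      next
    }
    dx2 <- (js - cx)^2
    dy2 <- (is - cy)^2
    inside <- outer(dy2, dx2, "+") <= r^2
    if (!any(inside)) { density[k] <- NA_real_; area[k] <- 0L; next }
    patch <- px[is + 1, js + 1, drop = FALSE]
    density[k] <- sum(patch[inside])
    area[k] <- sum(inside)
  }
  out <- as.data.frame(grid)
  out$density <- density
  out$area <- area
  out$clipped <- clipped
  structure(out, sample = sample, spot_radius = r,
            class = c("density_table", "data.frame"))
}

#' Flag dropout spots as missing
#'
#' A printed spot can fail (no antibody deposited, membrane defect); its
#' aperture then measures bare background at a grid position that no maximum
#' supported.  This QC step marks an analyte duplicate density as missing
#' when three conditions coincide: the position kept its interpolated
#' coordinates (no local maximum was found within snap range), the measured
#' density lies at or below the membrane's background threshold (see
#' [background_spot_set()]), and at least one duplicate of the same analyte
#' lies above the threshold.  The last condition separates a failed spot
#' (inconsistent duplicate pair) from a genuinely dim analyte (consistently
#' low duplicates, which are kept: low expression is information, not a
#' defect).  Downstream, the surviving duplicate carries the analyte
#' (single-survivor rule).
#'
#' @param table a \code{density_table} from [integrated_density()].
#' @param background_fraction dynamic-range fraction of the background rule.
#' @param exclude_reference exclude reference anchors from the background
#'   rule.
#' @return The table with dropout densities set to \code{NA} and a logical
#'   \code{dropout} column.
#' @export
flag_dropouts <- function(table, background_fraction = 0.05,
                          exclude_reference = TRUE) {
  stopifnot(inherits(table, "density_table"))
  pool <- if (exclude_reference)
    table$density[table$role != "reference"] else table$density
  bg <- background_spot_set(pool, background_fraction)
  low <- table$role == "analyte" & table$provenance == "interpolated" &
    !is.na(table$density) & table$density <= bg$threshold
  # only a duplicate pair that disagrees about the background threshold
  # marks a failed spot; consistently dim duplicates are real measurements
  above <- !is.na(table$density) & table$density > bg$threshold &
    table$role == "analyte"
  has_bright_twin <- table$analyte %in% unique(table$analyte[above])
  drop <- low & has_bright_twin
  table$dropout <- drop
  table$density[drop] <- NA_real_
  attr(table, "background_threshold") <- bg$threshold
  table
}

#' Collapse duplicate spots into one analyte value
#'
#' Averages the duplicate spot densities of each analyte (arithmetic mean;
#' the arrays print n = 2 duplicates, where a median has no advantage) and
#' records the duplicate coefficient of variation as QC.  Reference and
#' negative spots are excluded from the analyte rows but summarized in the
#' \code{qc} attribute.  Analytes whose duplicates are all missing are an
#' error, reported by name.
#'
#' @param table a \code{density_table}.
#' @param method collapse method; only \code{"mean"} is provided.
#' @return A single-column [expression_matrix()] (scale \code{"raw"}) with a
#'   \code{qc} attribute (per-analyte duplicate count, missing count, CV) and
#'   reference/negative summaries.
#' @export
collapse_duplicates <- function(table, method = "mean") {
  stopifnot(inherits(table, "density_table"))
  method <- match.arg(method, "mean")
  an <- table[table$role == "analyte", , drop = FALSE]
  if (!nrow(an)) stop("density table contains no analyte positions")
  sp <- split(an$density, an$analyte)
  nm <- names(sp)
  n_total <- vapply(sp, length, 0L)
  n_missing <- vapply(sp, function(d) sum(is.na(d)), 0L)
  all_missing <- nm[n_missing == n_total]
  if (length(all_missing))
    stop("analytes with all duplicate densities missing: ",
         paste(all_missing, collapse = ", "))
  val <- vapply(sp, function(d) mean(d, na.rm = TRUE), 0)
  cv <- vapply(sp, function(d) {
    d <- d[!is.na(d)]
    if (length(d) < 2 || mean(d) == 0) NA_real_ else stats::sd(d) / mean(d)
  }, 0)
  sample <- attr(table, "sample")
  sid <- if (!is.null(sample$sample_id)) sample$sample_id else "sample1"
  qc <- data.frame(analyte = nm, n_duplicates = n_total,
                   n_missing = n_missing, duplicate_cv = cv,
                   single_survivor = n_missing > 0 & n_missing < n_total,
                   row.names = NULL)
  ctrl <- table[table$role %in% c("reference", "negative"), , drop = FALSE]
  em <- expression_matrix(matrix(val, ncol = 1, dimnames = list(nm, sid)),
                          samples = .sample_row(sid, sample), scale = "raw")
  attr(em, "qc") <- qc
  attr(em, "controls") <- ctrl[c("block_row", "block_col", "row", "col",
                                 "analyte", "role", "density")]
  em
}

.sample_row <- function(sid, sample, replicate = NA_integer_) {
  data.frame(sample_id = sid,
             series = if (is.null(sample$series)) NA else sample$series,
             gender = if (is.null(sample$gender)) NA_character_ else sample$gender,
             group = if (is.null(sample$group)) NA_character_ else sample$group,
             replicate = replicate, stringsAsFactors = FALSE)
}

#' Per-duplicate expression columns of one membrane
#'
#' Builds an analyte-by-duplicate matrix (one column per duplicate spot, in
#' layout order) for use as technical replicates in the moderated-t model.
#'
#' @param table a \code{density_table}.
#' @return An [expression_matrix()] with one column per duplicate index.
#' @export
duplicate_matrix <- function(table) {
  stopifnot(inherits(table, "density_table"))
  an <- table[table$role == "analyte", , drop = FALSE]
  if (!nrow(an)) stop("density table contains no analyte positions")
  sp <- split(an$density, an$analyte)
  ndup <- max(vapply(sp, length, 0L))
  vals <- t(vapply(sp, function(d) c(d, rep(NA_real_, ndup - length(d))),
                   numeric(ndup)))
  sample <- attr(table, "sample")
  sid <- if (!is.null(sample$sample_id)) sample$sample_id else "sample1"
  colnames(vals) <- paste0(sid, ".d", seq_len(ndup))
  samples <- do.call(rbind, lapply(seq_len(ndup), function(r)
    .sample_row(paste0(sid, ".d", r), sample, replicate = r)))
  expression_matrix(vals, samples = samples, scale = "raw")
}

#' Construct an expression matrix
#'
#' Analytes-by-samples container used downstream of quantification: a
#' numeric matrix with per-column sample annotations (\code{sample_id},
#' \code{series}, \code{gender}, \code{group}, \code{replicate}) and a scale
#' flag.
#'
#' @param values numeric matrix, analytes as rows (rownames required).
#' @param samples data frame with one row per column of \code{values}.
#' @param scale one of \code{"raw"}, \code{"normalized"}, \code{"log2"}.
#' @return Object of class \code{expression_matrix} with fields
#'   \code{values}, \code{samples}, \code{scale}.
#' @export
expression_matrix <- function(values, samples, scale = c("raw", "normalized", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix")
  if (is.null(rownames(values)))
    stop("values must have analyte rownames")
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (nrow(samples) != ncol(values))
    stop("samples must have one row per matrix column")
  if (scale != "log2" && any(values < 0, na.rm = TRUE))
    stop("raw/normalized expression values must be >= 0")
  if (scale == "log2" && any(!is.finite(values) & !is.na(values)))
    stop("log2 expression values must be finite")
  structure(list(values = values, samples = samples, scale = scale),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d analytes x %d columns (scale: %s)\n",
              nrow(x$values), ncol(x$values), x$scale))
  invisible(x)
}

#' Column-bind expression matrices
#'
#' @param matrices list of \code{expression_matrix} objects over the same
#'   analyte set (any order) and on the same scale.
#' @return One \code{expression_matrix}; column order follows the input
#'   order, rows follow the first matrix.
#' @export
assemble_matrix <- function(matrices) {
  stopifnot(length(matrices) >= 1,
            all(vapply(matrices, inherits, TRUE, "expression_matrix")))
  ref <- rownames(matrices[[1]]$values)
  for (m in matrices[-1]) {
    other <- rownames(m$values)
    if (!setequal(ref, other)) {
      d <- union(setdiff(ref, other), setdiff(other, ref))
      stop("analyte sets differ between matrices: ", paste(d, collapse = ", "))
    }
  }
  scales <- unique(vapply(matrices, `[[`, "", "scale"))
  if (length(scales) > 1)
    stop("matrices are on different scales: ", paste(scales, collapse = ", "))
  vals <- do.call(cbind, lapply(matrices, function(m) m$values[ref, , drop = FALSE]))
  samples <- do.call(rbind, lapply(matrices, `[[`, "samples"))
  rownames(samples) <- NULL
  expression_matrix(vals, samples, scale = scales)
}
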