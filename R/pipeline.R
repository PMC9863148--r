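#' Quantify one membrane image
#'
#' The full per-membrane image pipeline: Gaussian blur, prominent-maxima
#' detection, corner detection, bilinear grid interpolation with alleyways,
#' one-to-one snapping to maxima, and integrated densitometry on the
#' original raster.
#'
#' @inheritParams fit_spot_grid
#' @param sample membrane annotations (\code{sample_id}, \code{series},
#'   \code{gender}, \code{group}).
#' @return List with \code{table} (a \code{density_table}), \code{grid},
#'   \code{maxima} and \code{corners}.
#' @export
quantify_membrane <- function(image, layout, blur_sigma = 4, prominence = NULL,
                              min_separation = NULL, snap_radius = NULL,
                              sample = list()) {
  fit <- fit_spot_grid(image, layout, blur_sigma = blur_sigma,
                       prominence = prominence,
                       min_separation = min_separation,
                       snap_radius = snap_radius)
  table <- integrated_density(image, fit$grid, layout, sample = sample)
  list(table = table, grid = fit$grid, maxima = fit$maxima,
       corners = fit$corners)
}

#' Differential expression of one CKD-vs-control contrast
#'
#' Builds the duplicate-level matrix of the two membranes, normalizes the
#' columns jointly, computes background-based detection calls per membrane
#' on the raw densities, and applies the moderated-t composite criteria.
#'
#' @param ckd_table,control_table \code{density_table}s of the CKD and
#'   control membranes of one series/gender.
#' @param criteria a [de_criteria()].
#' @return A \code{de_result}; the normalized matrix is kept as attribute
#'   \code{matrix}.
#' @export
analyze_contrast <- function(ckd_table, control_table,
                             criteria = de_criteria()) {
  ckd_table <- flag_dropouts(ckd_table)
  control_table <- flag_dropouts(control_table)
  det_ckd <- detect_analytes(ckd_table, alpha = criteria$alpha_detect)
  det_ctl <- detect_analytes(control_table, alpha = criteria$alpha_detect)
  detection <- data.frame(analyte = det_ckd$analyte,
                          detect_p_ckd = det_ckd$p,
                          detect_p_control = det_ctl$p[match(det_ckd$analyte,
                                                             det_ctl$analyte)])
  mat <- assemble_matrix(list(duplicate_matrix(ckd_table),
                              duplicate_matrix(control_table)))
  norm <- robust_spline_normalize(mat)
  de <- call_differential(norm, detection, criteria)
  attr(de, "matrix") <- norm
  de
}

#' Analyze a full membrane study
#'
#' Quantifies every membrane, runs the CKD-vs-control contrast per series
#' and gender, and intersects the per-gender marker calls across series into
#' the cross-series consensus panels (plus the per-series gender-overlap
#' panels).
#'
#' @param membranes named list of \code{membrane_image}s (or of lists with
#'   an \code{image} element, as returned by [simulate_study()]).
#' @param manifest data frame with columns \code{membrane_id},
#'   \code{series}, \code{gender}, \code{group} linking names of
#'   \code{membranes} to arms.
#' @param layout the \code{array_layout}.
#' @param criteria a [de_criteria()].
#' @param ... passed to [quantify_membrane()].
#' @return List with \code{tables}, \code{de} (per series/gender),
#'   \code{calls}, \code{consensus} (per gender) and \code{overlap} (per
#'   series).
#' @export
analyze_study <- function(membranes, manifest, layout,
                          criteria = de_criteria(), ...) {
  tables <- list()
  for (id in manifest$membrane_id) {
    mm <- membranes[[id]]
    img <- if (inherits(mm, "membrane_image")) mm else mm$image
    row <- manifest[manifest$membrane_id == id, ]
    tables[[id]] <- quantify_membrane(
      img, layout, sample = list(sample_id = id, series = row$series,
                                 gender = row$gender, group = row$group),
      ...)$table
  }
  is_ckd <- grepl("ckd", manifest$group, ignore.case = TRUE)
  de <- list(); calls <- list()
  for (s in unique(manifest$series)) {
    for (g in unique(manifest$gender)) {
      ckd_id <- manifest$membrane_id[manifest$series == s &
                                       manifest$gender == g & is_ckd]
      ctl_id <- manifest$membrane_id[manifest$series == s &
                                       manifest$gender == g & !is_ckd]
      if (length(ckd_id) != 1 || length(ctl_id) != 1) next
      key <- sprintf("s%s_%s", s, g)
      de[[key]] <- analyze_contrast(tables[[ckd_id]], tables[[ctl_id]],
                                    criteria)
      calls[[key]] <- marker_calls(de[[key]], series = s, gender = g)
    }
  }
  series_ids <- sort(unique(manifest$series))
  consensus <- list()
  if (length(series_ids) >= 2) {
    for (g in unique(manifest$gender)) {
      k1 <- sprintf("s%s_%s", series_ids[1], g)
      k2 <- sprintf("s%s_%s", series_ids[2], g)
      if (!is.null(calls[[k1]]) && !is.null(calls[[k2]]))
        consensus[[g]] <- consensus_across_series(calls[[k1]], calls[[k2]])
    }
  }
  overlap <- list()
  genders <- unique(manifest$gender)
  if (length(genders) >= 2) {
    for (s in series_ids) {
      km <- sprintf("s%s_%s", s, genders[1])
      kf <- sprintf("s%s_%s", s, genders[2])
      if (!is.null(calls[[km]]) && !is.null(calls[[kf]]))
        overlap[[as.character(s)]] <- gender_overlap(calls[[km]], calls[[kf]])
    }
  }
  list(tables = tables, de = de, calls = calls, consensus = consensus,
       overlap = overlap)
}
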