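#' Marker calls from a differential-expression result
#'
#' Extracts the called (non-\code{ns}) analytes of one contrast as a marker
#' call set tagged with its experiment series and gender.
#'
#' @param de a \code{de_result} (or any data frame with \code{analyte} and
#'   \code{call}/\code{direction} columns).
#' @param series experiment series identifier (1, 2 or 3).
#' @param gender \code{"M"}, \code{"F"} or \code{"mean"}.
#' @return data frame of class \code{marker_calls}: \code{analyte},
#'   \code{direction}, \code{series}, \code{gender}.
#' @export
marker_calls <- function(de, series = NA, gender = NA_character_) {
  df <- as.data.frame(de)
  dir <- if (!is.null(df$direction)) df$direction else df$call
  keep <- dir %in% c("up", "down")
  out <- data.frame(analyte = df$analyte[keep], direction = dir[keep],
                    series = rep(series, sum(keep)),
                    gender = rep(gender, sum(keep)),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$analyte))
    stop("duplicated analyte in marker calls: ",
         paste(unique(out$analyte[duplicated(out$analyte)]), collapse = ", "))
  structure(out, class = c("marker_calls", "data.frame"))
}

.as_calls <- function(x) {
  df <- as.data.frame(x)
  if (!all(c("analyte", "direction") %in% names(df)))
    stop("marker calls need columns 'analyte' and 'direction'")
  df
}

.consensus <- function(a, b, panel_type, names_ab) {
  a <- .as_calls(a); b <- .as_calls(b)
  shared <- intersect(a$analyte, b$analyte)
  dir_a <- a$direction[match(shared, a$analyte)]
  dir_b <- b$direction[match(shared, b$analyte)]
  same <- dir_a == dir_b
  members <- data.frame(analyte = shared[same], direction = dir_a[same],
                        stringsAsFactors = FALSE)
  members <- members[order(members$analyte), , drop = FALSE]
  rownames(members) <- NULL
  discordant <- data.frame(analyte = shared[!same],
                           direction_1 = dir_a[!same],
                           direction_2 = dir_b[!same],
                           stringsAsFactors = FALSE)
  names(discordant)[2:3] <- paste0("direction_", names_ab)
  discordant <- discordant[order(discordant$analyte), , drop = FALSE]
  rownames(discordant) <- NULL
  only_a <- a[!a$analyte %in% shared, c("analyte", "direction"), drop = FALSE]
  only_b <- b[!b$analyte %in% shared, c("analyte", "direction"), drop = FALSE]
  rownames(only_a) <- rownames(only_b) <- NULL
  specific <- stats::setNames(list(only_a, only_b), names_ab)
  structure(list(panel_type = panel_type, members = members,
                 discordant = discordant, specific = specific,
                 provenance = stats::setNames(list(a, b), names_ab)),
            class = "consensus_panel")
}

#' Cross-series consensus panel
#'
#' Robust marker panel across two independent experiment series: the members
#' are the analytes called in both series with the same direction.  Analytes
#' called in opposite directions are excluded from the panel and reported in
#' the \code{discordant} slot (such series-to-series reversals are a real
#' feature of pooled-membrane data and must not be dropped silently).
#'
#' @param calls_s1,calls_s2 marker call sets (see [marker_calls()]) of the
#'   two series, same gender.
#' @return Object of class \code{consensus_panel} with slots \code{members}
#'   (analyte, direction), \code{discordant}, \code{specific} (calls unique
#'   to one series) and \code{provenance}.  Empty inputs give an empty panel.
#' @export
consensus_across_series <- function(calls_s1, calls_s2) {
  .consensus(calls_s1, calls_s2, "cross_series", c("series1", "series2"))
}

#' Gender-overlap consensus panel
#'
#' Markers called in the same direction in both the male and the female
#' contrast of one series; the remainder is reported per gender in the
#' \code{specific} slot, and direction conflicts in \code{discordant}.
#'
#' @param calls_male,calls_female marker call sets of the two genders, same
#'   series.
#' @return A \code{consensus_panel} (\code{panel_type = "gender_overlap"}).
#' @export
gender_overlap <- function(calls_male, calls_female) {
  .consensus(calls_male, calls_female, "gender_overlap", c("male", "female"))
}

#' @export
print.consensus_panel <- function(x, ...) {
  cat(sprintf("consensus_panel (%s): %d members", x$panel_type, nrow(x$members)))
  if (nrow(x$members)) {
    up <- x$members$analyte[x$members$direction == "up"]
    dn <- x$members$analyte[x$members$direction == "down"]
    if (length(up)) cat("\n  up:  ", paste(up, collapse = ", "))
    if (length(dn)) cat("\n  down:", paste(dn, collapse = ", "))
  }
  if (nrow(x$discordant))
    cat("\n  discordant:", paste(x$discordant$analyte, collapse = ", "))
  cat("\n")
  invisible(x)
}

#' Gender-independent calls from averaged male/female values
#'
#' Re-runs the differential-expression calling with the CKD condition taken
#' as the per-duplicate mean of the male and female CKD values (averaging
#' normalized densities before the ratio computation), against the series'
#' control columns.
#'
#' @param x normalized linear-scale [expression_matrix()] of one series
#'   containing CKD columns for both genders and control column(s); sample
#'   annotations \code{group} and \code{gender} are required.
#' @param detection data frame with columns \code{analyte},
#'   \code{detect_p_ckd_m}, \code{detect_p_ckd_f}, \code{detect_p_control};
#'   the mean-CKD detection p is taken as the smaller of the two gender
#'   p-values (present in the mean when present in either gender).
#' @param criteria a [de_criteria()].
#' @param series series tag for the returned calls.
#' @return List with \code{de} (the \code{de_result} of the averaged
#'   contrast) and \code{calls} ([marker_calls()] tagged
#'   \code{gender = "mean"}).
#' @export
mean_gender_calls <- function(x, detection, criteria = de_criteria(),
                              series = NA) {
  stopifnot(inherits(x, "expression_matrix"))
  s <- x$samples
  is_ckd <- grepl("ckd", s$group, ignore.case = TRUE)
  m_cols <- which(is_ckd & s$gender == "M")
  f_cols <- which(is_ckd & s$gender == "F")
  c_cols <- which(!is_ckd)
  if (!length(m_cols) || !length(f_cols))
    stop("matrix must contain CKD columns for both genders")
  if (!length(c_cols)) stop("matrix must contain control columns")
  if (length(m_cols) != length(f_cols))
    stop("male and female CKD duplicate structures differ")
  mean_vals <- (x$values[, m_cols, drop = FALSE] +
                  x$values[, f_cols, drop = FALSE]) / 2
  colnames(mean_vals) <- paste0("CKD_mean.d", seq_along(m_cols))
  vals <- cbind(mean_vals, x$values[, c_cols, drop = FALSE])
  groups <- c(rep("CKD", length(m_cols)), rep("control", length(c_cols)))
  det <- as.data.frame(detection)
  need <- c("analyte", "detect_p_ckd_m", "detect_p_ckd_f", "detect_p_control")
  if (!all(need %in% names(det)))
    stop("detection must have columns ", paste(need, collapse = ", "))
  det2 <- data.frame(analyte = det$analyte,
                     detect_p_ckd = pmin(det$detect_p_ckd_m, det$detect_p_ckd_f),
                     detect_p_control = det$detect_p_control)
  de <- call_differential(vals, det2, criteria, groups = groups)
  list(de = de, calls = marker_calls(de, series = series, gender = "mean"))
}

#' Sample dendrogram with Pearson-correlation distance
#'
#' Agglomerative clustering of the matrix columns with distance
#' \code{1 - Pearson r} and complete linkage; merge heights are the
#' complete-linkage distances at each merge.
#'
#' @param x an [expression_matrix()] or numeric matrix (>= 2 columns, each
#'   with positive variance).
#' @return Object of class \code{correlation_dendrogram}: \code{merge},
#'   \code{height}, \code{order}, \code{labels} and the underlying
#'   \code{hclust}.
#' @export
correlation_dendrogram <- function(x) {
  m <- if (inherits(x, "expression_matrix")) x$values else as.matrix(x)
  if (ncol(m) < 2) stop("need at least 2 samples to cluster")
  if (is.null(colnames(m))) colnames(m) <- paste0("S", seq_len(ncol(m)))
  vs <- apply(m, 2, stats::var)
  if (any(vs == 0))
    stop("zero-variance sample(s): ",
         paste(colnames(m)[vs == 0], collapse = ", "))
  d <- stats::as.dist(1 - stats::cor(m))
  hc <- stats::hclust(d, method = "complete")
  structure(list(merge = hc$merge, height = hc$height, order = hc$order,
                 labels = hc$labels, hclust = hc),
            class = "correlation_dendrogram")
}

#' @export
print.correlation_dendrogram <- function(x, ...) {
  cat(sprintf("correlation_dendrogram: %d samples, %d merges (complete linkage, 1 - Pearson r)\n",
              length(x$labels), length(x$height)))
  invisible(x)
}

#' Newick serialization of a dendrogram
#'
#' @param dend a \code{correlation_dendrogram}.
#' @param path optional file to write to.
#' @return The Newick string (invisibly when written to a file).
#' @export
write_newick <- function(dend, path = NULL) {
  stopifnot(inherits(dend, "correlation_dendrogram"))
  if (!requireNamespace("ape", quietly = TRUE))
    stop("Newick export requires the 'ape' package")
  tr <- ape::as.phylo(dend$hclust)
  nwk <- ape::write.tree(tr)
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}

#' Export the called-marker matrix in dendrogram order
#'
#' Restricts the matrix to the called markers, orders rows by the leaf order
#' of a correlation dendrogram over the marker rows (columns by the sample
#' dendrogram), and optionally writes the ordered numeric matrix plus
#' row/column order sidecar files.  This is the table behind a marker
#' heatmap; plotting itself is left to the caller.
#'
#' @param x an [expression_matrix()] or numeric matrix.
#' @param calls marker calls ([marker_calls()] or a \code{de_result}).
#' @param file optional path prefix; writes \code{<file>.csv},
#'   \code{<file>_rows.txt}, \code{<file>_cols.txt}.
#' @return List with \code{matrix} (ordered), \code{row_order},
#'   \code{col_order}; empty (with a warning) when no markers are called.
#' @export
export_heatmap_table <- function(x, calls, file = NULL) {
  m <- if (inherits(x, "expression_matrix")) x$values else as.matrix(x)
  calls_df <- tryCatch(.as_calls(calls), error = function(e) {
    df <- as.data.frame(calls)
    data.frame(analyte = df$analyte[df$call %in% c("up", "down")],
               direction = df$call[df$call %in% c("up", "down")])
  })
  markers <- intersect(rownames(m), calls_df$analyte)
  if (!length(markers)) {
    warning("no called markers: empty export")
    return(list(matrix = m[integer(0), , drop = FALSE],
                row_order = character(0), col_order = colnames(m)))
  }
  sub <- m[markers, , drop = FALSE]
  row_order <- if (length(markers) >= 3 &&
                   all(apply(sub, 1, stats::var) > 0)) {
    markers[correlation_dendrogram(t(sub))$order]
  } else markers
  col_order <- if (ncol(sub) >= 3 && all(apply(sub, 2, stats::var) > 0)) {
    colnames(sub)[correlation_dendrogram(sub)$order]
  } else colnames(sub)
  out <- sub[row_order, col_order, drop = FALSE]
  if (!is.null(file)) {
    utils::write.csv(out, paste0(file, ".csv"), quote = FALSE)
    writeLines(row_order, paste0(file, "_rows.txt"))
    writeLines(col_order, paste0(file, "_cols.txt"))
  }
  list(matrix = out, row_order = row_order, col_order = col_order)
}

#' Read a digitized marker table
#'
#' Reads a wide TSV of published marker calls: a \code{cytokine} column plus
#' one column per contrast holding \code{up}, \code{down} or empty.  The
#' bundled fixtures (in \code{system.file("extdata", package = "blotgrid")})
#' digitize the study's summary tables: \code{markers_male_series12.tsv},
#' \code{markers_female_series12.tsv} (kidney-array series 1 and 2 per
#' gender) and \code{markers_series3.tsv} (XL-array series 3: mean, male,
#' female columns).
#'
#' @param path TSV path.
#' @return data frame, first column \code{cytokine}.
#' @export
load_marker_table <- function(path) {
  if (!file.exists(path)) stop("marker table not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "")
  if (names(tab)[1] != "cytokine") stop("first column must be 'cytokine'")
  for (j in seq_along(tab)[-1]) {
    bad <- !is.na(tab[[j]]) & !tab[[j]] %in% c("up", "down")
    if (any(bad))
      stop("invalid direction '", tab[[j]][bad][1], "' in ", path)
  }
  tab
}

#' Marker calls from one column of a digitized table
#'
#' @param tab wide table from [load_marker_table()].
#' @param column column name holding the directions.
#' @param series,gender tags for the returned calls.
#' @return A [marker_calls()] data frame.
#' @export
table_calls <- function(tab, column, series = NA, gender = NA_character_) {
  if (!column %in% names(tab)) stop("no column '", column, "' in table")
  keep <- !is.na(tab[[column]])
  marker_calls(data.frame(analyte = tab$cytokine[keep],
                          direction = tab[[column]][keep]),
               series = series, gender = gender)
}
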