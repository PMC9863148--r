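#' Construct a membrane-array layout
#'
#' An \code{array_layout} describes the geometry and annotation of one
#' membrane design: a lattice of spot blocks separated by alleyways, the
#' spot-to-spot pitch, the quantification aperture, and the role of every
#' position (analyte spot printed in duplicate, constant-intensity reference
#' spot, negative control, or empty).
#'
#' Indices are 0-based throughout: \code{block_row}/\code{block_col} index the
#' block lattice, \code{row}/\code{col} index spots within a block.  Pixel
#' coordinates elsewhere in the package are real-valued \code{(x right,
#' y down)} with the origin at the image top-left.
#'
#' @param name text identifier for the layout.
#' @param n_block_rows,n_block_cols number of blocks in each direction.
#' @param rows_per_block,cols_per_block spots per block in each direction.
#' @param pitch spot-to-spot distance in pixels.
#' @param alley_row,alley_col extra gap between adjacent blocks, in pitch
#'   units (0 means blocks abut at regular pitch).
#' @param spot_radius quantification aperture radius in pixels; must be
#'   smaller than half the pitch.
#' @param positions data frame with columns \code{block_row}, \code{block_col},
#'   \code{row}, \code{col}, \code{analyte}, \code{role}; \code{role} is one of
#'   \code{"analyte"}, \code{"reference"}, \code{"negative"}, \code{"empty"}.
#' @param n_duplicates expected number of duplicate positions per analyte
#'   (membrane arrays print each capture antibody as a duplicate pair, so the
#'   default is 2); use \code{NA} to allow a variable count.
#' @return An object of class \code{array_layout}.
#' @seealso [validate_layout()], [load_layout()], [default_layout()]
#' @export
array_layout <- function(name, n_block_rows, n_block_cols, rows_per_block,
                         cols_per_block, pitch, alley_row = 0, alley_col = 0,
                         spot_radius = pitch / 4, positions, n_duplicates = 2) {
  positions <- as.data.frame(positions, stringsAsFactors = FALSE)
  needed <- c("block_row", "block_col", "row", "col", "analyte", "role")
  miss <- setdiff(needed, names(positions))
  if (length(miss))
    stop("positions is missing columns: ", paste(miss, collapse = ", "))
  positions <- positions[needed]
  for (cc in c("block_row", "block_col", "row", "col"))
    positions[[cc]] <- as.integer(positions[[cc]])
  positions$analyte <- as.character(positions$analyte)
  positions$role <- as.character(positions$role)
  layout <- structure(list(
    name = as.character(name),
    n_block_rows = as.integer(n_block_rows),
    n_block_cols = as.integer(n_block_cols),
    rows_per_block = as.integer(rows_per_block),
    cols_per_block = as.integer(cols_per_block),
    pitch = as.numeric(pitch),
    alley_row = as.numeric(alley_row),
    alley_col = as.numeric(alley_col),
    spot_radius = as.numeric(spot_radius),
    n_duplicates = if (is.na(n_duplicates)) NA_integer_ else as.integer(n_duplicates),
    positions = positions
  ), class = "array_layout")
  viol <- validate_layout(layout)
  if (length(viol))
    stop("invalid array layout:\n  ", paste(viol, collapse = "\n  "))
  layout
}

#' Validate an array layout
#'
#' Pure check of the \code{array_layout} invariants; returns a character
#' vector of human-readable violations (empty when the layout is valid).
#' Checked: positive dimensions and pitch, non-negative alleys,
#' \code{spot_radius < pitch/2}, position indices within the declared block
#' dimensions, uniqueness of \code{(block_row, block_col, row, col)}, known
#' roles, at least one analyte position, non-empty analyte names, and (when
#' \code{n_duplicates} is declared) the duplicate count of every analyte.
#'
#' @param layout an \code{array_layout} (or a list with the same fields).
#' @return Character vector of violation descriptions; \code{character(0)}
#'   when all invariants hold.
#' @export
validate_layout <- function(layout) {
  v <- character(0)
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  for (f in c("n_block_rows", "n_block_cols", "rows_per_block", "cols_per_block"))
    if (!num1(layout[[f]]) || layout[[f]] < 1)
      v <- c(v, sprintf("%s must be a positive integer", f))
  if (!num1(layout$pitch) || layout$pitch <= 0)
    v <- c(v, "pitch must be a positive real")
  for (f in c("alley_row", "alley_col"))
    if (!num1(layout[[f]]) || layout[[f]] < 0)
      v <- c(v, sprintf("%s must be non-negative", f))
  if (!num1(layout$spot_radius) || layout$spot_radius <= 0)
    v <- c(v, "spot_radius must be a positive real")
  else if (num1(layout$pitch) && layout$pitch > 0 &&
           layout$spot_radius >= layout$pitch / 2)
    v <- c(v, "spot_radius must be < pitch/2")

  pos <- layout$positions
  if (is.null(pos) || nrow(pos) == 0) {
    v <- c(v, "positions must contain at least one spot")
    return(v)
  }
  bad_role <- !pos$role %in% c("analyte", "reference", "negative", "empty")
  if (any(bad_role))
    v <- c(v, sprintf("unknown role '%s' at position (%d,%d,%d,%d)",
                      pos$role[bad_role], pos$block_row[bad_role],
                      pos$block_col[bad_role], pos$row[bad_role],
                      pos$col[bad_role]))
  oob <- pos$block_row < 0 | pos$block_row >= layout$n_block_rows |
    pos$block_col < 0 | pos$block_col >= layout$n_block_cols |
    pos$row < 0 | pos$row >= layout$rows_per_block |
    pos$col < 0 | pos$col >= layout$cols_per_block
  if (any(oob))
    v <- c(v, sprintf("position (%d,%d,%d,%d) outside declared block dimensions",
                      pos$block_row[oob], pos$block_col[oob], pos$row[oob],
                      pos$col[oob]))
  key <- paste(pos$block_row, pos$block_col, pos$row, pos$col)
  dup <- duplicated(key)
  if (any(dup))
    v <- c(v, sprintf("duplicated position index (%s)",
                      gsub(" ", ",", key[dup])))
  is_an <- pos$role == "analyte"
  if (!any(is_an))
    v <- c(v, "layout declares no analyte positions")
  if (any(is_an & (is.na(pos$analyte) | pos$analyte == "")))
    v <- c(v, "analyte positions must carry a non-empty analyte name")
  if (!is.na(layout$n_duplicates) && any(is_an)) {
    cnt <- table(pos$analyte[is_an])
    off <- cnt != layout$n_duplicates
    if (any(off))
      v <- c(v, sprintf("analyte %s has %d positions but duplicates are declared as %d",
                        names(cnt)[off], as.integer(cnt[off]),
                        layout$n_duplicates))
  }
  v
}

#' Duplicate groups of a layout
#'
#' @param layout an \code{array_layout}.
#' @return Named list mapping each analyte name to the data frame of its
#'   duplicate positions.
#' @export
duplicate_groups <- function(layout) {
  pos <- layout$positions
  an <- pos[pos$role == "analyte", , drop = FALSE]
  split(an, an$analyte)
}

#' @export
print.array_layout <- function(x, ...) {
  cat(sprintf("array_layout '%s': %dx%d blocks of %dx%d spots, pitch %.3g px\n",
              x$name, x$n_block_rows, x$n_block_cols, x$rows_per_block,
              x$cols_per_block, x$pitch))
  cat(sprintf("  alleys (row, col) = (%.3g, %.3g) pitch units; aperture radius %.3g px\n",
              x$alley_row, x$alley_col, x$spot_radius))
  tab <- table(x$positions$role)
  cat("  positions:", nrow(x$positions),
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Read an array layout from disk
#'
#' The layout file dialect is a JSON file holding the geometry scalars
#' (\code{name}, \code{n_block_rows}, \code{n_block_cols},
#' \code{rows_per_block}, \code{cols_per_block}, \code{pitch},
#' \code{alley_row}, \code{alley_col}, \code{spot_radius},
#' \code{n_duplicates}) plus either an inline \code{positions} table or a
#' \code{positions_tsv} entry naming a sibling tab-separated file with columns
#' \code{block_row}, \code{block_col}, \code{row}, \code{col}, \code{analyte},
#' \code{role}.
#'
#' @param path path to the layout JSON file.
#' @return A validated \code{array_layout}.
#' @export
load_layout <- function(path) {
  if (!file.exists(path)) stop("layout file not found: ", path)
  geo <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("cannot parse layout JSON '", path,
                                           "': ", conditionMessage(e)))
  for (f in c("name", "n_block_rows", "n_block_cols", "rows_per_block",
              "cols_per_block", "pitch"))
    if (is.null(geo[[f]]))
      stop("layout JSON '", path, "' is missing required field '", f, "'")
  if (!is.null(geo[["positions"]])) {
    pos <- as.data.frame(geo[["positions"]], stringsAsFactors = FALSE)
  } else if (!is.null(geo[["positions_tsv"]])) {
    tsv <- file.path(dirname(path), geo[["positions_tsv"]])
    if (!file.exists(tsv)) stop("layout positions file not found: ", tsv)
    pos <- utils::read.delim(tsv, stringsAsFactors = FALSE)
  } else {
    stop("layout JSON '", path,
         "' must contain either 'positions' or 'positions_tsv'")
  }
  array_layout(
    name = geo$name,
    n_block_rows = geo$n_block_rows, n_block_cols = geo$n_block_cols,
    rows_per_block = geo$rows_per_block, cols_per_block = geo$cols_per_block,
    pitch = geo$pitch,
    alley_row = if (is.null(geo$alley_row)) 0 else geo$alley_row,
    alley_col = if (is.null(geo$alley_col)) 0 else geo$alley_col,
    spot_radius = if (is.null(geo$spot_radius)) geo$pitch / 4 else geo$spot_radius,
    positions = pos,
    n_duplicates = if (is.null(geo$n_duplicates)) 2 else geo$n_duplicates
  )
}

#' Write an array layout to disk
#'
#' Serializes the geometry to JSON and the per-position annotation to a
#' sibling TSV, the same dialect that [load_layout()] reads, so that
#' write-then-load is the identity on all fields.
#'
#' @param layout an \code{array_layout}.
#' @param path path of the JSON file to write; the positions TSV is written
#'   next to it with suffix \code{"_positions.tsv"}.
#' @return Invisibly, the JSON path.
#' @export
write_layout <- function(layout, path) {
  tsv_name <- paste0(sub("\\.json$", "", basename(path)), "_positions.tsv")
  geo <- layout[c("name", "n_block_rows", "n_block_cols", "rows_per_block",
                  "cols_per_block", "pitch", "alley_row", "alley_col",
                  "spot_radius", "n_duplicates")]
  geo$positions_tsv <- tsv_name
  jsonlite::write_json(geo, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.table(layout$positions, file.path(dirname(path), tsv_name),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' The bundled synthetic default layout
#'
#' A 2x2 block membrane with 10x10 spots per block (400 positions): 50
#' analytes printed in duplicate in adjacent columns, one reference spot at
#' each of the four extreme corners of the grid (used as anchors by corner
#' detection), four negative-control spots at the inner block corners, and
#' the remaining positions empty.  Pitch 16 px, alleyways of 2 pitch units,
#' aperture radius 5 px.  This layout is synthetic: the commercial kidney and
#' XL cytokine membranes it stands in for are supported only as user-supplied
#' layout files, since their spot maps are vendor documentation.
#'
#' @return An \code{array_layout} with 400 positions.
#' @export
default_layout <- function() {
  nb <- 2L; rpb <- 10L; cpb <- 10L
  grid <- expand.grid(col = 0:(cpb - 1), row = 0:(rpb - 1),
                      block_col = 0:(nb - 1), block_row = 0:(nb - 1))
  grid <- grid[c("block_row", "block_col", "row", "col")]
  grid$analyte <- NA_character_
  grid$role <- "empty"
  key <- function(br, bc, r, cc) {
    match(paste(br, bc, r, cc),
          paste(grid$block_row, grid$block_col, grid$row, grid$col))
  }
  # reference anchors at the four extreme corners of the full grid
  refs <- rbind(c(0, 0, 0, 0), c(0, 1, 0, 9), c(1, 0, 9, 0), c(1, 1, 9, 9))
  for (i in seq_len(nrow(refs))) {
    k <- key(refs[i, 1], refs[i, 2], refs[i, 3], refs[i, 4])
    grid$role[k] <- "reference"
    grid$analyte[k] <- "REF"
  }
  negs <- rbind(c(0, 0, 9, 9), c(0, 1, 9, 0), c(1, 0, 0, 9), c(1, 1, 0, 0))
  for (i in seq_len(nrow(negs))) {
    k <- key(negs[i, 1], negs[i, 2], negs[i, 3], negs[i, 4])
    grid$role[k] <- "negative"
    grid$analyte[k] <- "NEG"
  }
  # 50 analytes in duplicate (adjacent columns), spread over the 4 blocks
  per_block <- c(13L, 13L, 12L, 12L)
  blocks <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  analyte_id <- 0L
  for (b in seq_len(4)) {
    placed <- 0L
    for (r in 0:(rpb - 1)) {
      for (cp in seq(0, cpb - 2, by = 2)) {
        if (placed >= per_block[b]) break
        k1 <- key(blocks[b, 1], blocks[b, 2], r, cp)
        k2 <- key(blocks[b, 1], blocks[b, 2], r, cp + 1)
        if (grid$role[k1] != "empty" || grid$role[k2] != "empty") next
        analyte_id <- analyte_id + 1L
        nm <- sprintf("CYT%02d", analyte_id)
        grid$role[c(k1, k2)] <- "analyte"
        grid$analyte[c(k1, k2)] <- nm
        placed <- placed + 1L
      }
      if (placed >= per_block[b]) break
    }
  }
  array_layout(name = "synthetic_default", n_block_rows = nb, n_block_cols = nb,
               rows_per_block = rpb, cols_per_block = cpb, pitch = 16,
               alley_row = 2, alley_col = 2, spot_radius = 5,
               positions = grid, n_duplicates = 2)
}

#' Screen a cohort against the CKD eligibility rule
#'
#' Labels each record by the study's eligibility rule: \code{ckd} when
#' eGFR < 60 mL/min per 1.73 m2 or the albumin/creatinine ratio is
#' >= 3.0 mg/mmol (30 mg/g); \code{control} when eGFR >= 60 and ACR < 3.0.
#' When a record carries a declared group that contradicts the computed
#' label, it is flagged \code{ineligible_conflict} instead of silently
#' relabelled.
#'
#' @param records data frame with numeric columns \code{egfr} (mL/min per
#'   1.73 m2) and \code{acr} (mg/mmol), and optionally \code{group}
#'   (\code{"ckd"}/\code{"control"}, case-insensitive) as the declared group.
#' @param egfr_threshold,acr_threshold eligibility cutoffs (60 and 3.0).
#' @return Character vector of labels, one per record:
#'   \code{"ckd"}, \code{"control"} or \code{"ineligible_conflict"}.
#' @export
screen_cohort <- function(records, egfr_threshold = 60, acr_threshold = 3.0) {
  records <- as.data.frame(records)
  if (!all(c("egfr", "acr") %in% names(records)))
    stop("records must contain columns 'egfr' and 'acr'")
  egfr <- as.numeric(records$egfr)
  acr <- as.numeric(records$acr)
  if (any(!is.finite(egfr)) || any(!is.finite(acr)))
    stop("egfr and acr must be finite numbers")
  if (any(egfr < 0) || any(acr < 0))
    stop("egfr and acr must be non-negative")
  label <- ifelse(egfr < egfr_threshold | acr >= acr_threshold, "ckd", "control")
  if (!is.null(records$group)) {
    declared <- tolower(as.character(records$group))
    conflict <- !is.na(declared) & declared %in% c("ckd", "control") &
      declared != label
    label[conflict] <- "ineligible_conflict"
  }
  label
}

#' Read a cohort table
#'
#' Reads a CSV cohort table with columns \code{subject_id}, \code{age},
#' \code{egfr}, \code{acr}, \code{gender}, \code{group} (and optionally
#' \code{cohort} distinguishing recruitment groups).  The bundled fixture
#' \code{system.file("extdata", "cohort_table1.csv", package = "blotgrid")}
#' is the digitized study cohort.
#'
#' @param path CSV path.
#' @return data frame.
#' @export
load_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
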