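#' Simulation configuration
#'
#' Defines the synthetic study: the membrane layout, the study arms
#' (experiment series x gender x disease group, one pooled-urine membrane
#' per arm, mirroring a pooled case/control design with two independent
#' series), the log-normal baseline expression model, the planted marker
#' panel, and the imaging model (Gaussian spot PSF, corner and per-spot
#' geometric jitter, missing spots, constant background plus Gaussian read
#' noise, 16-bit quantization).
#'
#' Planted markers: the first \code{n_markers_up} analytes are up-regulated
#' in CKD by \code{marker_fold}, the next \code{n_markers_down} are
#' down-regulated by \code{1/marker_fold} (consistently in every series:
#' the consensus panel), and the next \code{n_discordant} flip direction
#' between series (up in odd, down in even series), emulating the
#' series-to-series reversals seen in pooled-membrane data.
#'
#' @param layout an \code{array_layout} (default [default_layout()]).
#' @param n_series number of experiment series.
#' @param genders,groups study factors; one membrane per combination.
#' @param n_markers_up,n_markers_down,n_discordant planted marker counts.
#' @param marker_fold linear fold change of planted markers (> 1).
#' @param baseline_log2_mean,baseline_log2_sd log2 peak-amplitude
#'   distribution of analyte spots (per-analyte baseline shared by all
#'   arms).
#' @param technical_cv duplicate-to-duplicate technical coefficient of
#'   variation (log-normal).
#' @param exposure_log2_sd SD (log2) of the per-membrane exposure factor
#'   (chemiluminescence development and scan exposure scale a whole
#'   membrane, signal and background alike; this is what normalization has
#'   to remove).
#' @param psf_sigma Gaussian spot PSF standard deviation in pixels.
#' @param corner_jitter_sd SD (px) of the random displacement of the four
#'   grid corner anchors (the whole grid is distorted bilinearly).
#' @param spot_jitter_sd SD (px) of the independent per-spot displacement.
#' @param missing_prob probability that an analyte duplicate spot fails to
#'   print (reference anchors never go missing).
#' @param background constant background intensity level.
#' @param read_noise_sd SD of the additive Gaussian read noise per pixel.
#' @param reference_amplitude peak amplitude of the corner reference spots.
#' @param image_width,image_height image size in pixels.
#' @param bit_depth image quantization depth.
#' @param seed base random seed; a fixed seed makes every simulation output
#'   byte-identical.
#' @return List of class \code{simulation_config}.
#' @export
simulation_config <- function(layout = default_layout(), n_series = 2,
                              genders = c("M", "F"),
                              groups = c("CKD", "control"),
                              n_markers_up = 4, n_markers_down = 4,
                              n_discordant = 2, marker_fold = 3,
                              baseline_log2_mean = 10, baseline_log2_sd = 0.8,
                              technical_cv = 0.15, exposure_log2_sd = 0.5,
                              psf_sigma = 1.7,
                              corner_jitter_sd = 2, spot_jitter_sd = 1,
                              missing_prob = 0.1, background = 50,
                              read_noise_sd = 3, reference_amplitude = 20000,
                              image_width = 600, image_height = 400,
                              bit_depth = 16, seed = 1) {
  if (marker_fold <= 0) stop("marker_fold must be > 0")
  if (missing_prob < 0 || missing_prob > 1)
    stop("missing_prob must lie in [0, 1]")
  if (technical_cv < 0) stop("technical_cv must be >= 0")
  if (psf_sigma <= 0) stop("psf_sigma must be > 0")
  if (3 * spot_jitter_sd >= layout$pitch / 2)
    stop("spot_jitter_sd too large: spots would overlap beyond pitch/2")
  analytes <- sort(unique(layout$positions$analyte[layout$positions$role == "analyte"]))
  n_mark <- n_markers_up + n_markers_down + n_discordant
  if (n_mark > length(analytes))
    stop("more planted markers than analytes in the layout")
  markers <- data.frame(analyte = analytes[seq_len(n_mark)],
                        role = rep(c("consensus_up", "consensus_down", "discordant"),
                                   c(n_markers_up, n_markers_down, n_discordant)),
                        stringsAsFactors = FALSE)
  cfg <- list(layout = layout, n_series = n_series, genders = genders,
              groups = groups, markers = markers, marker_fold = marker_fold,
              baseline_log2_mean = baseline_log2_mean,
              baseline_log2_sd = baseline_log2_sd,
              technical_cv = technical_cv,
              exposure_log2_sd = exposure_log2_sd, psf_sigma = psf_sigma,
              corner_jitter_sd = corner_jitter_sd,
              spot_jitter_sd = spot_jitter_sd, missing_prob = missing_prob,
              background = background, read_noise_sd = read_noise_sd,
              reference_amplitude = reference_amplitude,
              image_width = image_width, image_height = image_height,
              bit_depth = bit_depth, seed = seed)
  structure(cfg, class = "simulation_config")
}

# linear fold applied to a marker analyte in a CKD arm of a given series
.marker_folds <- function(config, series, group) {
  analytes <- sort(unique(config$layout$positions$analyte[
    config$layout$positions$role == "analyte"]))
  fold <- stats::setNames(rep(1, length(analytes)), analytes)
  if (!grepl("ckd", group, ignore.case = TRUE)) return(fold)
  mk <- config$markers
  fold[mk$analyte[mk$role == "consensus_up"]] <- config$marker_fold
  fold[mk$analyte[mk$role == "consensus_down"]] <- 1 / config$marker_fold
  disc <- mk$analyte[mk$role == "discordant"]
  if (length(disc))
    fold[disc] <- if (series %% 2 == 1) config$marker_fold else 1 / config$marker_fold
  fold
}

# ideal corner anchors: grid centered on the image
.ideal_corners <- function(config) {
  lay <- config$layout
  uv <- .grid_uv(lay)
  span_x <- uv$total_u * lay$pitch
  span_y <- uv$total_v * lay$pitch
  x0 <- (config$image_width - 1 - span_x) / 2
  y0 <- (config$image_height - 1 - span_y) / 2
  list(tl = c(x0, y0), tr = c(x0 + span_x, y0),
       bl = c(x0, y0 + span_y), br = c(x0 + span_x, y0 + span_y))
}

.lognorm_sd <- function(cv) sqrt(log(1 + cv^2))

#' Simulate one membrane image with ground truth
#'
#' Renders one arm's membrane: Gaussian spots of per-duplicate amplitude at
#' grid positions distorted by corner jitter (a bilinear warp of the whole
#' grid) and independent per-spot jitter, constant-intensity reference
#' anchors at the grid corners, a constant background, additive Gaussian
#' read noise, and quantization to the configured bit depth.  Analyte
#' duplicates share the analyte's true amplitude up to the technical CV;
#' each duplicate spot goes missing independently with
#' \code{missing_prob}.  The ground-truth sidecar records, per position, the
#' true center (for spots that are not rendered this is the nominal warped
#' grid position) and per analyte the true expected amplitude and integrated
#' mass.
#'
#' @param config a [simulation_config()].
#' @param arm list with \code{series}, \code{gender}, \code{group}.
#' @param seed random seed (default derived from the config seed).
#' @param baselines optional named vector of per-analyte baseline peak
#'   amplitudes (shared across the arms of a study); drawn from the
#'   log-normal baseline model when absent.
#' @return List with \code{image} (a \code{membrane_image}) and \code{truth}
#'   (centers, per-duplicate amplitudes, expected analyte amplitudes/masses,
#'   marker table, arm).
#' @export
simulate_membrane <- function(config, arm = list(series = 1, gender = "M",
                                                 group = "CKD"),
                              seed = NULL, baselines = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(seed)) seed <- config$seed
  set.seed(seed)
  lay <- config$layout
  pos <- lay$positions
  analytes <- sort(unique(pos$analyte[pos$role == "analyte"]))
  if (is.null(baselines)) {
    baselines <- stats::setNames(
      2^stats::rnorm(length(analytes), config$baseline_log2_mean,
                     config$baseline_log2_sd), analytes)
  }
  fold <- .marker_folds(config, arm$series, arm$group)
  expected <- baselines * fold[names(baselines)]
  exposure <- if (config$exposure_log2_sd > 0)
    2^stats::rnorm(1, 0, config$exposure_log2_sd) else 1

  corners <- .ideal_corners(config)
  jit <- lapply(corners, function(p) p + stats::rnorm(2, 0, config$corner_jitter_sd))
  grid <- interpolate_grid(jit, lay)

  n <- nrow(pos)
  rendered <- logical(n)
  amp <- numeric(n)
  s_cv <- .lognorm_sd(config$technical_cv)
  dup_index <- stats::ave(seq_len(n), pos$analyte, pos$role,
                          FUN = seq_along)
  for (k in seq_len(n)) {
    if (pos$role[k] == "reference") {
      rendered[k] <- TRUE
      amp[k] <- config$reference_amplitude * exposure
    } else if (pos$role[k] == "analyte") {
      rendered[k] <- stats::runif(1) >= config$missing_prob
      noise <- if (s_cv > 0) exp(stats::rnorm(1, 0, s_cv)) else 1
      amp[k] <- expected[pos$analyte[k]] * noise * exposure
    }
  }
  x_true <- grid$x
  y_true <- grid$y
  jx <- stats::rnorm(n, 0, config$spot_jitter_sd)
  jy <- stats::rnorm(n, 0, config$spot_jitter_sd)
  x_true[rendered] <- x_true[rendered] + jx[rendered]
  y_true[rendered] <- y_true[rendered] + jy[rendered]

  h <- config$image_height; w <- config$image_width
  canvas <- matrix(config$background * exposure, h, w)
  sp <- config$psf_sigma
  rad <- ceiling(5 * sp)
  for (k in which(rendered)) {
    cx <- x_true[k]; cy <- y_true[k]
    js <- max(0, floor(cx - rad)):min(w - 1, ceiling(cx + rad))
    is <- max(0, floor(cy - rad)):min(h - 1, ceiling(cy + rad))
    gx <- exp(-(js - cx)^2 / (2 * sp^2))
    gy <- exp(-(is - cy)^2 / (2 * sp^2))
    canvas[is + 1, js + 1] <- canvas[is + 1, js + 1] + amp[k] * outer(gy, gx)
  }
  if (config$read_noise_sd > 0)
    canvas <- canvas + stats::rnorm(h * w, 0, config$read_noise_sd * exposure)
  canvas <- pmin(pmax(round(canvas), 0), 2^config$bit_depth - 1)

  centers <- pos
  centers$x_true <- x_true
  centers$y_true <- y_true
  centers$rendered <- rendered
  dup_amps <- data.frame(analyte = pos$analyte, duplicate = dup_index,
                         role = pos$role, amplitude = amp,
                         mass = amp * 2 * pi * sp^2, rendered = rendered,
                         stringsAsFactors = FALSE)
  dup_amps <- dup_amps[dup_amps$role == "analyte", , drop = FALSE]
  truth <- list(centers = centers, duplicate_amplitudes = dup_amps,
                expected_amplitude = expected,
                expected_mass = expected * 2 * pi * sp^2,
                exposure = exposure,
                markers = config$markers, arm = arm, seed = seed)
  list(image = membrane_image(canvas), truth = truth)
}

#' Simulate a full study of membranes
#'
#' One membrane per arm (series x gender x group), sharing per-analyte
#' baselines so that planted fold changes are the only systematic
#' between-arm differences.  The planted cross-series consensus panel (and
#' the discordant markers excluded from it) is recorded in the truth.
#'
#' @param config a [simulation_config()].
#' @param seed base seed (default \code{config$seed}); each arm uses a
#'   deterministic offset of it.
#' @return List with \code{membranes} (named list of
#'   [simulate_membrane()] results), \code{manifest} (data frame linking
#'   membrane ids to arms and seeds) and \code{truth} (consensus panel,
#'   discordant markers, baselines).
#' @export
simulate_study <- function(config, seed = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(seed)) seed <- config$seed
  set.seed(seed)
  analytes <- sort(unique(config$layout$positions$analyte[
    config$layout$positions$role == "analyte"]))
  baselines <- stats::setNames(
    2^stats::rnorm(length(analytes), config$baseline_log2_mean,
                   config$baseline_log2_sd), analytes)
  arms <- expand.grid(group = config$groups, gender = config$genders,
                      series = seq_len(config$n_series),
                      stringsAsFactors = FALSE)[, 3:1]
  membranes <- list()
  manifest <- NULL
  for (i in seq_len(nrow(arms))) {
    arm <- list(series = arms$series[i], gender = arms$gender[i],
                group = arms$group[i])
    id <- sprintf("s%d_%s_%s", arm$series, arm$gender, arm$group)
    arm_seed <- (seed + 131 * i) %% .Machine$integer.max
    membranes[[id]] <- simulate_membrane(config, arm, seed = arm_seed,
                                         baselines = baselines)
    manifest <- rbind(manifest,
                      data.frame(membrane_id = id, series = arm$series,
                                 gender = arm$gender, group = arm$group,
                                 seed = arm_seed, stringsAsFactors = FALSE))
  }
  mk <- config$markers
  consensus <- data.frame(
    analyte = mk$analyte[mk$role != "discordant"],
    direction = ifelse(mk$role[mk$role != "discordant"] == "consensus_up",
                       "up", "down"),
    stringsAsFactors = FALSE)
  list(membranes = membranes, manifest = manifest,
       truth = list(consensus = consensus,
                    discordant = mk$analyte[mk$role == "discordant"],
                    baselines = baselines))
}

#' Simulate per-duplicate density tables (tabular shortcut)
#'
#' Generates, without rendering images, the analyte-by-arm duplicate density
#' matrix that the imaging path would measure: per duplicate, the analyte's
#' integrated spot mass (log-normal baseline x planted fold x technical
#' noise) plus the aperture background term \code{area * background} and
#' Gaussian measurement noise with SD \code{read_noise_sd * sqrt(area)}
#' (summing per-pixel read noise over the aperture); background positions
#' carry the aperture background term alone.
#'
#' @param config a [simulation_config()].
#' @param seed random seed (default \code{config$seed}).
#' @param arms optional list of arms (each \code{list(series, gender,
#'   group)}); defaults to the full study design.
#' @param amplitudes optional named vector fixing the true spot mass per
#'   analyte (bypasses the log-normal baseline model; planted folds still
#'   apply); analytes missing from the vector default to 0 (blank).
#' @param n_duplicates duplicate spots per analyte per arm.
#' @param n_background background positions measured per arm.
#' @return List with \code{matrix} (raw [expression_matrix()], one column
#'   per arm x duplicate), \code{background} (named list of background
#'   density vectors per arm), \code{truth} (true masses per arm, aperture
#'   area, noise SD).
#' @export
simulate_expression_table <- function(config, seed = NULL, arms = NULL,
                                      amplitudes = NULL, n_duplicates = 2,
                                      n_background = 30) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(seed)) seed <- config$seed
  set.seed(seed)
  lay <- config$layout
  analytes <- sort(unique(lay$positions$analyte[lay$positions$role == "analyte"]))
  r <- lay$spot_radius
  offs <- expand.grid(dx = -ceiling(r):ceiling(r), dy = -ceiling(r):ceiling(r))
  area <- sum(offs$dx^2 + offs$dy^2 <= r^2)
  noise_sd <- config$read_noise_sd * sqrt(area)
  bg_term <- area * config$background
  if (is.null(arms)) {
    g <- expand.grid(group = config$groups, gender = config$genders,
                     series = seq_len(config$n_series),
                     stringsAsFactors = FALSE)[, 3:1]
    arms <- lapply(seq_len(nrow(g)), function(i)
      list(series = g$series[i], gender = g$gender[i], group = g$group[i]))
  }
  if (is.null(amplitudes)) {
    base_mass <- stats::setNames(
      2^stats::rnorm(length(analytes), config$baseline_log2_mean,
                     config$baseline_log2_sd) * 2 * pi * config$psf_sigma^2,
      analytes)
  } else {
    base_mass <- stats::setNames(rep(0, length(analytes)), analytes)
    base_mass[names(amplitudes)] <- amplitudes
  }
  s_cv <- .lognorm_sd(config$technical_cv)
  mats <- list(); bgs <- list(); true_masses <- list()
  for (a in arms) {
    id <- sprintf("s%d_%s_%s", a$series, a$gender, a$group)
    fold <- .marker_folds(config, a$series, a$group)
    exposure <- if (config$exposure_log2_sd > 0)
      2^stats::rnorm(1, 0, config$exposure_log2_sd) else 1
    mass <- base_mass * fold[analytes]
    vals <- matrix(NA_real_, length(analytes), n_duplicates,
                   dimnames = list(analytes, paste0(id, ".d", seq_len(n_duplicates))))
    for (dd in seq_len(n_duplicates)) {
      tech <- if (s_cv > 0) exp(stats::rnorm(length(analytes), 0, s_cv)) else 1
      meas <- if (noise_sd > 0)
        stats::rnorm(length(analytes), 0, noise_sd * exposure) else 0
      vals[, dd] <- pmax((mass * tech + bg_term) * exposure + meas, 0)
    }
    samples <- do.call(rbind, lapply(seq_len(n_duplicates), function(dd)
      .sample_row(paste0(id, ".d", dd), a, replicate = dd)))
    mats[[id]] <- expression_matrix(vals, samples, scale = "raw")
    bgs[[id]] <- pmax(bg_term * exposure + if (noise_sd > 0)
      stats::rnorm(n_background, 0, noise_sd * exposure) else 0, 0)
    true_masses[[id]] <- mass
  }
  list(matrix = assemble_matrix(mats), background = bgs,
       truth = list(masses = true_masses, aperture_area = area,
                    background_term = bg_term, noise_sd = noise_sd,
                    markers = config$markers))
}
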