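#' Quantile-curve spline normalization
#'
#' Removes sample-to-sample intensity scale and shape differences by mapping
#' each sample's log2 quantiles onto the across-sample mean quantile curve
#' through a monotone Hermite spline fitted at evenly spaced quantile anchor
#' points (a robust, rank-preserving spline variant of quantile
#' normalization).  Zeros are offset by half the smallest positive value
#' before the log transform; results are returned on the linear scale.
#'
#' The mapping is monotone non-decreasing (strictly increasing wherever the
#' reference curve is), so within-sample rank order is preserved exactly, and
#' a sample identical to the reference maps onto itself.
#'
#' @param x an [expression_matrix()] (scale \code{"raw"}) or plain numeric
#'   matrix with >= 2 columns.
#' @param n_anchors number of quantile anchor points for the spline
#'   (default 11: a stiff map suits the small analyte panels of membrane
#'   arrays, where a fine-grained map would chase sampling noise of
#'   individual order statistics).
#' @param anchor_trim fraction of the rank range excluded from anchoring at
#'   each end (default 0.15).  Values beyond the anchored range are mapped by
#'   a linear extension with the boundary anchor slope, so genuinely
#'   regulated analytes at the extreme ranks are rescaled rather than forced
#'   onto the reference quantiles (full-range quantile mapping would shrink
#'   their fold changes toward the pooled distribution).
#' @return Normalized object of the same kind (scale \code{"normalized"}).
#'   With fewer than 2 columns the input is returned unchanged with a warning
#'   and attribute \code{normalization_skipped = TRUE}.
#' @export
robust_spline_normalize <- function(x, n_anchors = 11, anchor_trim = 0.15) {
  em <- inherits(x, "expression_matrix")
  m <- if (em) x$values else as.matrix(x)
  if (ncol(m) < 2) {
    warning("fewer than 2 samples: normalization skipped")
    attr(x, "normalization_skipped") <- TRUE
    return(x)
  }
  if (any(m < 0, na.rm = TRUE)) stop("expression values must be >= 0")
  if (any(m == 0, na.rm = TRUE)) {
    posmin <- min(m[m > 0], na.rm = TRUE)
    m[!is.na(m) & m == 0] <- posmin / 2
  }
  L <- log2(m)
  n <- nrow(L)
  # interior quantile anchors: the extreme ranks are deliberately left to a
  # linear slope extension, so the dimmest/brightest analytes are rescaled,
  # not pinned onto the reference extremes (rank pinning would erase real
  # fold changes at the boundary ranks)
  if (anchor_trim < 0 || anchor_trim >= 0.5)
    stop("anchor_trim must lie in [0, 0.5)")
  K <- max(2, min(n, n_anchors))
  probs <- seq(anchor_trim + (0.5 - anchor_trim) / K,
               1 - anchor_trim - (0.5 - anchor_trim) / K, length.out = K)
  Q <- vapply(seq_len(ncol(L)),
              function(j) stats::quantile(L[, j], probs, na.rm = TRUE,
                                          names = FALSE),
              numeric(length(probs)))
  ref <- rowMeans(Q)
  out <- L
  for (j in seq_len(ncol(L))) {
    ax <- Q[, j]; ay <- ref
    keep <- !duplicated(ax)
    if (sum(keep) < 2) {
      # degenerate constant sample: map everything onto the reference mean
      out[!is.na(L[, j]), j] <- mean(ref)
      next
    }
    # average the reference over tied anchor abscissae
    ay <- vapply(split(ay, match(ax, ax[keep])), mean, 0)
    ax <- ax[keep]
    f <- stats::splinefun(ax, ay, method = "monoH.FC")
    nk <- length(ax)
    obs <- which(!is.na(L[, j]))
    xv <- L[obs, j]
    yv <- f(xv)
    # beyond the anchored range: continue with unit slope (a pure log2
    # offset), which is exact for sample-to-sample scale factors and leaves
    # fold changes of extreme-rank analytes untouched
    lo <- xv < ax[1]; hi <- xv > ax[nk]
    yv[lo] <- ay[1] + (xv[lo] - ax[1])
    yv[hi] <- ay[nk] + (xv[hi] - ax[nk])
    out[obs, j] <- yv
  }
  res <- 2^out
  if (em) expression_matrix(res, x$samples, scale = "normalized") else res
}

#' Background spot set
#'
#' Identifies the background spots of one membrane by the dynamic-range rule:
#' the threshold is \code{min + background_fraction * (max - min)} of the
#' per-position densities, and every position at or below the threshold is
#' background (the minimum always qualifies, so the set is non-empty).
#'
#' @param values numeric vector of per-position densities (names, when
#'   present, identify the positions).
#' @param background_fraction fraction of the dynamic range above the
#'   minimum that still counts as background (default 0.05).
#' @return List with \code{threshold}, \code{background} (indices into
#'   \code{values}), \code{values} (the background densities) and
#'   \code{degenerate} (\code{TRUE} when all densities are equal, in which
#'   case every position is background).
#' @export
background_spot_set <- function(values, background_fraction = 0.05) {
  if (background_fraction <= 0 || background_fraction >= 1)
    stop("background_fraction must be in (0, 1)")
  v <- values[!is.na(values)]
  if (!length(v)) stop("no non-missing densities")
  lo <- min(v); hi <- max(v)
  threshold <- lo + background_fraction * (hi - lo)
  sel <- which(!is.na(values) & values <= threshold)
  list(threshold = threshold, background = sel,
       values = values[sel], degenerate = lo == hi)
}

#' Detection p-value of one analyte against the background spots
#'
#' One-sided two-sample t-test of the analyte's duplicate densities being
#' greater than the background spot densities.  The relevant null is that a
#' blank spot is just another draw from the background noise distribution,
#' so the variance is pooled by default: with only n = 2 duplicates the
#' Welch-Satterthwaite approximation is markedly anti-conservative (type-I
#' error near 0.08 at alpha 0.05), while the pooled test is exactly
#' calibrated under that null; set \code{var_equal = FALSE} for Welch.
#' With a single analyte replicate a z-score against the background mean
#' and SD is used instead; with zero background variance the call
#' degenerates to the exact rule p = 0 if the analyte mean exceeds the
#' background value, else 1.
#'
#' @param spot_replicates numeric vector of the analyte's duplicate
#'   densities (NAs dropped).
#' @param background numeric vector of background spot densities (>= 2
#'   values required).
#' @param var_equal pool the variance across analyte and background spots
#'   (default) or use the Welch test.
#' @return One-sided p-value in [0, 1].
#' @export
detection_pvalue <- function(spot_replicates, background, var_equal = TRUE) {
  x <- spot_replicates[!is.na(spot_replicates)]
  b <- background[!is.na(background)]
  if (!length(x)) stop("no analyte replicate densities")
  if (length(b) < 2) stop("need at least 2 background densities")
  sb <- stats::sd(b)
  if (sb == 0)
    return(if (mean(x) > b[1]) 0 else 1)
  if (length(x) == 1)
    return(stats::pnorm((x - mean(b)) / sb, lower.tail = FALSE))
  stats::t.test(x, b, alternative = "greater", var.equal = var_equal)$p.value
}

#' Detection calls for all analytes of a membrane
#'
#' Determines the background spot set from the membrane's per-position
#' densities (reference anchor spots excluded by default, since they are
#' constant bright controls) and computes a detection p-value per analyte.
#' An analyte's own duplicate positions are excluded from its background
#' comparison set.
#'
#' @param x a \code{density_table}, or a numeric matrix of analyte duplicate
#'   densities (analytes as rows) together with \code{background}.
#' @param alpha detection significance level (default 0.05).
#' @param background_fraction see [background_spot_set()].
#' @param exclude_reference drop reference spots before computing the
#'   background rule (density tables only).
#' @param background numeric vector of background densities (matrix method).
#' @param ... passed between methods.
#' @return data frame (class \code{detection_result}): \code{analyte},
#'   \code{p}, \code{detected}; the background threshold is kept as an
#'   attribute.
#' @export
detect_analytes <- function(x, ...) UseMethod("detect_analytes")

#' @rdname detect_analytes
#' @export
detect_analytes.density_table <- function(x, alpha = 0.05,
                                          background_fraction = 0.05,
                                          exclude_reference = TRUE, ...) {
  tab <- as.data.frame(x)
  pool <- if (exclude_reference) tab[tab$role != "reference", , drop = FALSE] else tab
  bg <- background_spot_set(pool$density, background_fraction)
  bg_rows <- pool[bg$background, , drop = FALSE]
  an <- tab[tab$role == "analyte", , drop = FALSE]
  sp <- split(an$density, an$analyte)
  p <- vapply(names(sp), function(a) {
    if (all(is.na(sp[[a]]))) return(NA_real_)
    bvals <- bg_rows$density[!(bg_rows$role == "analyte" & bg_rows$analyte == a)]
    if (length(bvals) < 2) bvals <- bg_rows$density
    detection_pvalue(sp[[a]], bvals)
  }, 0)
  structure(data.frame(analyte = names(sp), p = unname(p),
                       detected = !is.na(p) & unname(p) < alpha,
                       stringsAsFactors = FALSE),
            threshold = bg$threshold, alpha = alpha,
            class = c("detection_result", "data.frame"))
}

#' @rdname detect_analytes
#' @export
detect_analytes.matrix <- function(x, background, alpha = 0.05, ...) {
  if (is.null(rownames(x))) stop("analyte matrix must have rownames")
  p <- vapply(seq_len(nrow(x)), function(i) detection_pvalue(x[i, ], background), 0)
  structure(data.frame(analyte = rownames(x), p = p,
                       detected = !is.na(p) & p < alpha,
                       stringsAsFactors = FALSE),
            alpha = alpha, class = c("detection_result", "data.frame"))
}

# solve trigamma(x) = y (trigamma is strictly decreasing on (0, Inf))
.trigamma_inverse <- function(y) {
  if (y <= 1e-8) return(Inf)
  x <- 0.5 + 1 / y
  for (it in 1:75) {
    tri <- trigamma(x)
    step <- (tri - y) / psigamma(x, deriv = 2)
    xn <- x - step
    if (xn <= 0) xn <- x / 2
    if (abs(xn - x) < 1e-10 * x) { x <- xn; break }
    x <- xn
  }
  x
}

#' Empirical-Bayes moderated two-sample t-test
#'
#' Fits the two-group model per analyte and shrinks the per-analyte residual
#' variances s_g^2 (d_g residual df) toward a common prior: the prior
#' degrees of freedom d0 and prior variance s0^2 are estimated by closed-form
#' moment matching on log s_g^2 (digamma/trigamma inversion), the posterior
#' variance is \code{(d0 s0^2 + d_g s_g^2) / (d0 + d_g)}, and the moderated t
#' uses \code{d0 + d_g} degrees of freedom.  When the variance estimates are
#' homogeneous the moment equation has no positive solution; d0 is then
#' infinite and the posterior variance is the d_g-weighted pooled common
#' variance, so shrinkage has a fixed point at identical variances.
#'
#' With \code{prior_df = 0} the statistic reduces exactly to the ordinary
#' pooled-variance two-sample t; with \code{prior_df = Inf} and a supplied
#' \code{prior_var} it is the fixed-variance z-like statistic.
#'
#' @param x numeric matrix of log2 values (analytes as rows) or a log2-scale
#'   [expression_matrix()].
#' @param groups vector (length = columns) with exactly two distinct labels;
#'   the first label encountered is the "case" group, and the reported
#'   difference is case minus the other group.
#' @param prior_df optional fixed prior degrees of freedom (overrides
#'   estimation).
#' @param prior_var optional fixed prior variance s0^2.
#' @return Object of class \code{moderated_t}: data frame \code{table}
#'   (analyte, diff, t, p, s2, df_resid, s2_post, n1, n2) plus \code{prior_df}
#'   and \code{prior_var}.
#' @export
fit_moderated_t <- function(x, groups, prior_df = NULL, prior_var = NULL) {
  m <- if (inherits(x, "expression_matrix")) x$values else as.matrix(x)
  if (length(groups) != ncol(m))
    stop("groups must have one label per column")
  lev <- if (is.factor(groups)) levels(droplevels(groups)) else unique(as.character(groups))
  if (length(lev) != 2) stop("exactly two groups are required")
  groups <- as.character(groups)
  g1 <- which(groups == lev[1]); g2 <- which(groups == lev[2])
  X1 <- m[, g1, drop = FALSE]; X2 <- m[, g2, drop = FALSE]
  n1 <- rowSums(!is.na(X1)); n2 <- rowSums(!is.na(X2))
  if (all(n1 == 0) || all(n2 == 0)) stop("a group has zero observations")
  # analytes with no observation in one group get NA statistics
  m1 <- rowMeans(X1, na.rm = TRUE); m2 <- rowMeans(X2, na.rm = TRUE)
  m1[n1 == 0] <- NA_real_; m2[n2 == 0] <- NA_real_
  rss <- rowSums((X1 - m1)^2, na.rm = TRUE) + rowSums((X2 - m2)^2, na.rm = TRUE)
  d <- n1 + n2 - 2
  s2 <- ifelse(d > 0, rss / pmax(d, 1), NA_real_)
  diffv <- m1 - m2

  ok <- d > 0 & !is.na(s2) & s2 > 0
  if (is.null(prior_df)) {
    if (sum(ok) < 2) {
      d0 <- 0; s02 <- NA_real_
    } else {
      e <- log(s2[ok]) - digamma(d[ok] / 2) + log(d[ok] / 2)
      emean <- mean(e)
      evar <- stats::var(e) - mean(trigamma(d[ok] / 2))
      if (is.finite(evar) && evar > 0) {
        d0 <- 2 * .trigamma_inverse(evar)
        s02 <- if (is.finite(d0))
          exp(emean + digamma(d0 / 2) - log(d0 / 2)) else exp(emean)
      } else {
        d0 <- Inf
        s02 <- exp(emean)
      }
    }
  } else {
    d0 <- prior_df
    s02 <- if (!is.null(prior_var)) prior_var else {
      if (is.infinite(d0)) exp(mean(log(s2[ok]) - digamma(d[ok] / 2) + log(d[ok] / 2)))
      else NA_real_
    }
  }
  if (!is.null(prior_var)) s02 <- prior_var

  if (is.infinite(d0)) {
    s2_post <- rep(if (!is.null(prior_var)) prior_var else
      sum(d[ok] * s2[ok]) / sum(d[ok]), nrow(m))
    df_total <- rep(Inf, nrow(m))
  } else if (d0 == 0) {
    s2_post <- s2
    df_total <- d
  } else {
    s2_hat <- ifelse(is.na(s2), 0, s2)
    s2_post <- (d0 * s02 + d * s2_hat) / (d0 + d)
    df_total <- d0 + d
  }
  tstat <- diffv / sqrt(s2_post * (1 / n1 + 1 / n2))
  p <- ifelse(is.finite(df_total),
              2 * stats::pt(-abs(tstat), df_total),
              2 * stats::pnorm(-abs(tstat)))
  structure(list(
    table = data.frame(analyte = rownames(m), diff = diffv, t = tstat, p = p,
                       s2 = s2, df_resid = d, s2_post = s2_post,
                       n1 = n1, n2 = n2, row.names = NULL,
                       stringsAsFactors = FALSE),
    prior_df = d0, prior_var = s02, groups = lev),
    class = "moderated_t")
}

#' @export
print.moderated_t <- function(x, ...) {
  cat(sprintf("moderated_t: %d analytes, %s vs %s; prior df = %.3g, prior var = %.4g\n",
              nrow(x$table), x$groups[1], x$groups[2], x$prior_df, x$prior_var))
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values controlling the false discovery rate (input
#' order preserved).
#'
#' @param pvalues numeric vector of p-values in [0, 1].
#' @return Adjusted values in [0, 1].
#' @export
bh_adjust <- function(pvalues) {
  if (!is.numeric(pvalues)) stop("pvalues must be numeric")
  if (any(is.na(pvalues))) stop("pvalues must not contain NA")
  if (any(pvalues < 0 | pvalues > 1)) stop("pvalues must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Differential-expression criteria
#'
#' The composite call criteria: an analyte is \code{up} when it is detected
#' (p < \code{alpha_detect}) in at least one condition, the CKD/control
#' ratio exceeds \code{ratio_up}, the moderated-t p-value is below
#' \code{alpha_p} and the BH FDR is below \code{alpha_fdr}; \code{down}
#' symmetric with \code{ratio_down}; otherwise \code{ns}.
#'
#' @param ratio_down,ratio_up linear-ratio gates (defaults 0.667 and 1.5).
#' @param alpha_p moderated-t significance gate (0.05).
#' @param alpha_fdr BH FDR gate (0.25).
#' @param alpha_detect detection gate (0.05).
#' @param require_detect require detection in at least one condition.
#' @return List of class \code{de_criteria}.
#' @export
de_criteria <- function(ratio_down = 0.667, ratio_up = 1.5, alpha_p = 0.05,
                        alpha_fdr = 0.25, alpha_detect = 0.05,
                        require_detect = TRUE) {
  if (!(ratio_down < 1 && 1 < ratio_up))
    stop("criteria must satisfy ratio_down < 1 < ratio_up")
  for (a in c(alpha_p, alpha_fdr, alpha_detect))
    if (a <= 0 || a >= 1) stop("significance gates must lie in (0, 1)")
  structure(list(ratio_down = ratio_down, ratio_up = ratio_up,
                 alpha_p = alpha_p, alpha_fdr = alpha_fdr,
                 alpha_detect = alpha_detect, require_detect = require_detect),
            class = "de_criteria")
}

#' Composite differential-expression calls
#'
#' Runs the moderated-t model on log2 values, computes linear CKD/control
#' ratios on the normalized scale, adjusts p-values by Benjamini-Hochberg
#' within the contrast, and applies the composite criteria.  Analytes with
#' any missing statistic are flagged unevaluable and called \code{ns}.
#'
#' @param x normalized linear-scale [expression_matrix()] whose sample
#'   annotation \code{group} contains the two conditions, or a plain matrix
#'   plus \code{groups}.
#' @param detection data frame with columns \code{analyte},
#'   \code{detect_p_ckd}, \code{detect_p_control} (e.g. built from
#'   [detect_analytes()] of the two membranes).
#' @param criteria a [de_criteria()].
#' @param groups optional explicit group labels (first label = CKD-like
#'   numerator condition).
#' @return data frame of class \code{de_result}: \code{analyte},
#'   \code{ratio}, \code{log2ratio}, \code{p}, \code{fdr},
#'   \code{detect_p_ckd}, \code{detect_p_control}, \code{call},
#'   \code{unevaluable}; the fitted \code{moderated_t} is kept as attribute
#'   \code{model}.
#' @export
call_differential <- function(x, detection, criteria = de_criteria(),
                              groups = NULL) {
  if (inherits(x, "expression_matrix")) {
    v <- x$values
    if (is.null(groups)) groups <- x$samples$group
  } else {
    v <- as.matrix(x)
  }
  if (is.null(groups)) stop("group labels are required")
  groups <- as.character(groups)
  lev <- unique(groups)
  if (length(lev) != 2) stop("exactly two conditions are required")
  # numerator condition: a label matching 'ckd' if present, else first seen
  ckd_lev <- lev[grepl("ckd", lev, ignore.case = TRUE)]
  if (length(ckd_lev) != 1) ckd_lev <- lev[1]
  lev <- c(ckd_lev, setdiff(lev, ckd_lev))

  w <- v
  if (any(w == 0, na.rm = TRUE)) {
    posmin <- min(w[w > 0], na.rm = TRUE)
    w[w == 0] <- posmin / 2
  }
  fit <- fit_moderated_t(log2(w), factor(groups, levels = lev))
  ratio <- rowMeans(v[, groups == lev[1], drop = FALSE], na.rm = TRUE) /
    rowMeans(v[, groups == lev[2], drop = FALSE], na.rm = TRUE)
  res <- fit$table[c("analyte", "p")]
  res$ratio <- unname(ratio[res$analyte])
  res$log2ratio <- log2(res$ratio)
  res$fdr <- NA_real_
  ok_p <- !is.na(res$p)
  if (any(ok_p)) res$fdr[ok_p] <- bh_adjust(res$p[ok_p])
  det <- as.data.frame(detection)
  if (!all(c("analyte", "detect_p_ckd", "detect_p_control") %in% names(det)))
    stop("detection must have columns analyte, detect_p_ckd, detect_p_control")
  idx <- match(res$analyte, det$analyte)
  res$detect_p_ckd <- det$detect_p_ckd[idx]
  res$detect_p_control <- det$detect_p_control[idx]
  detected_any <- (!is.na(res$detect_p_ckd) & res$detect_p_ckd < criteria$alpha_detect) |
    (!is.na(res$detect_p_control) & res$detect_p_control < criteria$alpha_detect)
  res$unevaluable <- !is.finite(res$ratio) | is.na(res$p) |
    (criteria$require_detect & is.na(res$detect_p_ckd) & is.na(res$detect_p_control))
  gate_detect <- if (criteria$require_detect) detected_any else TRUE
  up <- !res$unevaluable & gate_detect & res$ratio > criteria$ratio_up &
    res$p < criteria$alpha_p & res$fdr < criteria$alpha_fdr
  down <- !res$unevaluable & gate_detect & res$ratio < criteria$ratio_down &
    res$p < criteria$alpha_p & res$fdr < criteria$alpha_fdr
  res$call <- ifelse(up, "up", ifelse(down, "down", "ns"))
  res <- res[c("analyte", "ratio", "log2ratio", "p", "fdr",
               "detect_p_ckd", "detect_p_control", "call", "unevaluable")]
  structure(res, model = fit, criteria = criteria,
            class = c("de_result", "data.frame"))
}

#' Write a differential-expression result as CSV
#'
#' @param de a \code{de_result}.
#' @param path CSV path.
#' @return Invisibly, \code{path}.
#' @export
write_de_csv <- function(de, path) {
  utils::write.csv(as.data.frame(de), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
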