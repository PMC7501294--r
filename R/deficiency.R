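# Classification of OXPHOS deficiency relative to mitochondrial mass:
# control regression with predictive intervals, and the theta / kernel
# density likelihood classifier.

# Replace non-positive intensities by half the smallest positive value so
# that logs are defined; IMC means are ion counts and true zeros are rare.
log_with_pseudo <- function(v) {
  if (any(v <= 0)) {
    pos <- v[v > 0]
    if (length(pos) == 0) abort("all values non-positive under log scale")
    v[v <= 0] <- min(pos) / 2
  }
  log(v)
}

scale_values <- function(v, scale) {
  if (scale == "log") log_with_pseudo(v) else v
}

#' Fit the control regression band for one channel
#'
#' Ordinary least squares of a target channel on the mitochondrial-mass
#' reference (VDAC1) over control fibres, retaining everything needed to
#' evaluate the predictive interval for a new control fibre at any
#' reference value x0:
#' `yhat(x0) +/- t[(1+level)/2, n-2] * s * sqrt(1 + 1/n + (x0 - xbar)^2 / Sxx)`.
#' Patient fibres outside this band are candidates for biochemical
#' deficiency (below) or compensatory upregulation (above).
#'
#' @param controls Data frame of control fibres with the channel columns.
#' @param channel Target channel column name.
#' @param reference Mitochondrial-mass reference column (default
#'   `"VDAC1"`).
#' @param level Predictive-interval level in (0, 1), default 0.95.
#' @param scale `"log"` (natural log of intensities, the default) or
#'   `"linear"`.
#'
#' @return An object of class `regression_band`.
#' @examples
#' ctrl <- sample_fibre_table(control_model(), 200, seed = 3)
#' fit_control_band(ctrl, "NDUFB8")
#' @export
fit_control_band <- function(controls, channel, reference = "VDAC1",
                             level = 0.95, scale = c("log", "linear")) {
  scale <- match.arg(scale)
  if (!all(c(channel, reference) %in% names(controls))) {
    abort("channel or reference column missing from controls")
  }
  if (nrow(controls) < 3) abort("need at least 3 control fibres")
  if (level <= 0 || level >= 1) abort("level must be in (0, 1)")
  x <- scale_values(controls[[reference]], scale)
  y <- scale_values(controls[[channel]], scale)
  if (sd(x) == 0) abort("degenerate reference: zero variance")
  fit <- lm(y ~ x)
  n <- length(x)
  s <- sqrt(sum(fit$residuals^2) / (n - 2))
  structure(list(channel = channel, reference = reference,
                 intercept = unname(coef(fit)[1]),
                 slope = unname(coef(fit)[2]),
                 sigma = s, n_control = n, xbar = mean(x),
                 sxx = sum((x - mean(x))^2), level = level, scale = scale),
            class = "regression_band")
}

#' Predictive-interval bounds of a control band
#'
#' @param band A [regression_band()] from [fit_control_band()].
#' @param x0 Reference values on the band's working scale (log if the band
#'   was fitted on logs).
#'
#' @return Tibble with columns `x`, `fit`, `lwr`, `upr`.
#' @export
band_bounds <- function(band, x0) {
  stopifnot(inherits(band, "regression_band"))
  fit <- band$intercept + band$slope * x0
  tq <- qt((1 + band$level) / 2, band$n_control - 2)
  half <- tq * band$sigma *
    sqrt(1 + 1 / band$n_control + (x0 - band$xbar)^2 / band$sxx)
  tibble(x = x0, fit = fit, lwr = fit - half, upr = fit + half)
}

#' @export
print.regression_band <- function(x, ...) {
  cat(sprintf(
    "<regression_band> %s ~ %s (%s scale): y = %.3f + %.3f x, s = %.3f, n = %d, level = %.2f\n",
    x$channel, x$reference, x$scale, x$intercept, x$slope, x$sigma,
    x$n_control, x$level))
  invisible(x)
}

#' @method tidy regression_band
#' @export
tidy.regression_band <- function(x, ...) {
  tibble(term = c("(Intercept)", x$reference),
         estimate = c(x$intercept, x$slope))
}

#' @method glance regression_band
#' @export
glance.regression_band <- function(x, ...) {
  tibble(channel = x$channel, reference = x$reference, sigma = x$sigma,
         n_control = x$n_control, level = x$level, scale = x$scale)
}

#' Classify fibres against a control predictive band
#'
#' A fibre is `below` if its (scaled) target intensity is strictly below
#' the lower predictive bound at its reference value, `above` if strictly
#' above the upper bound, and `within` otherwise (band boundaries count as
#' within). `below` for an OXPHOS subunit channel indicates expression
#' deficit relative to mitochondrial mass; `above` indicates relative
#' upregulation.
#'
#' @param fibres Data frame with the band's channel and reference columns.
#' @param band A [regression_band()].
#'
#' @return The input as a tibble plus columns `.x`, `.y` (working-scale
#'   coordinates), `lwr`, `upr` and `call` (factor below/within/above).
#'   The `(above, within, below)` counts are attached as attribute
#'   `"counts"` and printed by [call_counts()].
#' @examples
#' ctrl <- sample_fibre_table(control_model(), 300, seed = 3)
#' band <- fit_control_band(ctrl, "NDUFB8")
#' pat <- sample_fibre_table(control_model(), 100, 0.4, 0.1, seed = 4)
#' call_counts(classify_2dmito(pat, band))
#' @export
classify_2dmito <- function(fibres, band) {
  stopifnot(inherits(band, "regression_band"))
  if (!all(c(band$channel, band$reference) %in% names(fibres))) {
    abort("fibres lack the band's channel or reference column")
  }
  fibres <- as_tibble(fibres)
  lv <- factor(character(), levels = c("below", "within", "above"))
  if (nrow(fibres) == 0) {
    out <- dplyr::mutate(fibres, .x = numeric(0), .y = numeric(0),
                         lwr = numeric(0), upr = numeric(0), call = lv)
  } else {
    x <- scale_values(fibres[[band$reference]], band$scale)
    y <- scale_values(fibres[[band$channel]], band$scale)
    b <- band_bounds(band, x)
    call <- factor(ifelse(y < b$lwr, "below",
                          ifelse(y > b$upr, "above", "within")),
                   levels = levels(lv))
    out <- dplyr::mutate(fibres, .x = x, .y = y, lwr = b$lwr, upr = b$upr,
                         call = call)
  }
  counts <- table(out$call)
  attr(out, "counts") <- c(above = unname(counts["above"]),
                           within = unname(counts["within"]),
                           below = unname(counts["below"]))
  out
}

#' Counts of above/within/below calls
#'
#' @param calls Result of [classify_2dmito()].
#' @return Named integer vector `(above, within, below)`.
#' @export
call_counts <- function(calls) {
  attr(calls, "counts") %||%
    c(above = sum(calls$call == "above"),
      within = sum(calls$call == "within"),
      below = sum(calls$call == "below"))
}

#' Theta: the 2Dmito angle of a fibre
#'
#' The angle, in degrees, that the point (reference, target) makes with
#' the origin and the x-axis of a 2Dmito plot: `atan2(y, x) * 180 / pi`.
#' Theta summarises target expression relative to mitochondrial mass in a
#' single number: on the log scale control fibres sit around 45--70
#' degrees, and deficiency pushes theta towards 0. Both coordinates must
#' be non-negative and on the same scale as the plot; a fibre with both
#' coordinates zero has no angle and returns `NA` with a warning (such
#' fibres are excluded from density estimates).
#'
#' @param y Target intensity (vectorised).
#' @param x Reference intensity (vectorised).
#'
#' @return Numeric vector of angles in `[0, 90]` degrees (`NA` where
#'   undefined).
#' @examples
#' theta(1, 1)   # 45
#' theta(sqrt(3), 1)  # 60
#' @export
theta <- function(y, x) {
  if (any(x < 0 | y < 0, na.rm = TRUE)) abort("theta needs x >= 0 and y >= 0")
  out <- atan2(y, x) * 180 / pi
  both0 <- x == 0 & y == 0
  if (any(both0, na.rm = TRUE)) {
    warn("theta undefined where both coordinates are zero; returning NA")
    out[both0] <- NA_real_
  }
  out
}

#' Kernel density estimate of a theta distribution
#'
#' Gaussian-kernel density on a 512-point grid spanning the data plus
#' three bandwidths each side (Silverman's rule-of-thumb bandwidth), with
#' linear interpolation between grid points and zero density outside the
#' grid. This is the probability density used to compare the likelihood of
#' a theta value under the control and patient populations.
#'
#' @param values Numeric vector of at least 2 finite values (degrees).
#' @param bw Bandwidth rule or value, passed to [stats::density()];
#'   default `"nrd0"`.
#' @param source Optional label (`"control"` or `"patient"`).
#'
#' @return An object of class `pdf_estimate` with fields `x` (grid), `y`
#'   (density), `bw`, `source`; evaluate it with [pdf_eval()].
#' @export
kde_pdf <- function(values, bw = "nrd0", source = NA_character_) {
  values <- values[is.finite(values)]
  if (length(values) < 2) abort("need at least 2 finite values")
  if (sd(values) == 0 && is.character(bw)) {
    warn("zero-variance sample: falling back to a minimal positive bandwidth")
    bw <- max(abs(values[1]) * 1e-3, 1e-3)
  }
  d <- density(values, bw = bw, n = 512, cut = 3)
  structure(list(x = d$x, y = d$y, bw = d$bw, n = length(values),
                 source = source),
            class = "pdf_estimate")
}

#' Evaluate a density estimate at arbitrary points
#'
#' Linear interpolation on the KDE grid; zero outside the grid.
#'
#' @param pdf A [kde_pdf()] result.
#' @param at Numeric vector of evaluation points.
#' @return Numeric vector of densities.
#' @export
pdf_eval <- function(pdf, at) {
  stopifnot(inherits(pdf, "pdf_estimate"))
  approxfun(pdf$x, pdf$y, yleft = 0, yright = 0)(at)
}

#' @export
print.pdf_estimate <- function(x, ...) {
  cat(sprintf("<pdf_estimate> n = %d, bw = %.3f, grid [%.2f, %.2f]%s\n",
              x$n, x$bw, min(x$x), max(x$x),
              if (is.na(x$source)) "" else paste0(", source = ", x$source)))
  invisible(x)
}

#' Central percentile range of control thetas
#'
#' The central `level` interval of the control theta sample, i.e. the
#' `[(1-level)/2, 1-(1-level)/2]` empirical quantiles (2.5th and 97.5th
#' percentiles at the default level). Used as the second gate of the
#' theta/KDE classifier: only fibres outside this range can be called
#' affected.
#'
#' @param control Numeric vector of control thetas.
#' @param level Coverage level, default 0.95.
#' @return Numeric length-2 vector `c(lower, upper)`.
#' @export
theta_percentile_range <- function(control, level = 0.95) {
  if (level <= 0 || level >= 1) abort("level must be in (0, 1)")
  a <- (1 - level) / 2
  unname(quantile(control, c(a, 1 - a), na.rm = TRUE))
}

#' Theta/KDE likelihood classification of patient fibres
#'
#' A patient fibre is called `affected` when (i) the likelihood of its
#' theta under the patient-population density exceeds its likelihood
#' under the control density, and (ii) its theta lies outside the central
#' `level` percentile range of control thetas. The percentile gate keeps
#' the false-positive rate of the classifier near `1 - level` when the
#' patient fibres are in fact control-like. The patient density is
#' estimated from all patient fibres, including the fibre being
#' classified (no leave-one-out).
#'
#' @param patient_thetas,control_thetas Numeric vectors (>= 2 finite
#'   values each), in degrees.
#' @param level Percentile-gate level, default 0.95.
#' @param bw Bandwidth rule for [kde_pdf()].
#'
#' @return A tibble with one row per patient fibre: `theta`,
#'   `lik_patient`, `lik_control`, `outside_range`, `affected`.
#' @examples
#' ctrl <- rnorm(500, 55, 8)
#' pat <- c(rnorm(300, 55, 8), rnorm(200, 15, 5))  # mixed-deficiency patient
#' mean(classify_theta_kde(pat, ctrl)$affected)
#' @export
classify_theta_kde <- function(patient_thetas, control_thetas, level = 0.95,
                               bw = "nrd0") {
  patient_thetas <- patient_thetas[is.finite(patient_thetas)]
  control_thetas <- control_thetas[is.finite(control_thetas)]
  if (length(patient_thetas) < 2 || length(control_thetas) < 2) {
    abort("both populations need at least 2 finite theta values")
  }
  ppdf <- kde_pdf(patient_thetas, bw = bw, source = "patient")
  cpdf <- kde_pdf(control_thetas, bw = bw, source = "control")
  rng <- theta_percentile_range(control_thetas, level)
  lp <- pdf_eval(ppdf, patient_thetas)
  lc <- pdf_eval(cpdf, patient_thetas)
  outside <- patient_thetas < rng[1] | patient_thetas > rng[2]
  tibble(theta = patient_thetas, lik_patient = lp, lik_control = lc,
         outside_range = outside, affected = lp > lc & outside)
}

#' Pairwise Pearson correlation of per-fibre thetas across channels
#'
#' Computes theta for every fibre and channel against the reference, then
#' the channel-by-channel Pearson correlation matrix over fibres
#' (pairwise-complete). Strong off-diagonal blocks indicate subunits whose
#' relative expression co-varies across fibres (e.g. two subunits of the
#' same OXPHOS complex).
#'
#' @param fibres Data frame with the channel and reference columns.
#' @param channels Character vector of target channel names (>= 2).
#' @param reference Reference channel, default `"VDAC1"`.
#' @param scale `"log"` or `"linear"`, as in [fit_control_band()].
#'
#' @return Symmetric correlation matrix with unit diagonal; entries for
#'   constant theta columns are `NA` (with a warning).
#' @export
theta_correlation_matrix <- function(fibres, channels, reference = "VDAC1",
                                     scale = c("log", "linear")) {
  scale <- match.arg(scale)
  if (length(channels) < 2) abort("need at least 2 channels")
  if (nrow(fibres) < 3) abort("need at least 3 fibres")
  x <- scale_values(fibres[[reference]], scale)
  th <- vapply(channels, function(ch) {
    theta(scale_values(fibres[[ch]], scale), x)
  }, numeric(nrow(fibres)))
  if (any(apply(th, 2, function(v) sd(v, na.rm = TRUE) == 0))) {
    warn("constant theta column: correlation undefined (NA)")
  }
  suppressWarnings(cor(th, use = "pairwise.complete.obs"))
}
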