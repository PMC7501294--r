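# Regression predictive band, theta, KDE likelihood classification.

test_that("a zero-residual fit collapses the band onto the line", {
  ctrl <- tibble::tibble(VDAC1 = exp(1:5), CH = exp(2 * (1:5)))
  band <- fit_control_band(ctrl, "CH")   # log scale: y = 2x exactly
  expect_equal(band$slope, 2, tolerance = 1e-10)
  expect_equal(band$intercept, 0, tolerance = 1e-9)
  expect_equal(band$sigma, 0, tolerance = 1e-9)
  bb <- band_bounds(band, 3)
  expect_equal(bb$lwr, bb$upr, tolerance = 1e-8)
  expect_equal(bb$fit, 6, tolerance = 1e-9)
})

test_that("band bounds match predict.lm's prediction interval", {
  x <- 1:5
  y <- x + c(0.1, -0.1, 0.2, -0.2, 0)
  d <- tibble::tibble(VDAC1 = x, CH = y)
  band <- fit_control_band(d, "CH", level = 0.95, scale = "linear")
  got <- band_bounds(band, 3)
  # independent oracle: stats::predict.lm interval = "prediction"
  fit <- lm(y ~ x)
  exp_ <- predict(fit, newdata = data.frame(x = 3),
                  interval = "prediction", level = 0.95)
  expect_equal(got$fit, exp_[1, "fit"], tolerance = 1e-12)
  expect_equal(got$lwr, exp_[1, "lwr"], tolerance = 1e-12)
  expect_equal(got$upr, exp_[1, "upr"], tolerance = 1e-12)
})

test_that("band width grows monotonically with the level", {
  ctrl <- sample_fibre_table(control_model(), 100, seed = 2)
  widths <- vapply(c(0.5, 0.8, 0.95, 0.99, 0.999), function(lv) {
    b <- band_bounds(fit_control_band(ctrl, "NDUFB8", level = lv), 5)
    b$upr - b$lwr
  }, numeric(1))
  expect_true(all(diff(widths) > 0))
})

test_that("band fitting validates its inputs", {
  expect_error(fit_control_band(tibble::tibble(VDAC1 = 1:2, CH = 1:2), "CH"),
               "at least 3")
  expect_error(fit_control_band(
    tibble::tibble(VDAC1 = rep(2, 5), CH = 1:5), "CH"), "zero variance")
  expect_error(fit_control_band(
    tibble::tibble(VDAC1 = 1:5, CH = 1:5), "CH", level = 1), "level")
  expect_error(fit_control_band(tibble::tibble(a = 1:5), "CH"), "missing")
})

test_that("2Dmito calls split on the band as expected", {
  ctrl <- sample_fibre_table(control_model(), 500, seed = 3)
  band <- fit_control_band(ctrl, "NDUFB8")
  # a fibre exactly on the regression line is within
  x0 <- 5
  y0 <- exp(band$intercept + band$slope * x0)
  on_line <- tibble::tibble(VDAC1 = exp(x0), NDUFB8 = y0)
  expect_equal(as.character(classify_2dmito(on_line, band)$call), "within")
  # empty table: zero counts, correct shape
  empty <- classify_2dmito(ctrl[0, ], band)
  expect_equal(nrow(empty), 0)
  expect_equal(unname(call_counts(empty)), c(0L, 0L, 0L))
  expect_error(classify_2dmito(tibble::tibble(a = 1), band), "lack")
})

test_that("strong suppression of a labelled subset is recovered as below", {
  ctrl <- sample_fibre_table(control_model(), 1000, seed = 4)
  band <- fit_control_band(ctrl, "NDUFB8")
  pat <- sample_fibre_table(control_model(), 2000, deficient_fraction = 0.3,
                            deficiency_factor = 0.1, seed = 5)
  calls <- classify_2dmito(pat, band)
  frac_below <- mean(calls$call == "below")
  expect_lt(abs(frac_below - 0.3), 0.035)  # within ~3 percentage points
  # the truly deficient fibres are the ones called below
  expect_gt(mean(calls$call[pat$deficient] == "below"), 0.99)
})

test_that("theta reproduces the textbook angles and flags the origin", {
  expect_equal(theta(1, 1), 45)
  expect_equal(theta(0, 1), 0)
  expect_equal(theta(sqrt(3), 1), 60)
  expect_warning(th <- theta(c(0, 1), c(0, 1)), "undefined")
  expect_true(is.na(th[1]) && th[2] == 45)
  expect_error(theta(-1, 1), "x >= 0")
})

test_that("theta is invariant to joint positive rescaling", {
  y <- withr::with_seed(7, runif(50, 1, 100))
  x <- withr::with_seed(8, runif(50, 1, 100))
  for (s in c(0.1, 3, 1000)) {
    expect_equal(theta(s * y, s * x), theta(y, x), tolerance = 1e-12)
  }
})

test_that("KDE matches normal-theory location and integrates to one", {
  th <- withr::with_seed(10, rnorm(1e4, 45, 5))
  pdf <- kde_pdf(th)
  expect_equal(pdf$x[which.max(pdf$y)], 45, tolerance = 1 / 45)
  area <- sum(diff(pdf$x) * (head(pdf$y, -1) + tail(pdf$y, -1)) / 2)
  expect_equal(area, 1, tolerance = 0.01)
  # interpolation: zero outside the grid, positive at the mode
  expect_equal(pdf_eval(pdf, c(min(pdf$x) - 1, max(pdf$x) + 1)), c(0, 0))
  expect_gt(pdf_eval(pdf, 45), 0.05)
})

test_that("two-point KDE is symmetric about the midpoint", {
  pdf <- kde_pdf(c(30, 60))
  expect_equal(pdf_eval(pdf, 30), pdf_eval(pdf, 60), tolerance = 1e-6)
  expect_equal(sum(pdf$x * pdf$y) / sum(pdf$y), 45, tolerance = 0.1)
})

test_that("KDE guards degenerate inputs", {
  expect_error(kde_pdf(5), "at least 2")
  expect_warning(pdf <- kde_pdf(rep(45, 10)), "bandwidth")
  expect_gt(pdf_eval(pdf, 45), 0)
})

test_that("theta/KDE classifier calls displaced fibres and spares the null", {
  ctrl <- withr::with_seed(20, rnorm(2000, 55, 8))
  # patient with a strong deficient mode far below the control range
  pat <- withr::with_seed(21, c(rnorm(300, 55, 8), rnorm(300, 15, 4)))
  res <- classify_theta_kde(pat, ctrl)
  expect_gt(mean(res$affected[pat < 30]), 0.98)
  # a fibre at the control median is never affected
  med <- median(ctrl)
  expect_false(res$affected[which.min(abs(pat - med))])
  # null patient: percentile gate bounds the affected fraction near 5%
  null_pat <- withr::with_seed(22, rnorm(10000, 55, 8))
  res0 <- classify_theta_kde(null_pat, ctrl)
  expect_lt(mean(res0$affected), 0.07)
  expect_error(classify_theta_kde(1, ctrl), "at least 2")
})

test_that("band and KDE classifiers agree on extreme fibres", {
  ctrl <- sample_fibre_table(control_model(), 1000, seed = 30)
  band <- fit_control_band(ctrl, "NDUFB8")
  pat <- sample_fibre_table(control_model(), 500, deficient_fraction = 0.3,
                            deficiency_factor = 0.05, seed = 31)
  cl <- classify_2dmito(pat, band)
  th_ctrl <- theta(log(ctrl$NDUFB8), log(ctrl$VDAC1))
  th_pat <- theta(cl$.y, cl$.x)
  kde <- classify_theta_kde(th_pat, th_ctrl)
  extreme <- cl$call == "below" & th_pat < min(th_ctrl)
  expect_gt(sum(extreme), 0)
  expect_true(all(kde$affected[extreme]))
})

test_that("called-below fraction is monotone in suppression strength", {
  ctrl <- sample_fibre_table(control_model(), 1000, seed = 40)
  band <- fit_control_band(ctrl, "NDUFB8")
  fracs <- vapply(c(0.8, 0.4, 0.1), function(fac) {
    pat <- sample_fibre_table(control_model(), 1000, 0.3, fac, seed = 41)
    mean(classify_2dmito(pat, band)$call == "below")
  }, numeric(1))
  expect_true(all(diff(fracs) >= 0))
})

test_that("theta correlation matrix matches direct Pearson computation", {
  # intensities constructed so that (linear-scale) thetas are exactly the
  # worked values A = (10,20,30,40), B = (12,18,33,37) degrees
  thA <- c(10, 20, 30, 40); thB <- c(12, 18, 33, 37)
  fib <- tibble::tibble(REF = 1, A = tan(thA * pi / 180),
                        B = tan(thB * pi / 180))
  cm <- theta_correlation_matrix(rbind(fib, fib[1, ]), c("A", "B"),
                                 reference = "REF", scale = "linear")
  # oracle: direct formula on 5 paired thetas
  a5 <- c(thA, thA[1]); b5 <- c(thB, thB[1])
  r <- sum((a5 - mean(a5)) * (b5 - mean(b5))) /
    sqrt(sum((a5 - mean(a5))^2) * sum((b5 - mean(b5))^2))
  expect_equal(cm["A", "B"], r, tolerance = 1e-12)
  expect_equal(diag(cm), c(A = 1, B = 1))
  expect_equal(cm, t(cm))
})

test_that("duplicated and mirrored channels give correlations 1 and -1", {
  th <- c(20, 35, 50, 65)
  fib <- tibble::tibble(REF = 1, A = tan(th * pi / 180),
                        A2 = tan(th * pi / 180),
                        M = tan((90 - th) * pi / 180))
  cm <- theta_correlation_matrix(fib, c("A", "A2", "M"),
                                 reference = "REF", scale = "linear")
  expect_equal(cm["A", "A2"], 1, tolerance = 1e-12)
  expect_equal(cm["A", "M"], -1, tolerance = 1e-12)
  # constant theta column flagged as NA
  fib$C <- tan(45 * pi / 180)
  expect_warning(cm2 <- theta_correlation_matrix(
    fib, c("A", "C"), reference = "REF", scale = "linear"), "constant")
  expect_true(is.na(cm2["A", "C"]))
})

test_that("tidy and glance summarise a band", {
  ctrl <- sample_fibre_table(control_model(), 100, seed = 50)
  band <- fit_control_band(ctrl, "NDUFB8")
  td <- generics::tidy(band)
  expect_equal(td$term, c("(Intercept)", "VDAC1"))
  gl <- generics::glance(band)
  expect_equal(gl$n_control, 100)
  expect_equal(gl$level, 0.95)
})
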