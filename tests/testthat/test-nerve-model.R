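test_that("stimulus normalization anchors P1 at zero and is unit-free", {
  expect_equal(normalize_stimulus(c(100, 110, 120, 130, 140)),
               c(0, 50 / 7, 100 / 7, 150 / 7, 200 / 7))
  set.seed(4)
  for (i in 1:20) {
    lev <- sort(runif(5, 0.5, 5))
    x <- normalize_stimulus(lev)
    expect_equal(x[1], 0)
    expect_true(all(diff(x) > 0))
    expect_equal(normalize_stimulus(lev * runif(1, 0.1, 10)), x)
  }
  expect_error(normalize_stimulus(c(3, 2, 1)), "increasing")
})

test_that("baseline normalization divides by the initial condition's maximal response", {
  m <- cmap_matrix(rbind(c(100, 200, 300, 400, 500),
                         c(50, 100, 150, 200, 250),
                         c(80, 80, 80, 80, 80),
                         c(10, 20, 30, 40, 50)))
  expect_equal(unname(normalize_baseline(m, 0)), c(0, 20, 40, 60, 80))
  expect_equal(unname(normalize_baseline(m, 2)), rep(0, 5))  # flat responses
  # an injured row at half the baseline row gives half the normalized curve
  expect_equal(normalize_baseline(m, 1), normalize_baseline(m, 0) / 2)

  degen <- cmap_matrix(rbind(c(0, 0, 0, 0, 0), diag(0, 3, 5) + 1))
  expect_error(normalize_baseline(degen, 1), "baseline response absent")
})

test_that("per-trial normalization is self-scaled and equals Eq-3 form on the baseline", {
  m <- cmap_matrix(rbind(c(100, 200, 300, 400, 500),
                         c(50, 100, 150, 200, 250),
                         c(80, 80, 80, 80, 80),
                         c(10, 20, 30, 40, 50)))
  expect_equal(unname(normalize_per_trial(m, 0)), c(0, 20, 40, 60, 80))
  expect_equal(normalize_per_trial(m, 0), normalize_baseline(m, 0))
  # invariance under uniform scaling of a condition's responses
  expect_equal(normalize_per_trial(m, 1), normalize_per_trial(m, 0))
  expect_equal(normalize_per_trial(m, 3), normalize_per_trial(m, 0))

  m$vpp[4, ] <- 0
  expect_error(normalize_per_trial(m, 3), "non-conducting")

  set.seed(6)
  for (i in 1:50) {
    m <- rand_cmap_matrix()
    expect_equal(normalize_per_trial(m, 0), normalize_baseline(m, 0))
    expect_equal(normalize_per_trial(m, 2)[1], 0, ignore_attr = TRUE)
    c_scale <- runif(1, 0.1, 5)
    m2 <- m; m2$vpp[3, ] <- m2$vpp[3, ] * c_scale
    expect_equal(normalize_per_trial(m2, 2), normalize_per_trial(m, 2))
    expect_equal(normalize_baseline(m2, 2), normalize_baseline(m, 2) * c_scale)
  }
})

test_that("the linear fit solves ordinary least squares with named coefficients", {
  f <- fit_nerve_model(c(0, 1, 2), c(1, 3, 5))
  expect_equal(coef(f), c(a = 2, b = 1))
  expect_equal(f$residual_ss, 0)

  f2 <- fit_nerve_model(c(0, 5, 9, 20), rep(7, 4))
  expect_equal(coef(f2), c(a = 0, b = 7))

  expect_error(fit_nerve_model(rep(3, 5), 1:5), "singular")

  set.seed(8)
  for (i in 1:200) {
    x <- runif(5, 0, 30)
    y <- runif(1, -4, 4) * x + runif(1, -4, 4) + rnorm(5)
    f <- fit_nerve_model(x, y)
    # closed-form covariance/variance oracle
    a_ref <- cov(x, y) / var(x)
    expect_equal(f$a, a_ref, tolerance = 1e-9)
    expect_equal(f$b, mean(y) - a_ref * mean(x), tolerance = 1e-9)
    # independent implementation oracle
    lm_ref <- unname(coef(lm(y ~ x)))
    expect_equal(unname(coef(f)), rev(lm_ref), tolerance = 1e-9)
    expect_equal(f$residual_ss, sum(residuals(f)^2))
    expect_equal(predict(f, 10), f$a * 10 + f$b)
  }
})

test_that("noiseless linear recruitment is recovered to machine precision", {
  # 160 equally spaced thresholds over (1, 1.4], unit amplitudes: the
  # recruitment curve is exactly linear and the per-trial slope is 100/x5
  pop <- axon_population(thresholds = 1 + (1:160) / 160 * 0.4,
                         amps = rep(1, 160))
  v <- simulate_amplitudes(pop, injury_model(), 0, noise_sd_uv = 0, seed = 1)
  expect_equal(as.numeric(v), c(0, 40, 80, 120, 160))
  m <- cmap_matrix(rbind(as.numeric(v), matrix(NA, 3, 5)), partial = TRUE)
  # per-trial curve: y = (v - 0)/160 * 100, slope exactly 3.5 = 100/(200/7)
  f <- fit_nerve_model(normalized_curve(m, 0, "per_trial"))
  expect_equal(f$a, 3.5, tolerance = 1e-12)
  expect_equal(f$b, 0, tolerance = 1e-9)
})

test_that("cohort fitting tabulates parameters and flags non-conducting conditions", {
  set.seed(10)
  mats <- list(rand_cmap_matrix("s1"), rand_cmap_matrix("s2"))
  mats[[2]]$vpp[4, ] <- 0  # damage3 non-conducting
  params <- fit_cohort(mats)
  expect_equal(nrow(params), 16)  # 2 subjects x 4 conditions x 2 modes
  nc <- attr(params, "non_conducting")
  expect_equal(unique(nc$subject), "s2")
  expect_equal(unique(nc$condition), 3)
  expect_equal(unique(nc$mode), "per_trial")
  s2d3 <- params[params$subject == "s2" & params$condition == 3, ]
  # per-trial normalization has a zero denominator: flagged, not fitted
  expect_true(is.na(s2d3$a[s2d3$mode == "per_trial"]))
  # the baseline-normalized curve of a silent nerve is identically zero
  expect_equal(s2d3$a[s2d3$mode == "baseline"], 0)
})

test_that("CMAP matrices round-trip through the long CSV format", {
  set.seed(12)
  mats <- list(rand_cmap_matrix("s1"), rand_cmap_matrix("s2"))
  tf <- withr::local_tempfile(fileext = ".csv")
  write_cmap_csv(mats, tf)
  back <- read_cmap_csv(tf)
  expect_equal(back[["s1"]]$vpp, mats[[1]]$vpp, tolerance = 1e-8)
  expect_equal(back[["s2"]]$vpp, mats[[2]]$vpp, tolerance = 1e-8)
})
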