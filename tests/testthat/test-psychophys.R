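test_that("Michelson contrast matches the display luminances", {
  expect_equal(michelson_contrast(43.8, 43.8), 0)
  # psychophysics display: bar 78.9, background 43.8 cd/m^2
  expect_equal(michelson_contrast(78.9, 43.8), 0.28606, tolerance = 1e-4)
  # scanner display: bar 87.5, background 0.4 cd/m^2
  expect_equal(michelson_contrast(87.5, 0.4), 0.99090, tolerance = 1e-4)
  expect_error(michelson_contrast(1, 0), "positive")
  expect_error(michelson_contrast(1, 2), ">=")
})

test_that("Weibull observer has 2AFC range and hits the criterion", {
  obs <- make_weibull_observer(0.1, 3, lapse = 0.02)
  expect_equal(obs(0), 0.5)
  expect_equal(obs(1e6), 1 - 0.02 / 2, tolerance = 1e-9)
  obs0 <- make_weibull_observer(0.1, 3, lapse = 0)
  expect_equal(obs0(1e6), 1, tolerance = 1e-9)
  # calibration: criterion accuracy exactly at the threshold contrast
  expect_equal(obs(0.1), 0.80, tolerance = 1e-12)
  cc <- seq(0, 0.5, 0.01)
  expect_true(all(diff(obs(cc)) >= 0))
  expect_error(make_weibull_observer(-1, 3), "positive")
  expect_error(make_weibull_observer(0.1, 0), "positive")
})

test_that("staircase limits, bounds and determinism", {
  always_right <- function(contrast) rep(1, length(contrast))
  always_wrong <- function(contrast) rep(0, length(contrast))
  lo <- 1e-3
  hi <- michelson_contrast(78.9, 43.8)
  down <- run_staircase(always_right, n_trials = 200, seed = 1)
  expect_equal(down$contrast[200], lo)
  up <- run_staircase(always_wrong, n_trials = 200, seed = 1)
  expect_equal(up$contrast[200], hi)
  expect_true(all(down$contrast >= lo & down$contrast <= hi))
  obs <- make_weibull_observer(0.05, 3)
  a <- run_staircase(obs, seed = 42)
  b <- run_staircase(obs, seed = 42)
  expect_identical(a, b)
  expect_false(identical(a, run_staircase(obs, seed = 43)))
})

test_that("3-down-1-up converges near the 79.4% point", {
  # long staircases: asymptotic accuracy approaches 0.5^(1/3)
  acc <- vapply(1:20, function(s) {
    obs <- make_weibull_observer(0.06, 3)
    tr <- run_staircase(obs, n_trials = 600, seed = s)
    mean(tr$correct[401:600])
  }, numeric(1))
  expect_gte(mean(acc), 0.76)
  expect_lte(mean(acc), 0.83)
})

test_that("Weibull fit recovers simulated observers", {
  sims <- vapply(1:50, function(s) {
    thr <- exp(stats::runif(1, log(0.04), log(0.2)))
    obs <- make_weibull_observer(thr, slope = 3)
    tr <- do.call(rbind, lapply(1:4, function(k) {
      run_staircase(obs, seed = derive_seed(s, k), staircase_id = k)
    }))
    fit_weibull(tr)$threshold / thr
  }, numeric(1))
  # median recovered threshold within 15% of truth
  expect_lt(abs(stats::median(sims) - 1), 0.15)
})

test_that("Weibull fit is order invariant and scale equivariant", {
  obs <- make_weibull_observer(0.08, 3)
  tr <- do.call(rbind, lapply(1:4, function(k) {
    run_staircase(obs, seed = k, staircase_id = k)
  }))
  f1 <- fit_weibull(tr)
  f2 <- fit_weibull(tr[sample.int(nrow(tr)), ])
  expect_equal(f1$threshold, f2$threshold, tolerance = 1e-8)
  tr3 <- tr
  tr3$contrast <- tr3$contrast * 3
  f3 <- fit_weibull(tr3)
  expect_equal(f3$threshold, 3 * f1$threshold, tolerance = 1e-4)
  expect_equal(f3$slope, f1$slope, tolerance = 1e-4)
  expect_equal(f1$sensitivity * f1$threshold, 1)
  # fitted curve passes through the criterion at the threshold
  expect_equal(predict(f1, f1$threshold), f1$criterion, tolerance = 1e-6)
})

test_that("non-identifiable trial data is rejected with a diagnostic", {
  tr <- data.frame(contrast = c(0.1, 0.2, 0.1, 0.2),
                   correct = c(TRUE, TRUE, TRUE, TRUE))
  expect_error(fit_weibull(tr), "all 4 responses are correct")
  tr$correct <- FALSE
  expect_error(fit_weibull(tr), "incorrect")
  expect_error(fit_weibull(data.frame(contrast = rep(0.1, 6),
                                      correct = rep(c(TRUE, FALSE), 3))),
               "distinct contrast")
})

test_that("behavioural saliency sensitivity is the sensitivity difference", {
  expect_equal(behavioral_saliency_sensitivity(10, 10), 0)
  # sensitivities reported for the two orientation contrasts
  expect_equal(behavioral_saliency_sensitivity(18.719, 9.720), 8.999)
  expect_equal(behavioral_saliency_sensitivity(9.720, 18.719), -8.999)
})
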