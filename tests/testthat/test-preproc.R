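make_series <- function(nulled_fun, notnulled_fun, n_pairs = 100,
                        paired_tr = 5.02, n_runs = 1) {
  tt <- (seq_len(2 * n_pairs * n_runs) - 1) * paired_tr / 2
  lab <- rep(c("nulled", "notnulled"), n_pairs * n_runs)
  x <- ifelse(lab == "nulled", nulled_fun(tt), notnulled_fun(tt))
  laminar_series(rbind(x), tt, lab,
                 rep(seq_len(n_runs), each = 2 * n_pairs))
}

test_that("alignment reproduces constants and linear ramps exactly", {
  s <- make_series(function(t) 7, function(t) 3)
  al <- split_and_align(s)
  expect_equal(al$nulled[1, ], rep(7, ncol(al$nulled)))
  expect_equal(al$notnulled[1, ], rep(3, ncol(al$notnulled)))
  ramp <- function(t) 1 + 0.25 * t
  s <- make_series(ramp, ramp, n_pairs = 50)
  al <- split_and_align(s)
  inner <- 2:(ncol(al$nulled) - 1) # edge-hold at the run ends
  expect_equal(al$nulled[1, inner], ramp(s$frame_times)[inner],
               tolerance = 1e-12)
  expect_equal(al$notnulled[1, inner], ramp(s$frame_times)[inner],
               tolerance = 1e-12)
})

test_that("alignment error on a slow sinusoid is within the linear bound", {
  ptr <- 5.02
  f <- 1 / (8 * ptr)
  s <- make_series(function(t) sin(2 * pi * f * t),
                   function(t) sin(2 * pi * f * t), n_pairs = 200)
  al <- split_and_align(s)
  truth <- sin(2 * pi * f * s$frame_times)
  rel_rms <- function(e) sqrt(mean(e^2)) / sqrt(mean(truth^2))
  bound <- (2 * pi * f * ptr)^2 / 8 # midpoint error of linear interpolation
  expect_lt(rel_rms(al$nulled[1, ] - truth), bound)
  expect_lt(rel_rms(al$notnulled[1, ] - truth), bound)
})

test_that("misordered frame labels are rejected", {
  s <- make_series(function(t) 1, function(t) 1, n_pairs = 4)
  s$frame_labels <- rev(s$frame_labels)
  expect_error(split_and_align(s), "alternate")
})

test_that("BOCO division: identity, forward model, scale invariance", {
  n <- matrix(rep(1:10, 2), 2, 10, byrow = TRUE)
  v <- boco_correct(n, n)
  expect_equal(v$data, matrix(1, 2, 10))
  expect_equal(percent_signal_change(v)$data, matrix(0, 2, 10))
  # 2% nulled dip during blocks -> +2% CBV response
  box <- rep(c(0, 1), each = 10)
  nulled <- 100 * (1 - 0.02 * (box - mean(box)))
  notnull <- rep(100, 20)
  cbv <- percent_signal_change(boco_correct(rbind(nulled), rbind(notnull)),
                               sign = "cbv")
  expect_equal(unname(diff(range(cbv$data))), 2, tolerance = 1e-9)
  # doubling both streams leaves the ratio unchanged
  v2 <- boco_correct(2 * n, 2 * n)
  expect_equal(v2$data, v$data)
})

test_that("nonpositive not-nulled samples mask the voxel with a warning", {
  n <- matrix(1, 2, 6)
  b <- matrix(1, 2, 6)
  b[2, 3] <- 0
  expect_warning(v <- boco_correct(n, b), "1 voxel")
  expect_true(all(is.na(v$data[2, ])))
  expect_true(all(is.finite(v$data[1, ])))
  expect_equal(v$masked, 2L)
})

test_that("percent signal change is per-run mean-zero", {
  set.seed(5)
  x <- matrix(rexp(3 * 40) + 1, 3, 40)
  run <- rep(1:2, each = 20)
  p <- percent_signal_change(x, run)
  expect_equal(rowMeans(p[, run == 1]), rep(0, 3), tolerance = 1e-12)
  expect_equal(rowMeans(p[, run == 2]), rep(0, 3), tolerance = 1e-12)
  # constructed 1% boxcar scales to 1% (boxcar centred within the run)
  box <- rep(c(-0.5, 0.5), 10)
  y <- rbind(100 * (1 + 0.01 * box))
  p <- percent_signal_change(y, rep(1L, 20))
  expect_equal(max(p) - min(p), 1, tolerance = 1e-9)
})

test_that("GLM recovers a noiseless regressor multiple exactly", {
  d <- tiny_design()
  fr <- design_frames(d)
  X <- lamsal:::condition_regressors(d, fr$times, fr$run, aligned = TRUE)
  y <- 3 * X[, "cond_90"]
  ser <- structure(list(data = rbind(y), times = fr$times, run = fr$run),
                   class = "vaso_series")
  fit <- fit_glm(ser, d)
  expect_equal(unname(fit$betas[1, "cond_90"]), 3, tolerance = 1e-9)
  expect_equal(unname(fit$betas[1, "cond_15"]), 0, tolerance = 1e-9)
  expect_equal(unname(fit$betas[1, "cond_0"]), 0, tolerance = 1e-9)
  # adding a constant moves only the baseline (intercept) regressors
  ser2 <- ser
  ser2$data <- ser$data + 11
  fit2 <- fit_glm(ser2, d)
  cond_cols <- paste0("cond_", c("90", "15", "0"))
  expect_equal(fit2$betas[, cond_cols], fit$betas[, cond_cols],
               tolerance = 1e-9)
})

test_that("GLM beta variability matches OLS sampling theory", {
  d <- tiny_design()
  fr <- design_frames(d)
  nv <- 800 # voxels double as Monte-Carlo replicates
  set.seed(9)
  ser <- structure(list(data = matrix(rnorm(nv * length(fr$times)),
                                      nv, length(fr$times)),
                        times = fr$times, run = fr$run),
                   class = "vaso_series")
  fit <- fit_glm(ser, d)
  b90 <- fit$betas[, "cond_90"]
  expect_lt(abs(mean(b90)), 3 * sd(b90) / sqrt(nv))
  # empirical SD across replicates vs closed-form OLS SE (sigma = 1)
  X <- fit$X
  se_theory <- sqrt(chol2inv(chol(crossprod(X)))[1, 1])
  expect_equal(sd(b90), se_theory, tolerance = 0.1)
})

test_that("rank-deficient designs are reported with column names", {
  d <- tiny_design()
  fr <- design_frames(d)
  ser <- structure(list(data = rbind(rnorm(length(fr$times))),
                        times = fr$times, run = fr$run),
                   class = "vaso_series")
  dup <- matrix(1, length(fr$times), 1) # duplicates the intercepts
  colnames(dup) <- "dup"
  expect_error(fit_glm(ser, d, motion = dup), "collinear")
})

test_that("full chain is linear in the simulated gain", {
  m <- tiny_model()
  d <- tiny_design()
  sc1 <- exact_scenario()
  g3 <- sc1$gains * 3
  sc3 <- scenario_spec("v1sh", gains = g3, noise_sd = 0, drift_amp = 0,
                       bold_scale = 0)
  p1 <- estimate_profile(simulate_vaso_session(m, d, sc1), d, m, "V1")
  p3 <- estimate_profile(simulate_vaso_session(m, d, sc3), d, m, "V1")
  expect_equal(unclass(p3), 3 * unclass(p1), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("BOCO removes contamination applied identically to both streams", {
  m <- tiny_model()
  d <- tiny_design()
  sim <- simulate_vaso_session(m, d, exact_scenario())
  al <- split_and_align(sim)
  # reference betas without contamination
  ref <- condition_betas(fit_glm(
    percent_signal_change(boco_correct(al), sign = "cbv"), d))
  # identical multiplicative BOLD-like factor on both aligned streams
  fr <- design_frames(d)
  X <- lamsal:::condition_regressors(d, fr$times, fr$run, aligned = TRUE)
  bold <- 1 + 0.02 * rowSums(X)
  al2 <- al
  al2$nulled <- sweep(al$nulled, 2, bold, `*`)
  al2$notnulled <- sweep(al$notnulled, 2, bold, `*`)
  got <- condition_betas(fit_glm(
    percent_signal_change(boco_correct(al2), sign = "cbv"), d))
  expect_equal(got, ref, tolerance = 1e-3)
})
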