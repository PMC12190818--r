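test_that("unmixing inverts known mixtures", {
  W <- diag(5)
  colnames(W) <- c("WM", "CSF", "deep", "middle", "superficial")
  out <- unmix_layers(c(0, 0, 1, 2, 0.5), W)
  expect_equal(unname(out[, 1]), c(1, 2, 0.5))
  # construct-and-invert on random nonnegative weights
  set.seed(3)
  Wr <- matrix(rexp(40 * 5), 40, 5)
  Wr <- Wr / rowSums(Wr)
  colnames(Wr) <- colnames(W)
  truth <- c(WM = 0, CSF = 0, deep = 1, middle = 2, superficial = 0.5)
  y <- Wr %*% truth
  got <- unmix_layers(y, Wr)
  expect_equal(unname(got[, 1]), unname(truth[3:5]), tolerance = 1e-9)
  # adding pure-WM voxels with zero beta leaves GM estimates unchanged
  W2 <- rbind(Wr, matrix(rep(c(1, 0, 0, 0, 0), 5), 5, byrow = TRUE))
  colnames(W2) <- colnames(W)
  got2 <- unmix_layers(c(y, rep(0, 5)), W2)
  expect_equal(unname(got2[, 1]), unname(truth[3:5]), tolerance = 1e-9)
})

test_that("unmixing errors name unidentifiable compartments", {
  W <- cbind(WM = c(1, 1, 1), CSF = 0, deep = c(0, 1, 0.5),
             middle = c(0, 1, 0.5), superficial = 0)
  # deep and middle columns identical -> collinear
  expect_error(unmix_layers(c(1, 2, 1.5), W), "deep|middle")
  expect_error(unmix_layers(1:3, matrix(runif(12), 3, 4)), "fewer voxels",
               fixed = FALSE)
})

test_that("unmixing is unbiased under zero-mean noise", {
  set.seed(11)
  W <- matrix(rexp(60 * 5), 60, 5)
  W <- W / rowSums(W)
  colnames(W) <- c("WM", "CSF", "deep", "middle", "superficial")
  truth <- c(0.2, -0.1, 1, 2, 0.5)
  reps <- vapply(1:500, function(i) {
    y <- W %*% truth + rnorm(60, 0, 0.5)
    unmix_layers(y, W)[, 1]
  }, numeric(3))
  est <- rowMeans(reps)
  mc_se <- apply(reps, 1, sd) / sqrt(500)
  expect_true(all(abs(est - truth[3:5]) < 2.5 * mc_se))
})

test_that("ROI selection recovers a known active patch", {
  m <- tiny_model()
  d <- localizer_design(n_runs = 2)
  fr <- design_frames(d)
  X <- lamsal:::condition_regressors(d, fr$times, fr$run, aligned = TRUE)
  nv <- nrow(m$voxels)
  active <- which(m$voxels$region == "V1")[1:20]
  beta_true <- numeric(nv)
  beta_true[active] <- 1
  set.seed(21)
  noise_sd <- 0.2 # SNR 5
  data <- beta_true %o% (X[, "cond_left"] + X[, "cond_right"]) +
    matrix(rnorm(nv * nrow(X), 0, noise_sd), nv)
  ser <- structure(list(data = data, times = fr$times, run = fr$run,
                        voxel_region = m$voxels$region),
                   class = "vaso_series")
  fit <- fit_glm(ser, d)
  roi <- select_foreground_roi(fit, c("left", "right"), region = "V1")
  recall <- length(intersect(roi, active)) / length(active)
  precision <- length(intersect(roi, active)) / length(roi)
  expect_gte(recall, 0.9)
  expect_gte(precision, 0.9)
  # degenerate threshold admits the whole anatomical region
  roi_all <- select_foreground_roi(fit, c("left", "right"), region = "V1",
                                   alpha = 1)
  expect_true(all(which(m$voxels$region == "V1" & beta_true > 0) %in%
                    roi_all) ||
                length(roi_all) <= sum(m$voxels$region == "V1"))
  # all-zero betas -> empty ROI with warning
  fit0 <- fit
  fit0$betas[] <- 0
  expect_warning(r0 <- select_foreground_roi(fit0, "left"), "empty")
  expect_length(r0, 0)
})

test_that("ROI layer profile equals pure-voxel betas and ignores order", {
  W <- rbind(c(0, 0, 1, 0, 0), c(0, 0, 0, 1, 0), c(0, 0, 0, 0, 1))
  colnames(W) <- c("WM", "CSF", "deep", "middle", "superficial")
  betas <- cbind(`90` = c(1, 2, 3), `15` = c(0.5, 1, 1.5))
  prof <- roi_layer_profile(betas, W)
  expect_equal(unname(prof["deep", ]), c(1, 0.5))
  expect_equal(unname(prof["superficial", ]), c(3, 1.5))
  perm <- c(3, 1, 2)
  prof2 <- roi_layer_profile(betas[perm, ], W[perm, ])
  expect_equal(prof, prof2, tolerance = 1e-12)
  expect_error(roi_layer_profile(betas, W, integer(0)), "empty")
})
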