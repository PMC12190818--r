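test_that("scenario specifications enforce laminar orderings", {
  sc <- scenario_spec("v1sh")
  expect_gt(sc$gains["V1", "superficial", "90"], sc$gains["V1", "deep", "90"])
  expect_gt(sc$gains["IPS", "middle", "90"], sc$gains["IPS", "deep", "90"])
  fb <- scenario_spec("feedback_parietal")
  expect_equal(names(which.max(fb$gains["IPS", , "90"])), "deep")
  bad <- sc$gains
  bad["V1", "superficial", "90"] <- 0
  expect_error(scenario_spec("v1sh", gains = bad), "favour")
  bad2 <- sc$gains
  bad2[1] <- -1
  expect_error(scenario_spec("v1sh", gains = bad2), "nonnegative")
})

test_that("null scenario yields a flat series at baseline", {
  gains0 <- array(0, c(3, 3, 3))
  sc <- scenario_spec("sc_tectothalamic", gains = gains0, noise_sd = 0,
                      drift_amp = 0, bold_scale = 0)
  sim <- simulate_vaso_session(tiny_model(), tiny_design(), sc)
  expect_equal(sim$data, matrix(100, nrow(sim$data), ncol(sim$data)),
               ignore_attr = TRUE)
})

test_that("simulation is bitwise reproducible under a seed", {
  m <- tiny_model()
  d <- tiny_design()
  sc <- scenario_spec("v1sh", seed = 5)
  a <- simulate_vaso_session(m, d, sc)
  b <- simulate_vaso_session(m, d, sc)
  expect_identical(a, b)
  c2 <- simulate_vaso_session(m, d, sc, seed = 6)
  expect_false(identical(a$data, c2$data))
})

test_that("noiseless GLM beta after BOCO equals the generative gain", {
  m <- tiny_model()
  d <- tiny_design()
  sc <- exact_scenario()
  sim <- simulate_vaso_session(m, d, sc)
  cbv <- percent_signal_change(boco_correct(split_and_align(sim)),
                               sign = "cbv")
  cb <- condition_betas(fit_glm(cbv, d))
  # a voxel fully inside the superficial compartment of V1
  W <- layer_weights(m)
  vox <- which(m$voxels$region == "V1" & W[, "superficial"] == 1)[1]
  expect_false(is.na(vox))
  expect_equal(unname(cb[vox, "90"]), sc$gains["V1", "superficial", "90"],
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("VASO sign convention: activation dips the nulled frames", {
  m <- tiny_model()
  d <- tiny_design()
  sim <- simulate_vaso_session(m, d, exact_scenario())
  W <- layer_weights(m)
  vox <- which(W[, "superficial"] == 1)[1]
  sel <- sim$frame_labels == "nulled"
  nulled <- sim$data[vox, sel]
  fr <- design_frames(d)
  X <- lamsal:::condition_regressors(d, fr$times, fr$run,
                                     aligned = FALSE)[, "cond_90"]
  # activation decreases the nulled signal
  expect_lt(cor(nulled, X[sel]), -0.9)
  # and raises the not-nulled (BOLD) signal when the BOLD channel is on
  sim2 <- simulate_vaso_session(m, d, scenario_spec("v1sh", noise_sd = 0,
                                                    drift_amp = 0,
                                                    bold_scale = 2))
  notn <- sim2$data[vox, !sel]
  expect_gt(cor(notn, X[!sel]), 0.9)
})

test_that("gaze simulation: degenerate cases and statistics", {
  g0 <- simulate_gaze(1000, sd_x = 0, sd_y = 0, blink_rate = 0, seed = 1)
  expect_true(all(g0$x == 0 & g0$y == 0))
  expect_true(all(g0$valid))
  g <- simulate_gaze(1e5, sd_x = 1, sd_y = 1, rho = 0, blink_rate = 0,
                     seed = 2)
  expect_lt(abs(cor(g$x, g$y)), 0.05)
  expect_equal(sd(g$x), 1, tolerance = 0.02)
  gb <- simulate_gaze(5000, blink_rate = 2, seed = 3)
  expect_true(any(!gb$valid))
  expect_true(all(is.na(gb$x[!gb$valid])))
  expect_identical(simulate_gaze(500, seed = 9), simulate_gaze(500, seed = 9))
})

test_that("series container validates its invariants", {
  expect_error(laminar_series(matrix(1, 1, 4), c(0, 1, 1, 2),
                              rep(c("nulled", "notnulled"), 2), rep(1, 4)),
               "increasing")
  expect_error(laminar_series(matrix(1, 1, 4), 0:3,
                              c("nulled", "nulled", "nulled", "notnulled"),
                              rep(1, 4)),
               "unequal")
})
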