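ppi_grid <- function(n_runs = 2) {
  d <- block_design(n_runs = n_runs, seed = 4)
  fr <- design_frames(d)
  sel <- fr$labels == "notnulled" # BOLD stream grid
  list(design = d, times = fr$times[sel], run = fr$run[sel])
}

test_that("PPI terms are the shifted boxcar gated by the seed", {
  g <- ppi_grid()
  ones <- rep(1, length(g$times))
  # a unit seed makes PPI == boxcar (rank-deficient by construction, so
  # only the column structure is inspected)
  pd <- build_ppi_design(ones, g$design, g$times, g$run,
                         check_rank = FALSE)
  B <- pd$X[, pd$box_cols]
  P <- pd$X[, pd$ppi_cols]
  expect_equal(unname(P), unname(B))
  # PPI vanishes wherever the shifted boxcar is zero
  set.seed(10)
  seed_tc <- rnorm(length(g$times))
  pd2 <- build_ppi_design(seed_tc, g$design, g$times, g$run)
  P2 <- pd2$X[, pd2$ppi_cols]
  expect_true(all(P2[B == 0] == 0))
  # a null seed collapses the design
  expect_error(build_ppi_design(rep(0, length(g$times)), g$design,
                                g$times, g$run),
               "collinear")
})

test_that("gPPI recovers exact coupling on noiseless data", {
  g <- ppi_grid()
  set.seed(11)
  seed_tc <- rnorm(length(g$times))
  pd <- build_ppi_design(seed_tc, g$design, g$times, g$run)
  box90 <- pd$X[, "box_90"]
  target <- 0.8 * seed_tc + 0.5 * box90 * seed_tc
  fit <- fit_gppi(target, pd)
  expect_equal(unname(fit$ppi_betas["90"]), 0.5, tolerance = 1e-6)
  expect_equal(unname(fit$ppi_betas["15"]), 0, tolerance = 1e-6)
  expect_equal(unname(fit$betas["seed"]), 0.8, tolerance = 1e-6)
  expect_equal(saliency_connectivity(fit), 0.5, tolerance = 1e-6)
  # linearity: scaling the target scales every beta
  fit2 <- fit_gppi(2 * target, pd)
  expect_equal(unname(fit2$ppi_betas), unname(2 * fit$ppi_betas),
               tolerance = 1e-9)
  # adding any multiple of the seed is absorbed by the seed regressor
  fit3 <- fit_gppi(target + 3.7 * seed_tc, pd)
  expect_equal(unname(fit3$ppi_betas), unname(fit$ppi_betas),
               tolerance = 1e-9)
})

test_that("gPPI coupling estimates are unbiased", {
  g <- ppi_grid()
  set.seed(12)
  seed_tc <- rnorm(length(g$times))
  pd <- build_ppi_design(seed_tc, g$design, g$times, g$run)
  # independent-noise targets: PPI betas centre on zero
  b90 <- vapply(1:300, function(i) {
    fit_gppi(rnorm(length(g$times)), pd)$ppi_betas["90"]
  }, numeric(1))
  expect_lt(abs(mean(b90)), 3 * sd(b90) / sqrt(300))
  # known coupling contrast recovered through simulate_coupled_target
  deltas <- vapply(1:40, function(i) {
    targ <- simulate_coupled_target(seed_tc, g$times, g$run, g$design,
                                    coupling = c("90" = 0.5, "15" = 0.2,
                                                 "0" = 0.2),
                                    self = 0.8, noise_sd = 0.5,
                                    rng_seed = i)
    saliency_connectivity(fit_gppi(targ, pd))
  }, numeric(1))
  expect_lt(abs(mean(deltas) - 0.3), 0.05)
})

test_that("group pathway test flags only the coupled pathway", {
  g <- ppi_grid(n_runs = 1)
  set.seed(13)
  seed_tc <- rnorm(length(g$times))
  pd <- build_ppi_design(seed_tc, g$design, g$times, g$run)
  n_sub <- 12
  D <- sapply(c(ff = 0.3, fb = 0), function(contrast) {
    vapply(seq_len(n_sub), function(s) {
      cp <- c("90" = 0.2 + contrast, "15" = 0.2, "0" = 0.2)
      targ <- simulate_coupled_target(seed_tc, g$times, g$run, g$design,
                                      coupling = cp, noise_sd = 0.5,
                                      rng_seed = 100 * contrast * 17 + s)
      saliency_connectivity(fit_gppi(targ, pd))
    }, numeric(1))
  })
  res <- connectivity_group_test(D)
  expect_lt(res$p_holm[res$pathway == "ff"], 0.05)
  expect_gt(res$p_holm[res$pathway == "fb"], 0.05)
})
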