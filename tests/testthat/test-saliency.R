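random_profile <- function(n_sub = 20, seed = 1) {
  set.seed(seed)
  arr <- array(rnorm(n_sub * 9, 1, 0.5), c(n_sub, 3, 3),
               dimnames = list(paste0("s", 1:n_sub),
                               c("deep", "middle", "superficial"),
                               c("90", "15", "0")))
  arr
}

test_that("normalization preserves the group scale and removes gain", {
  # single subject, constant cells: normalization is the identity
  arr <- array(2, c(1, 3, 3),
               dimnames = list("s1", c("deep", "middle", "superficial"),
                               c("90", "15", "0")))
  norm <- normalize_responses(arr)
  expect_equal(as.numeric(norm), rep(2, 9))
  expect_equal(attr(norm, "rbar"), 2)
  # per-subject rescaling is removed: subject B = 2 x subject A
  a <- random_profile(1, seed = 2)
  arr2 <- array(c(a[1, , ], 2 * a[1, , ]), c(2, 3, 3),
                dimnames = list(c("sA", "sB"), dimnames(a)[[2]],
                                dimnames(a)[[3]]))
  arr2[1, , ] <- a[1, , ]
  arr2[2, , ] <- 2 * a[1, , ]
  norm2 <- unclass(normalize_responses(arr2))
  expect_equal(norm2[1, , ], norm2[2, , ], tolerance = 1e-12)
})

test_that("per-subject RMS of the normalized response equals rbar", {
  for (seed in 1:5) {
    arr <- random_profile(20, seed)
    norm <- normalize_responses(arr)
    rms <- sqrt(rowMeans(matrix(unclass(norm), nrow = 20)^2))
    expect_equal(rms, rep(attr(norm, "rbar"), 20), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
  arr0 <- random_profile(3)
  arr0[2, , ] <- 0
  expect_error(normalize_responses(arr0), "all-zero")
})

test_that("saliency-sensitive response is the 90 - 15 difference", {
  arr <- random_profile(10, 4)
  norm <- normalize_responses(arr)
  ss <- saliency_sensitive_response(norm)
  expect_equal(unclass(ss), unclass(norm)[, , "90"] - unclass(norm)[, , "15"],
               ignore_attr = TRUE)
  same <- arr
  same[, , "15"] <- same[, , "90"]
  expect_equal(max(abs(saliency_sensitive_response(
    normalize_responses(same)))), 0)
})

test_that("noiseless v1sh simulation has the expected SS laminar pattern", {
  m <- tiny_model()
  d <- tiny_design()
  prof <- estimate_profile(simulate_vaso_session(m, d, exact_scenario()),
                           d, m, "V1")
  arr <- array(prof, c(1, 3, 3), dimnames = c(list("s1"), dimnames(prof)))
  ss <- saliency_sensitive_response(normalize_responses(arr))
  expect_equal(strongest_ss_layer(ss), "superficial")
  prof_ips <- estimate_profile(simulate_vaso_session(m, d, exact_scenario()),
                               d, m, "IPS")
  arr2 <- array(prof_ips, c(1, 3, 3),
                dimnames = c(list("s1"), dimnames(prof_ips)))
  expect_equal(strongest_ss_layer(saliency_sensitive_response(
    normalize_responses(arr2))), "middle")
})

test_that("strongest-layer selection is invariant to subject order", {
  arr <- random_profile(15, 7)
  ss <- saliency_sensitive_response(normalize_responses(arr))
  perm <- sample(15)
  expect_equal(strongest_ss_layer(ss),
               strongest_ss_layer(unclass(ss)[perm, ]))
})
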