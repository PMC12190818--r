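# Shared fixtures, built once per test session.

tiny_model <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- build_column_model(20)
    val
  }
})

tiny_design <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- block_design(n_runs = 2, seed = 3)
    val
  }
})

# Noise-free scenario with the BOLD channel off: the estimation chain is
# exact under this forward model.
exact_scenario <- function(name = "v1sh", ...) {
  scenario_spec(name, noise_sd = 0, drift_amp = 0, bold_scale = 0, ...)
}

# Estimated layer x condition profile of one region from one session.
estimate_profile <- function(sim, design, model, region) {
  cbv <- suppressWarnings(
    percent_signal_change(boco_correct(split_and_align(sim)), sign = "cbv"))
  cb <- condition_betas(fit_glm(cbv, design))
  roi_layer_profile(cb, layer_weights(model),
                    which(model$voxels$region == region))
}
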