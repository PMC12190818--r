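#' Configuration for a full simulated study
#'
#' Bundles the generator and analysis settings of one end-to-end study.
#' Defaults mirror the experimental conditions of the target study: 20
#' subjects, 9 runs of 270 s with 6 blocks (2 per orientation contrast),
#' paired TR 5.02 s, and per-frame noise of 0.5% signal change.
#'
#' @param scenario Scenario name for [scenario_spec()].
#' @param n_subjects Number of simulated subjects.
#' @param n_runs Runs per subject.
#' @param n_voxels_per_region Minimum GM voxels per region.
#' @param noise_sd,drift_amp,bold_scale Passed to [scenario_spec()].
#' @param subject_sd SD of the log-normal overall amplitude factor per
#'   subject (removed again by normalization; realism only).
#' @param saliency_sd SD of the log-normal per-subject saliency gain
#'   multiplying the 90-degree condition (the individual difference that
#'   survives normalization and drives brain-behavior correlation).
#' @param coupling Named feedforward gPPI coupling gains per condition
#'   injected into the IPS-middle target (`NULL` disables connectivity
#'   simulation).
#' @param behavior_s90,behavior_s15 Group-mean behavioural contrast
#'   sensitivities for the two conditions.
#' @param behavior_noise_sd SD of behavioural sensitivity noise.
#' @param run_psychophysics If TRUE behavioural sensitivities are
#'   measured by simulated staircases + Weibull fits; otherwise the true
#'   observer sensitivities are used directly.
#' @param n_perm Permutations for the brain-behavior FWE test.
#' @param drift_order GLM drift order.
#' @param geometry Geometry overrides for [build_column_model()].
#' @param seed Master seed; every stage derives its own via
#'   [derive_seed()].
#' @return List of class `study_config`.
#' @export
study_config <- function(scenario = "v1sh", n_subjects = 20, n_runs = 9,
                         n_voxels_per_region = 60, noise_sd = 0.5,
                         drift_amp = 0.3, bold_scale = 2,
                         subject_sd = 0.2, saliency_sd = 0.25,
                         coupling = c("90" = 0.5, "15" = 0.2, "0" = 0.2),
                         behavior_s90 = 18.719, behavior_s15 = 9.720,
                         behavior_noise_sd = 1.0,
                         run_psychophysics = FALSE,
                         n_perm = 2000, drift_order = 3,
                         geometry = list(), seed = 1L) {
  structure(as.list(environment()), class = "study_config")
}

# Deterministic scenario signatures: (V1 argmax layer, IPS argmax layer)
# of the group saliency-sensitive profile implied by each origin.
scenario_signatures <- function() {
  list(feedback_parietal = c(V1 = "deep", IPS = "deep"),
       sc_tectothalamic = c(V1 = "middle", IPS = "middle"),
       v1sh = c(V1 = "superficial", IPS = "middle"))
}

#' Classify the generative scenario from laminar SS signatures
#'
#' Matches the observed argmax layers of the group-mean
#' saliency-sensitive response in V1 and IPS against the canonical
#' signature of each laminar-origin scenario; the scenario with the most
#' matching regions wins (deterministic first-listed tie-break).
#'
#' @param v1_layer,ips_layer Observed argmax layer names.
#' @return Scenario name.
#' @export
classify_scenario <- function(v1_layer, ips_layer) {
  sig <- scenario_signatures()
  score <- vapply(sig, function(s) {
    (s["V1"] == v1_layer) + (s["IPS"] == ips_layer)
  }, numeric(1))
  names(sig)[which.max(score)]
}

# Layer-dominant voxel indices of a region (majority weight in `layer`).
dominant_voxels <- function(model, region, layer) {
  v <- model$voxels
  which(v$region == region & v[[paste0("w_", layer)]] >= 0.5)
}

# Per-run percent signal change of the native not-nulled (BOLD) stream.
bold_stream <- function(series) {
  sel <- series$frame_labels == "notnulled"
  data <- percent_signal_change(series$data[, sel, drop = FALSE],
                                run = series$run[sel])
  list(data = data, times = series$frame_times[sel], run = series$run[sel])
}

#' Run a full simulated laminar saliency study
#'
#' End-to-end composition of the package: simulates a cohort of subjects
#' under a laminar-origin scenario, preprocesses each session (split /
#' align, BOCO, percent signal change), estimates condition amplitudes
#' with the block GLM, unmixes layer profiles per region, normalizes
#' responses and computes the saliency-sensitive response, runs the
#' repeated-measures ANOVAs and pairwise layer tests, measures (or
#' simulates) behavioural saliency sensitivity and its brain-behavior
#' correlation with max-statistic FWE control, fits the layer-specific
#' gPPI pathways on the BOLD stream, reconstructs visual-field maps per
#' depth, and classifies the generative scenario from the laminar
#' signature.
#'
#' @param config A [study_config()].
#' @return List of class `lamsal_study`; see `print()` for a summary.
#' @export
run_full_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  master <- config$seed
  scenario <- scenario_spec(config$scenario, noise_sd = config$noise_sd,
                            drift_amp = config$drift_amp,
                            bold_scale = config$bold_scale)
  model <- build_column_model(config$n_voxels_per_region, config$geometry)
  design <- block_design(n_runs = config$n_runs,
                         seed = derive_seed(master, 1))
  W_full <- layer_weights(model)

  rng <- local_rng(derive_seed(master, 2))
  amp_s <- exp(stats::rnorm(config$n_subjects, 0, config$subject_sd))
  sal_s <- exp(stats::rnorm(config$n_subjects, 0, config$saliency_sd))
  restore_rng(rng)

  profiles <- stats::setNames(
    lapply(REGIONS, function(rg) vector("list", config$n_subjects)),
    REGIONS)
  deltas <- matrix(NA_real_, config$n_subjects, 2,
                   dimnames = list(NULL, c("V1sup_to_IPSmid",
                                           "IPSdeep_to_V1deep")))
  ff_seed_vox <- dominant_voxels(model, "V1", "superficial")
  ff_targ_vox <- dominant_voxels(model, "IPS", "middle")
  fb_seed_vox <- dominant_voxels(model, "IPS", "deep")
  fb_targ_vox <- dominant_voxels(model, "V1", "deep")

  for (s in seq_len(config$n_subjects)) {
    gains_s <- scenario$gains
    gains_s[, , "90"] <- gains_s[, , "90"] * sal_s[s]
    scen_s <- scenario_spec(config$scenario, gains = gains_s,
                            noise_sd = config$noise_sd,
                            drift_amp = config$drift_amp,
                            bold_scale = config$bold_scale)
    sim <- simulate_vaso_session(model, design, scen_s,
                                 seed = derive_seed(master, 100 + s),
                                 subject_scale = amp_s[s])
    al <- split_and_align(sim)
    cbv <- percent_signal_change(boco_correct(al), sign = "cbv")
    fit <- fit_glm(cbv, design, drift_order = config$drift_order)
    cb <- condition_betas(fit)
    for (rg in REGIONS) {
      roi <- which(model$voxels$region == rg)
      profiles[[rg]][[s]] <- roi_layer_profile(cb, W_full, roi)
    }
    if (!is.null(config$coupling)) {
      bold <- bold_stream(sim)
      seed_ff <- colMeans(bold$data[ff_seed_vox, , drop = FALSE])
      targ_ff <- colMeans(bold$data[ff_targ_vox, , drop = FALSE]) +
        simulate_coupled_target(seed_ff, bold$times, bold$run, design,
                                coupling = config$coupling, self = 0,
                                noise_sd = 0,
                                rng_seed = derive_seed(master, 300 + s))
      pd_ff <- build_ppi_design(seed_ff, design, bold$times, bold$run,
                                drift_order = config$drift_order)
      deltas[s, 1] <- saliency_connectivity(fit_gppi(targ_ff, pd_ff))
      seed_fb <- colMeans(bold$data[fb_seed_vox, , drop = FALSE])
      targ_fb <- colMeans(bold$data[fb_targ_vox, , drop = FALSE])
      pd_fb <- build_ppi_design(seed_fb, design, bold$times, bold$run,
                                drift_order = config$drift_order)
      deltas[s, 2] <- saliency_connectivity(fit_gppi(targ_fb, pd_fb))
    }
  }

  group <- stats::setNames(lapply(REGIONS, function(rg) {
    prof <- layer_profile(profiles[[rg]], region = rg)
    norm <- normalize_responses(prof)
    ss <- saliency_sensitive_response(norm)
    list(profile = prof, normalized = norm, ss = ss,
         argmax_layer = strongest_ss_layer(ss),
         anova_two_way = rm_anova_two_way(unclass(norm)),
         anova_ss = rm_anova_one_way(unclass(ss), "depth"),
         pairwise = ss_pairwise_tests(ss))
  }), REGIONS)

  behavior <- simulate_behavior(config, sal_s,
                                seed = derive_seed(master, 3))
  ss_at_layer <- sapply(REGIONS, function(rg) {
    unclass(group[[rg]]$ss)[, group[[rg]]$argmax_layer]
  })
  correlation <- brain_behavior_correlation(
    ss_at_layer, behavior$ss_behavior, n_perm = config$n_perm,
    seed = derive_seed(master, 4))

  connectivity <- if (!is.null(config$coupling)) {
    connectivity_group_test(deltas)
  } else NULL

  fieldmaps <- study_fieldmaps(model, group, sal_s,
                               ecc = model$geometry$foreground_ecc,
                               seed = derive_seed(master, 5))

  inferred <- classify_scenario(group$V1$argmax_layer,
                                group$IPS$argmax_layer)
  structure(list(config = config, scenario = scenario, model = model,
                 design = design, group = group, behavior = behavior,
                 correlation = correlation, connectivity = connectivity,
                 ppi_deltas = deltas, fieldmaps = fieldmaps,
                 scenario_inferred = inferred),
            class = "lamsal_study")
}

# Pairwise layer t tests on the SS profile (3-level follow-up).
ss_pairwise_tests <- function(ss) {
  ss <- unclass(ss)
  pairs <- utils::combn(colnames(ss), 2, simplify = FALSE)
  do.call(rbind, lapply(pairs, function(pr) {
    tt <- paired_t(ss[, pr[1]], ss[, pr[2]])
    data.frame(contrast = paste(pr, collapse = " vs "), t = tt$t,
               df = tt$df, p = tt$p)
  }))
}

# Behavioural sensitivities per subject, linked to the per-subject
# saliency gain; optionally measured through staircases + Weibull fits.
simulate_behavior <- function(config, sal_s, seed) {
  n <- config$n_subjects
  rng <- local_rng(seed)
  on.exit(restore_rng(rng))
  s90_true <- config$behavior_s90 * sal_s +
    stats::rnorm(n, 0, config$behavior_noise_sd)
  s15_true <- config$behavior_s15 +
    stats::rnorm(n, 0, config$behavior_noise_sd)
  s90_true <- pmax(s90_true, 4)
  s15_true <- pmax(s15_true, 4)
  if (config$run_psychophysics) {
    measure <- function(s_true, sub, cond) {
      obs <- make_weibull_observer(1 / s_true, slope = 3)
      trials <- do.call(rbind, lapply(1:4, function(k) {
        run_staircase(obs, n_trials = 60,
                      seed = derive_seed(seed, sub * 10 + k + cond),
                      staircase_id = k)
      }))
      fit_weibull(trials)$sensitivity
    }
    s90 <- vapply(seq_len(n), function(s) measure(s90_true[s], s, 1),
                  numeric(1))
    s15 <- vapply(seq_len(n), function(s) measure(s15_true[s], s, 5),
                  numeric(1))
  } else {
    s90 <- s90_true
    s15 <- s15_true
  }
  list(s90 = s90, s15 = s15,
       ss_behavior = behavioral_saliency_sensitivity(s90, s15))
}

# Visual-field maps per depth from the group SS profile: V1 vertices
# respond with their layer's SS scaled by a Gaussian hotspot at the
# foreground location (lower-right), plus pRF noise.
study_fieldmaps <- function(model, group, sal_s, ecc = 4.3, seed = 1L,
                            grid = list(x = seq(-8, 8, 0.2),
                                        y = seq(-8, 0, 0.2))) {
  fg <- c(ecc / sqrt(2), -ecc / sqrt(2))
  nodes0 <- model$vertices[model$vertices$region == "V1", , drop = FALSE]
  ss <- unclass(group$V1$ss)
  rng <- local_rng(seed)
  on.exit(restore_rng(rng))
  maps <- lapply(seq_len(nrow(ss)), function(s) {
    nd <- nodes0
    nd$depth <- nd$layer
    hot <- exp(-((nd$x0 - fg[1])^2 + (nd$y0 - fg[2])^2) / (2 * 1.5^2))
    nd$response <- ss[s, nd$layer] * hot +
      stats::rnorm(nrow(nd), 0, 0.02)
    reconstruct_fieldmap(nd, grid = grid)
  })
  avg <- group_average_fieldmaps(maps)
  peak_depth <- names(avg)[which.max(vapply(avg, max, numeric(1)))]
  list(maps = avg, peak_depth = peak_depth, foreground = fg,
       peaks = lapply(avg, fieldmap_peak, grid = attr(avg, "grid")))
}

#' @export
print.lamsal_study <- function(x, ...) {
  cat(sprintf("Simulated laminar saliency study: scenario '%s', %d subjects\n",
              x$scenario$name, x$config$n_subjects))
  for (rg in names(x$group)) {
    g <- x$group[[rg]]
    cat(sprintf("  %-3s argmax SS layer: %-11s (mean SS %s)\n", rg,
                g$argmax_layer,
                paste(sprintf("%.3f", colMeans(unclass(g$ss))),
                      collapse = "/")))
  }
  cat(sprintf("  inferred scenario: %s\n", x$scenario_inferred))
  if (!is.null(x$correlation)) {
    v1 <- x$correlation[x$correlation$roi == "V1", ]
    cat(sprintf("  brain-behavior r (V1): %.3f (raw p %.3g, FWE p %.3g)\n",
                v1$r, v1$p_raw, v1$p_fwe))
  }
  if (!is.null(x$connectivity)) {
    cat("  gPPI pathway contrasts:\n")
    for (i in seq_len(nrow(x$connectivity))) {
      cat(sprintf("    %-18s delta %.3f, t(%d) = %.2f, Holm p %.3g\n",
                  x$connectivity$pathway[i], x$connectivity$mean_delta[i],
                  x$connectivity$df[i], x$connectivity$t[i],
                  x$connectivity$p_holm[i]))
    }
  }
  cat(sprintf("  field-map peak depth: %s\n", x$fieldmaps$peak_depth))
  invisible(x)
}

#' Scenario-recovery experiment
#'
#' Repeatedly simulates whole cohorts under each laminar-origin scenario,
#' runs the estimation pipeline (align, BOCO, percent change, GLM, layer
#' unmixing, normalization, saliency-sensitive response) and classifies
#' each replicate's generative scenario from the group laminar
#' signature. Reports the confusion matrix and accuracy.
#'
#' @param scenarios Scenario names to include.
#' @param n_replicates Replicates per scenario (`>= 10` for a meaningful
#'   confusion matrix; smaller values allowed for smoke tests).
#' @param n_subjects Subjects per replicate.
#' @param n_runs Runs per subject (scaled-down default keeps the
#'   experiment desk-sized; accuracy is conservative in the number of
#'   runs).
#' @param n_voxels_per_region Minimum GM voxels per region.
#' @param noise_sd,drift_amp,bold_scale Scenario noise settings.
#' @param seed Master seed.
#' @return List of class `scenario_recovery`: `confusion` (truth x
#'   inferred), `accuracy`, `n_replicates`.
#' @export
scenario_recovery_experiment <- function(scenarios = c("feedback_parietal",
                                                       "v1sh",
                                                       "sc_tectothalamic"),
                                         n_replicates = 100,
                                         n_subjects = 20, n_runs = 2,
                                         n_voxels_per_region = 24,
                                         noise_sd = 0.5, drift_amp = 0.3,
                                         bold_scale = 2, seed = 1L) {
  stopifnot(length(scenarios) >= 2, n_replicates >= 1)
  model <- build_column_model(n_voxels_per_region)
  design <- block_design(n_runs = n_runs, seed = derive_seed(seed, 1))
  W <- layer_weights(model)
  labels <- scenarios
  confusion <- matrix(0L, length(labels), length(labels),
                      dimnames = list(truth = labels, inferred = labels))
  ctr <- 0L
  for (sc_name in scenarios) {
    for (rep in seq_len(n_replicates)) {
      ctr <- ctr + 1L
      scen <- scenario_spec(sc_name, noise_sd = noise_sd,
                            drift_amp = drift_amp,
                            bold_scale = bold_scale)
      prof_v1 <- vector("list", n_subjects)
      prof_ips <- vector("list", n_subjects)
      for (s in seq_len(n_subjects)) {
        sim <- simulate_vaso_session(model, design, scen,
                                     seed = derive_seed(seed,
                                                        1000L * ctr + s))
        cbv <- percent_signal_change(boco_correct(split_and_align(sim)),
                                     sign = "cbv")
        cb <- condition_betas(fit_glm(cbv, design))
        prof_v1[[s]] <- roi_layer_profile(
          cb, W, which(model$voxels$region == "V1"))
        prof_ips[[s]] <- roi_layer_profile(
          cb, W, which(model$voxels$region == "IPS"))
      }
      ss_v1 <- saliency_sensitive_response(
        normalize_responses(layer_profile(prof_v1, "V1")))
      ss_ips <- saliency_sensitive_response(
        normalize_responses(layer_profile(prof_ips, "IPS")))
      inferred <- classify_scenario(strongest_ss_layer(ss_v1),
                                    strongest_ss_layer(ss_ips))
      confusion[sc_name, inferred] <- confusion[sc_name, inferred] + 1L
    }
  }
  structure(list(confusion = confusion,
                 accuracy = sum(diag(confusion)) / sum(confusion),
                 n_replicates = n_replicates),
            class = "scenario_recovery")
}

#' @export
print.scenario_recovery <- function(x, ...) {
  cat(sprintf("Scenario recovery: accuracy %.3f over %d replicates/scenario\n",
              x$accuracy, x$n_replicates))
  print(x$confusion)
  invisible(x)
}
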