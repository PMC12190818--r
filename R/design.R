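#' Block design for the saliency fMRI experiment
#'
#' The main experiment presents oriented-texture stimuli at three
#' foreground orientation contrasts (theta = 90, 15, 0 degrees) in 30-s
#' blocks separated by 15-s fixation, 6 blocks per 270-s run (2 per
#' condition), acquired with an alternating blood-nulled / not-nulled
#' readout at a paired TR of 5.02 s (frame interval 2.51 s). Block onsets
#' are snapped to the nearest frame time. Block order is permuted per run
#' under `seed`.
#'
#' @param n_runs Number of runs.
#' @param conditions Condition labels; the three orientation contrasts by
#'   default.
#' @param blocks_per_condition Blocks per condition per run.
#' @param block_s Block duration (s).
#' @param fix_s Fixation gap before each block (s).
#' @param paired_tr Duration of one nulled + not-nulled frame pair (s).
#' @param seed Integer seed for the per-run block orders.
#' @return A `block_design`: data frame with columns `run`, `onset`
#'   (run-relative, s), `duration`, `condition`, plus timing attributes
#'   (`paired_tr`, `frame_dt`, `n_pairs`, `run_length`).
#' @export
#' @examples
#' d <- block_design(n_runs = 2, seed = 1)
#' table(d$condition)
block_design <- function(n_runs = 9,
                         conditions = c("90", "15", "0"),
                         blocks_per_condition = 2,
                         block_s = 30, fix_s = 15,
                         paired_tr = 5.02, seed = 1L) {
  stopifnot(n_runs >= 1, blocks_per_condition >= 1, block_s > 0, fix_s >= 0)
  conditions <- as.character(conditions)
  frame_dt <- paired_tr / 2
  cycle <- block_s + fix_s
  n_blocks <- length(conditions) * blocks_per_condition
  run_length_nominal <- n_blocks * cycle
  n_pairs <- round(run_length_nominal / paired_tr)
  rng <- local_rng(seed)
  rows <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    ord <- sample(rep(conditions, blocks_per_condition))
    onsets_nominal <- fix_s + cycle * (seq_len(n_blocks) - 1)
    onsets <- round(onsets_nominal / frame_dt) * frame_dt
    if (any(diff(onsets) < block_s)) stop("overlapping blocks after onset snapping")
    rows[[r]] <- data.frame(run = r, onset = onsets, duration = block_s,
                            condition = ord, stringsAsFactors = FALSE)
  }
  restore_rng(rng)
  out <- do.call(rbind, rows)
  structure(out,
            paired_tr = paired_tr, frame_dt = frame_dt,
            n_pairs = n_pairs, run_length = n_pairs * paired_tr,
            conditions = conditions,
            class = c("block_design", "data.frame"))
}

#' Localizer block design (left / right foreground patches)
#'
#' Two runs of eight 30-s stimulus blocks (4 per side) interleaved with
#' 15-s fixation, used to define the foreground region of interest.
#'
#' @inheritParams block_design
#' @export
localizer_design <- function(n_runs = 2, paired_tr = 5.02, seed = 2L) {
  block_design(n_runs = n_runs, conditions = c("left", "right"),
               blocks_per_condition = 4, paired_tr = paired_tr, seed = seed)
}

#' Acquisition frame times and labels for a design
#'
#' @param design A [block_design()].
#' @return List with `times` (absolute seconds across all runs), `labels`
#'   (`"nulled"` / `"notnulled"`, nulled first within each pair), `run`
#'   (run index per frame), and per-run relative times in `rel_times`.
#' @export
design_frames <- function(design) {
  stopifnot(inherits(design, "block_design"))
  n_pairs <- attr(design, "n_pairs")
  frame_dt <- attr(design, "frame_dt")
  run_length <- attr(design, "run_length")
  runs <- sort(unique(design$run))
  rel <- (seq_len(2 * n_pairs) - 1) * frame_dt
  times <- unlist(lapply(runs, function(r) (r - 1) * run_length + rel))
  list(times = times,
       labels = rep(rep(c("nulled", "notnulled"), n_pairs), length(runs)),
       run = rep(runs, each = 2 * n_pairs),
       rel_times = rel,
       frame_dt = frame_dt, n_pairs = n_pairs, run_length = run_length)
}

#' Condition rows of a design for one run
#' @keywords internal
design_run <- function(design, run, condition = NULL) {
  d <- design[design$run == run, , drop = FALSE]
  if (!is.null(condition)) d <- d[d$condition == condition, , drop = FALSE]
  d
}

#' @export
print.block_design <- function(x, ...) {
  cat(sprintf("Block design: %d run(s), %d blocks/run, conditions {%s}\n",
              length(unique(x$run)), sum(x$run == x$run[1]),
              paste(attr(x, "conditions"), collapse = ", ")))
  cat(sprintf("  paired TR %.2f s, %d frame pairs/run, run length %.2f s\n",
              attr(x, "paired_tr"), attr(x, "n_pairs"), attr(x, "run_length")))
  invisible(x)
}
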