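# Internal helpers: scoped RNG and small utilities.

# Save the caller's RNG state and seed a local stream. Pair with
# restore_rng() so package functions are reproducible under their own
# `seed` arguments without disturbing the global stream.
local_rng <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(as.integer(seed))
  old
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' Derive a stage seed from a master seed
#'
#' Counter-based derivation keeping every stage of a study reproducible
#' from one master seed. Results stay in `[1, 2^31 - 2]`.
#'
#' @param master Master seed (integer-like).
#' @param stage Stage counter (integer-like, may be a vector).
#' @return Integer seed(s).
#' @export
derive_seed <- function(master, stage) {
  m <- 2147483647 # 2^31 - 1, prime
  s <- (as.numeric(master) %% m) * 48271 + as.numeric(stage) * 16807 + 1
  as.integer(s %% (m - 1) + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Memoised block_regressor: designs repeat across subjects and
# replicates, so identical (onsets, durations, times) calls are cached.
.regressor_cache <- new.env(parent = emptyenv())

cached_block_regressor <- function(onsets, durations, times, dt = 0.1) {
  key <- paste(signif(c(onsets, durations, times, dt), 10),
               collapse = ",")
  hit <- .regressor_cache[[key]]
  if (!is.null(hit)) return(hit)
  val <- block_regressor(onsets, durations, times, dt)
  if (length(ls(.regressor_cache)) > 512) {
    rm(list = ls(.regressor_cache), envir = .regressor_cache)
  }
  .regressor_cache[[key]] <- val
  val
}

LAYERS <- c("deep", "middle", "superficial")
COMPARTMENTS <- c("WM", "CSF", "deep", "middle", "superficial")
REGIONS <- c("V1", "V2", "IPS")
THETAS <- c("90", "15", "0")
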