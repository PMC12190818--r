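# Repeated-measures ANOVA via the multivariate route (car::Anova with an
# intra-subject design), returning the univariate within-subject tests
# with Mauchly sphericity and Greenhouse-Geisser adjustment.

rm_anova_car <- function(Y, idata, idesign) {
  mod <- stats::lm(Y ~ 1)
  an <- car::Anova(mod, idata = idata, idesign = idesign, type = 3)
  # car warns when the Huynh-Feldt epsilon exceeds 1; irrelevant here
  # since only the Greenhouse-Geisser adjustment is reported
  s <- withCallingHandlers(
    summary(an, multivariate = FALSE),
    warning = function(w) {
      if (grepl("HF eps", conditionMessage(w))) invokeRestart("muffleWarning")
    })
  ut <- s$univariate.tests
  eff <- setdiff(rownames(ut), "(Intercept)")
  adj <- s$pval.adjustments
  sph <- s$sphericity.tests
  res <- data.frame(effect = eff,
                    df1 = ut[eff, "num Df"], df2 = ut[eff, "den Df"],
                    F = ut[eff, "F value"], p = ut[eff, "Pr(>F)"],
                    mauchly_p = NA_real_, gg_epsilon = NA_real_,
                    p_gg = NA_real_, row.names = NULL)
  if (!is.null(sph) && nrow(sph) > 0) {
    i <- match(rownames(sph), res$effect)
    ok <- !is.na(i)
    res$mauchly_p[i[ok]] <- sph[ok, "p-value"]
  }
  if (!is.null(adj) && nrow(adj) > 0) {
    i <- match(rownames(adj), res$effect)
    ok <- !is.na(i)
    gg_p_col <- grep("GG", colnames(adj), fixed = TRUE)[2]
    res$gg_epsilon[i[ok]] <- adj[ok, "GG eps"]
    res$p_gg[i[ok]] <- adj[ok, gg_p_col]
  }
  # report the GG-adjusted p only where Mauchly indicates a sphericity
  # violation; otherwise the uncorrected p
  res$p_reported <- ifelse(!is.na(res$mauchly_p) & res$mauchly_p < 0.05 &
                             !is.na(res$p_gg), res$p_gg, res$p)
  class(res) <- c("rm_anova", "data.frame")
  res
}

#' One-way repeated-measures ANOVA
#'
#' Within-subject one-way ANOVA on a subject x level matrix, with
#' Mauchly's sphericity test and Greenhouse-Geisser correction (the
#' corrected p is reported when Mauchly's p < 0.05).
#'
#' @param y Subject x level numeric matrix (complete, >= 3 subjects).
#' @param factor_name Name of the within-subject factor.
#' @return Data frame of class `rm_anova`: `effect`, `df1`, `df2`, `F`,
#'   `p`, `mauchly_p`, `gg_epsilon`, `p_gg`, `p_reported`.
#' @export
rm_anova_one_way <- function(y, factor_name = "condition") {
  y <- as.matrix(y)
  if (any(!is.finite(y))) stop("design has missing cells")
  stopifnot(nrow(y) >= 3, ncol(y) >= 2)
  idata <- data.frame(f = factor(seq_len(ncol(y))))
  names(idata) <- factor_name
  rm_anova_car(y, idata, stats::as.formula(paste0("~", factor_name)))
}

#' Two-way repeated-measures ANOVA
#'
#' Within-subject two-way ANOVA on a subject x A x B array (e.g. cortical
#' depth x orientation contrast), with sphericity tests and
#' Greenhouse-Geisser correction per effect.
#'
#' @param arr Subject x A x B numeric array (complete, >= 3 subjects).
#' @param names_ab Names of the two within-subject factors.
#' @return Data frame of class `rm_anova` with one row per within-subject
#'   effect (A, B, A:B).
#' @export
rm_anova_two_way <- function(arr, names_ab = c("depth", "theta")) {
  stopifnot(is.array(arr), length(dim(arr)) == 3)
  if (any(!is.finite(arr))) stop("design has missing cells")
  stopifnot(dim(arr)[1] >= 3)
  a <- dim(arr)[2]; b <- dim(arr)[3]
  Y <- matrix(arr, nrow = dim(arr)[1])
  idata <- expand.grid(A = factor(seq_len(a)), B = factor(seq_len(b)))
  names(idata) <- names_ab
  rm_anova_car(Y, idata,
               stats::as.formula(paste0("~", names_ab[1], "*", names_ab[2])))
}

#' @export
print.rm_anova <- function(x, ...) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) signif(v, 4))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Monte-Carlo power of the within-subject one-way ANOVA
#'
#' Simulates `n_reps` repeated-measures experiments
#' (`y = condition mean + subject effect + error`) and reports the
#' rejection rate of the within-subject F test at level `alpha`. Cohen's
#' f is specified against the total within-cell SD
#' `sqrt(tau^2 + sigma^2)`; the subject SD `tau` is set from the
#' correlation among repeated measures `rho = tau^2 / (tau^2 + sigma^2)`
#' with unit error variance, matching the convention of standard power
#' software for repeated-measures designs. The F statistic is computed
#' with a vectorized closed-form kernel identical to
#' [rm_anova_one_way()]'s uncorrected test.
#'
#' @param n_subjects Subjects per experiment.
#' @param n_conditions Repeated conditions.
#' @param f Cohen's f effect size.
#' @param rho Correlation among repeated measures.
#' @param sigma Error SD.
#' @param n_reps Monte-Carlo replicates.
#' @param alpha Test level.
#' @param seed Integer seed.
#' @return List: `power` (rejection rate), `n_reps`, `ncp` (theoretical
#'   noncentrality), `power_theory` (noncentral-F closed form).
#' @export
anova_power_sim <- function(n_subjects = 20, n_conditions = 3, f = 0.4,
                            rho = 0.5, sigma = 1, n_reps = 5000,
                            alpha = 0.05, seed = 1L) {
  stopifnot(n_subjects >= 2, n_conditions >= 2, f >= 0, rho >= 0, rho < 1)
  n <- n_subjects; k <- n_conditions
  tau <- sigma * sqrt(rho / (1 - rho))
  sd_tot <- sqrt(tau^2 + sigma^2)
  # condition means with population SD (divisor k) equal to f * sd_tot
  m <- seq(-1, 1, length.out = k)
  m <- m - mean(m)
  m <- m * f * sd_tot / sqrt(mean(m^2))
  rng <- local_rng(seed)
  on.exit(restore_rng(rng))
  crit <- stats::qf(1 - alpha, k - 1, (n - 1) * (k - 1))
  rej <- logical(n_reps)
  Fs <- numeric(n_reps)
  for (i in seq_len(n_reps)) {
    y <- matrix(m, n, k, byrow = TRUE) +
      stats::rnorm(n, 0, tau) +
      matrix(stats::rnorm(n * k, 0, sigma), n, k)
    gm <- mean(y)
    cm <- colMeans(y); sm <- rowMeans(y)
    ss_cond <- n * sum((cm - gm)^2)
    ss_err <- sum((y - outer(sm, cm, "+") + gm)^2)
    Fs[i] <- (ss_cond / (k - 1)) / (ss_err / ((n - 1) * (k - 1)))
  }
  ncp <- n * sum(m^2) / sigma^2
  list(power = mean(Fs > crit), n_reps = n_reps, ncp = ncp,
       power_theory = 1 - stats::pf(crit, k - 1, (n - 1) * (k - 1),
                                    ncp = ncp))
}

#' Paired t test
#'
#' Identical samples (all differences exactly zero) give `t = 0, p = 1`;
#' a nonzero constant difference has zero variance and is a degenerate
#' test (error).
#'
#' @param x,y Paired samples (equal length >= 2).
#' @return List: `t`, `df`, `p` (two-sided).
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  if (stats::sd(d) == 0) {
    if (all(d == 0)) {
      return(list(t = 0, df = length(d) - 1, p = 1))
    }
    stop("degenerate test: zero variance of paired differences")
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Holm step-down multiple-comparison adjustment
#'
#' @param pvals Raw p values.
#' @return Adjusted p values (monotone, `>=` raw, `<= 1`).
#' @export
holm_correct <- function(pvals) stats::p.adjust(pvals, method = "holm")
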