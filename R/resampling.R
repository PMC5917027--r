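resolve_statistic <- function(statistic) {
  if (is.function(statistic)) return(statistic)
  switch(statistic,
         Hd = function(aln) haplotype_diversity(call_haplotypes(aln)),
         pi = function(aln) pairwise_diff_stats(aln)$pi,
         k_bar = function(aln) pairwise_diff_stats(aln)$k_bar,
         S = function(aln) pairwise_diff_stats(aln)$S,
         H = function(aln) call_haplotypes(aln)$H,
         stop("unknown statistic: ", statistic))
}

#' Subsample a diversity statistic to a common sample size
#'
#' Controls for unequal group sizes: repeatedly draws `target_n` sequences
#' *without replacement* from the group and recomputes the statistic,
#' yielding the distribution of the statistic at a standardized sample size
#' (e.g. the smallest group in the study design).
#'
#' @param aln An [mt_alignment] for one group.
#' @param target_n Subsample size; must not exceed the group size.
#' @param n_reps Number of replicates (default 1000).
#' @param statistic Statistic name (`"Hd"`, `"pi"`, `"k_bar"`, `"S"`, `"H"`)
#'   or a function `mt_alignment -> numeric`.
#' @param seed Integer seed; fixed seed gives a bit-identical distribution.
#' @return A `resample_distribution`: list with `statistic`, `target_n`,
#'   `n_reps`, `values`, `seed`.
#' @export
subsample_stat <- function(aln, target_n, n_reps = 1000L, statistic = "Hd",
                           seed = 1L) {
  n <- aln_nseq(aln)
  if (target_n > n) stop("target_n (", target_n, ") exceeds group size (", n, ")")
  if (n_reps < 1L) stop("n_reps must be >= 1")
  f <- resolve_statistic(statistic)
  set.seed(seed)
  values <- vapply(seq_len(n_reps), function(i) {
    f(aln_subset(aln, rows = sample.int(n, target_n)))
  }, numeric(1))
  structure(list(statistic = if (is.character(statistic)) statistic else "custom",
                 target_n = as.integer(target_n), n_reps = as.integer(n_reps),
                 values = values, seed = seed),
            class = "resample_distribution")
}

#' @export
print.resample_distribution <- function(x, ...) {
  cat(sprintf("resample_distribution: %s at n = %d, %d reps; mean %.4f (sd %.4f)\n",
              x$statistic, x$target_n, x$n_reps, mean(x$values), stats::sd(x$values)))
  invisible(x)
}

#' Compare two resampled statistic distributions
#'
#' Welch's two-sample t-test between the replicate values, plus a label
#' permutation p-value (fraction of shuffles with `|mean difference|` at
#' least as extreme). Because subsampling replicates are not independent
#' observations, the permutation p-value is the preferred inferential
#' quantity; the t-test is reported for comparability with common practice.
#'
#' @param distA,distB `resample_distribution` objects (or plain numeric
#'   vectors).
#' @param n_perm Number of label permutations (default 10000).
#' @param seed Seed for the permutation draw.
#' @return A `comparison_result`: list with group means, mean difference,
#'   `t`, `p_t` (Welch), `p_perm`, and each group's 2.5/97.5% resample
#'   quantiles.
#' @export
compare_groups <- function(distA, distB, n_perm = 10000L, seed = 1L) {
  a <- if (inherits(distA, "resample_distribution")) distA$values else as.numeric(distA)
  b <- if (inherits(distB, "resample_distribution")) distB$values else as.numeric(distB)
  if (!length(a) || !length(b)) stop("empty distribution")
  obs_diff <- mean(a) - mean(b)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    # degenerate: no variation in either distribution
    p_t <- if (obs_diff == 0) 1 else 0
    tstat <- if (obs_diff == 0) 0 else Inf * sign(obs_diff)
  } else {
    tt <- stats::t.test(a, b)
    p_t <- tt$p.value
    tstat <- unname(tt$statistic)
  }
  set.seed(seed)
  pool <- c(a, b)
  na <- length(a)
  exceed <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(length(pool), na)
    abs(mean(pool[idx]) - mean(pool[-idx])) >= abs(obs_diff)
  }, logical(1))
  p_perm <- (sum(exceed) + 1) / (n_perm + 1)
  structure(list(statistic = if (inherits(distA, "resample_distribution"))
                   distA$statistic else "custom",
                 mean_a = mean(a), mean_b = mean(b), mean_diff = obs_diff,
                 t = tstat, p_t = p_t, p_perm = p_perm,
                 ci_a = stats::quantile(a, c(0.025, 0.975), names = FALSE),
                 ci_b = stats::quantile(b, c(0.025, 0.975), names = FALSE)),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("comparison of %s: mean %.4f vs %.4f (diff %.4f)\n",
              x$statistic, x$mean_a, x$mean_b, x$mean_diff))
  cat(sprintf("  Welch t = %.3f, p_t = %.4g; permutation p = %.4g\n",
              x$t, x$p_t, x$p_perm))
  invisible(x)
}

#' Write replicate values of a resample distribution as CSV
#' @param dist A `resample_distribution`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_resample_csv <- function(dist, path) {
  utils::write.csv(data.frame(replicate = seq_along(dist$values),
                              value = dist$values), path, row.names = FALSE)
  invisible(path)
}
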