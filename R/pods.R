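#' Pseudo-observed-dataset power analysis
#'
#' Simulates `n_pods` datasets under a known ("true") demographic model,
#' pushes each through ABC model choice and regression-adjusted parameter
#' estimation against the supplied reference table, and aggregates how often
#' the truth is recovered. The "correct model" call uses the posterior at
#' the median acceptance proportion; a POD "covers" when the nominal 95%
#' credible interval of the size ratio `N_historical / N_present` contains
#' the true ratio.
#'
#' @param table An `abc_reference` (the same table is reused for every POD).
#' @param true_demo A [demographic_model]: the truth the PODs are simulated
#'   under.
#' @param n_pods Number of pseudo-observed datasets.
#' @param proportions Acceptance proportions for model choice.
#' @param est_proportion Acceptance proportion for parameter estimation.
#' @param seed Integer master seed (each POD gets a derived seed, so the
#'   report is bit-reproducible).
#' @return A `pod_power` report: list with `n_pods`, `true_model`,
#'   `true_ratio`, `fraction_correct`, `mean_posterior_true`, `coverage95`,
#'   `median_abs_log_ratio_error`, and the per-POD `records` data frame.
#' @export
run_pods <- function(table, true_demo, n_pods = 100L,
                     proportions = c(0.005, 0.01, 0.02),
                     est_proportion = 0.01, seed = 1L) {
  if (n_pods < 1L) stop("n_pods must be >= 1")
  design <- attr(table, "design")
  mut <- attr(table, "mut")
  gd <- attr(table, "gd")
  if (is.null(design) || is.null(mut)) {
    stop("reference table is missing its design/mutation metadata")
  }
  props <- sort(proportions)
  median_prop <- props[ceiling(length(props) / 2)]
  true_ratio <- true_demo$N_historical / true_demo$N_present
  multi_model <- length(unique(table$model)) >= 2L

  records <- lapply(seq_len(n_pods), function(i) {
    set.seed(row_seed(seed, i))
    obs <- sim_summary_stats(design, true_demo, mut, gd = gd)
    if (multi_model) {
      mc <- model_posterior(table, obs, proportions = props)
      at_med <- mc$posterior[mc$posterior$proportion == median_prop, ]
      top <- at_med$model[which.max(at_med$posterior)]
      post_true <- at_med$posterior[at_med$model == true_demo$model_class]
      if (!length(post_true)) post_true <- 0
    } else {
      top <- unique(table$model)
      post_true <- as.numeric(top == true_demo$model_class)
    }
    est <- abc_estimate(table, obs, proportion = est_proportion)
    data.frame(pod = i, top_model = top, posterior_true = post_true,
               ratio_median = est$reduction$median,
               ratio_lo = est$reduction$ci95[1L],
               ratio_hi = est$reduction$ci95[2L],
               covered = est$reduction$ci95[1L] <= true_ratio &
                 true_ratio <= est$reduction$ci95[2L],
               abs_log_ratio_error = abs(log(est$reduction$median / true_ratio)))
  })
  rec <- do.call(rbind, records)
  structure(list(n_pods = n_pods,
                 true_model = true_demo$model_class,
                 true_ratio = true_ratio,
                 fraction_correct = mean(rec$top_model == true_demo$model_class),
                 mean_posterior_true = mean(rec$posterior_true),
                 coverage95 = mean(rec$covered),
                 median_abs_log_ratio_error = stats::median(rec$abs_log_ratio_error),
                 median_proportion = median_prop,
                 records = rec),
            class = "pod_power")
}

#' @export
print.pod_power <- function(x, ...) {
  cat(sprintf("POD power: true model '%s' (ratio %.2f), %d PODs\n",
              x$true_model, x$true_ratio, x$n_pods))
  cat(sprintf("  correct top model: %.2f; mean posterior of truth: %.3f\n",
              x$fraction_correct, x$mean_posterior_true))
  cat(sprintf("  95%% CI coverage of ratio: %.2f; median |log ratio error|: %.3f\n",
              x$coverage95, x$median_abs_log_ratio_error))
  invisible(x)
}

#' POD power across a grid of reduction factors
#'
#' Convenience wrapper running [run_pods] for several true reduction
#' factors at a fixed present-day size, e.g. to check that power to detect a
#' decline does not decrease with effect size.
#'
#' @param table An `abc_reference`.
#' @param ratios Reduction factors `N_historical / N_present` (1 = constant).
#' @param N_present True present-day female effective size.
#' @param t_change True change time (years).
#' @param n_pods PODs per ratio.
#' @param ... Passed to [run_pods].
#' @param seed Master seed; each ratio gets a derived seed.
#' @return `data.frame` with one row per ratio (power = fraction of PODs
#'   whose top model is `decline`, or `constant` for ratio 1).
#' @export
pod_power_grid <- function(table, ratios = c(1, 2.5, 4.5, 10),
                           N_present = 2000, t_change = 70, n_pods = 50L,
                           seed = 1L, ...) {
  rows <- lapply(seq_along(ratios), function(j) {
    r <- ratios[j]
    demo <- if (r == 1) {
      demographic_model("constant", N_present, N_present, t_change)
    } else {
      demographic_model("decline", N_present, N_present * r, t_change)
    }
    rep <- run_pods(table, demo, n_pods = n_pods, seed = row_seed(seed, j), ...)
    decline_top <- mean(rep$records$top_model == "decline")
    data.frame(ratio = r, true_model = demo$model_class,
               power_decline = decline_top,
               fraction_correct = rep$fraction_correct,
               mean_posterior_true = rep$mean_posterior_true,
               coverage95 = rep$coverage95)
  })
  do.call(rbind, rows)
}
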