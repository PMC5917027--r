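ABC_STAT_NAMES <- c("H_modern", "H_historical", "P_modern", "P_historical",
                    "GD_modern", "GD_historical", "k_between", "fst_between")

# Group summary from an integer state matrix with no missing data
# (the simulator's sparse variable-site representation).
stats_from_tip_mat <- function(tip_mat, modern, historical, L, gd = "hd") {
  n <- nrow(tip_mat)
  S <- ncol(tip_mat)
  key <- if (S) {
    raw_mat <- matrix(as.raw(tip_mat + 64L), nrow = n)
    vapply(seq_len(n), function(i) rawToChar(raw_mat[i, ]), character(1))
  } else rep("", n)
  cm <- table(key[modern]); ch <- table(key[historical])
  H_m <- length(cm); H_h <- length(ch)
  P_m <- sum(!names(cm) %in% names(ch))
  P_h <- sum(!names(ch) %in% names(cm))
  gd_hap <- function(cnt) {
    nn <- sum(cnt)
    (nn / (nn - 1)) * (1 - sum((cnt / nn)^2))
  }
  if (S) {
    cnt_m <- site_base_counts(tip_mat[modern, , drop = FALSE])
    cnt_h <- site_base_counts(tip_mat[historical, , drop = FALSE])
    nm <- length(modern); nh <- length(historical)
    k_m <- sum(choose2(nm) - .rowSums(choose2(cnt_m), S, 4L)) / choose2(nm)
    k_h <- sum(choose2(nh) - .rowSums(choose2(cnt_h), S, 4L)) / choose2(nh)
    k_b <- sum(nm * nh - .rowSums(cnt_m * cnt_h, S, 4L)) / (nm * nh)
  } else {
    k_m <- k_h <- k_b <- 0
  }
  fst <- if (k_b == 0) 0 else 1 - ((k_m + k_h) / 2) / k_b
  GD_m <- if (gd == "hd") gd_hap(as.integer(cm)) else k_m / L
  GD_h <- if (gd == "hd") gd_hap(as.integer(ch)) else k_h / L
  stats::setNames(c(H_m, H_h, P_m, P_h, GD_m, GD_h, k_b, fst), ABC_STAT_NAMES)
}

# One ABC simulation replicate -> summary statistic vector (fast path:
# never materializes the monomorphic columns).
sim_summary_stats <- function(design, demo, mut, gd = "hd") {
  gen <- simulate_genealogy(design, demo, generation_time = mut$generation_time)
  vs <- sim_variable_sites(gen, mut)
  era <- gen$tips$era
  stats_from_tip_mat(vs$tip_mat, which(era == "modern"),
                     which(era == "historical"), mut$length, gd = gd)
}

#' Summary statistics for the temporal comparison
#'
#' Computes the 8-component summary statistic vector used by the ABC
#' analyses: haplotype counts, private haplotype counts and genetic
#' diversity for the modern and historical groups, plus mean pairwise
#' differences and Hudson's FST between the groups. "Genetic diversity" is
#' haplotype (gene) diversity by default; set `gd = "pi"` for per-site
#' nucleotide diversity. A monomorphic comparison (no differences within or
#' between groups) reports FST 0 by convention, applied identically to
#' observed and simulated data.
#'
#' @param modern,historical [mt_alignment] objects on a common column
#'   space, each with at least 2 sequences.
#' @param gd `"hd"` (haplotype diversity) or `"pi"`.
#' @param mode Haplotype-calling mode, see [call_haplotypes].
#' @return Named numeric vector of length 8 in fixed order.
#' @export
summarize_groups <- function(modern, historical, gd = c("hd", "pi"),
                             mode = "compatible") {
  gd <- match.arg(gd)
  if (aln_length(modern) != aln_length(historical)) {
    stop("groups must share a common column space")
  }
  if (aln_nseq(modern) < 2 || aln_nseq(historical) < 2) {
    stop("both groups need at least 2 sequences")
  }
  hm <- call_haplotypes(modern, mode = mode)
  hh <- call_haplotypes(historical, mode = mode)
  priv <- private_haplotypes(hm, hh)
  pwm <- pairwise_diff_stats(modern)
  pwh <- pairwise_diff_stats(historical)
  k_b <- between_group_diffs(unclass(modern), unclass(historical))$k_between
  fst <- if (k_b == 0) 0 else 1 - ((pwm$k_bar + pwh$k_bar) / 2) / k_b
  GD_m <- if (gd == "hd") haplotype_diversity(hm) else pwm$pi
  GD_h <- if (gd == "hd") haplotype_diversity(hh) else pwh$pi
  stats::setNames(c(hm$H, hh$H, priv$private_a, priv$private_b,
                    GD_m, GD_h, k_b, fst), ABC_STAT_NAMES)
}

#' Prior specification for the demographic models
#'
#' Default priors: log-uniform effective sizes on `[100, 100000]` females
#' per epoch (spanning plausible great-ape matrilineal scales without being
#' informative) and a uniform change time on `[30, 110]` years before
#' present. Order constraints of the decline/expansion models are enforced
#' at draw time. Model prior weights are equal.
#'
#' @param N_range Length-2 range of the log-uniform size prior.
#' @param t_range Length-2 range (years) of the uniform change-time prior.
#' @param model_weights Named or unnamed prior weights for
#'   constant/decline/expansion (normalized internally).
#' @return A `prior_spec`.
#' @export
prior_spec <- function(N_range = c(100, 1e5), t_range = c(30, 110),
                       model_weights = c(1, 1, 1)) {
  if (any(N_range <= 0) || N_range[2] <= N_range[1]) stop("invalid N_range")
  if (t_range[2] < t_range[1] || t_range[1] <= 0) stop("invalid t_range")
  structure(list(N_range = as.numeric(N_range), t_range = as.numeric(t_range),
                 model_weights = model_weights / sum(model_weights)),
            class = "prior_spec")
}

#' Draw a demographic model from the prior
#'
#' @param model `"constant"`, `"decline"` or `"expansion"`.
#' @param spec A [prior_spec].
#' @return A [demographic_model] satisfying the model's order constraint.
#' @export
draw_prior <- function(model = c("constant", "decline", "expansion"),
                       spec = prior_spec()) {
  model <- match.arg(model)
  lr <- log(spec$N_range)
  rN <- function(k) exp(stats::runif(k, lr[1], lr[2]))
  t_change <- stats::runif(1, spec$t_range[1], spec$t_range[2])
  if (model == "constant") {
    N <- rN(1L)
    return(demographic_model("constant", N, N, t_change))
  }
  repeat {
    N2 <- rN(2L)
    if (N2[1] != N2[2]) break
  }
  if (model == "decline") {
    demographic_model("decline", min(N2), max(N2), t_change)
  } else {
    demographic_model("expansion", max(N2), min(N2), t_change)
  }
}

row_seed <- function(seed, i) {
  as.integer((as.double(seed) %% 2147483629 + 104729 * as.double(i)) %% 2147483629) + 1L
}

#' Build an ABC reference table
#'
#' Runs `n_sims` simulations (equal numbers per model), each drawing
#' parameters from the prior and recording the 8 summary statistics. Every
#' row gets its own RNG seed derived from `seed`, so the table is
#' bit-identical regardless of the number of workers.
#'
#' @param n_sims Total number of simulations (>= 100, divisible by the
#'   number of models).
#' @param design A [sampling_design].
#' @param mut A [mutation_model].
#' @param spec A [prior_spec].
#' @param models Character vector of model classes to include.
#' @param seed Integer master seed.
#' @param workers Number of parallel workers (forked; per-row seeding keeps
#'   results identical across worker counts).
#' @param gd Genetic-diversity statistic, `"hd"` or `"pi"`.
#' @return An `abc_reference`: `data.frame` with model, parameters and
#'   statistics, plus standardization constants as attributes.
#' @export
build_reference_table <- function(n_sims, design, mut, spec = prior_spec(),
                                  models = c("constant", "decline", "expansion"),
                                  seed = 1L, workers = 1L, gd = "hd") {
  if (n_sims < 100) stop("n_sims must be >= 100")
  m <- length(models)
  per <- n_sims %/% m
  if (per * m != n_sims) {
    warning("n_sims not divisible by the number of models; using ", per * m, " rows")
  }
  model_of_row <- rep(models, each = per)
  n_rows <- length(model_of_row)

  one_row <- function(i) {
    set.seed(row_seed(seed, i))
    demo <- draw_prior(model_of_row[i], spec)
    st <- sim_summary_stats(design, demo, mut, gd = gd)
    c(N_present = demo$N_present, N_historical = demo$N_historical,
      t_change = demo$t_change, st)
  }
  rows <- if (workers > 1L) {
    parallel::mclapply(seq_len(n_rows), one_row, mc.cores = workers,
                       mc.preschedule = TRUE)
  } else {
    lapply(seq_len(n_rows), one_row)
  }
  tab <- as.data.frame(do.call(rbind, rows))
  tab <- cbind(model = model_of_row, tab, stringsAsFactors = FALSE)

  sm <- as.matrix(tab[, ABC_STAT_NAMES])
  structure(tab,
            class = c("abc_reference", "data.frame"),
            stat_means = colMeans(sm),
            stat_sds = apply(sm, 2L, stats::sd),
            design = design, mut = mut, prior = spec, gd = gd, seed = seed)
}

# Standardized Euclidean distances of every table row to the observed vector.
abc_distances <- function(table, observed) {
  means <- attr(table, "stat_means")
  sds <- attr(table, "stat_sds")
  use <- sds > 0
  sm <- as.matrix(table[, ABC_STAT_NAMES, drop = FALSE])
  z <- sweep(sweep(sm[, use, drop = FALSE], 2L, means[use]), 2L, sds[use], "/")
  z0 <- (observed[ABC_STAT_NAMES][use] - means[use]) / sds[use]
  sqrt(.rowSums(sweep(z, 2L, z0)^2, nrow(z), sum(use)))
}

#' Rejection step
#'
#' Accepts the `ceiling(proportion * nrow)` rows of the reference table
#' whose SD-standardized summary statistics are closest (Euclidean
#' distance) to the observed vector. Statistics with zero table SD carry no
#' information and are skipped. Ties are broken by row index, so the result
#' does not depend on table row order beyond that rule.
#'
#' @param table An `abc_reference`.
#' @param observed Named summary statistic vector from [summarize_groups].
#' @param proportion Acceptance proportion in `(0, 1]`.
#' @return The accepted subset of `table` with an extra `.distance` column;
#'   standardization attributes are carried along.
#' @export
abc_reject <- function(table, observed, proportion) {
  if (proportion <= 0 || proportion > 1) stop("proportion must be in (0, 1]")
  d <- abc_distances(table, observed)
  k <- ceiling(proportion * nrow(table))
  ord <- order(d, seq_along(d))[seq_len(k)]
  acc <- as.data.frame(table)[ord, , drop = FALSE]
  acc$.distance <- d[ord]
  structure(acc,
            stat_means = attr(table, "stat_means"),
            stat_sds = attr(table, "stat_sds"),
            observed = observed,
            class = c("abc_accepted", "data.frame"))
}

#' Posterior model probabilities across acceptance proportions
#'
#' For each acceptance proportion the posterior probability of each model is
#' its fraction among accepted rows. Reporting several proportions allows a
#' consistency check of the model-choice result.
#'
#' @param table An `abc_reference` built from at least 2 models.
#' @param observed Named summary statistic vector.
#' @param proportions Numeric vector of acceptance proportions; the default
#'   is 10 values evenly log-spaced on `[5e-5, 5e-4]`.
#' @return A `model_choice` list: `posterior` (`data.frame` proportion x
#'   model), `consistency` (per-model posterior range across proportions),
#'   `models`.
#' @export
model_posterior <- function(table, observed,
                            proportions = default_acceptance_proportions()) {
  models <- unique(table$model)
  if (length(models) < 2L) stop("model choice requires at least 2 models")
  d <- abc_distances(table, observed)
  ord <- order(d, seq_along(d))
  rows <- lapply(sort(proportions), function(p) {
    k <- ceiling(p * nrow(table))
    mm <- table$model[ord[seq_len(k)]]
    post <- vapply(models, function(m) mean(mm == m), numeric(1))
    data.frame(proportion = p, model = models, posterior = post,
               n_accepted = k, row.names = NULL)
  })
  post <- do.call(rbind, rows)
  consistency <- do.call(rbind, lapply(models, function(m) {
    v <- post$posterior[post$model == m]
    data.frame(model = m, min = min(v), max = max(v), range = max(v) - min(v))
  }))
  structure(list(posterior = post, consistency = consistency, models = models),
            class = "model_choice")
}

#' Default acceptance proportions (10 values, log-spaced on 5e-5 to 5e-4)
#' @return Numeric vector of length 10.
#' @export
default_acceptance_proportions <- function() {
  exp(seq(log(5e-5), log(5e-4), length.out = 10L))
}

#' @export
print.model_choice <- function(x, ...) {
  cat("ABC model choice over", length(unique(x$posterior$proportion)),
      "acceptance proportions\n")
  agg <- stats::aggregate(posterior ~ model, data = x$posterior, FUN = mean)
  print(agg, row.names = FALSE)
  invisible(x)
}

#' Local-linear regression adjustment of accepted parameters
#'
#' Beaumont-style post-rejection correction: the accepted parameter draws
#' (effective sizes on the log scale, change time raw) are regressed on the
#' standardized summary statistics with Epanechnikov weights in the
#' acceptance distance, and every draw is projected to the observed
#' statistics (`fitted value at the observed point + residual`). Effective
#' sizes are back-transformed to the natural scale. If the weighted design
#' matrix is singular the unadjusted draws are returned with a warning.
#'
#' @param accepted An `abc_accepted` from [abc_reject] (>= 30 rows
#'   recommended).
#' @param observed Named summary statistic vector; defaults to the vector
#'   stored during rejection.
#' @return A `data.frame` of adjusted posterior draws (`N_present`,
#'   `N_historical`, `t_change`, `model`, `weight`).
#' @export
regression_adjust <- function(accepted, observed = attr(accepted, "observed")) {
  means <- attr(accepted, "stat_means")
  sds <- attr(accepted, "stat_sds")
  use <- sds > 0
  sm <- as.matrix(accepted[, ABC_STAT_NAMES, drop = FALSE])
  X <- sweep(sweep(sm[, use, drop = FALSE], 2L, means[use]), 2L, sds[use], "/")
  x0 <- (observed[ABC_STAT_NAMES][use] - means[use]) / sds[use]
  d <- accepted$.distance
  dmax <- max(d)
  w <- if (dmax > 0) 1 - (d / dmax)^2 else rep(1, length(d))
  if (!any(w > 0)) w <- rep(1, length(d))
  w[w <= 0] <- min(w[w > 0], 1e-8) / 2   # keep the boundary draw in the sample

  Y <- cbind(log_N_present = log(accepted$N_present),
             log_N_historical = log(accepted$N_historical),
             t_change = accepted$t_change)
  # center predictors at the observed point: intercept = fit at observed
  Xc <- sweep(X, 2L, x0)
  fit <- stats::lm.wfit(cbind(1, Xc), Y, w)
  beta <- fit$coefficients
  # lm.wfit pivots rank-deficient designs: redundant predictors get NA
  # coefficients but fitted values and residuals stay valid, and the
  # intercept of the observed-centered design is the fit at the observed
  # point.
  if (is.na(beta[1L, 1L])) {
    warning("singular regression design; returning unadjusted draws")
    adj <- Y
  } else {
    fitted0 <- beta[1L, ]
    adj <- sweep(fit$residuals, 2L, fitted0, "+")
  }
  data.frame(N_present = exp(adj[, "log_N_present"]),
             N_historical = exp(adj[, "log_N_historical"]),
             t_change = adj[, "t_change"],
             model = accepted$model,
             weight = w, row.names = NULL)
}

# Weighted equal-tailed quantiles (linear interpolation on the weighted CDF).
weighted_quantile <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) - w / 2
  cw <- cw / sum(w)
  stats::approx(cw, x, xout = probs, rule = 2)$y
}

#' Estimate the population size reduction factor
#'
#' Summarizes the posterior of the ratio `N_historical / N_present` (values
#' above 1 indicate a decline) by its weighted median and equal-tailed 95%
#' credible interval.
#'
#' @param posterior `data.frame` of posterior draws from
#'   [regression_adjust] (or an unadjusted `abc_accepted`).
#' @return List with `median`, `ci95` (length-2), and the per-draw `ratio`.
#' @export
estimate_reduction <- function(posterior) {
  if (!NROW(posterior)) stop("empty posterior sample")
  ratio <- posterior$N_historical / posterior$N_present
  w <- if (!is.null(posterior$weight)) posterior$weight else rep(1, length(ratio))
  q <- weighted_quantile(ratio, w, c(0.025, 0.5, 0.975))
  list(median = q[2L], ci95 = c(q[1L], q[3L]), ratio = ratio, weight = w)
}

#' Full ABC parameter estimation
#'
#' Convenience wrapper: rejection at the given acceptance proportion,
#' regression adjustment, and reduction-factor summary.
#'
#' @param table An `abc_reference`.
#' @param observed Named summary statistic vector.
#' @param proportion Acceptance proportion.
#' @param models Optional subset of model classes to estimate from (default:
#'   all rows).
#' @return List with `posterior` (adjusted draws), `reduction`
#'   (see [estimate_reduction]), and `n_accepted`.
#' @export
abc_estimate <- function(table, observed, proportion = 0.01, models = NULL) {
  if (!is.null(models)) {
    keep <- table$model %in% models
    sub <- as.data.frame(table)[keep, , drop = FALSE]
    table <- structure(sub, class = c("abc_reference", "data.frame"),
                       stat_means = attr(table, "stat_means"),
                       stat_sds = attr(table, "stat_sds"))
  }
  acc <- abc_reject(table, observed, proportion)
  post <- regression_adjust(acc)
  list(posterior = post, reduction = estimate_reduction(post),
       n_accepted = nrow(acc))
}
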