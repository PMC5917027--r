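# Transition partner (A<->G, C<->T) and transversion partners per base code.
TS_PARTNER <- c(3L, 4L, 1L, 2L)
TV_PARTNERS <- matrix(c(2L, 4L,   # A -> C/T
                        1L, 3L,   # C -> A/G
                        2L, 4L,   # G -> C/T
                        1L, 3L),  # T -> A/G
                      nrow = 4L, byrow = TRUE)

#' Specify a single-change demographic model
#'
#' Piecewise-constant female effective population size with at most one
#' change event: `N_present` applies from the present back to `t_change`
#' years ago, `N_historical` before that. The three model classes used for
#' model choice are `constant` (sizes equal), `decline` (historical size
#' larger than present: the population shrank), and `expansion` (historical
#' smaller than present).
#'
#' @param model_class `"constant"`, `"decline"` or `"expansion"`.
#' @param N_present Present female effective size (number of females).
#' @param N_historical Historical female effective size; defaults to
#'   `N_present` for the constant model.
#' @param t_change Time of the size change in years before present.
#' @return A `demographic_model`.
#' @export
demographic_model <- function(model_class = c("constant", "decline", "expansion"),
                              N_present, N_historical = NULL, t_change = 70) {
  model_class <- match.arg(model_class)
  if (is.null(N_historical)) {
    if (model_class != "constant") stop("N_historical required for ", model_class)
    N_historical <- N_present
  }
  if (N_present <= 0 || N_historical <= 0) stop("effective sizes must be > 0")
  if (t_change <= 0) stop("t_change must be > 0")
  ok <- switch(model_class,
               constant = N_present == N_historical,
               decline = N_historical > N_present,
               expansion = N_historical < N_present)
  if (!ok) stop("sizes inconsistent with model class '", model_class, "'")
  structure(list(model_class = model_class, N_present = N_present,
                 N_historical = N_historical, t_change = t_change),
            class = "demographic_model")
}

#' Specify the mutation model
#'
#' Finite-sites substitution model with a transition/transversion bias and
#' symmetric base exchange (no gamma rate heterogeneity, equal base
#' frequencies). Each mutation event hits a uniformly chosen site; it is a
#' transition with probability `R/(R+1)` where `R = ts_tv_bias`, otherwise
#' one of the two possible transversions chosen uniformly.
#'
#' @param rate Substitution rate per site. By default interpreted per
#'   *year* (the mitochondrial rate in this system, 1.28e-8, comes from a
#'   deep-time calibration in years) and converted internally with
#'   `generation_time`; set `rate_units = "per_generation"` to skip the
#'   conversion.
#' @param ts_tv_bias Expected transition:transversion count ratio.
#' @param length Sequence length in sites.
#' @param generation_time Generation time in years (default 20).
#' @param rate_units `"per_year"` or `"per_generation"`.
#' @return A `mutation_model` with derived field `rate_per_gen`.
#' @export
mutation_model <- function(rate = 1.28e-8, ts_tv_bias = 0.933, length = 15000L,
                           generation_time = 20, rate_units = c("per_year", "per_generation")) {
  rate_units <- match.arg(rate_units)
  if (rate < 0 || ts_tv_bias <= 0 || generation_time <= 0 || length <= 0) {
    stop("rate must be >= 0; ts_tv_bias, length and generation_time must be > 0")
  }
  rate_per_gen <- if (rate_units == "per_year") rate * generation_time else rate
  structure(list(rate = rate, ts_tv_bias = ts_tv_bias, length = as.integer(length),
                 generation_time = generation_time, rate_units = rate_units,
                 rate_per_gen = rate_per_gen),
            class = "mutation_model")
}

#' Specify a heterochronous sampling design
#'
#' Lists how many sequences were sampled at which ages. Tips with age 0 form
#' the modern group, older tips the historical group, unless `era` is given
#' explicitly.
#'
#' @param ages_ybp Numeric vector of sample ages in years before the
#'   reference year.
#' @param counts Integer vector of sample counts per age (recycled).
#' @param reference_year Calendar year counted as the present.
#' @param era Optional character vector (`"historical"`/`"modern"`) per age
#'   entry.
#' @return A `sampling_design`.
#' @export
sampling_design <- function(ages_ybp, counts = 1L, reference_year = 2014L,
                            era = NULL) {
  counts <- rep_len(as.integer(counts), length(ages_ybp))
  if (any(ages_ybp < 0)) stop("sample ages must be >= 0")
  if (any(counts < 1L)) stop("sample counts must be >= 1")
  if (is.null(era)) era <- ifelse(ages_ybp == 0, "modern", "historical")
  era <- rep_len(era, length(ages_ybp))
  structure(list(ages_ybp = as.numeric(ages_ybp), counts = counts,
                 reference_year = reference_year, era = era),
            class = "sampling_design")
}

design_n <- function(design) sum(design$counts)

# Per-tip expansion of a sampling design.
design_tips <- function(design) {
  ages <- rep.int(design$ages_ybp, design$counts)
  era <- rep.int(design$era, design$counts)
  n <- length(ages)
  data.frame(id = sprintf("s%04d", seq_len(n)), age_ybp = ages, era = era,
             stringsAsFactors = FALSE)
}

#' Simulate a genealogy under the serial coalescent
#'
#' Backward-in-time haploid (mtDNA, female-only) coalescent with
#' heterochronous tips: each lineage becomes active at its sampling age
#' (converted to generations), and while `k` lineages are active they
#' coalesce at rate `k(k-1)/2 * 1/N(t)` per generation, with `N(t)`
#' piecewise constant switching from `N_present` to `N_historical` at
#' `t_change`. Waiting times are redrawn at activation and epoch boundaries
#' (valid by memorylessness of the exponential).
#'
#' @param design A [sampling_design] with at least 2 tips.
#' @param demo A [demographic_model].
#' @param generation_time Generation time in years.
#' @return A `genealogy`: list with `n_tips`, `parent` (0 for the root),
#'   `time` (node times in generations before present), `tip_ages`
#'   (generations), `tips` (per-tip metadata).
#' @export
simulate_genealogy <- function(design, demo, generation_time = 20) {
  tips <- design_tips(design)
  n <- nrow(tips)
  if (n < 2L) stop("at least 2 tips are required")
  tip_ages <- tips$age_ybp / generation_time
  t_change <- demo$t_change / generation_time

  n_nodes <- 2L * n - 1L
  parent <- integer(n_nodes)
  node_time <- numeric(n_nodes)
  node_time[seq_len(n)] <- tip_ages

  ord <- order(tip_ages)
  pend <- ord
  pend_age <- tip_ages[ord]
  active <- integer(0)
  t <- 0
  next_node <- n + 1L

  repeat {
    while (length(pend) && pend_age[1L] <= t) {
      active <- c(active, pend[1L])
      pend <- pend[-1L]
      pend_age <- pend_age[-1L]
    }
    k <- length(active)
    if (!length(pend) && k <= 1L) break
    boundary <- if (length(pend)) pend_age[1L] else Inf
    if (t < t_change) boundary <- min(boundary, t_change)
    if (k >= 2L) {
      N_cur <- if (t < t_change) demo$N_present else demo$N_historical
      w <- stats::rexp(1L, k * (k - 1L) / 2 / N_cur)
      if (t + w < boundary) {
        t <- t + w
        pick <- sample.int(k, 2L)
        parent[active[pick]] <- next_node
        node_time[next_node] <- t
        active <- c(active[-pick], next_node)
        next_node <- next_node + 1L
        next
      }
    }
    t <- boundary
  }

  structure(list(n_tips = n, parent = parent, time = node_time,
                 tip_ages = tip_ages, tips = tips),
            class = "genealogy")
}

#' Time to the most recent common ancestor of a genealogy
#' @param gen A `genealogy`.
#' @return TMRCA in generations before present.
#' @export
tmrca <- function(gen) gen$time[2L * gen$n_tips - 1L]

# Simulate mutation events on a genealogy and return the tip states at the
# mutated sites only (sparse representation used by the ABC fast path).
sim_variable_sites <- function(gen, mut) {
  n <- gen$n_tips
  L <- mut$length
  nodes <- seq_len(2L * n - 2L)
  blen <- gen$time[gen$parent[nodes]] - gen$time[nodes]
  counts <- stats::rpois(length(nodes), blen * mut$rate_per_gen * L)
  M <- sum(counts)
  empty <- list(sites = integer(0),
                tip_mat = matrix(integer(0), nrow = n, ncol = 0,
                                 dimnames = list(gen$tips$id, NULL)),
                root_states = integer(0), n_mutations = 0L, n_transitions = 0L)
  if (M == 0L) return(empty)

  branch <- rep.int(nodes, counts)
  sites <- sample.int(L, M, replace = TRUE)
  is_ts <- stats::runif(M) < mut$ts_tv_bias / (1 + mut$ts_tv_bias)
  tv_pick <- sample.int(2L, M, replace = TRUE)
  cand <- sort(unique(sites))
  S <- length(cand)
  site_idx <- match(sites, cand)
  root_states <- sample.int(4L, S, replace = TRUE)

  n_nodes <- 2L * n - 1L
  preorder <- order(gen$time[seq_len(n_nodes)], decreasing = TRUE)
  states <- matrix(0L, nrow = n_nodes, ncol = S)
  states[preorder[1L], ] <- root_states
  ev_by_branch <- split(seq_len(M), branch)
  for (node in preorder[-1L]) {
    st <- states[gen$parent[node], ]
    evs <- ev_by_branch[[as.character(node)]]
    if (!is.null(evs)) {
      for (e in evs) {
        s <- site_idx[e]
        cur <- st[s]
        st[s] <- if (is_ts[e]) TS_PARTNER[cur] else TV_PARTNERS[cur, tv_pick[e]]
      }
    }
    states[node, ] <- st
  }
  tip_mat <- states[seq_len(n), , drop = FALSE]
  rownames(tip_mat) <- gen$tips$id
  list(sites = cand, tip_mat = tip_mat, root_states = root_states,
       n_mutations = M, n_transitions = sum(is_ts))
}

#' Superimpose mutations on a genealogy
#'
#' Places `Poisson(branch_length * rate_per_generation * length)` mutation
#' events on every branch and evolves sequences down from a uniform-random
#' root sequence under the finite-sites Ts/Tv model of [mutation_model]
#' (repeat hits at a site are allowed). Attributes `n_mutations` and
#' `n_transitions` record the realized event counts.
#'
#' @param gen A `genealogy` from [simulate_genealogy].
#' @param mut A [mutation_model].
#' @return An [mt_alignment] with one row per tip.
#' @export
drop_mutations <- function(gen, mut) {
  vs <- sim_variable_sites(gen, mut)
  n <- gen$n_tips
  L <- mut$length
  root_full <- sample.int(4L, L, replace = TRUE)
  root_full[vs$sites] <- vs$root_states
  mat <- matrix(rep(root_full, each = n), nrow = n)
  if (length(vs$sites)) mat[, vs$sites] <- vs$tip_mat
  rownames(mat) <- gen$tips$id
  out <- validate_mt_alignment(structure(mat, class = "mt_alignment"))
  attr(out, "n_mutations") <- vs$n_mutations
  attr(out, "n_transitions") <- vs$n_transitions
  out
}

#' Simulate one heterochronous dataset
#'
#' One call corresponds to one simulation replicate: a genealogy under the
#' demographic model, mutations under the mutation model, and a sample table
#' with era labels derived from the sampling ages.
#'
#' @param design A [sampling_design].
#' @param demo A [demographic_model].
#' @param mut A [mutation_model] (its `generation_time` drives the
#'   year-to-generation conversion).
#' @param seed Optional integer seed for exact reproducibility.
#' @return List with `alignment` ([mt_alignment]), `table` (sample metadata
#'   `data.frame`), `genealogy`, and `tmrca_gen`.
#' @export
simulate_dataset <- function(design, demo, mut, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gen <- simulate_genealogy(design, demo, generation_time = mut$generation_time)
  aln <- drop_mutations(gen, mut)
  tab <- gen$tips
  tab$collection_year <- design$reference_year - tab$age_ybp
  tab$taxon <- "synthetic"
  list(alignment = aln, table = tab, genealogy = gen, tmrca_gen = tmrca(gen))
}
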