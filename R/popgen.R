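# Per-site counts of resolved bases (A,C,G,T) -> 4 x S integer matrix.
site_base_counts <- function(mat) {
  matrix(vapply(1:4, function(b) .colSums(mat == b, nrow(mat), ncol(mat)),
                numeric(ncol(mat))),
         ncol = 4L)
}

# Number of resolved-site differences between two encoded sequences.
resolved_diff <- function(a, b) {
  sum(a != b & a <= 4L & b <= 4L)
}

choose2 <- function(x) x * (x - 1) / 2

#' Call haplotypes from an alignment
#'
#' Groups sequences into haplotypes. Two rules are available for sequences
#' with missing data (`N`/`-`):
#'
#' * `"compatible"` (default): a sequence joins a haplotype iff it has zero
#'   differences over sites resolved in both against *every* current member.
#'   Sequences are processed from most to least complete (ties broken by id),
#'   so the most complete sequence seeds each haplotype. This avoids
#'   inflating the haplotype count from runs of `N` in museum samples.
#' * `"strict"`: columns with any missing data are excluded for all samples,
#'   then haplotypes are exact string matches on the remaining columns.
#'
#' Haplotype labels are deterministic: the lexicographically smallest member
#' id.
#'
#' @param aln An [mt_alignment].
#' @param mode `"compatible"` or `"strict"`.
#' @return A `haplotype_table`: list with `labels`, `counts`, `members`
#'   (list of id vectors), `representatives` (list of encoded sequences used
#'   for inter-haplotype distances), `n`, `H`, `mode`.
#' @export
call_haplotypes <- function(aln, mode = c("compatible", "strict")) {
  mode <- match.arg(mode)
  mat <- unclass(aln)
  ids <- rownames(mat)
  n <- nrow(mat)
  has_missing <- any(mat > 4L)

  if (mode == "strict" && has_missing) {
    keep <- .colSums(mat > 4L, n, ncol(mat)) == 0L
    if (!any(keep)) stop("strict mode: every column contains missing data")
    mat_cmp <- mat[, keep, drop = FALSE]
    groups <- split(seq_len(n), apply(mat_cmp, 1L, paste, collapse = ","))
    rep_source <- mat_cmp
  } else if (!has_missing) {
    groups <- split(seq_len(n), apply(mat, 1L, paste, collapse = ","))
    rep_source <- mat
  } else {
    # compatible merge: greedy, most-complete sequence first
    resolved <- .rowSums(mat <= 4L, n, ncol(mat))
    ord <- order(-resolved, ids)
    groups <- list()
    for (r in ord) {
      placed <- FALSE
      for (g in seq_along(groups)) {
        ok <- all(vapply(groups[[g]], function(m) {
          resolved_diff(mat[m, ], mat[r, ]) == 0L
        }, logical(1)))
        if (ok) {
          groups[[g]] <- c(groups[[g]], r)
          placed <- TRUE
          break
        }
      }
      if (!placed) groups[[length(groups) + 1L]] <- r
    }
    rep_source <- mat
  }

  names(groups) <- NULL
  labels <- vapply(groups, function(idx) min(ids[idx]), character(1))
  o <- order(labels)
  groups <- groups[o]
  labels <- labels[o]
  structure(list(
    labels = labels,
    counts = vapply(groups, length, integer(1)),
    members = lapply(groups, function(idx) sort(ids[idx])),
    representatives = lapply(groups, function(idx) rep_source[idx[1L], ]),
    n = n,
    H = length(groups),
    mode = mode
  ), class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat("haplotype_table:", x$H, "haplotypes from", x$n, "sequences (mode:", x$mode, ")\n")
  print(data.frame(label = x$labels, count = x$counts), row.names = FALSE)
  invisible(x)
}

#' Haplotype (gene) diversity
#'
#' `Hd = n/(n-1) * (1 - sum(p_i^2))` with `p_i` the haplotype frequencies:
#' the small-sample-corrected probability that two randomly drawn sequences
#' carry different haplotypes.
#'
#' @param counts Integer vector of haplotype counts, or a `haplotype_table`.
#' @param n Total sample size; defaults to `sum(counts)`.
#' @return Haplotype diversity in `[0, 1]`.
#' @export
haplotype_diversity <- function(counts, n = NULL) {
  if (inherits(counts, "haplotype_table")) counts <- counts$counts
  if (is.null(n)) n <- sum(counts)
  if (n < 2) stop("haplotype diversity requires n >= 2")
  p <- counts / n
  (n / (n - 1)) * (1 - sum(p^2))
}

#' Mean pairwise differences and nucleotide diversity
#'
#' `k_bar` is the mean number of nucleotide differences over all unordered
#' sequence pairs, counting only sites resolved in both members of a pair
#' (pairwise deletion). `pi` is `k_bar` normalized by the mean
#' pairwise-resolved comparison length, i.e. per-site nucleotide diversity.
#'
#' @param aln An [mt_alignment].
#' @return List with `k_bar`, `pi`, `S` (segregating sites) and
#'   `mean_resolved_length`.
#' @export
pairwise_diff_stats <- function(aln) {
  mat <- unclass(aln)
  n <- nrow(mat)
  if (n < 2) stop("pairwise statistics require n >= 2")
  cnt <- site_base_counts(mat)                      # sites x 4
  r <- .rowSums(cnt, nrow(cnt), 4L)                 # resolved sequences per site
  same <- .rowSums(choose2(cnt), nrow(cnt), 4L)     # resolved equal pairs per site
  diff_pairs <- choose2(r) - same                   # resolved differing pairs per site
  npairs <- choose2(n)
  k_bar <- sum(diff_pairs) / npairs
  mean_len <- sum(choose2(r)) / npairs
  if (mean_len == 0) stop("no pair of sequences shares a resolved site")
  list(k_bar = k_bar,
       pi = k_bar / mean_len,
       S = sum(.rowSums(cnt > 0L, nrow(cnt), 4L) >= 2L),
       mean_resolved_length = mean_len)
}

# Tajima (1989) constants for sample size n.
tajima_constants <- function(n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D
#'
#' Standardized difference between the mean-pairwise-difference and
#' segregating-sites estimators of the population mutation rate. Negative
#' values indicate an excess of rare variants, consistent with population
#' expansion or purifying selection. Missing sites are handled by pairwise
#' deletion; `S` is the total number of segregating sites.
#'
#' @param aln An [mt_alignment] with at least 4 sequences.
#' @return Tajima's D, or `NA` (with a warning) when undefined (`S = 0`).
#' @export
tajimas_d <- function(aln) {
  n <- aln_nseq(aln)
  if (n < 4) stop("Tajima's D requires n >= 4")
  st <- pairwise_diff_stats(aln)
  S <- st$S
  if (S < 1) {
    warning("Tajima's D is undefined on a monomorphic alignment (S = 0)")
    return(NA_real_)
  }
  cst <- tajima_constants(n)
  (st$k_bar - S / cst$a1) / sqrt(cst$e1 * S + cst$e2 * S * (S - 1))
}

# Mean pairwise differences between two groups (pairwise deletion).
between_group_diffs <- function(matA, matB) {
  cntA <- site_base_counts(matA)
  cntB <- site_base_counts(matB)
  rA <- .rowSums(cntA, nrow(cntA), 4L)
  rB <- .rowSums(cntB, nrow(cntB), 4L)
  same <- .rowSums(cntA * cntB, nrow(cntA), 4L)
  cross <- rA * rB
  npairs <- nrow(matA) * nrow(matB)
  list(k_between = sum(cross - same) / npairs,
       mean_len = sum(cross) / npairs)
}

#' Hudson's FST between two groups
#'
#' `FST = 1 - Hw / Hb`, where `Hw` is the average of the two within-group
#' mean pairwise difference counts and `Hb` the between-group mean pairwise
#' difference count (Hudson, Slatkin & Maddison 1992 form), all means taken
#' over distinct sequence pairs. The raw estimate is returned; like any
#' unbiased FST estimator it can be slightly negative for panmictic groups
#' (two groups of identical composition give `-1/(n-1)`, which vanishes with
#' sample size).
#'
#' @param groupA,groupB [mt_alignment] objects on a common column space,
#'   each with at least 2 sequences.
#' @return The raw FST estimate; `NA` (with a warning) when both within- and
#'   between-group differences are zero.
#' @export
hudson_fst <- function(groupA, groupB) {
  if (aln_length(groupA) != aln_length(groupB)) {
    stop("groups must share a common column space")
  }
  kw <- (pairwise_diff_stats(groupA)$k_bar + pairwise_diff_stats(groupB)$k_bar) / 2
  kb <- between_group_diffs(unclass(groupA), unclass(groupB))$k_between
  if (kb == 0) {
    if (kw == 0) {
      warning("FST undefined: no variation within or between groups")
      return(NA_real_)
    }
    stop("FST undefined: zero between-group differences with within-group variation")
  }
  1 - kw / kb
}

#' Private and shared haplotypes between two groups
#'
#' Haplotypes of the two groups are matched on a common column space using
#' the same zero-resolved-difference rule as [call_haplotypes]: a haplotype
#' is shared when some haplotype of the other group is compatible with it,
#' private otherwise. `privA + privB + shared` equals the number of distinct
#' haplotypes in the union.
#'
#' @param tabA,tabB `haplotype_table` objects from alignments on a common
#'   column space (and the same calling mode).
#' @return List with `private_a`, `private_b`, `shared`.
#' @export
private_haplotypes <- function(tabA, tabB) {
  reps <- c(tabA$representatives, tabB$representatives)
  origin <- rep(c("a", "b"), c(tabA$H, tabB$H))
  if (length(unique(lengths(reps))) != 1L) {
    stop("haplotype tables are not on a common column space")
  }
  resolved <- vapply(reps, function(x) sum(x <= 4L), integer(1))
  ord <- order(-resolved)
  clusters <- list()
  for (i in ord) {
    placed <- FALSE
    for (g in seq_along(clusters)) {
      ok <- all(vapply(clusters[[g]], function(j) {
        resolved_diff(reps[[j]], reps[[i]]) == 0L
      }, logical(1)))
      if (ok) {
        clusters[[g]] <- c(clusters[[g]], i)
        placed <- TRUE
        break
      }
    }
    if (!placed) clusters[[length(clusters) + 1L]] <- i
  }
  origins <- lapply(clusters, function(idx) unique(origin[idx]))
  shared <- sum(vapply(origins, function(o) length(o) == 2L, logical(1)))
  priv_a <- sum(vapply(origins, function(o) identical(o, "a"), logical(1)))
  priv_b <- sum(vapply(origins, function(o) identical(o, "b"), logical(1)))
  list(private_a = priv_a, private_b = priv_b, shared = shared)
}

#' Per-group diversity summary
#'
#' Computes the standard diversity panel for one alignment: sample size,
#' haplotype count, haplotype diversity, mean pairwise differences, per-site
#' nucleotide diversity, segregating sites and Tajima's D.
#'
#' @param aln An [mt_alignment] with at least 2 sequences.
#' @param mode Haplotype-calling mode, see [call_haplotypes].
#' @return One-row `data.frame` with columns `n`, `H`, `Hd`, `k_bar`, `pi`,
#'   `S`, `tajima_d`.
#' @export
diversity_stats <- function(aln, mode = "compatible") {
  hap <- call_haplotypes(aln, mode = mode)
  pw <- pairwise_diff_stats(aln)
  td <- if (aln_nseq(aln) >= 4 && pw$S >= 1) tajimas_d(aln) else NA_real_
  data.frame(n = hap$n, H = hap$H,
             Hd = haplotype_diversity(hap),
             k_bar = pw$k_bar, pi = pw$pi, S = pw$S,
             tajima_d = td)
}

#' Diversity summary for a list of groups
#' @param groups Named list of [mt_alignment] objects (e.g. from
#'   [partition_alignment]).
#' @param mode Haplotype-calling mode.
#' @return `data.frame` with one row per group.
#' @export
group_diversity <- function(groups, mode = "compatible") {
  out <- do.call(rbind, lapply(groups, diversity_stats, mode = mode))
  cbind(group = names(groups), out, row.names = NULL)
}

#' Write a per-group diversity table as CSV
#' @param stats `data.frame` from [group_diversity].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_diversity_csv <- function(stats, path) {
  utils::write.csv(stats, path, row.names = FALSE)
  invisible(path)
}
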