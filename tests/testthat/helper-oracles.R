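# Independent oracle implementations used to cross-check the package's
# statistics. These deliberately use naive enumeration (double loops over
# sequence pairs, per-column scans) rather than the package's count-based
# identities.

aln_strings <- function(aln) as.character(aln)

# Brute-force mean pairwise differences and mean resolved comparison length.
oracle_pairwise <- function(aln) {
  s <- strsplit(aln_strings(aln), "")
  n <- length(s)
  diffs <- 0
  lens <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !(s[[i]] %in% c("N", "-")) & !(s[[j]] %in% c("N", "-"))
      diffs <- diffs + sum(s[[i]][ok] != s[[j]][ok])
      lens <- lens + sum(ok)
    }
  }
  np <- n * (n - 1) / 2
  list(k_bar = diffs / np, mean_len = lens / np, pi = diffs / lens)
}

# Brute-force segregating sites: columns with two or more distinct resolved
# bases.
oracle_S <- function(aln) {
  s <- do.call(rbind, strsplit(aln_strings(aln), ""))
  sum(apply(s, 2, function(col) {
    length(unique(col[!col %in% c("N", "-")])) >= 2
  }))
}

# Tajima's D written out directly from the 1989 definitions.
oracle_tajima <- function(aln) {
  n <- length(aln_strings(aln))
  S <- oracle_S(aln)
  k <- oracle_pairwise(aln)$k_bar
  a1 <- sum(1 / (1:(n - 1)))
  a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (k - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Haplotype diversity from exact string identity (valid when no missing
# data are present).
oracle_hd <- function(aln) {
  cnt <- as.integer(table(aln_strings(aln)))
  n <- sum(cnt)
  (n / (n - 1)) * (1 - sum((cnt / n)^2))
}

# All spanning trees of a small complete graph, by brute force over
# Pruefer sequences; returns the minimum total weight.
oracle_mst_weight <- function(d) {
  H <- nrow(d)
  if (H == 2) return(d[1, 2])
  seqs <- expand.grid(rep(list(seq_len(H)), H - 2))
  best <- Inf
  for (r in seq_len(nrow(seqs))) {
    prufer <- as.integer(seqs[r, ])
    degree <- rep(1L, H) + tabulate(prufer, H)
    w <- 0
    pr <- prufer
    for (step in seq_len(H - 2)) {
      leaf <- which(degree == 1L)[1L]
      w <- w + d[leaf, pr[1L]]
      degree[leaf] <- 0L
      degree[pr[1L]] <- degree[pr[1L]] - 1L
      pr <- pr[-1L]
    }
    last <- which(degree >= 1L)
    w <- w + d[last[1L], last[2L]]
    best <- min(best, w)
  }
  best
}

# Random small alignment generator for property-style tests.
random_alignment <- function(n, L, missing_frac = 0, n_hap = NULL) {
  if (is.null(n_hap)) {
    mat <- matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE), nrow = n)
  } else {
    haps <- matrix(sample(c("A", "C", "G", "T"), n_hap * L, replace = TRUE),
                   nrow = n_hap)
    mat <- haps[sample.int(n_hap, n, replace = TRUE), , drop = FALSE]
  }
  if (missing_frac > 0) {
    idx <- sample.int(n * L, round(missing_frac * n * L))
    mat[idx] <- "N"
  }
  mt_alignment(apply(mat, 1, paste, collapse = ""),
               ids = sprintf("r%03d", seq_len(n)))
}

mask_columns_for_test <- function(m) {
  unlist(lapply(seq_len(nrow(m)), function(i) (m[i, "start"] + 1):m[i, "end"]))
}

aln_subset_for_test <- function(aln, rows) {
  m <- unclass(aln)[rows, , drop = FALSE]
  class(m) <- "mt_alignment"
  m
}

resolved_diff_for_test <- function(a, b) sum(a != b & a <= 4L & b <= 4L)
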