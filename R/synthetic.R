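#' Built-in study-like sampling designs
#'
#' Returns the sampling design of the two eastern gorilla mitogenome study
#' groups emulated by the synthetic-data generator: Grauer's gorillas with
#' 68 historical samples (collection years 1910-1980) and 29 modern samples
#' (2014), and mountain gorillas with 18 historical samples (1913-1956) and
#' 8 modern samples. Sequence length defaults to 15,000 sites
#' (a mitogenome with the D-loop removed); the reference year is 2014.
#'
#' @param taxon `"grauer"` or `"mountain"`.
#' @param length Sequence length in sites.
#' @return A `study_design`: list with per-era counts and year ranges.
#' @export
builtin_design <- function(taxon = c("grauer", "mountain"), length = 15000L) {
  taxon <- match.arg(taxon)
  des <- switch(taxon,
    grauer = list(historical_n = 68L, historical_years = c(1910L, 1980L),
                  modern_n = 29L, modern_year = 2014L),
    mountain = list(historical_n = 18L, historical_years = c(1913L, 1956L),
                    modern_n = 8L, modern_year = 2014L))
  structure(c(des, list(taxon = taxon, length = as.integer(length),
                        reference_year = 2014L)),
            class = "study_design")
}

#' Realize a study design as an explicit sampling design
#'
#' Converts the per-era counts and year ranges of a [builtin_design] into a
#' per-sample [sampling_design]. Historical collection years are drawn
#' uniformly from the design's year range (seeded), or supplied explicitly.
#'
#' @param design A `study_design`.
#' @param seed Seed for the uniform year draw.
#' @param historical_years Optional explicit vector of historical collection
#'   years (length `historical_n`), overriding the uniform draw.
#' @return A [sampling_design] with one age per sample.
#' @export
realize_design <- function(design, seed = 1L, historical_years = NULL) {
  if (is.null(historical_years)) {
    set.seed(seed)
    historical_years <- sample(seq(design$historical_years[1L],
                                   design$historical_years[2L]),
                               design$historical_n, replace = TRUE)
  }
  if (length(historical_years) != design$historical_n) {
    stop("need ", design$historical_n, " historical years")
  }
  ages <- c(design$reference_year - historical_years,
            rep(design$reference_year - design$modern_year, design$modern_n))
  era <- c(rep("historical", design$historical_n),
           rep("modern", design$modern_n))
  sampling_design(ages, counts = 1L, reference_year = design$reference_year,
                  era = era)
}

#' Generate a complete synthetic study dataset
#'
#' Simulates a study-like dataset (FASTA alignment, TSV metadata and a JSON
#' truth file recording the generating model, parameters, per-sample ages,
#' TMRCA and seed) under a given demographic and mutation model. Optionally
#' plants missing data (`N` runs) in a subset of sequences to exercise the
#' missing-data filters.
#'
#' @param design A `study_design` from [builtin_design].
#' @param demo A [demographic_model].
#' @param mut A [mutation_model]; its `length` is overridden by the design's.
#' @param seed Integer seed (drives the year draw, the coalescent and the
#'   mutation process).
#' @param dir Output directory (created if needed); when `NULL`, nothing is
#'   written and only the in-memory objects are returned.
#' @param missing_frac Optional numeric vector: for each element, one
#'   sequence receives that fraction of missing (`N`) sites.
#' @return List with `alignment`, `table`, `truth`, and (when `dir` is
#'   given) `paths`.
#' @export
generate_study <- function(design, demo, mut, seed = 1L, dir = NULL,
                           missing_frac = NULL) {
  mut$length <- design$length
  sdes <- realize_design(design, seed = seed)
  sim <- simulate_dataset(sdes, demo, mut, seed = row_seed(seed, 1L))
  aln <- sim$alignment
  tab <- sim$table
  tab$taxon <- design$taxon

  if (!is.null(missing_frac)) {
    if (length(missing_frac) > aln_nseq(aln)) stop("more missing fractions than sequences")
    mat <- unclass(aln)
    set.seed(row_seed(seed, 2L))
    for (i in seq_along(missing_frac)) {
      k <- round(missing_frac[i] * ncol(mat))
      mat[i, sample.int(ncol(mat), k)] <- 5L
    }
    aln <- validate_mt_alignment(structure(mat, class = "mt_alignment"))
  }

  truth <- list(taxon = design$taxon, model = demo$model_class,
                N_present = demo$N_present, N_historical = demo$N_historical,
                t_change = demo$t_change,
                mutation = list(rate = mut$rate, ts_tv_bias = mut$ts_tv_bias,
                                length = mut$length,
                                generation_time = mut$generation_time),
                tmrca_gen = sim$tmrca_gen,
                sample_ages_ybp = tab$age_ybp,
                missing_frac = missing_frac,
                seed = seed)

  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(fasta = file.path(dir, paste0(design$taxon, "_synthetic.fasta")),
                  metadata = file.path(dir, paste0(design$taxon, "_synthetic.tsv")),
                  truth = file.path(dir, paste0(design$taxon, "_truth.json")))
    write_alignment(aln, paths$fasta)
    utils::write.table(tab[, c("id", "taxon", "era", "collection_year", "age_ybp")],
                       paths$metadata, sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
  }
  list(alignment = aln, table = tab, truth = truth, paths = paths)
}

#' Hand-checkable toy fixtures
#'
#' Small alignments whose statistics are known exactly, each paired with its
#' truth values:
#'
#' * `tajima_n4`: 4 sequences, 2 singleton sites; Tajima's D = -0.710.
#' * `fst_fixed`: two fixed monomorphic groups; Hudson's FST = 1.
#' * `mono`: monomorphic; `Hd = 0`, `S = 0`, Tajima's D undefined.
#' * `hap_missing`: `{AA, AN, TT}`; compatible merging gives 2 haplotypes.
#' * `counts211`: haplotype counts `{2, 1, 1}`; `Hd = 0.8333`.
#'
#' @return Named list; each element has `alignment` and `truth`.
#' @export
toy_fixtures <- function() {
  list(
    tajima_n4 = list(
      alignment = mt_alignment(c(a = "TA", b = "AT", c = "AA", d = "AA")),
      truth = list(S = 2L, k_bar = 1.0, tajima_d = -0.70989)),
    fst_fixed = list(
      alignment = mt_alignment(c(a1 = "AAAA", a2 = "AAAA",
                                 b1 = "TTTT", b2 = "TTTT")),
      truth = list(groups = c("a", "a", "b", "b"), fst = 1.0, k_between = 4.0)),
    mono = list(
      alignment = mt_alignment(c(m1 = "ACGT", m2 = "ACGT", m3 = "ACGT",
                                 m4 = "ACGT")),
      truth = list(Hd = 0.0, S = 0L, tajima_d = NA)),
    hap_missing = list(
      alignment = mt_alignment(c(x = "AA", y = "AN", z = "TT")),
      truth = list(H_compatible = 2L)),
    counts211 = list(
      alignment = mt_alignment(c(h1 = "AAAA", h2 = "AAAA", h3 = "ATAA",
                                 h4 = "AATA")),
      truth = list(H = 3L, counts = c(2L, 1L, 1L), Hd = 5 / 6))
  )
}
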