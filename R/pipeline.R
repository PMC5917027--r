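#' Run a pipeline stage
#'
#' Single programmatic entry point wiring the package's stages. `config` is
#' a named list (or path to a JSON file with the same structure). Common
#' fields: `fasta`, `meta`, `mask`, `annotation` (input paths), `outdir`
#' (required), `group_by`, `seed` (required for stochastic subcommands),
#' plus stage-specific settings. Every run writes its artifacts plus a
#' machine-readable `manifest.json` (package version, config echo, MD5 of
#' all inputs and outputs); two runs with identical config and seed produce
#' identical artifacts and manifests.
#'
#' Subcommands:
#' * `stats`: per-group diversity table (`group_stats.csv`).
#' * `permute`: subsampled diversity comparison between two groups
#'   (`resample_*.csv`, `comparison.json`).
#' * `network`: minimum spanning haplotype network (`network.graphml`,
#'   `network_edges.tsv`).
#' * `variants`: variant classification table (`variants.tsv`).
#' * `synth`: synthetic study dataset (FASTA/TSV/truth JSON).
#' * `simulate`: one simulated dataset under an explicit model.
#' * `abc-build`: reference table (`reference_table.csv`).
#' * `abc-modelchoice`: model posteriors (`model_choice.json`).
#' * `abc-estimate`: reduction-factor posterior (`estimate.json`,
#'   `posterior.csv`).
#' * `pods`: POD power report (`pod_power.json`, `pod_records.csv`).
#'
#' @param subcommand One of the stage names above.
#' @param config Named list or path to a JSON config.
#' @return Invisibly, a list with `outputs` (paths) and `manifest`.
#' @export
run_pipeline <- function(subcommand, config) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  cfg <- config
  if (is.null(cfg$outdir)) stop("config$outdir is required")
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  stochastic <- c("permute", "synth", "simulate", "abc-build",
                  "abc-modelchoice", "abc-estimate", "pods")
  if (subcommand %in% stochastic && is.null(cfg$seed)) {
    stop("config$seed is required for subcommand '", subcommand, "'")
  }

  inputs <- character(0)
  out <- list()
  add_input <- function(p) if (!is.null(p)) inputs <<- c(inputs, p)

  load_groups <- function() {
    aln <- read_alignment(cfg$fasta)
    add_input(cfg$fasta)
    if (!is.null(cfg$mask)) {
      aln <- apply_mask(aln, read_mask_bed(cfg$mask))
      add_input(cfg$mask)
    }
    if (!is.null(cfg$max_missing_frac)) aln <- filter_missing(aln, cfg$max_missing_frac)
    tab <- read_sample_table(cfg$meta)
    add_input(cfg$meta)
    keys <- if (!is.null(cfg$group_by)) cfg$group_by else "era"
    list(aln = aln, tab = tab,
         groups = partition_alignment(aln, tab, keys))
  }
  get_mut <- function() {
    m <- cfg$mutation
    mutation_model(rate = m$rate %||% 1.28e-8,
                   ts_tv_bias = m$ts_tv_bias %||% 0.933,
                   length = m$length %||% 15000L,
                   generation_time = m$generation_time %||% 20)
  }
  get_prior <- function() {
    p <- cfg$prior
    if (is.null(p)) prior_spec() else
      prior_spec(N_range = p$N_range %||% c(100, 1e5),
                 t_range = p$t_range %||% c(30, 110))
  }
  read_table_csv <- function() {
    add_input(cfg$reference_table)
    read_reference_table(cfg$reference_table)
  }
  get_observed <- function() {
    g <- load_groups()
    if (!all(c("modern", "historical") %in% names(g$groups))) {
      stop("grouping must yield 'modern' and 'historical' groups; set group_by = \"era\"")
    }
    summarize_groups(g$groups$modern, g$groups$historical,
                     gd = cfg$gd %||% "hd")
  }

  if (subcommand == "stats") {
    g <- load_groups()
    st <- group_diversity(g$groups)
    out$stats <- file.path(cfg$outdir, "group_stats.csv")
    write_diversity_csv(st, out$stats)
  } else if (subcommand == "permute") {
    g <- load_groups()
    if (length(g$groups) < 2L) stop("permute needs at least 2 groups")
    nm <- names(g$groups)[1:2]
    target <- cfg$target_n %||% min(vapply(g$groups, aln_nseq, integer(1)))
    stat <- cfg$statistic %||% "Hd"
    dA <- subsample_stat(g$groups[[nm[1]]], target, cfg$n_reps %||% 1000L,
                         stat, seed = row_seed(cfg$seed, 1L))
    dB <- subsample_stat(g$groups[[nm[2]]], target, cfg$n_reps %||% 1000L,
                         stat, seed = row_seed(cfg$seed, 2L))
    cmp <- compare_groups(dA, dB, seed = row_seed(cfg$seed, 3L))
    out$resample_a <- file.path(cfg$outdir, paste0("resample_", nm[1], ".csv"))
    out$resample_b <- file.path(cfg$outdir, paste0("resample_", nm[2], ".csv"))
    out$comparison <- file.path(cfg$outdir, "comparison.json")
    write_resample_csv(dA, out$resample_a)
    write_resample_csv(dB, out$resample_b)
    jsonlite::write_json(unclass(cmp), out$comparison, auto_unbox = TRUE, digits = NA)
  } else if (subcommand == "network") {
    g <- load_groups()
    hap <- call_haplotypes(g$aln, mode = cfg$haplotype_mode %||% "compatible")
    keys <- if (!is.null(cfg$group_by)) cfg$group_by else "era"
    grp_of <- stats::setNames(
      do.call(paste, c(lapply(keys, function(k) g$tab[[k]]), sep = ".")),
      g$tab$id)
    net <- min_spanning_network(hap, groups = grp_of)
    out$graphml <- file.path(cfg$outdir, "network.graphml")
    out$edges <- file.path(cfg$outdir, "network_edges.tsv")
    write_network_graphml(net, out$graphml)
    write_network_edgelist(net, out$edges)
  } else if (subcommand == "variants") {
    g <- load_groups()
    ann <- read_annotation(cfg$annotation)
    add_input(cfg$annotation)
    v <- classify_variants(g$aln, ann)
    out$variants <- file.path(cfg$outdir, "variants.tsv")
    write_variant_tsv(v, out$variants)
  } else if (subcommand == "synth") {
    des <- builtin_design(cfg$taxon %||% "grauer",
                          length = cfg$length %||% 15000L)
    demo <- demographic_model(cfg$model %||% "constant",
                              N_present = cfg$N_present %||% 5000,
                              N_historical = cfg$N_historical,
                              t_change = cfg$t_change %||% 70)
    res <- generate_study(des, demo, get_mut(), seed = cfg$seed,
                          dir = cfg$outdir,
                          missing_frac = cfg$missing_frac)
    out <- res$paths
  } else if (subcommand == "simulate") {
    demo <- demographic_model(cfg$model %||% "constant",
                              N_present = cfg$N_present %||% 5000,
                              N_historical = cfg$N_historical,
                              t_change = cfg$t_change %||% 70)
    mut <- get_mut()
    des <- sampling_design(cfg$ages_ybp, cfg$counts %||% 1L)
    sim <- simulate_dataset(des, demo, mut, seed = cfg$seed)
    out$fasta <- file.path(cfg$outdir, "simulated.fasta")
    out$meta <- file.path(cfg$outdir, "simulated.tsv")
    out$truth <- file.path(cfg$outdir, "truth.json")
    write_alignment(sim$alignment, out$fasta)
    utils::write.table(sim$table, out$meta, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    jsonlite::write_json(list(model = demo$model_class,
                              N_present = demo$N_present,
                              N_historical = demo$N_historical,
                              t_change = demo$t_change,
                              tmrca_gen = sim$tmrca_gen, seed = cfg$seed),
                         out$truth, auto_unbox = TRUE, digits = NA)
  } else if (subcommand == "abc-build") {
    des <- realize_design(builtin_design(cfg$taxon %||% "grauer",
                                         length = cfg$length %||% 15000L),
                          seed = cfg$seed)
    tab <- build_reference_table(cfg$n_sims %||% 30000L, des, get_mut(),
                                 spec = get_prior(), seed = cfg$seed,
                                 workers = cfg$workers %||% 1L,
                                 gd = cfg$gd %||% "hd")
    out$table <- file.path(cfg$outdir, "reference_table.csv")
    write_reference_table(tab, out$table)
  } else if (subcommand == "abc-modelchoice") {
    tab <- read_table_csv()
    obs <- get_observed()
    props <- cfg$acceptance %||% c(0.005, 0.01, 0.02)
    mc <- model_posterior(tab, obs, proportions = props)
    out$model_choice <- file.path(cfg$outdir, "model_choice.json")
    jsonlite::write_json(list(observed = as.list(obs),
                              posterior = mc$posterior,
                              consistency = mc$consistency),
                         out$model_choice, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  } else if (subcommand == "abc-estimate") {
    tab <- read_table_csv()
    obs <- get_observed()
    est <- abc_estimate(tab, obs, proportion = cfg$acceptance %||% 0.01,
                        models = cfg$models)
    out$estimate <- file.path(cfg$outdir, "estimate.json")
    out$posterior <- file.path(cfg$outdir, "posterior.csv")
    jsonlite::write_json(list(observed = as.list(obs),
                              n_accepted = est$n_accepted,
                              reduction_median = est$reduction$median,
                              reduction_ci95 = est$reduction$ci95),
                         out$estimate, auto_unbox = TRUE, digits = NA)
    utils::write.csv(est$posterior, out$posterior, row.names = FALSE)
  } else if (subcommand == "pods") {
    tab <- read_table_csv()
    demo <- demographic_model(cfg$model %||% "decline",
                              N_present = cfg$N_present %||% 2000,
                              N_historical = cfg$N_historical %||% 9000,
                              t_change = cfg$t_change %||% 70)
    rep <- run_pods(tab, demo, n_pods = cfg$n_pods %||% 50L,
                    seed = cfg$seed)
    out$power <- file.path(cfg$outdir, "pod_power.json")
    out$records <- file.path(cfg$outdir, "pod_records.csv")
    jsonlite::write_json(rep[setdiff(names(rep), "records")], out$power,
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(rep$records, out$records, row.names = FALSE)
  } else {
    stop("unknown subcommand: ", subcommand)
  }

  manifest <- list(
    package = "mitotempo",
    version = as.character(utils::packageVersion("mitotempo")),
    subcommand = subcommand,
    config = cfg,
    inputs = as.list(tools::md5sum(unique(inputs))),
    outputs = as.list(tools::md5sum(unlist(out, use.names = FALSE)))
  )
  manifest_path <- file.path(cfg$outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(list(outputs = out, manifest = manifest,
                 manifest_path = manifest_path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Persist an ABC reference table as CSV with a metadata header
#'
#' The table is written as plain CSV preceded by `#`-prefixed JSON metadata
#' lines carrying the standardization constants and run settings, so a
#' reloaded table behaves identically in rejection and adjustment.
#'
#' @param table An `abc_reference`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_reference_table <- function(table, path) {
  design <- attr(table, "design")
  mut <- attr(table, "mut")
  meta <- list(stat_means = as.list(attr(table, "stat_means")),
               stat_sds = as.list(attr(table, "stat_sds")),
               gd = attr(table, "gd"), seed = attr(table, "seed"),
               design = unclass(design), mut = unclass(mut),
               prior = unclass(attr(table, "prior")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA)),
             con)
  utils::write.csv(as.data.frame(table), con, row.names = FALSE)
  invisible(path)
}

#' Load an ABC reference table written by [write_reference_table]
#' @param path Path to the CSV file.
#' @return An `abc_reference`.
#' @export
read_reference_table <- function(path) {
  if (!file.exists(path)) stop("reference table not found: ", path)
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "# ")) stop("missing metadata header in ", path)
  meta <- jsonlite::fromJSON(sub("^# ", "", first))
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  design <- sampling_design(meta$design$ages_ybp, meta$design$counts,
                            reference_year = meta$design$reference_year,
                            era = meta$design$era)
  mut <- mutation_model(rate = meta$mut$rate, ts_tv_bias = meta$mut$ts_tv_bias,
                        length = meta$mut$length,
                        generation_time = meta$mut$generation_time,
                        rate_units = meta$mut$rate_units)
  prior <- prior_spec(N_range = meta$prior$N_range, t_range = meta$prior$t_range)
  structure(tab, class = c("abc_reference", "data.frame"),
            stat_means = unlist(meta$stat_means)[ABC_STAT_NAMES],
            stat_sds = unlist(meta$stat_sds)[ABC_STAT_NAMES],
            design = design, mut = mut, prior = prior,
            gd = meta$gd, seed = meta$seed)
}
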