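# Complement in the internal encoding (A<->T, C<->G; N/- unchanged).
COMPLEMENT_CODE <- c(4L, 3L, 2L, 1L, 5L, 6L)

get_pam250 <- function() {
  e <- new.env()
  utils::data("PAM250", package = "Biostrings", envir = e)
  e$PAM250
}

#' Read a gene annotation table
#'
#' Tab-separated, header required, columns: `gene`, `start`, `end` (0-based
#' half-open on the alignment), `strand` (`+`/`-`), `frame` (0-2 offset of
#' the first complete codon), `type` (`coding`, `rRNA`, `tRNA`).
#'
#' @param path Path to the annotation TSV.
#' @return A `data.frame`.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("gene", "start", "end", "strand", "frame", "type")
  missing_cols <- setdiff(needed, names(ann))
  if (length(missing_cols)) {
    stop("annotation is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (any(ann$end <= ann$start)) stop("annotation intervals must satisfy start < end")
  if (!all(ann$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  ann
}

# Majority-rule consensus in internal codes; ties resolved toward the
# alphabetically first base; all-missing columns stay N (code 5).
consensus_codes <- function(mat) {
  cnt <- site_base_counts(mat)
  cons <- max.col(cnt, ties.method = "first")
  cons[.rowSums(cnt, nrow(cnt), 4L) == 0L] <- 5L
  as.integer(cons)
}

# Translate a length-3 vector of internal codes with the vertebrate
# mitochondrial genetic code; NA when any base is missing.
translate_codon <- function(codes, code_table) {
  if (any(codes > 4L)) return(NA_character_)
  codon <- paste(MT_ALPHABET[codes], collapse = "")
  unname(code_table[codon])
}

#' Classify segregating sites
#'
#' Classifies every segregating site of the alignment: substitution class
#' (transition for A/G and C/T pairs, transversion otherwise, `multiallelic`
#' for >2 resolved alleles), genomic context from the annotation, and for
#' biallelic sites inside coding genes the coding effect (synonymous,
#' nonsynonymous, stop_gained) with the PAM250 score of the amino-acid
#' change. Changes with PAM250 score >= 0 are flagged as substitutions
#' commonly observed in nature. The reference allele at each site is the
#' majority allele; codon context comes from the majority-rule consensus.
#'
#' @param aln An [mt_alignment].
#' @param annotation `data.frame` from [read_annotation]. Coordinates must
#'   refer to the same column space as `aln` (mask the alignment and the
#'   annotation consistently).
#' @return `data.frame` with one row per segregating site: `position`
#'   (0-based), `major`, `minor` (or `alleles` for multiallelic sites),
#'   `class`, `context`, `gene`, `effect`, `aa_ref`, `aa_alt`, `pam250`,
#'   `pam250_acceptable`.
#' @export
classify_variants <- function(aln, annotation) {
  mat <- unclass(aln)
  cnt <- site_base_counts(mat)
  n_alleles <- .rowSums(cnt > 0L, nrow(cnt), 4L)
  seg <- which(n_alleles >= 2L)
  cons <- consensus_codes(mat)
  code_table <- Biostrings::getGeneticCode("2")
  pam <- get_pam250()

  rows <- lapply(seg, function(s) {
    pos0 <- s - 1L
    alleles <- order(cnt[s, ], decreasing = TRUE)[seq_len(n_alleles[s])]
    hit <- which(annotation$start <= pos0 & pos0 < annotation$end)
    gene <- if (length(hit)) annotation$gene[hit[1L]] else NA_character_
    context <- if (length(hit)) annotation$type[hit[1L]] else "non-coding"
    out <- data.frame(position = pos0,
                      major = MT_ALPHABET[alleles[1L]],
                      minor = MT_ALPHABET[alleles[2L]],
                      alleles = paste(MT_ALPHABET[sort(alleles)], collapse = "/"),
                      class = NA_character_, context = context, gene = gene,
                      effect = NA_character_, aa_ref = NA_character_,
                      aa_alt = NA_character_, pam250 = NA_integer_,
                      pam250_acceptable = NA)
    if (n_alleles[s] > 2L) {
      out$class <- "multiallelic"
      out$major <- NA_character_
      out$minor <- NA_character_
      return(out)
    }
    a <- alleles[1L]; b <- alleles[2L]
    out$class <- if (sum(c(a, b) %in% c(1L, 3L)) %in% c(0L, 2L)) "transition" else "transversion"
    if (context != "coding" || !length(hit)) return(out)

    h <- hit[1L]
    strand <- annotation$strand[h]
    frame <- annotation$frame[h]
    if (strand == "+") {
      idx <- pos0 - (annotation$start[h] + frame)
      if (idx < 0L) return(out)
      codon_pos0 <- annotation$start[h] + frame + (idx %/% 3L) * 3L + 0:2
      if (max(codon_pos0) >= annotation$end[h]) return(out)
      ref_codes <- cons[codon_pos0 + 1L]
      at <- idx %% 3L + 1L
    } else {
      first <- annotation$end[h] - 1L - frame
      idx <- first - pos0
      if (idx < 0L) return(out)
      codon_pos0 <- first - ((idx %/% 3L) * 3L + 0:2)
      if (min(codon_pos0) < annotation$start[h]) return(out)
      ref_codes <- COMPLEMENT_CODE[cons[codon_pos0 + 1L]]
      at <- idx %% 3L + 1L
    }
    site_major <- if (strand == "+") a else COMPLEMENT_CODE[a]
    site_minor <- if (strand == "+") b else COMPLEMENT_CODE[b]
    ref_codes[at] <- site_major
    alt_codes <- ref_codes
    alt_codes[at] <- site_minor
    aa_ref <- translate_codon(ref_codes, code_table)
    aa_alt <- translate_codon(alt_codes, code_table)
    out$aa_ref <- aa_ref
    out$aa_alt <- aa_alt
    if (is.na(aa_ref) || is.na(aa_alt)) return(out)
    if (aa_alt == aa_ref) {
      out$effect <- "synonymous"
    } else if (aa_alt == "*") {
      out$effect <- "stop_gained"
    } else {
      out$effect <- "nonsynonymous"
    }
    if (!aa_ref %in% rownames(pam) || !aa_alt %in% rownames(pam)) return(out)
    out$pam250 <- pam[aa_ref, aa_alt]
    out$pam250_acceptable <- out$pam250 >= 0L
    out
  })
  if (!length(rows)) {
    return(data.frame(position = integer(0), major = character(0),
                      minor = character(0), alleles = character(0),
                      class = character(0), context = character(0),
                      gene = character(0), effect = character(0),
                      aa_ref = character(0), aa_alt = character(0),
                      pam250 = integer(0), pam250_acceptable = logical(0)))
  }
  do.call(rbind, rows)
}

#' Write a variant classification table as TSV
#' @param variants `data.frame` from [classify_variants].
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_variant_tsv <- function(variants, path) {
  utils::write.table(variants, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
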