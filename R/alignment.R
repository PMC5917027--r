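# Internal base encoding used throughout the package.
# A=1, C=2, G=3, T=4, N=5, -=6. Codes 5 and 6 count as missing:
# museum-sample assemblies use both N and the alignment gap character
# for unresolved positions.
MT_ALPHABET <- c("A", "C", "G", "T", "N", "-")
MT_MISSING <- 5L:6L

#' Construct an alignment of mitochondrial genome sequences
#'
#' An `mt_alignment` holds equal-length aligned sequences over the alphabet
#' `A, C, G, T, N, -`. Internally sequences are stored as an integer matrix
#' (one row per sample, one column per alignment site); `N` and `-` are
#' treated as missing data by every downstream statistic.
#'
#' @param seqs Character vector of aligned sequences (equal length), or an
#'   integer matrix already in the internal encoding.
#' @param ids Character vector of unique sample identifiers.
#' @return An object of class `mt_alignment`.
#' @export
mt_alignment <- function(seqs, ids = names(seqs)) {
  if (is.matrix(seqs) && is.integer(seqs)) {
    mat <- seqs
    if (!is.null(ids)) rownames(mat) <- ids
  } else {
    ids <- if (is.null(ids)) names(seqs) else ids
    seqs <- toupper(as.character(seqs))
    if (length(seqs) == 0L) stop("alignment must contain at least one sequence")
    widths <- nchar(seqs)
    if (length(unique(widths)) != 1L) {
      stop("sequences are not aligned: lengths ", paste(sort(unique(widths)), collapse = ", "))
    }
    if (widths[1L] == 0L) stop("alignment length must be > 0")
    chars <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                    nrow = length(seqs), byrow = TRUE)
    mat <- matrix(match(chars, MT_ALPHABET), nrow = nrow(chars))
    if (anyNA(mat)) {
      bad <- unique(chars[is.na(mat)])
      stop("invalid characters in alignment: ", paste(bad, collapse = " "))
    }
    rownames(mat) <- ids
  }
  validate_mt_alignment(structure(mat, class = "mt_alignment"))
}

validate_mt_alignment <- function(x) {
  if (!is.matrix(x) || typeof(x) != "integer") stop("alignment must be an integer matrix")
  if (ncol(x) == 0L) stop("alignment length must be > 0")
  if (nrow(x) == 0L) stop("alignment must contain at least one sequence")
  ids <- rownames(x)
  if (is.null(ids) || anyNA(ids) || any(ids == "")) stop("every sequence needs an identifier")
  if (anyDuplicated(ids)) {
    stop("duplicate sequence identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (anyNA(x) || any(x < 1L) || any(x > 6L)) stop("invalid base codes in alignment")
  x
}

#' @export
print.mt_alignment <- function(x, ...) {
  cat("mt_alignment:", nrow(x), "sequences x", ncol(x), "sites\n")
  miss <- mean(unclass(x) %in% MT_MISSING)
  cat(sprintf("  missing (N/-): %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
as.character.mt_alignment <- function(x, ...) {
  out <- apply(unclass(x), 1L, function(r) paste(MT_ALPHABET[r], collapse = ""))
  names(out) <- rownames(x)
  out
}

#' Sample identifiers of an alignment
#' @param aln An `mt_alignment`.
#' @return Character vector of sample ids.
#' @export
aln_ids <- function(aln) rownames(aln)

#' Alignment length in sites
#' @param aln An `mt_alignment`.
#' @return Integer number of columns (sites).
#' @export
aln_length <- function(aln) ncol(aln)

#' Number of sequences in an alignment
#' @param aln An `mt_alignment`.
#' @return Integer number of sequences.
#' @export
aln_nseq <- function(aln) nrow(aln)

# Row/column subsetting that preserves the class and validates.
aln_subset <- function(aln, rows = NULL, cols = NULL) {
  m <- unclass(aln)
  if (!is.null(rows)) m <- m[rows, , drop = FALSE]
  if (!is.null(cols)) m <- m[, cols, drop = FALSE]
  validate_mt_alignment(structure(m, class = "mt_alignment"))
}

#' Read an aligned FASTA file
#'
#' Reads a multiple sequence alignment from FASTA. Records must be of equal
#' length; lowercase bases are normalized to uppercase; any character outside
#' `A, C, G, T, N, -` is rejected. The id of each record is the first
#' whitespace-separated token of its header.
#'
#' @param path Path to a FASTA file.
#' @return An [mt_alignment].
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(ss))
  mt_alignment(as.character(ss), ids = ids)
}

#' Write an alignment to FASTA
#' @param aln An [mt_alignment].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_alignment <- function(aln, path) {
  ss <- Biostrings::BStringSet(as.character(aln))
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}

#' Construct a set of mask intervals
#'
#' Intervals are 0-based half-open (BED convention). Overlapping or adjacent
#' intervals are merged during normalization.
#'
#' @param start,end Integer vectors of interval starts (inclusive) and ends
#'   (exclusive), 0-based.
#' @return A `mask_set`: a two-column integer matrix with attributes.
#' @export
mask_set <- function(start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (length(start) != length(end)) stop("start and end must have equal length")
  if (any(is.na(start)) || any(is.na(end))) stop("NA interval bounds")
  if (any(start < 0L)) stop("interval starts must be >= 0")
  if (any(end <= start)) stop("intervals must satisfy start < end")
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  # merge overlapping intervals
  if (length(start) > 1L) {
    ks <- start[1L]; ke <- end[1L]; ms <- integer(0); me <- integer(0)
    for (i in 2L:length(start)) {
      if (start[i] <= ke) {
        ke <- max(ke, end[i])
      } else {
        ms <- c(ms, ks); me <- c(me, ke); ks <- start[i]; ke <- end[i]
      }
    }
    start <- c(ms, ks); end <- c(me, ke)
  }
  structure(cbind(start = start, end = end), class = "mask_set")
}

#' Read mask intervals from a BED file
#'
#' BED coordinates are 0-based half-open and are used unchanged. The
#' chromosome column is ignored: masks address alignment columns, not genome
#' coordinates, so all intervals are expected to refer to the single aligned
#' reference.
#'
#' @param path Path to a BED file.
#' @return A [mask_set].
#' @export
read_mask_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  gr <- rtracklayer::import(path, format = "BED")
  if (length(gr) == 0L) stop("BED file contains no intervals: ", path)
  # GRanges is 1-based closed; convert back to BED 0-based half-open.
  mask_set(GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr))
}

check_mask_bounds <- function(mask, len) {
  if (!inherits(mask, "mask_set")) mask <- mask_set(mask[, 1L], mask[, 2L])
  if (any(mask[, "end"] > len)) {
    stop("mask interval out of bounds for alignment of length ", len)
  }
  mask
}

mask_columns <- function(mask) {
  unlist(lapply(seq_len(nrow(mask)), function(i) {
    (mask[i, "start"] + 1L):mask[i, "end"]
  }), use.names = FALSE)
}

#' Delete masked columns from an alignment
#'
#' Removes all alignment columns covered by the mask (e.g. the hypervariable
#' D-loop, which is prone to assembly error in degraded samples). Remaining
#' columns keep their original order.
#'
#' @param aln An [mt_alignment].
#' @param mask A [mask_set] of 0-based half-open intervals.
#' @return The masked [mt_alignment].
#' @export
apply_mask <- function(aln, mask) {
  mask <- check_mask_bounds(mask, aln_length(aln))
  drop <- mask_columns(mask)
  if (length(drop) >= aln_length(aln)) {
    stop("mask covers the whole alignment; a zero-length alignment is not valid")
  }
  aln_subset(aln, cols = -drop)
}

#' Extract named regions from an alignment
#'
#' Returns only the columns inside the given intervals, concatenated in
#' interval order: the complement of [apply_mask]. Used, for instance, to
#' restrict a mitogenome alignment to single marker genes (COX1-3, CYTB,
#' 16S rRNA) for marker-resolution comparisons.
#'
#' @param aln An [mt_alignment].
#' @param intervals A [mask_set] of 0-based half-open intervals.
#' @return The extracted [mt_alignment].
#' @export
extract_region <- function(aln, intervals) {
  intervals <- check_mask_bounds(intervals, aln_length(aln))
  keep <- mask_columns(intervals)
  aln_subset(aln, cols = keep)
}

#' Drop sequences with too much missing data
#'
#' Removes sequences whose fraction of missing sites (`N` or `-`) is strictly
#' greater than `max_missing_frac`. The ids of dropped sequences are attached
#' as attribute `"dropped"` and can be written out with
#' [write_dropped_report].
#'
#' @param aln An [mt_alignment].
#' @param max_missing_frac Maximum tolerated missing fraction in `[0, 1]`;
#'   default 0.25.
#' @return The filtered [mt_alignment] with attribute `"dropped"`.
#' @export
filter_missing <- function(aln, max_missing_frac = 0.25) {
  if (max_missing_frac < 0 || max_missing_frac > 1) {
    stop("max_missing_frac must be in [0, 1]")
  }
  frac <- rowMeans(matrix(unclass(aln) %in% MT_MISSING, nrow = nrow(aln)))
  drop <- frac > max_missing_frac
  if (all(drop)) stop("all sequences exceed the missing-data threshold")
  out <- aln_subset(aln, rows = !drop)
  attr(out, "dropped") <- data.frame(id = rownames(aln)[drop],
                                     missing_frac = frac[drop])
  out
}

#' Write the dropped-sample report of [filter_missing] as TSV
#' @param aln A filtered alignment carrying a `"dropped"` attribute.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_dropped_report <- function(aln, path) {
  rep <- attr(aln, "dropped")
  if (is.null(rep)) rep <- data.frame(id = character(0), missing_frac = numeric(0))
  utils::write.table(rep, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-sample metadata from TSV
#'
#' The file must be tab-separated with a header and columns `id`, `taxon`,
#' `era` (`historical`/`modern`), `collection_year`; optional columns
#' `region_flag` (`inside`/`outside` the current range), `lat`, `lon`.
#' `age_ybp` (years before the reference year) is derived from
#' `collection_year`.
#'
#' @param path Path to a TSV file.
#' @param reference_year Calendar year counted as "the present"; default 2014.
#' @return A `data.frame` with one row per sample.
#' @export
read_sample_table <- function(path, reference_year = 2014L) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("id", "taxon", "era", "collection_year")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols)) {
    stop("metadata is missing required columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(tab$id)) stop("duplicate sample ids in metadata")
  bad_era <- setdiff(unique(tab$era), c("historical", "modern"))
  if (length(bad_era)) stop("unknown era values: ", paste(bad_era, collapse = ", "))
  tab$age_ybp <- reference_year - tab$collection_year
  if (any(tab$age_ybp < 0, na.rm = TRUE)) {
    stop("collection_year after the reference year ", reference_year)
  }
  tab
}

#' Partition an alignment by metadata keys
#'
#' Splits an alignment into groups by one or more metadata columns (for
#' example `c("taxon", "era")` to form the historical/modern groups of each
#' subspecies). The groups are disjoint and exhaustive.
#'
#' @param aln An [mt_alignment].
#' @param table Metadata `data.frame` from [read_sample_table].
#' @param keys Character vector of column names in `table`.
#' @return Named list of [mt_alignment] objects; names are the key values
#'   joined by `"."`.
#' @export
partition_alignment <- function(aln, table, keys) {
  ids <- aln_ids(aln)
  missing_ids <- setdiff(ids, table$id)
  if (length(missing_ids)) {
    stop("alignment ids missing from metadata: ", paste(missing_ids, collapse = ", "))
  }
  bad_keys <- setdiff(keys, names(table))
  if (length(bad_keys)) stop("unknown metadata columns: ", paste(bad_keys, collapse = ", "))
  row <- match(ids, table$id)
  label <- do.call(paste, c(lapply(keys, function(k) table[[k]][row]), sep = "."))
  lapply(split(seq_along(ids), label), function(idx) aln_subset(aln, rows = idx))
}
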