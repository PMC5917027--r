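test_that("FASTA reading validates and normalizes records", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1 some description", "acgt", ">s2", "ACGA"), fa)
  aln <- read_alignment(fa)
  expect_equal(aln_length(aln), 4L)
  expect_equal(aln_ids(aln), c("s1", "s2"))
  expect_equal(unname(as.character(aln)), c("ACGT", "ACGA"))

  writeLines(c(">a", "ACGT", ">b", "ACGTA"), fa)
  expect_error(read_alignment(fa), "aligned")
  writeLines(c(">a", "ACGT", ">a", "ACGA"), fa)
  expect_error(read_alignment(fa), "[Dd]uplicate")
  writeLines(character(0), fa)
  expect_error(read_alignment(fa), "empty")
  writeLines(c(">a", "ACRT"), fa)
  expect_error(read_alignment(fa), "invalid characters")
})

test_that("masking deletes columns and respects bounds", {
  aln <- mt_alignment(c(x = "ACGTACGTAC"))
  masked <- apply_mask(aln, mask_set(2, 4))
  expect_equal(unname(as.character(masked)), "ACACGTAC")
  expect_error(apply_mask(aln, mask_set(0, 10)), "whole alignment")
  expect_error(apply_mask(aln, mask_set(5, 12)), "out of bounds")
  # overlapping intervals are merged during normalization
  m <- mask_set(c(2, 3, 8), c(5, 6, 9))
  expect_equal(nrow(m), 2L)
  expect_equal(aln_length(apply_mask(aln, m)), 10L - 4L - 1L)
})

test_that("extract_region is the complement of apply_mask", {
  set.seed(11)
  aln <- random_alignment(5, 40)
  mask <- mask_set(c(3, 20), c(10, 31))
  comp <- mask_set(c(0, 10, 31), c(3, 20, 40))
  expect_equal(as.character(extract_region(aln, comp)),
               as.character(apply_mask(aln, mask)))
  expect_equal(unname(as.character(extract_region(mt_alignment(c(a = "ACGTACGT")),
                                                  mask_set(0, 4)))), "ACGT")
  # stitching masked and kept columns back together restores the original
  kept <- extract_region(aln, comp)
  cut <- extract_region(aln, mask)
  rebuilt <- matrix(NA_integer_, nrow = 5, ncol = 40)
  rebuilt[, mask_columns_for_test(comp)] <- unclass(kept)
  rebuilt[, mask_columns_for_test(mask)] <- unclass(cut)
  expect_equal(unname(rebuilt), unname(unclass(aln)[, , drop = FALSE]))
})

test_that("extracting a region never increases the haplotype count", {
  set.seed(12)
  for (rep in 1:5) {
    aln <- random_alignment(25, 60, n_hap = 12)
    H_full <- call_haplotypes(aln)$H
    sub <- extract_region(aln, mask_set(10, 35))
    expect_lte(call_haplotypes(sub)$H, H_full)
  }
})

test_that("filter_missing drops by strict threshold and is idempotent", {
  aln <- mt_alignment(c(keep0 = "ACGTACGTAC",   # 0 missing
                        keep1 = "ACGTACGTNN",   # 0.2
                        drop1 = "ACGTACGNNN",   # 0.3 > 0.25
                        drop2 = "NNNNN-----"))  # 1.0
  out <- filter_missing(aln, 0.25)
  expect_equal(aln_ids(out), c("keep0", "keep1"))
  expect_equal(attr(out, "dropped")$id, c("drop1", "drop2"))
  # a sequence exactly at the threshold is kept (strictly greater rule)
  at <- mt_alignment(c(a = "ACGTACGTAC", b = "ACNNGTACGT", c = "ANNNNACGTA"))
  expect_equal(aln_ids(filter_missing(at, 0.2)), c("a", "b"))
  out2 <- filter_missing(out, 0.25)
  expect_equal(as.character(out2), as.character(out))
  expect_error(filter_missing(mt_alignment(c(x = "NNNN")), 0.25), "all sequences")
})

test_that("partition is a disjoint exhaustive split keyed on metadata", {
  tab <- data.frame(id = c("a", "b", "c", "d"),
                    taxon = c("g", "g", "m", "m"),
                    era = c("historical", "modern", "historical", "historical"))
  aln <- mt_alignment(c(a = "AAAA", b = "CCCC", c = "GGGG", d = "TTTT"))
  parts <- partition_alignment(aln, tab, c("taxon", "era"))
  expect_setequal(names(parts), c("g.historical", "g.modern", "m.historical"))
  all_ids <- unlist(lapply(parts, aln_ids), use.names = FALSE)
  expect_setequal(all_ids, aln_ids(aln))
  expect_equal(length(all_ids), aln_nseq(aln))
  expect_error(partition_alignment(aln, tab[1:3, ], "era"), "missing from metadata")
  # single key covering everything is the identity partition
  one <- partition_alignment(aln, transform(tab, g = "all"), "g")
  expect_equal(length(one), 1L)
  expect_setequal(aln_ids(one$all), aln_ids(aln))
})

test_that("BED masks round-trip through rtracklayer import", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("ref\t2\t4", "ref\t6\t8"), bed)
  m <- read_mask_bed(bed)
  expect_equal(unname(m[, "start"]), c(2L, 6L))
  expect_equal(unname(m[, "end"]), c(4L, 8L))
  aln <- mt_alignment(c(x = "ACGTACGTAC"))
  expect_equal(unname(as.character(apply_mask(aln, m))), "ACACAC")
})

test_that("sample tables validate required columns and derive ages", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\ttaxon\tera\tcollection_year",
               "a\tgrauer\thistorical\t1950",
               "b\tgrauer\tmodern\t2014"), tsv)
  tab <- read_sample_table(tsv)
  expect_equal(tab$age_ybp, c(64, 0))
  writeLines(c("id\ttaxon\tera\tcollection_year",
               "a\tgrauer\tancient\t1950"), tsv)
  expect_error(read_sample_table(tsv), "era")
  writeLines(c("id\ttaxon\tcollection_year", "a\tgrauer\t1950"), tsv)
  expect_error(read_sample_table(tsv), "missing required columns")
})
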