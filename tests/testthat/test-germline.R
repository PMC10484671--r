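# Germline reference reading, filtering, trimming and collapsing.

test_that("FASTA reading parses IMGT pipe headers, plain headers and gaps", {
  path <- write_fasta(
    c("X92343|IGHV3-64*02|Homo sapiens|F|V-REGION|1..296",
      "IGHV1-2*01 some description",
      "IGHV9-9*01|Homo sapiens|P|"),
    c("AC...GT", "ACGTACGT", "ACGTACGTA"))
  ref <- read_germline_fasta(path)
  expect_equal(ref$allele, c("IGHV3-64*02", "IGHV1-2*01", "IGHV9-9*01"))
  expect_equal(ref$functionality, c("functional", "unknown", "pseudogene"))
  expect_equal(ref$sequence[1], "ACGT")
  expect_equal(ref$gapped_sequence[1], "AC...GT")
  expect_equal(ref$gene, c("IGHV3-64", "IGHV1-2", "IGHV9-9"))
  expect_equal(ref$subgroup, c("IGHV3", "IGHV1", "IGHV9"))
  expect_equal(attr(ref, "coordinates"), "imgt_gapped")
})

test_that("read errors are distinct: missing file, empty file, duplicates", {
  expect_error(read_germline_fasta(tempfile()), class = "ascgeno_io_error")
  empty <- tempfile(fileext = ".fasta"); file.create(empty)
  expect_error(read_germline_fasta(empty), class = "ascgeno_empty_error")
  dup <- write_fasta(c("IGHV1-2*01", "IGHV1-2*01"), c("ACGT", "ACGA"))
  expect_error(read_germline_fasta(dup), class = "ascgeno_duplicate_error")
})

test_that("functionality table overrides header annotations", {
  path <- write_fasta(c("IGHV1-2*01", "IGHV1-3*01"), c("ACGT", "ACGA"))
  ft <- tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(allele = "IGHV1-3*01", functionality = "P"), ft)
  ref <- read_germline_fasta(path, functionality_table = ft)
  expect_equal(ref$functionality, c("unknown", "pseudogene"))
})

test_that("filter_functional removes non-functional alleles and whole subgroups", {
  ref <- germline_reference(
    c("IGHV8-1*01", "IGHV8-2*01", "IGHV1-1*01", "IGHV1-1*02"),
    c("AAAA", "AAAC", "CCCC", "CCCA"),
    functionality = c("pseudogene", "ORF", "functional", "unknown"))
  out <- filter_functional(ref)
  expect_false("IGHV8" %in% out$subgroup)
  expect_equal(out$allele, c("IGHV1-1*01", "IGHV1-1*02"))
  expect_equal(attr(out, "removed"), c("IGHV8-1*01", "IGHV8-2*01"))
  strict <- filter_functional(ref, strict = TRUE)
  expect_equal(strict$allele, "IGHV1-1*01")
  all_f <- germline_reference("IGHV1-1*01", "ACGT", "functional")
  expect_equal(filter_functional(all_f)$allele, all_f$allele)
  empty <- germline_reference(character(0), character(0))
  expect_equal(nrow(filter_functional(empty)), 0L)
})

test_that("filter_complete_v keeps alleles covering positions 1 through end", {
  ref <- germline_reference(
    c("IGHV1-1*01", "IGHV1-2*01", "IGHV1-3*01"),
    c(strrep("A", 10),                       # covers 1-10
      paste0("....", strrep("C", 6)),        # starts at position 5
      strrep("G", 8)),                       # covers 1-8 only
    functionality = "functional")
  out <- filter_complete_v(ref, end = 10L)
  expect_equal(out$allele, "IGHV1-1*01")
  ungapped <- germline_reference("IGHV1-1*01", "ACGT", coordinates = "unknown")
  expect_error(filter_complete_v(ungapped, end = 2L),
               class = "ascgeno_coordinates_error")
})

test_that("3' trimming truncates at the trim position and enables collapsing", {
  base <- strrep("ACGT", 80)                  # 320 nt
  ref <- germline_reference(
    c("IGHV3-66*01", "IGHV3-66*04", "IGHV1-1*01"),
    c(base,
      paste0(substr(base, 1, 318), "AA"),     # differs only at 319-320
      substr(base, 1, 318)),
    functionality = "functional")
  out <- trim_three_prime(ref, end = 318L)
  expect_true(all(nchar(out$gapped_sequence) == 318L))
  expect_equal(attr(out, "trim_end"), 318L)
  # alleles differing only beyond the trim point become identical
  expect_equal(out$sequence[1], out$sequence[2])
  # already-short-enough allele unchanged
  expect_equal(out$sequence[3], ref$sequence[3])
  short <- germline_reference("IGHV1-1*01", "ACGT")
  expect_error(trim_three_prime(short, end = 318L),
               class = "ascgeno_coverage_error")
})

test_that("amplicon variants trim 5' windows and only collapse sequences", {
  base <- strrep("ACGT", 80)
  # two alleles differing only in the first 20 nt (FW1-like region)
  fw1_variant <- paste0(strrep("T", 20), substr(base, 21, 320))
  ref <- germline_reference(
    c("IGHV1-1*01", "IGHV1-1*02"), c(base, fw1_variant),
    functionality = "functional")
  s1 <- make_amplicon_variant(ref, amplicon_spec("S1", 1, 318))
  expect_equal(s1$sequence, trim_three_prime(ref, 318)$sequence)
  expect_equal(attr(s1, "amplicon_class"), "S1")
  s2 <- make_amplicon_variant(ref, amplicon_spec("S2", 25, 318))
  expect_equal(s2$sequence[1], s2$sequence[2])
  expect_error(amplicon_spec("bad", 10, 10), class = "ascgeno_spec_error")
})

test_that("unique-sequence counts are non-increasing along nested amplicon windows", {
  set.seed(42)
  seqs <- replicate(12, paste(sample(c("A", "C", "G", "T"), 318, replace = TRUE),
                              collapse = ""))
  # force some sequences to agree beyond position 100
  seqs[2] <- paste0(strrep("A", 100), substr(seqs[1], 101, 318))
  seqs[4] <- paste0(strrep("C", 250), substr(seqs[3], 251, 318))
  ref <- germline_reference(sprintf("IGHV1-%d*01", 1:12), seqs,
                            functionality = "functional")
  counts <- vapply(list(c(1, 318), c(101, 318), c(251, 318)), function(w) {
    v <- make_amplicon_variant(ref, amplicon_spec("w", w[1], w[2]))
    length(unique(v$sequence))
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("collapse_identical merges duplicates deterministically and maps every name", {
  ref <- germline_reference(
    c("IGHV3-64D*06", "IGHV3-64*06", "IGHV1-2*01"),
    c("ACGTACGT", "ACGTACGT", "TTTTAAAA"),
    functionality = "functional")
  out <- collapse_identical(ref)
  expect_equal(nrow(out), 2L)
  # natural-sort-smallest representative ("IGHV3-64*06" < "IGHV3-64D*06")
  expect_true("IGHV3-64*06" %in% out$allele)
  cm <- collapse_map(out)
  expect_setequal(unlist(cm), ref$allele)   # expansion recovers all input names
  expect_equal(cm[["IGHV3-64*06"]], c("IGHV3-64*06", "IGHV3-64D*06"))
  nodup <- collapse_identical(germline_reference(
    c("A1*01", "A2*01"), c("AAAA", "CCCC")))
  expect_equal(unname(lengths(collapse_map(nodup))), c(1L, 1L))
})

test_that("trim then extend restores original full-length sequences", {
  base <- strrep("ACGT", 80)
  ref <- germline_reference(
    c("IGHV3-66*01", "IGHV3-66*04", "IGHV1-1*01"),
    c(base, paste0(substr(base, 1, 318), "AA"), strrep("GGCA", 80)),
    functionality = "functional")
  trimmed <- collapse_identical(trim_three_prime(ref, 318))
  expect_equal(nrow(trimmed), 2L)
  extended <- extend_to_full_length(trimmed, ref)
  # the collapsed 3'-divergent pair is exported twice under one shared name
  both <- extended[extended$ambiguous_three_prime, ]
  expect_equal(nrow(both), 2L)
  expect_true(all(grepl("^IGHV3-66\\*01_seq", both$allele)))
  expect_setequal(extended$gapped_sequence, ref$gapped_sequence)
  # round trip on a duplicate-free, trim-invariant reference is the identity
  flat <- germline_reference(c("IGHV1-1*01", "IGHV1-2*01"),
                             c(substr(base, 1, 318), strrep("T", 318)),
                             functionality = "functional")
  rt <- extend_to_full_length(collapse_identical(trim_three_prime(flat, 318)), flat)
  expect_equal(rt$sequence[order_naturally(rt$allele)],
               flat$sequence[order_naturally(flat$allele)])
})
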