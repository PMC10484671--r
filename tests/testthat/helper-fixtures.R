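# Fixture builders: everything is generated in code at test time.

write_fasta <- function(headers, seqs, path = tempfile(fileext = ".fasta")) {
  writeLines(paste0(">", headers, "\n", seqs), path)
  path
}

# minimal annotated rearrangement table
airr_fixture <- function(v_call,
                         j_call = rep("IGHJ6*02", length(v_call)),
                         clone_id = as.character(seq_along(v_call)),
                         v_mutation_count = rep(0L, length(v_call)),
                         v_coverage_start = rep(1L, length(v_call)),
                         v_alignment_length = rep(318L, length(v_call)),
                         subject_id = "subjA") {
  as_airr(tibble::tibble(
    sequence_id = sprintf("seq%03d", seq_along(v_call)),
    v_call = v_call, j_call = j_call, clone_id = clone_id,
    v_mutation_count = v_mutation_count,
    v_coverage_start = v_coverage_start,
    v_alignment_length = v_alignment_length
  ), subject_id = subject_id)
}

# two-gene toy reference whose key table merges a duplicated allele pair
toy_asc_setup <- function() {
  ref <- germline_reference(
    c("IGHV1-1*01", "IGHV1-1*02", "IGHV1-1D*01", "IGHV2-5*01"),
    c("ACGTACGTACGTACGTACGT",
      "ACGTACGTACGTACGTACGA",
      "ACGTACGTACGTACGTACGT",     # identical to IGHV1-1*01
      "TTTTGGGGCCCCAAAATTTT"),
    functionality = "functional",
    coordinates = "aligned_from_1")
  collapsed <- collapse_identical(ref)
  asc <- build_asc_reference(collapsed, amplicon = "S1")
  list(ref = ref, collapsed = collapsed, asc = asc,
       key = as_key_table(asc))
}

rbind_dummy <- function(ref) {
  # pairwise_distances needs >= 2 sequences; add a distant partner
  germline_reference(c(ref$allele, "IGHV7-7*01"),
                     c(ref$sequence, strrep("T", nchar(ref$sequence[1]))))
}

rebuild_collapsed <- function(df) {
  out <- germline_reference(df$allele, df$sequence,
                            functionality = df$functionality,
                            coordinates = "aligned_from_1")
  attr(out, "collapse_map") <- attr(df, "collapse_map")[df$allele]
  out
}

mutate_positions <- function(seq, positions) {
  chars <- strsplit(seq, NULL)[[1]]
  swap <- c(A = "C", C = "G", G = "T", T = "A")
  chars[positions] <- swap[chars[positions]]
  paste(chars, collapse = "")
}

usage_fixture <- function(alleles, freqs, total = 10000L, subject = "s1") {
  structure(tibble::tibble(allele = alleles,
                           fractional_count = freqs * total,
                           absolute_frequency = freqs),
            total_sequences = total, subject_id = subject,
            class = c("allele_usage", class(tibble::tibble())))
}
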