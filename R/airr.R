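# AIRR rearrangement tables: reading, clone representatives, and the
# pre-genotyping filters for naive full-length repertoires.

AIRR_REQUIRED <- c("sequence_id", "v_call")

#' Read an AIRR rearrangement table
#'
#' Reads a tab-separated rearrangement file following the AIRR Community
#' schema. `sequence_id` and `v_call` are required; `j_call`, `clone_id`
#' and the mutation/coverage columns used by the filters are optional and
#' validated where needed.
#'
#' @param path TSV path.
#' @param subject_id Optional subject label attached as an attribute.
#' @return A tibble of rearrangement records (class `airr_tbl`).
#' @export
read_airr <- function(path, subject_id = NULL) {
  if (!file.exists(path))
    abort_ascgeno(paste0("cannot read AIRR file: ", path), "ascgeno_io_error")
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(tbl) == 0L)
    abort_ascgeno(paste0("empty AIRR file: ", path), "ascgeno_empty_error")
  as_airr(tbl, subject_id = subject_id)
}

#' Validate a data frame as a rearrangement table
#'
#' @param tbl Data frame with AIRR-style columns.
#' @param subject_id Optional subject label.
#' @return The validated tibble with class `airr_tbl`.
#' @export
as_airr <- function(tbl, subject_id = NULL) {
  tbl <- tibble::as_tibble(tbl)
  missing_cols <- setdiff(AIRR_REQUIRED, names(tbl))
  if (length(missing_cols))
    abort_ascgeno(paste0("missing required AIRR column(s): ",
                         paste(missing_cols, collapse = ", ")),
                  "ascgeno_schema_error")
  if (anyDuplicated(tbl$sequence_id))
    abort_ascgeno("sequence_id values must be unique", "ascgeno_duplicate_error")
  structure(tbl,
            subject_id = subject_id %||% attr(tbl, "subject_id"),
            class = unique(c("airr_tbl", class(tbl))))
}

#' Write a rearrangement table as AIRR TSV
#' @param tbl An `airr_tbl`.
#' @param path Output path.
#' @export
write_airr <- function(tbl, path) {
  readr::write_tsv(tibble::as_tibble(tbl), path)
  invisible(path)
}

rebuild_airr <- function(tbl, template) {
  as_airr(tbl, subject_id = attr(template, "subject_id"))
}

require_columns <- function(tbl, cols, why) {
  missing_cols <- setdiff(cols, names(tbl))
  if (length(missing_cols))
    abort_ascgeno(paste0(why, " requires column(s): ",
                         paste(missing_cols, collapse = ", ")),
                  "ascgeno_schema_error")
  invisible(TRUE)
}

#' Parsed v_call names per record
#'
#' Splits comma-separated calls, trims whitespace and removes duplicate
#' names within a call.
#'
#' @param tbl An `airr_tbl`.
#' @param column Call column, default `"v_call"`.
#' @return List of character vectors, one per record.
#' @export
parse_calls <- function(tbl, column = "v_call") {
  require_columns(tbl, column, "call parsing")
  split_call(tbl[[column]])
}

#' Select one representative record per clone
#'
#' Keeps, for each clone, the record with the fewest V mutations (the
#' record closest to the naive ancestor); ties break to the
#' lexicographically smallest `sequence_id`. Records without a `clone_id`
#' are treated as singleton clones and kept.
#'
#' @param tbl An `airr_tbl` with `clone_id` and `v_mutation_count`.
#' @return Filtered `airr_tbl`, at most one record per clone, in
#'   `sequence_id` order.
#' @export
select_clone_representative <- function(tbl) {
  require_columns(tbl, "v_mutation_count", "clone representative selection")
  require_columns(tbl, "clone_id", "clone representative selection")
  if (anyNA(tbl$v_mutation_count))
    abort_ascgeno("v_mutation_count contains missing values",
                  "ascgeno_schema_error")
  has_clone <- !is.na(tbl$clone_id) & nzchar(as.character(tbl$clone_id))
  singletons <- tbl[!has_clone, , drop = FALSE]
  cloned <- tbl[has_clone, , drop = FALSE]
  if (nrow(cloned)) {
    picked <- unlist(lapply(split(seq_len(nrow(cloned)), cloned$clone_id),
                            function(idx) {
                              sub <- cloned[idx, ]
                              idx[order(sub$v_mutation_count, sub$sequence_id)][1L]
                            }))
    cloned <- cloned[picked, , drop = FALSE]
  }
  out <- dplyr::bind_rows(cloned, singletons)
  out <- out[order(out$sequence_id), , drop = FALSE]
  rebuild_airr(out, tbl)
}

#' Keep records with no V mutations up to a position
#'
#' For naive repertoires, records carrying any mutation within IMGT
#' positions 1..`max_pos` (default 316, leaving the last V codon free to
#' absorb sequencing errors) are removed. Mutations are counted either
#' from a precomputed `v_mutation_count` column (interpreted as the count
#' within the window) or, when `sequence_alignment` and
#' `germline_alignment` are both present, by comparing the two gapped
#' alignments position by position.
#'
#' @param tbl An `airr_tbl`.
#' @param max_pos Last position of the mutation-free window, default 316.
#' @return Filtered `airr_tbl`.
#' @export
filter_unmutated <- function(tbl, max_pos = 316L) {
  if (all(c("sequence_alignment", "germline_alignment") %in% names(tbl))) {
    muts <- count_alignment_mutations(tbl$sequence_alignment,
                                      tbl$germline_alignment, max_pos)
  } else {
    require_columns(tbl, "v_mutation_count", "mutation filtering")
    muts <- tbl$v_mutation_count
  }
  if (anyNA(muts))
    abort_ascgeno("mutation information missing for some records",
                  "ascgeno_schema_error")
  rebuild_airr(tbl[muts == 0L, , drop = FALSE], tbl)
}

count_alignment_mutations <- function(seq_aln, germ_aln, max_pos) {
  vapply(seq_along(seq_aln), function(i) {
    s <- strsplit(substr(seq_aln[[i]], 1L, max_pos), NULL)[[1L]]
    g <- strsplit(substr(germ_aln[[i]], 1L, max_pos), NULL)[[1L]]
    n <- min(length(s), length(g))
    s <- s[seq_len(n)]; g <- g[seq_len(n)]
    informative <- s %in% c("A", "C", "G", "T") & g %in% c("A", "C", "G", "T")
    sum(s[informative] != g[informative])
  }, integer(1))
}

#' Keep records whose V coverage starts at position 1
#'
#' Full V amplicons only: 5'-trimmed records are removed.
#' @param tbl An `airr_tbl` with `v_coverage_start` (or AIRR
#'   `v_germline_start`).
#' @return Filtered `airr_tbl`.
#' @export
filter_five_prime_complete <- function(tbl) {
  col <- intersect(c("v_coverage_start", "v_germline_start"), names(tbl))[1]
  if (is.na(col))
    abort_ascgeno("5' filtering requires v_coverage_start or v_germline_start",
                  "ascgeno_schema_error")
  rebuild_airr(tbl[!is.na(tbl[[col]]) & tbl[[col]] == 1L, , drop = FALSE], tbl)
}

#' Keep records with sufficient 3' V coverage
#'
#' @param tbl An `airr_tbl` with `v_alignment_length`.
#' @param min_len Minimum aligned V length in nucleotides, default 312
#'   (inclusive).
#' @return Filtered `airr_tbl`.
#' @export
filter_three_prime_coverage <- function(tbl, min_len = 312L) {
  require_columns(tbl, "v_alignment_length", "3' coverage filtering")
  keep <- !is.na(tbl$v_alignment_length) & tbl$v_alignment_length >= min_len
  rebuild_airr(tbl[keep, , drop = FALSE], tbl)
}
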