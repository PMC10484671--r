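# Germline reference sets: reading, filtering, trimming, collapsing.
#
# A germline reference is a tibble with one row per allele and columns
# allele, gapped_sequence, sequence, functionality, gene, subgroup, plus
# attributes describing the amplicon window and sequence coordinates.

#' Construct a germline reference
#'
#' Low-level constructor used by [read_germline_fasta()] and by the
#' simulator. Most users will read references from FASTA instead.
#'
#' @param alleles Character vector of IUIS-style allele names
#'   (e.g. `"IGHV3-64*02"`); must be unique.
#' @param sequences Character vector of nucleotide sequences. May contain
#'   IMGT gap characters (`.`), in which case sequences are interpreted in
#'   IMGT unique (gapped) numbering.
#' @param functionality Character vector, one of `"functional"`, `"ORF"`,
#'   `"pseudogene"`, `"unknown"`; recycled.
#' @param amplicon_class Amplicon label for the set (`"S1"`, `"S2"`,
#'   `"S3"` or `"custom"`).
#' @param coordinates Coordinate declaration: `"imgt_gapped"` when gapped
#'   sequences follow IMGT unique numbering, `"aligned_from_1"` when
#'   ungapped sequences are declared to start at position 1, otherwise
#'   `"unknown"`. Position-based operations refuse `"unknown"`.
#' @param provenance Free-text origin note.
#' @return A `germline_ref` tibble.
#' @export
germline_reference <- function(alleles, sequences,
                               functionality = "unknown",
                               amplicon_class = "custom",
                               coordinates = c("imgt_gapped", "aligned_from_1", "unknown"),
                               provenance = NULL) {
  coordinates <- match.arg(coordinates)
  alleles <- as.character(alleles)
  sequences <- toupper(as.character(sequences))
  if (anyDuplicated(alleles))
    abort_ascgeno(paste0("duplicate allele names: ",
                         paste(unique(alleles[duplicated(alleles)]), collapse = ", ")),
                  "ascgeno_duplicate_error")
  ungapped <- gsub(".", "", sequences, fixed = TRUE)
  if (any(!nzchar(ungapped)))
    abort_ascgeno("empty sequence after gap removal", "ascgeno_empty_error")
  functionality <- rep_len(functionality, length(alleles))
  df <- tibble::tibble(
    allele = alleles,
    gapped_sequence = sequences,
    sequence = ungapped,
    functionality = functionality,
    gene = iuis_gene(alleles),
    subgroup = iuis_subgroup(alleles)
  )
  new_germline_ref(df, amplicon_class = amplicon_class,
                   coordinates = coordinates, provenance = provenance)
}

new_germline_ref <- function(df, amplicon_class = "custom",
                             coordinates = "unknown",
                             trim_end = NULL, provenance = NULL,
                             collapse_map = NULL) {
  structure(tibble::as_tibble(df),
            amplicon_class = amplicon_class,
            coordinates = coordinates,
            trim_end = trim_end,
            provenance = provenance,
            collapse_map = collapse_map,
            class = c("germline_ref", class(tibble::tibble())))
}

# carry reference attributes through a row-subsetting transformation
rebuild_ref <- function(df, template, ...) {
  dots <- list(...)
  new_germline_ref(
    df,
    amplicon_class = dots$amplicon_class %||% attr(template, "amplicon_class"),
    coordinates = dots$coordinates %||% attr(template, "coordinates"),
    trim_end = if ("trim_end" %in% names(dots)) dots$trim_end else attr(template, "trim_end"),
    provenance = dots$provenance %||% attr(template, "provenance"),
    collapse_map = dots$collapse_map %||% attr(template, "collapse_map")
  )
}

#' Read a V-gene germline reference set from FASTA
#'
#' Accepts plain headers (name is the first whitespace-delimited token) and
#' IMGT-style pipe-delimited headers, from which the allele name and the
#' functionality field (`F`, `ORF`, `P`, possibly bracketed) are extracted.
#' Gapped versus ungapped input is auto-detected from the presence of IMGT
#' gap characters (`.`).
#'
#' @param path FASTA file.
#' @param functionality_table Optional TSV with columns `allele` and
#'   `functionality`, overriding header-derived annotations.
#' @param aligned_from_one Declare ungapped input as starting at V position
#'   1 so that position-based trimming is meaningful.
#' @return A `germline_ref` tibble.
#' @export
read_germline_fasta <- function(path, functionality_table = NULL,
                                aligned_from_one = FALSE) {
  if (!file.exists(path))
    abort_ascgeno(paste0("cannot read FASTA file: ", path), "ascgeno_io_error")
  seqs <- tryCatch(Biostrings::readBStringSet(path),
                   error = function(e)
                     abort_ascgeno(paste0("unreadable FASTA: ", conditionMessage(e)),
                                   "ascgeno_io_error"))
  if (length(seqs) == 0L)
    abort_ascgeno(paste0("empty FASTA file: ", path), "ascgeno_empty_error")
  headers <- names(seqs)
  parsed <- parse_fasta_headers(headers)
  sequences <- toupper(as.character(seqs))
  func <- parsed$functionality
  if (!is.null(functionality_table)) {
    ft <- readr::read_tsv(functionality_table, show_col_types = FALSE,
                          progress = FALSE)
    if (!all(c("allele", "functionality") %in% names(ft)))
      abort_ascgeno("functionality table needs columns allele, functionality",
                    "ascgeno_schema_error")
    idx <- match(parsed$allele, ft$allele)
    func <- ifelse(is.na(idx), func, normalize_functionality(ft$functionality[idx]))
  }
  gapped <- any(grepl(".", sequences, fixed = TRUE))
  coordinates <- if (gapped) "imgt_gapped" else if (aligned_from_one) "aligned_from_1" else "unknown"
  germline_reference(parsed$allele, sequences, functionality = func,
                     coordinates = coordinates,
                     provenance = paste0("read from ", path))
}

parse_fasta_headers <- function(headers) {
  allele_rx <- "^[A-Za-z][A-Za-z0-9./-]*\\*[0-9]+"
  allele <- character(length(headers))
  func <- rep("unknown", length(headers))
  for (i in seq_along(headers)) {
    h <- headers[[i]]
    if (grepl("|", h, fixed = TRUE)) {
      fields <- trimws(strsplit(h, "|", fixed = TRUE)[[1L]])
      hit <- grep(allele_rx, fields, value = TRUE)
      allele[i] <- if (length(hit)) hit[[1L]] else fields[[1L]]
      bare <- gsub("[][()]", "", fields)
      fhit <- bare[bare %in% c("F", "ORF", "P")]
      if (length(fhit)) func[i] <- normalize_functionality(fhit[[1L]])
    } else {
      allele[i] <- strsplit(trimws(h), "\\s+")[[1L]][[1L]]
    }
  }
  list(allele = allele, functionality = func)
}

normalize_functionality <- function(x) {
  x <- gsub("[][()]", "", trimws(as.character(x)))
  out <- rep("unknown", length(x))
  out[x %in% c("F", "functional", "Functional")] <- "functional"
  out[x %in% c("ORF", "orf")] <- "ORF"
  out[x %in% c("P", "pseudogene", "Pseudogene", "pseudo")] <- "pseudogene"
  out
}

#' Write a germline reference to FASTA
#'
#' @param ref A `germline_ref`.
#' @param path Output file.
#' @param gapped Write IMGT-gapped sequences (default) or ungapped.
#' @export
write_germline_fasta <- function(ref, path, gapped = TRUE) {
  seqs <- if (gapped) ref$gapped_sequence else ref$sequence
  x <- Biostrings::BStringSet(setNames(seqs, ref$allele))
  Biostrings::writeXStringSet(x, filepath = path, width = 80L)
  invisible(path)
}

#' Keep functional alleles
#'
#' Non-functional alleles (ORF and pseudogene) are removed before
#' clustering; in the human IGHV reference this removes entire subgroups
#' whose alleles are all non-functional. Removed names are recorded in the
#' `"removed"` attribute of the result.
#'
#' @param ref A `germline_ref`.
#' @param strict Treat `"unknown"` functionality as non-functional.
#' @return Filtered `germline_ref`.
#' @export
filter_functional <- function(ref, strict = FALSE) {
  keep_vals <- if (strict) "functional" else c("functional", "unknown")
  keep <- ref$functionality %in% keep_vals
  out <- rebuild_ref(ref[keep, , drop = FALSE], ref)
  attr(out, "removed") <- ref$allele[!keep]
  out
}

#' Keep alleles that cover the full comparison window
#'
#' Retains alleles whose sequence starts at V position 1 and extends
#' through at least position `end` (default 318) in the declared
#' coordinate system.
#'
#' @param ref A `germline_ref` with IMGT-gapped sequences or an explicit
#'   aligned-from-position-1 declaration.
#' @param end Last required position (IMGT unique numbering), default 318.
#' @return Filtered `germline_ref`.
#' @export
filter_complete_v <- function(ref, end = 318L) {
  require_coordinates(ref)
  g <- ref$gapped_sequence
  first_non_gap <- regexpr("[^.]", g)
  last_non_gap <- nchar(g) - regexpr("[^.]", vapply(g, rev_string, "")) + 1L
  keep <- first_non_gap == 1L & last_non_gap >= end
  rebuild_ref(ref[keep, , drop = FALSE], ref)
}

rev_string <- function(s) paste(rev(strsplit(s, NULL)[[1L]]), collapse = "")

require_coordinates <- function(ref) {
  if (!attr(ref, "coordinates") %in% c("imgt_gapped", "aligned_from_1"))
    abort_ascgeno(paste0(
      "sequence positions are undefined: provide IMGT-gapped sequences or ",
      "declare ungapped input as aligned from position 1 ",
      "(read_germline_fasta(aligned_from_one = TRUE))"),
      "ascgeno_coordinates_error")
  invisible(TRUE)
}

#' Trim 3' ends at a fixed position
#'
#' Truncates every allele at IMGT position `end` (default 318), the last
#' position at which AIRR-seq reads can reliably resolve germline variation;
#' alleles differing only beyond this point become identical and are merged
#' by [collapse_identical()].
#'
#' @inheritParams filter_complete_v
#' @return Trimmed `germline_ref` with `trim_end` recorded.
#' @export
trim_three_prime <- function(ref, end = 318L) {
  require_coordinates(ref)
  short <- nchar(ref$gapped_sequence) < end
  if (any(short))
    abort_ascgeno(paste0("alleles not covered through position ", end, ": ",
                         paste(head(ref$allele[short], 5L), collapse = ", ")),
                  "ascgeno_coverage_error")
  df <- ref
  df$gapped_sequence <- substr(ref$gapped_sequence, 1L, end)
  df$sequence <- gsub(".", "", df$gapped_sequence, fixed = TRUE)
  rebuild_ref(df, ref, trim_end = as.integer(end))
}

#' Amplicon window specification
#'
#' Describes the stretch of the V region covered by a sequencing protocol,
#' in IMGT unique numbering: `S1` covers the full V (positions 1-318);
#' shorter amplicons (BIOMED-2-style `S2`, ImmunoSeq-style `S3`) start
#' further 3'. Start positions for partial protocols are configurable
#' because primer placement varies by assay.
#'
#' @param name Amplicon label.
#' @param five_prime_start First included IMGT position.
#' @param three_prime_end Last included IMGT position, default 318.
#' @return An `amplicon_spec` list.
#' @export
amplicon_spec <- function(name, five_prime_start = 1L, three_prime_end = 318L) {
  five_prime_start <- as.integer(five_prime_start)
  three_prime_end <- as.integer(three_prime_end)
  if (!(five_prime_start >= 1L && five_prime_start < three_prime_end))
    abort_ascgeno("amplicon window must satisfy 1 <= start < end",
                  "ascgeno_spec_error")
  structure(list(name = name, five_prime_start = five_prime_start,
                 three_prime_end = three_prime_end),
            class = "amplicon_spec")
}

#' Restrict a reference to an amplicon window
#'
#' Truncates every allele to the positions covered by `spec`, emulating a
#' partial-coverage sequencing protocol. Windows that remove 5' sequence
#' collapse alleles that differ only upstream, so the number of unique
#' sequences can only decrease.
#'
#' @param ref A `germline_ref` covering the window.
#' @param spec An [amplicon_spec()].
#' @return A `germline_ref` labeled with `spec$name`.
#' @export
make_amplicon_variant <- function(ref, spec) {
  stopifnot(inherits(spec, "amplicon_spec"))
  require_coordinates(ref)
  short <- nchar(ref$gapped_sequence) < spec$three_prime_end
  if (any(short))
    abort_ascgeno(paste0("amplicon window extends past coverage for: ",
                         paste(head(ref$allele[short], 5L), collapse = ", ")),
                  "ascgeno_coverage_error")
  df <- ref
  df$gapped_sequence <- substr(ref$gapped_sequence,
                               spec$five_prime_start, spec$three_prime_end)
  df$sequence <- gsub(".", "", df$gapped_sequence, fixed = TRUE)
  if (any(!nzchar(df$sequence)))
    abort_ascgeno("amplicon window contains no sequence for some alleles",
                  "ascgeno_coverage_error")
  rebuild_ref(df, ref, amplicon_class = spec$name,
              trim_end = spec$three_prime_end)
}

#' Collapse identical sequences into single allele records
#'
#' Alleles with identical (ungapped) sequences -- duplicated genes, or
#' alleles made indistinguishable by trimming -- are merged into one record.
#' The representative is the natural-sort-smallest IUIS name; the full
#' mapping from representative to merged names is retained and available
#' via [collapse_map()].
#'
#' @param ref A `germline_ref`.
#' @return A `germline_ref` with one row per unique sequence.
#' @export
collapse_identical <- function(ref) {
  groups <- split(seq_len(nrow(ref)), ref$sequence)
  reps <- vapply(groups, function(idx) natural_min(ref$allele[idx]), "")
  ord <- natural_order(reps)
  groups <- groups[ord]
  reps <- reps[ord]
  rows <- vapply(seq_along(groups),
                 function(k) groups[[k]][ref$allele[groups[[k]]] == reps[[k]]][1L],
                 integer(1))
  df <- ref[rows, , drop = FALSE]
  reps <- unname(reps)
  df$allele <- reps
  df$gene <- iuis_gene(reps)
  df$subgroup <- iuis_subgroup(reps)
  cmap <- lapply(groups, function(idx) natural_sort(ref$allele[idx]))
  names(cmap) <- reps
  rebuild_ref(df, ref, collapse_map = cmap)
}

#' Collapse mapping of a reference
#'
#' @param ref A `germline_ref` produced by [collapse_identical()].
#' @return Named list: representative name -> merged IUIS names.
#' @export
collapse_map <- function(ref) {
  cm <- attr(ref, "collapse_map")
  if (is.null(cm)) cm <- setNames(as.list(ref$allele), ref$allele)
  cm
}

#' Write the collapse mapping as TSV
#'
#' Columns: `asc_representative`, `merged_iuis_names` (semicolon-joined),
#' `sequence`.
#' @param ref A collapsed `germline_ref`.
#' @param path Output TSV.
#' @export
write_collapse_map <- function(ref, path) {
  cm <- collapse_map(ref)
  df <- tibble::tibble(
    asc_representative = names(cm),
    merged_iuis_names = vapply(cm, paste, "", collapse = ";"),
    sequence = ref$sequence[match(names(cm), ref$allele)]
  )
  readr::write_tsv(df, path)
  invisible(path)
}

#' Restore full-length sequences for an aligner reference
#'
#' Sequences trimmed for clustering are re-extended to their original 3'
#' length so that the exported reference does not bias alignment. When a
#' collapsed group contains originals that differ beyond the trim point
#' (e.g. allele pairs distinguished only at position 319), every distinct
#' full-length sequence is emitted under the shared representative name
#' with a disambiguating `_seqN` suffix and flagged in the
#' `ambiguous_three_prime` column.
#'
#' @param trimmed A trimmed, collapsed `germline_ref` (collapse map
#'   attached).
#' @param original The pre-trim `germline_ref` the set was derived from.
#' @return A `germline_ref` with an `ambiguous_three_prime` column.
#' @export
extend_to_full_length <- function(trimmed, original) {
  cm <- collapse_map(trimmed)
  rows <- list()
  for (rep_name in names(cm)) {
    members <- cm[[rep_name]]
    idx <- match(members, original$allele)
    if (anyNA(idx))
      abort_ascgeno(paste0("cannot trace back to original alleles: ",
                           paste(members[is.na(idx)], collapse = ", ")),
                    "ascgeno_trace_error")
    full <- original$gapped_sequence[idx]
    uniq <- !duplicated(gsub(".", "", full, fixed = TRUE))
    sub <- original[idx[uniq], , drop = FALSE]
    ambiguous <- sum(uniq) > 1L
    sub$allele <- if (ambiguous)
      paste0(rep_name, "_seq", seq_len(nrow(sub))) else rep_name
    sub$gene <- iuis_gene(rep_name)
    sub$subgroup <- iuis_subgroup(rep_name)
    sub$ambiguous_three_prime <- ambiguous
    rows[[rep_name]] <- sub
  }
  df <- dplyr::bind_rows(rows)
  rebuild_ref(df, original, trim_end = NULL,
              collapse_map = attr(trimmed, "collapse_map"))
}
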