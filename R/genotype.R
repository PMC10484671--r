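# Absolute allele usage, allele-specific thresholds, genotype inference,
# the gene-based baseline and ambiguity/usage reporting.

#' Absolute allele usage with fractional multi-assignment counting
#'
#' Each record contributes total weight 1; a record whose call lists `k`
#' distinct ASC alleles (after translation through the key table and
#' deduplication) contributes `1/k` to each. Absolute frequencies are the
#' fractional counts divided by the total number of records in the
#' repertoire -- not by a per-gene total, which is what distinguishes this
#' method from relative-frequency genotyping.
#'
#' @param tbl An `airr_tbl` (already filtered; frequencies are computed on
#'   the filtered total).
#' @param key_table Optional key table used to translate IUIS calls to ASC
#'   alleles; calls already in ASC naming may pass `NULL`.
#' @param strict Raise on calls that cannot be translated.
#' @return An `allele_usage` tibble with columns `allele`,
#'   `fractional_count`, `absolute_frequency`; attributes `total_sequences`
#'   and `subject_id`.
#' @export
compute_allele_usage <- function(tbl, key_table = NULL, strict = FALSE) {
  if (nrow(tbl) == 0L)
    abort_ascgeno("empty rearrangement table", "ascgeno_empty_error")
  calls <- tbl$v_call
  if (!is.null(key_table))
    calls <- translate_call(calls, key_table, "iuis_to_asc", strict = strict)
  names_per_record <- split_call(calls)
  k <- lengths(names_per_record)
  w <- rep(1 / k, k)
  counts <- tapply(w, unlist(names_per_record), sum)
  total <- nrow(tbl)
  out <- tibble::tibble(allele = names(counts),
                        fractional_count = as.numeric(counts),
                        absolute_frequency = as.numeric(counts) / total)
  out <- out[natural_order(out$allele), , drop = FALSE]
  structure(out, total_sequences = total,
            subject_id = attr(tbl, "subject_id"),
            class = c("allele_usage", class(tibble::tibble())))
}

#' Allele-specific threshold table
#'
#' @param allele Character vector of allele names (may be empty).
#' @param threshold Numeric thresholds in `(0, 1]`.
#' @param default_threshold Threshold applied to alleles absent from the
#'   table; `1e-4` reflects typical AIRR-seq depths of 10-20k sequences,
#'   at which it admits alleles seen once or twice.
#' @return A `threshold_table` tibble with attribute `default_threshold`.
#' @export
threshold_table <- function(allele = character(0), threshold = numeric(0),
                            default_threshold = 1e-4) {
  threshold <- as.numeric(threshold)
  if (any(threshold <= 0 | threshold > 1) ||
      default_threshold <= 0 || default_threshold > 1)
    abort_ascgeno("thresholds must lie in (0, 1]", "ascgeno_threshold_error")
  if (anyDuplicated(allele))
    abort_ascgeno("duplicate alleles in threshold table", "ascgeno_duplicate_error")
  structure(tibble::tibble(allele = as.character(allele), threshold = threshold),
            default_threshold = default_threshold,
            class = c("threshold_table", class(tibble::tibble())))
}

#' Read / write an allele threshold table (TSV with columns `allele`,
#' `threshold`)
#' @param path TSV path.
#' @param default_threshold Default for alleles not listed.
#' @rdname threshold_io
#' @export
read_threshold_table <- function(path, default_threshold = 1e-4) {
  if (!file.exists(path))
    abort_ascgeno(paste0("cannot read threshold table: ", path), "ascgeno_io_error")
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("allele", "threshold") %in% names(df)))
    abort_ascgeno("threshold table needs columns allele, threshold",
                  "ascgeno_schema_error")
  threshold_table(df$allele, df$threshold, default_threshold)
}

#' @param thresholds A `threshold_table`.
#' @rdname threshold_io
#' @export
write_threshold_table <- function(thresholds, path) {
  readr::write_tsv(tibble::as_tibble(thresholds), path)
  invisible(path)
}

#' Audit a threshold table against its default
#'
#' @param thresholds A `threshold_table`.
#' @return List with `n_alleles`, `n_adjusted` (thresholds differing from
#'   the default) and the `default_threshold`.
#' @export
audit_thresholds <- function(thresholds) {
  d <- attr(thresholds, "default_threshold")
  list(n_alleles = nrow(thresholds),
       n_adjusted = sum(thresholds$threshold != d),
       default_threshold = d)
}

lookup_threshold <- function(alleles, thresholds) {
  idx <- match(alleles, thresholds$allele)
  out <- thresholds$threshold[idx]
  out[is.na(out)] <- attr(thresholds, "default_threshold")
  out
}

#' Infer a genotype from absolute allele usage
#'
#' An allele enters the genotype exactly when its absolute usage frequency
#' is at least its allele-specific threshold (the comparison is inclusive;
#' alleles landing exactly on the threshold are kept). The full audit
#' trail -- counts, frequencies, thresholds and pass flags for every
#' observed allele -- is returned.
#'
#' @param usage An `allele_usage` from [compute_allele_usage()].
#' @param thresholds A `threshold_table`; alleles absent from it receive
#'   the default threshold.
#' @return A `genotype` tibble with columns `allele`, `fractional_count`,
#'   `absolute_frequency`, `threshold`, `in_genotype`.
#' @export
infer_genotype_asc <- function(usage, thresholds = threshold_table()) {
  out <- tibble::as_tibble(usage)
  out$threshold <- lookup_threshold(out$allele, thresholds)
  out$in_genotype <- out$absolute_frequency >= out$threshold
  structure(out,
            subject_id = attr(usage, "subject_id"),
            total_sequences = attr(usage, "total_sequences"),
            class = c("genotype", class(tibble::tibble())))
}

#' Alleles present in a genotype
#' @param genotype A `genotype` tibble.
#' @return Character vector of alleles with `in_genotype = TRUE`.
#' @export
genotype_alleles <- function(genotype) genotype$allele[genotype$in_genotype]

#' Gene-based relative-frequency genotype baseline
#'
#' The conventional approach used for comparison: an allele enters the
#' genotype when its fractional count is at least `fraction` of the total
#' count of its IUIS gene. This is a simplification of fraction-based
#' genotyping tools, retained here only as a comparison baseline; it
#' inherits their blind spot for alleles expressed far below their
#' gene-mates.
#'
#' @param tbl An `airr_tbl` carrying IUIS calls.
#' @param fraction Within-gene relative-frequency cutoff, conventionally
#'   0.125 or 0.05.
#' @return A `genotype` tibble with columns `allele`, `gene`,
#'   `fractional_count`, `gene_total`, `relative_frequency`, `in_genotype`.
#' @export
infer_genotype_gene_based <- function(tbl, fraction = 0.125) {
  if (fraction <= 0 || fraction >= 1)
    abort_ascgeno("fraction must lie in (0, 1)", "ascgeno_threshold_error")
  if (nrow(tbl) == 0L)
    abort_ascgeno("empty rearrangement table", "ascgeno_empty_error")
  names_per_record <- split_call(tbl$v_call)
  k <- lengths(names_per_record)
  w <- rep(1 / k, k)
  alleles <- unlist(names_per_record)
  counts <- tapply(w, alleles, sum)
  out <- tibble::tibble(allele = names(counts),
                        gene = iuis_gene(names(counts)),
                        fractional_count = as.numeric(counts))
  gene_tot <- tapply(out$fractional_count, out$gene, sum)
  out$gene_total <- as.numeric(gene_tot[out$gene])
  out$relative_frequency <- out$fractional_count / out$gene_total
  out$in_genotype <- out$relative_frequency >= fraction
  out <- out[natural_order(out$allele), , drop = FALSE]
  structure(out,
            subject_id = attr(tbl, "subject_id"),
            class = c("genotype", class(tibble::tibble())))
}

#' Threshold for an undocumented allele
#'
#' An allele absent from the threshold table inherits the threshold of the
#' reference allele nearest to it by normalized Levenshtein distance.
#' When several reference alleles are equidistant, the smallest threshold
#' among them is returned (the conservative, inclusion-favouring choice)
#' and the tie is flagged.
#'
#' @param novel_sequence Ungapped nucleotide sequence of the novel allele.
#' @param thresholds A `threshold_table`.
#' @param asc_ref An `asc_reference` (or any tibble with `asc_allele`/
#'   `allele` and `sequence` columns) providing reference sequences.
#' @return Numeric threshold with attributes `nearest` (allele name(s) at
#'   minimum distance) and `tie` (logical).
#' @export
novel_allele_threshold <- function(novel_sequence, thresholds, asc_ref) {
  name_col <- intersect(c("asc_allele", "allele"), names(asc_ref))[1]
  if (is.na(name_col) || !"sequence" %in% names(asc_ref))
    abort_ascgeno("reference needs allele-name and sequence columns",
                  "ascgeno_schema_error")
  if (nrow(asc_ref) == 0L)
    abort_ascgeno("empty reference", "ascgeno_empty_error")
  d <- normalized_levenshtein(rep(novel_sequence, nrow(asc_ref)),
                              asc_ref$sequence)
  nearest <- asc_ref[[name_col]][d == min(d)]
  th <- lookup_threshold(nearest, thresholds)
  tie <- length(nearest) > 1L
  if (tie)
    message("novel allele equidistant from: ", paste(nearest, collapse = ", "),
            "; using the smallest threshold")
  structure(min(th), nearest = nearest, tie = tie)
}

#' Fraction of records with multiple assignments
#'
#' The fraction of records whose call maps to more than one distinct name
#' at the chosen level. At the ASC level, calls listing several IUIS
#' alleles that share one sequence translate to a single ASC name and are
#' therefore not ambiguous -- the mechanism by which the ASC reference
#' reduces multiple assignments.
#'
#' @param tbl An `airr_tbl`.
#' @param key_table Key table for ASC translation (required for
#'   `level = "asc"` when calls are IUIS-named).
#' @param level `"gene"` (IUIS gene names) or `"asc"`.
#' @return Fraction in `[0, 1]`.
#' @export
multiple_assignment_fraction <- function(tbl, key_table = NULL,
                                         level = c("asc", "gene")) {
  level <- match.arg(level)
  if (nrow(tbl) == 0L)
    abort_ascgeno("empty rearrangement table", "ascgeno_empty_error")
  calls <- tbl$v_call
  if (level == "asc") {
    if (!is.null(key_table))
      calls <- translate_call(calls, key_table, "iuis_to_asc")
    per <- split_call(calls)
    n_distinct <- lengths(lapply(per, function(v) unique(iuis_gene(v))))
  } else {
    per <- split_call(calls)
    n_distinct <- lengths(lapply(per, function(v) unique(iuis_gene(v))))
  }
  mean(n_distinct > 1L)
}

#' Summed cluster usage by genotype allele combination
#'
#' Groups subjects by the combination of a cluster's alleles present in
#' their genotype (e.g. `"04_05"`) and reports each subject's summed
#' absolute usage over the cluster's alleles, normalized by the whole
#' repertoire. Combinations are ordered by the number of carriers. This
#' exposes expression differences between genotype combinations that
#' aggregated per-cluster usage would mask.
#'
#' @param usages List of `allele_usage` objects (one per subject) or a
#'   tibble with a `subject_id` column.
#' @param genotypes List of `genotype` objects aligned with `usages`.
#' @param asc_ref An `asc_reference`.
#' @param cluster Cluster index (integer) or cluster label such as `"G5"`.
#' @return Tibble with columns `subject_id`, `combination`,
#'   `summed_frequency`, `n_carriers`.
#' @export
usage_by_genotype_combination <- function(usages, genotypes, asc_ref, cluster) {
  if (is.character(cluster)) cluster <- as.integer(sub("^G", "", cluster))
  members <- asc_ref$asc_allele[asc_ref$cluster == cluster]
  if (length(members) == 0L)
    abort_ascgeno(paste0("cluster ", cluster, " not present in reference"),
                  "ascgeno_unknown_cluster_error")
  if (!is.list(usages) || tibble::is_tibble(usages)) usages <- list(usages)
  if (!is.list(genotypes) || tibble::is_tibble(genotypes)) genotypes <- list(genotypes)
  stopifnot(length(usages) == length(genotypes))
  rows <- lapply(seq_along(usages), function(i) {
    u <- usages[[i]]; g <- genotypes[[i]]
    subj <- attr(u, "subject_id") %||% as.character(i)
    carried <- intersect(genotype_alleles(g), members)
    num <- sub("^.*\\*", "", carried)
    combo <- if (length(carried)) paste(sort(num), collapse = "_") else "none"
    freq <- sum(u$absolute_frequency[u$allele %in% members])
    tibble::tibble(subject_id = subj, combination = combo,
                   summed_frequency = freq)
  })
  out <- dplyr::bind_rows(rows)
  carriers <- table(out$combination)
  out$n_carriers <- as.integer(carriers[out$combination])
  out[order(-out$n_carriers, out$combination, out$subject_id), , drop = FALSE]
}

#' Cross-tabulate ASC-based and gene-based genotypes
#'
#' Produces the allele-by-subject concordance matrix between the two
#' genotyping routes: `"both"`, `"asc_only"`, `"gene_only"` or
#' `"neither"` per allele and subject. Gene-based calls are translated to
#' ASC names through the key table before comparison.
#'
#' @param asc_genotypes,gene_genotypes Lists of `genotype` objects aligned
#'   by subject.
#' @param key_table Key table for translating IUIS calls to ASC naming.
#' @return Tibble with columns `subject_id`, `allele`, `status`.
#' @export
compare_genotypes <- function(asc_genotypes, gene_genotypes, key_table) {
  stopifnot(length(asc_genotypes) == length(gene_genotypes))
  rows <- lapply(seq_along(asc_genotypes), function(i) {
    subj <- attr(asc_genotypes[[i]], "subject_id") %||% as.character(i)
    asc_set <- genotype_alleles(asc_genotypes[[i]])
    gene_set <- unique(unlist(split_call(
      translate_call(genotype_alleles(gene_genotypes[[i]]), key_table,
                     "iuis_to_asc"))))
    all_alleles <- union(asc_set, gene_set)
    status <- ifelse(all_alleles %in% asc_set & all_alleles %in% gene_set, "both",
              ifelse(all_alleles %in% asc_set, "asc_only", "gene_only"))
    tibble::tibble(subject_id = subj, allele = all_alleles, status = status)
  })
  dplyr::bind_rows(rows)
}
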