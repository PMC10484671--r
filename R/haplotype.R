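# Anchor-gene haplotype partitioning, the binomial dominance test, and
# threshold adjustment suggestions (the three curation cases).

#' Partition V-allele usage by a heterozygous anchor gene
#'
#' For a subject heterozygous at an anchor gene (typically IGHJ6), each
#' record with an unambiguous anchor call is attributed to the chromosome
#' carrying that anchor allele. V-allele fractional counts split by anchor
#' allele then reveal which chromosome a V allele resides on.
#'
#' @param tbl An `airr_tbl` with `j_call` (or the anchor locus call
#'   column).
#' @param key_table Optional key table used to translate V calls to ASC
#'   names.
#' @param anchor_gene Anchor gene name, default `"IGHJ6"`.
#' @param anchor_column Column holding anchor calls, default `"j_call"`.
#' @return A `haplotype_counts` object: list with `subject_id`,
#'   `anchor_gene`, `anchor_alleles` (length 2), `matrix` (V allele x
#'   anchor allele fractional counts) and `n_ambiguous_anchor` (records
#'   excluded for ambiguous or foreign anchor calls).
#' @export
partition_by_anchor <- function(tbl, key_table = NULL,
                                anchor_gene = "IGHJ6",
                                anchor_column = "j_call") {
  require_columns(tbl, anchor_column, "haplotype partitioning")
  anchors <- split_call(tbl[[anchor_column]])
  anchors <- lapply(anchors, function(v) v[iuis_gene(v) == anchor_gene])
  usable <- lengths(anchors) == 1L
  anchor_allele <- rep(NA_character_, nrow(tbl))
  anchor_allele[usable] <- unlist(anchors[usable])
  seen <- sort(unique(anchor_allele[usable]))
  if (length(seen) != 2L)
    abort_ascgeno(paste0("subject is not haplotypable at ", anchor_gene,
                         ": found ", length(seen),
                         " anchor allele(s) [", paste(seen, collapse = ", "),
                         "], need exactly 2"),
                  "ascgeno_haplotype_error")
  calls <- tbl$v_call[usable]
  if (!is.null(key_table))
    calls <- translate_call(calls, key_table, "iuis_to_asc")
  per <- split_call(calls)
  k <- lengths(per)
  v_allele <- unlist(per)
  w <- rep(1 / k, k)
  chrom <- rep(anchor_allele[usable], k)
  v_levels <- natural_sort(unique(v_allele))
  mat <- matrix(0, nrow = length(v_levels), ncol = 2L,
                dimnames = list(v_levels, seen))
  for (cc in seen) {
    sums <- tapply(w[chrom == cc], v_allele[chrom == cc], sum)
    mat[names(sums), cc] <- as.numeric(sums)
  }
  structure(list(subject_id = attr(tbl, "subject_id"),
                 anchor_gene = anchor_gene,
                 anchor_alleles = seen,
                 matrix = mat,
                 n_ambiguous_anchor = sum(!usable)),
            class = "haplotype_counts")
}

#' Write a haplotype count matrix as TSV
#' @param hap A `haplotype_counts` object.
#' @param path Output TSV.
#' @export
write_haplotype_counts <- function(hap, path) {
  df <- tibble::as_tibble(hap$matrix, rownames = "allele")
  readr::write_tsv(df, path)
  invisible(path)
}

#' Binomial dominance test for an unlikely allele ratio
#'
#' Tests whether observing `count_minor` sequences of a normally dominant
#' allele against `count_major` of a normally minor one is plausible given
#' the population usage ratio between them. Under the null, each of the
#' `n = count_minor + count_major` sequences is the minor allele with
#' probability `1/(1 + usage_ratio)`; the upper-tail probability
#' `P(X >= count_minor)` is computed by exact summation of binomial
#' probabilities.
#'
#' @param count_minor Observed count of the allele that is minor in the
#'   population.
#' @param count_major Observed count of the dominant allele.
#' @param usage_ratio Population usage ratio major/minor (e.g. 33 when the
#'   dominant allele is used 33 times more).
#' @param parameterization `"one_over_one_plus_ratio"` (default; success
#'   probability `1/(1+r)`) or `"one_over_ratio"` (`1/r`).
#' @return Upper-tail p-value.
#' @export
binomial_dominance_test <- function(count_minor, count_major, usage_ratio,
                                    parameterization = c("one_over_one_plus_ratio",
                                                         "one_over_ratio")) {
  parameterization <- match.arg(parameterization)
  if (usage_ratio <= 0)
    abort_ascgeno("usage_ratio must be positive", "ascgeno_threshold_error")
  if (count_minor < 0 || count_major < 0 || (count_minor + count_major) == 0)
    abort_ascgeno("counts must be non-negative and not both zero",
                  "ascgeno_count_error")
  p <- if (parameterization == "one_over_one_plus_ratio")
    1 / (1 + usage_ratio) else 1 / usage_ratio
  n <- count_minor + count_major
  if (count_minor == 0) return(1)
  sum(dbinom(seq(count_minor, n), n, p))
}

#' Suggest allele-specific threshold adjustments
#'
#' Implements the curation procedure for tailoring allele thresholds to a
#' study population, grouping observations by allele and applying three
#' cases:
#'
#' * **Case 1** -- every carrier expresses the allele far above its
#'   threshold (minimum carrier frequency exceeding `case1_ratio` times
#'   the threshold): suggest raising the threshold to just below the
#'   lowest carrier frequency (`raise_factor` times it).
#' * **Case 2** -- subjects express the allele below its threshold but
#'   haplotype evidence places it cleanly on a chromosome: suggest
#'   lowering the threshold to the smallest supported frequency, so those
#'   subjects are included. If two alleles of the same IUIS gene co-occur
#'   on one anchor chromosome, the evidence is contradictory and the
#'   threshold is left unchanged with a contradiction flag.
#' * **Case 3** -- an undocumented allele (absent from the threshold
#'   table) is first seeded with its nearest reference allele's threshold
#'   via [novel_allele_threshold()], then re-evaluated under cases 1-2.
#'
#' Suggestions are advisory; they are never applied automatically.
#'
#' @param usages List of `allele_usage` objects, one per subject.
#' @param thresholds A `threshold_table`.
#' @param haplotypes Optional list of `haplotype_counts` aligned with
#'   `usages` (`NULL` entries allowed).
#' @param key_table Optional key table used to recover IUIS gene identities
#'   for the contradiction check.
#' @param asc_ref Optional reference with sequences, needed to seed
#'   undocumented alleles whose sequences appear in `novel_sequences`.
#' @param novel_sequences Named character vector: undocumented allele name
#'   -> ungapped sequence.
#' @param case1_ratio Multiple of the threshold every carrier must exceed
#'   to trigger Case 1 (default 10).
#' @param raise_factor Fraction of the minimum carrier frequency used as
#'   the raised threshold (default 0.9).
#' @param hap_min_count Minimum per-chromosome fractional count regarded
#'   as haplotype support (default 1).
#' @return Tibble of suggestions: `allele`, `case`, `current_threshold`,
#'   `suggested_threshold`, `evidence`, `contradiction`.
#' @export
suggest_threshold_adjustments <- function(usages, thresholds,
                                          haplotypes = NULL,
                                          key_table = NULL,
                                          asc_ref = NULL,
                                          novel_sequences = NULL,
                                          case1_ratio = 10,
                                          raise_factor = 0.9,
                                          hap_min_count = 1) {
  if (length(usages) == 0L)
    abort_ascgeno("no usage data supplied", "ascgeno_empty_error")
  if (tibble::is_tibble(usages)) usages <- list(usages)
  freqs <- dplyr::bind_rows(lapply(seq_along(usages), function(i) {
    u <- usages[[i]]
    tibble::tibble(subject = attr(u, "subject_id") %||% as.character(i),
                   allele = u$allele,
                   frequency = u$absolute_frequency)
  }))
  freqs <- freqs[freqs$frequency > 0, , drop = FALSE]
  suggestions <- list()
  for (al in natural_sort(unique(freqs$allele))) {
    obs <- freqs[freqs$allele == al, , drop = FALSE]
    documented <- al %in% thresholds$allele
    cur <- lookup_threshold(al, thresholds)
    case3 <- FALSE
    if (!documented && !is.null(novel_sequences) && al %in% names(novel_sequences) &&
        !is.null(asc_ref)) {
      cur <- as.numeric(novel_allele_threshold(novel_sequences[[al]],
                                               thresholds, asc_ref))
      case3 <- TRUE
    }
    below <- obs[obs$frequency < cur, , drop = FALSE]
    carriers <- obs[obs$frequency >= cur, , drop = FALSE]

    # Case 2: sub-threshold subjects with clean haplotype support
    if (nrow(below) > 0L && !is.null(haplotypes)) {
      support <- vapply(seq_len(nrow(below)), function(r) {
        subj_idx <- match(below$subject[[r]], vapply(seq_along(usages), function(i)
          attr(usages[[i]], "subject_id") %||% as.character(i), ""))
        if (is.na(subj_idx) || subj_idx > length(haplotypes)) return(NA)
        hap <- haplotypes[[subj_idx]]
        if (is.null(hap)) return(NA)
        haplotype_support(hap, al, key_table, hap_min_count)
      }, logical(1))
      if (any(!is.na(support) & !support)) {
        suggestions[[al]] <- tibble::tibble(
          allele = al, case = if (case3) 3L else 2L,
          current_threshold = cur, suggested_threshold = cur,
          evidence = "same-gene alleles share an anchor chromosome",
          contradiction = TRUE)
        next
      }
      if (any(support %in% TRUE)) {
        new_thr <- min(below$frequency[support %in% TRUE])
        suggestions[[al]] <- tibble::tibble(
          allele = al, case = if (case3) 3L else 2L,
          current_threshold = cur, suggested_threshold = new_thr,
          evidence = sprintf("haplotype support in %d subject(s) below threshold",
                             sum(support %in% TRUE)),
          contradiction = FALSE)
        next
      }
    }

    # Case 1: every carrier far above the threshold
    if (nrow(carriers) > 0L && nrow(below) == 0L &&
        min(carriers$frequency) > case1_ratio * cur) {
      new_thr <- min(carriers$frequency) * raise_factor
      suggestions[[al]] <- tibble::tibble(
        allele = al, case = if (case3) 3L else 1L,
        current_threshold = cur, suggested_threshold = new_thr,
        evidence = sprintf("minimum carrier frequency %.3g exceeds %gx threshold",
                           min(carriers$frequency), case1_ratio),
        contradiction = FALSE)
      next
    }

    if (case3) {
      suggestions[[al]] <- tibble::tibble(
        allele = al, case = 3L, current_threshold = cur,
        suggested_threshold = cur,
        evidence = "undocumented allele seeded from nearest reference allele",
        contradiction = FALSE)
    }
  }
  if (length(suggestions) == 0L)
    return(tibble::tibble(allele = character(0), case = integer(0),
                          current_threshold = numeric(0),
                          suggested_threshold = numeric(0),
                          evidence = character(0), contradiction = logical(0)))
  dplyr::bind_rows(suggestions)
}

# TRUE: allele sits on >=1 chromosome without a same-gene conflict
# FALSE: a same-gene allele shares its chromosome (contradiction)
# NA: no haplotype signal for this allele
haplotype_support <- function(hap, allele, key_table, hap_min_count) {
  mat <- hap$matrix
  if (!allele %in% rownames(mat)) return(NA)
  on_chrom <- mat[allele, ] >= hap_min_count
  if (!any(on_chrom)) return(NA)
  genes_of <- function(a) {
    if (!is.null(key_table)) {
      kt <- tibble::as_tibble(key_table)
      row <- match(a, kt$asc_allele)
      if (!is.na(row))
        return(unique(iuis_gene(strsplit(kt$iuis_names[row], ";")[[1L]])))
    }
    iuis_gene(a)
  }
  my_genes <- genes_of(allele)
  others <- setdiff(rownames(mat), allele)
  for (chrom in colnames(mat)[on_chrom]) {
    for (o in others) {
      if (mat[o, chrom] >= hap_min_count &&
          length(intersect(genes_of(o), my_genes)) > 0L)
        return(FALSE)
    }
  }
  TRUE
}

#' Apply suggested thresholds to a threshold table
#'
#' Convenience for iterating the tuning procedure: returns a new
#' `threshold_table` in which each suggested (non-contradictory) threshold
#' replaces the current one.
#'
#' @param thresholds A `threshold_table`.
#' @param suggestions Output of [suggest_threshold_adjustments()].
#' @return Updated `threshold_table`.
#' @export
apply_threshold_suggestions <- function(thresholds, suggestions) {
  keep <- !suggestions$contradiction &
    suggestions$suggested_threshold != suggestions$current_threshold
  sug <- suggestions[keep, , drop = FALSE]
  allele <- thresholds$allele
  thr <- thresholds$threshold
  for (r in seq_len(nrow(sug))) {
    i <- match(sug$allele[[r]], allele)
    if (is.na(i)) {
      allele <- c(allele, sug$allele[[r]])
      thr <- c(thr, sug$suggested_threshold[[r]])
    } else {
      thr[i] <- sug$suggested_threshold[[r]]
    }
  }
  threshold_table(allele, thr,
                  default_threshold = attr(thresholds, "default_threshold"))
}
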