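# Allele similarity clusters: distances, complete-linkage tree, threshold
# cuts, the two-level F/G naming scheme, and clustering comparisons.

#' Normalized Levenshtein dissimilarity between two sequences
#'
#' Edit distance with unit costs divided by the length of the longer
#' sequence, giving a dissimilarity in `[0, 1]` that is 0 exactly for
#' identical sequences. Levenshtein distance is used (rather than a
#' positional mismatch count) so that indels between alleles are modeled
#' directly on ungapped sequences.
#'
#' @param a,b Non-empty ungapped nucleotide strings (vectors are paired
#'   elementwise).
#' @return Numeric dissimilarity in `[0, 1]`.
#' @export
normalized_levenshtein <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  if (any(!nzchar(a)) || any(!nzchar(b)))
    abort_ascgeno("sequences must be non-empty", "ascgeno_empty_error")
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  d <- vapply(seq_len(n),
              function(i) utils::adist(a[[i]], b[[i]])[1L, 1L],
              numeric(1))
  d / pmax(nchar(a), nchar(b))
}

#' Pairwise normalized Levenshtein distance matrix
#'
#' @param ref A `germline_ref` (typically trimmed and collapsed).
#' @return Symmetric numeric matrix with zero diagonal, labeled by allele
#'   name, values in `[0, 1]`.
#' @export
pairwise_distances <- function(ref) {
  seqs <- ref$sequence
  if (length(seqs) < 2L)
    abort_ascgeno("need at least two sequences to compute distances",
                  "ascgeno_size_error")
  D <- utils::adist(seqs)
  norm <- outer(nchar(seqs), nchar(seqs), pmax)
  D <- D / norm
  dimnames(D) <- list(ref$allele, ref$allele)
  D
}

validate_distance_matrix <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D))
    abort_ascgeno("distance matrix must be square", "ascgeno_matrix_error")
  if (any(abs(D - t(D)) > 1e-12))
    abort_ascgeno("distance matrix must be symmetric", "ascgeno_matrix_error")
  if (any(diag(D) != 0))
    abort_ascgeno("distance matrix must have zero diagonal", "ascgeno_matrix_error")
  if (any(D < 0) || any(D > 1 + 1e-12))
    abort_ascgeno("distances must lie in [0, 1]", "ascgeno_matrix_error")
  invisible(TRUE)
}

#' Complete-linkage hierarchical clustering tree
#'
#' Agglomerates with complete (maximum) linkage and a fully deterministic
#' tie-break: leaves are first put in natural-sort order of their labels,
#' and among merge candidates at equal height the pair involving the
#' earliest-created clusters is merged first. The result is therefore
#' invariant to the input row order. Returned as a standard `hclust`
#' object, so [stats::cutree()], [stats::cophenetic()] and
#' [ape::as.phylo()] apply.
#'
#' @param D Symmetric distance matrix (as from [pairwise_distances()]) or
#'   a [stats::dist] object with labels.
#' @return An object of class `hclust`.
#' @export
build_tree <- function(D) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  validate_distance_matrix(D)
  labels <- rownames(D)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(D)))
  ord <- natural_order(labels)
  D <- D[ord, ord, drop = FALSE]
  labels <- labels[ord]
  n <- length(labels)
  if (n < 2L)
    abort_ascgeno("need at least two leaves", "ascgeno_size_error")

  M <- D
  code <- -seq_len(n)   # hclust codes of active clusters, creation order
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    k <- ncol(M)
    Up <- M
    Up[lower.tri(Up, diag = TRUE)] <- Inf
    h <- min(Up)
    cand <- which(Up == h, arr.ind = TRUE)
    cand <- cand[order(cand[, 1L], cand[, 2L]), , drop = FALSE]
    i <- cand[1L, 1L]; j <- cand[1L, 2L]
    merge[step, ] <- c(code[i], code[j])
    height[step] <- h
    newrow <- pmax(M[i, ], M[j, ])[-c(i, j)]
    keep <- setdiff(seq_len(k), c(i, j))
    M <- M[keep, keep, drop = FALSE]
    M <- rbind(cbind(M, newrow), c(newrow, 0))
    dimnames(M) <- NULL
    code <- c(code[keep], step)
  }
  structure(list(merge = merge, height = height,
                 order = tree_leaf_order(merge),
                 labels = labels, method = "complete",
                 call = match.call(),
                 dist.method = "normalized_levenshtein"),
            class = "hclust")
}

tree_leaf_order <- function(merge) {
  expand <- function(node) {
    if (node < 0L) return(-node)
    c(expand(merge[node, 1L]), expand(merge[node, 2L]))
  }
  expand(nrow(merge))
}

#' Cut a clustering tree at a similarity threshold
#'
#' Leaves are joined into one cluster exactly when their cophenetic
#' (complete-linkage) dissimilarity is at most `1 - similarity`; the
#' boundary is inclusive. Cluster labels are assigned in order of first
#' appearance over the natural-sorted leaves, so they are deterministic.
#'
#' @param tree An `hclust` tree from [build_tree()].
#' @param similarity Similarity threshold in `(0, 1]`; 0.75 yields allele
#'   families, 0.95 yields ASCs.
#' @return Named integer vector of cluster labels, one per leaf.
#' @export
cut_tree <- function(tree, similarity) {
  if (!is.numeric(similarity) || length(similarity) != 1L ||
      similarity <= 0 || similarity > 1)
    abort_ascgeno("similarity must be a single value in (0, 1]",
                  "ascgeno_threshold_error")
  h <- (1 - similarity) + 1e-9
  cutree(tree, h = h)
}

#' Build an ASC-named reference from a germline set
#'
#' The main clustering entry point: computes pairwise normalized
#' Levenshtein distances over the (collapsed) reference, builds the
#' complete-linkage tree, cuts it at the family and ASC similarity
#' thresholds (75% and 95% by default) and assigns similarity-based names.
#'
#' @param ref A trimmed, collapsed `germline_ref`.
#' @param family_sim Similarity threshold defining allele families
#'   (default 0.75).
#' @param asc_sim Similarity threshold defining ASCs (default 0.95).
#' @param amplicon Amplicon tag embedded in names (e.g. `"S1"`); defaults
#'   to the reference's amplicon class, empty for `"custom"`.
#' @param prefix Locus prefix for names (e.g. `"IGHV"`); inferred from the
#'   allele names when `NULL`.
#' @param key_table Optional previously published key table used to pin
#'   names (see [assign_asc_names()]).
#' @return An `asc_reference` (see [assign_asc_names()]) with the tree in
#'   attribute `"tree"`.
#' @export
build_asc_reference <- function(ref, family_sim = 0.75, asc_sim = 0.95,
                                amplicon = NULL, prefix = NULL,
                                key_table = NULL) {
  if (asc_sim < family_sim)
    abort_ascgeno("asc_sim must be at least family_sim", "ascgeno_threshold_error")
  D <- pairwise_distances(ref)
  tree <- build_tree(D)
  fam <- cut_tree(tree, family_sim)
  cl <- cut_tree(tree, asc_sim)
  out <- assign_asc_names(ref, fam, cl, amplicon = amplicon, prefix = prefix,
                          key_table = key_table)
  attr(out, "tree") <- tree
  attr(out, "family_sim") <- family_sim
  attr(out, "asc_sim") <- asc_sim
  out
}

#' Assign similarity-based allele names
#'
#' Names each unique sequence `"{prefix}{amplicon}F{f}-G{g}*{aa}"`, where
#' `f` is the allele family (75% cut), `g` the ASC index (95% cut, global
#' across families) and `aa` a two-digit allele number within the ASC.
#' Families, clusters and alleles are numbered in ascending natural-sort
#' order of their smallest member IUIS name; an externally supplied key
#' table can pin previously published names instead.
#'
#' @param ref Collapsed `germline_ref` the cuts were computed on.
#' @param family_labels,cluster_labels Named integer label vectors as
#'   returned by [cut_tree()]; clusters must nest within families.
#' @param amplicon,prefix,key_table See [build_asc_reference()].
#' @return An `asc_reference` tibble with columns `asc_allele`, `family`,
#'   `cluster`, `allele_number`, `iuis_names` (semicolon-joined synonyms),
#'   `sequence`.
#' @export
assign_asc_names <- function(ref, family_labels, cluster_labels,
                             amplicon = NULL, prefix = NULL,
                             key_table = NULL) {
  alleles <- ref$allele
  fam <- family_labels[alleles]
  cl <- cluster_labels[alleles]
  if (anyNA(fam) || anyNA(cl))
    abort_ascgeno("labels missing for some alleles", "ascgeno_label_error")
  # nesting check: every 95% cluster must lie inside one 75% family
  if (any(tapply(fam, cl, function(f) length(unique(f))) > 1L))
    abort_ascgeno("cluster partition does not nest within family partition",
                  "ascgeno_nesting_error")
  if (is.null(amplicon)) {
    amplicon <- attr(ref, "amplicon_class") %||% ""
    if (identical(amplicon, "custom")) amplicon <- ""
  }
  if (is.null(prefix)) {
    hit <- regmatches(alleles, regexpr("^[A-Z]+", alleles))
    prefix <- if (length(hit)) names(sort(table(hit), decreasing = TRUE))[1L] else "V"
  }
  fam_index <- index_by_smallest_member(fam, alleles)
  cl_index <- index_by_smallest_member(cl, alleles)
  f <- fam_index[as.character(fam)]
  g <- cl_index[as.character(cl)]
  a <- integer(length(alleles))
  for (gg in unique(g)) {
    idx <- which(g == gg)
    a[idx][natural_order(alleles[idx])] <- seq_along(idx)
  }
  asc_allele <- sprintf("%s%sF%d-G%d*%02d", prefix, amplicon, f, g, a)
  cm <- collapse_map(ref)
  iuis <- vapply(cm[alleles], paste, "", collapse = ";")
  out <- tibble::tibble(asc_allele = asc_allele,
                        family = f, cluster = g, allele_number = a,
                        iuis_names = iuis,
                        sequence = ref$sequence)
  if (!is.null(key_table)) out <- pin_names(out, key_table)
  ord <- order(out$family, out$cluster, out$allele_number)
  out <- out[ord, , drop = FALSE]
  structure(out, amplicon = amplicon, prefix = prefix,
            class = c("asc_reference", class(tibble::tibble())))
}

index_by_smallest_member <- function(labels, alleles) {
  smallest <- vapply(split(alleles, labels), natural_min, "")
  rk <- integer(length(smallest))
  rk[natural_order(smallest)] <- seq_along(smallest)
  setNames(rk, names(smallest))
}

pin_names <- function(out, key_table) {
  key_table <- tibble::as_tibble(key_table)
  if (!all(c("asc_allele", "sequence") %in% names(key_table)))
    abort_ascgeno("key table needs asc_allele and sequence columns",
                  "ascgeno_schema_error")
  idx <- match(out$sequence, key_table$sequence)
  pinned <- !is.na(idx)
  out$asc_allele[pinned] <- key_table$asc_allele[idx[pinned]]
  if (anyDuplicated(out$asc_allele))
    abort_ascgeno("key table pins the same name onto distinct sequences",
                  "ascgeno_key_conflict_error")
  out
}

#' Evaluate cut thresholds against IUIS gene labels
#'
#' For each similarity on the grid, cuts the complete-linkage tree and
#' computes two quality metrics relating clusters to IUIS genes: the
#' fraction of genes whose alleles span more than one cluster, and the
#' fraction of clusters containing alleles from more than one gene. The
#' crossing region of the two curves identifies a sensible ASC threshold.
#'
#' @param ref Collapsed `germline_ref` carrying IUIS names (merged names
#'   kept in the collapse map contribute all of their genes).
#' @param grid Numeric vector of similarity thresholds.
#' @return Tibble with columns `similarity`, `gene_split`, `cluster_mixed`.
#' @export
evaluate_cut_thresholds <- function(ref, grid) {
  if (length(grid) == 0L)
    abort_ascgeno("threshold grid is empty", "ascgeno_empty_error")
  tree <- build_tree(pairwise_distances(ref))
  cm <- collapse_map(ref)
  genes_of <- lapply(cm[ref$allele], function(v) unique(iuis_gene(v)))
  all_genes <- unique(unlist(genes_of))
  rows <- lapply(grid, function(s) {
    cl <- cut_tree(tree, s)[ref$allele]
    gene_clusters <- lapply(all_genes, function(gn) {
      unique(cl[vapply(genes_of, function(gs) gn %in% gs, logical(1))])
    })
    split_frac <- mean(lengths(gene_clusters) > 1L)
    mixed <- tapply(seq_along(cl), cl, function(idx) {
      length(unique(unlist(genes_of[idx]))) > 1L
    })
    tibble::tibble(similarity = s,
                   gene_split = split_frac,
                   cluster_mixed = mean(mixed))
  })
  dplyr::bind_rows(rows)
}

#' Compare two ASC clusterings of overlapping references
#'
#' Classifies every cluster of reference `a` by its image in reference
#' `b` (typically a re-clustering after alleles were added or removed):
#' `"dropped"` when none of its sequences remain, `"split"` when its
#' sequences land in several `b` clusters, `"merged"` when its `b` cluster
#' also absorbs sequences from another `a` cluster, else `"unchanged"`.
#'
#' @param a,b `asc_reference` objects; `b`'s sequences should be a subset
#'   of `a`'s (the intersection is used otherwise, with a warning).
#' @return Tibble with columns `a_cluster`, `status`, `b_clusters`,
#'   `partners` (other `a` clusters sharing the merged `b` cluster).
#' @export
compare_clusterings <- function(a, b) {
  shared <- intersect(a$sequence, b$sequence)
  if (length(shared) == 0L)
    abort_ascgeno("clusterings share no sequences", "ascgeno_disjoint_error")
  if (!all(b$sequence %in% a$sequence))
    warning("b contains sequences absent from a; using the intersection")
  a_cl <- a$cluster[match(shared, a$sequence)]
  b_cl <- b$cluster[match(shared, b$sequence)]
  rows <- lapply(sort(unique(a$cluster)), function(ac) {
    in_a <- a$sequence[a$cluster == ac]
    present <- in_a[in_a %in% shared]
    if (length(present) == 0L)
      return(tibble::tibble(a_cluster = ac, status = "dropped",
                            b_clusters = "", partners = ""))
    bc <- unique(b_cl[match(present, shared)])
    if (length(bc) > 1L)
      return(tibble::tibble(a_cluster = ac, status = "split",
                            b_clusters = paste(sort(bc), collapse = ";"),
                            partners = ""))
    partners <- setdiff(unique(a_cl[b_cl == bc]), ac)
    status <- if (length(partners)) "merged" else "unchanged"
    tibble::tibble(a_cluster = ac, status = status,
                   b_clusters = as.character(bc),
                   partners = paste(sort(partners), collapse = ";"))
  })
  dplyr::bind_rows(rows)
}

#' Translate allele calls between IUIS and ASC naming
#'
#' Maps every name inside (possibly comma-separated, possibly ambiguous)
#' calls through the key table. IUIS to ASC translation deduplicates, so a
#' call listing two IUIS alleles with identical sequence becomes a single
#' ASC name; ASC to IUIS expands to all merged synonyms. Unknown names
#' pass through with a warning, or raise when `strict = TRUE`.
#'
#' @param call Character vector of calls (comma-separated names).
#' @param key_table An `asc_reference` or a tibble with columns
#'   `asc_allele` and `iuis_names` (semicolon-joined).
#' @param direction `"iuis_to_asc"` or `"asc_to_iuis"`.
#' @param strict Raise on unknown names instead of passing them through.
#' @return Character vector of translated, deduplicated calls.
#' @export
translate_call <- function(call, key_table,
                           direction = c("iuis_to_asc", "asc_to_iuis"),
                           strict = FALSE) {
  direction <- match.arg(direction)
  kt <- tibble::as_tibble(key_table)
  if (!all(c("asc_allele", "iuis_names") %in% names(kt)))
    abort_ascgeno("key table needs asc_allele and iuis_names columns",
                  "ascgeno_schema_error")
  syn <- strsplit(kt$iuis_names, ";", fixed = TRUE)
  if (direction == "iuis_to_asc") {
    map <- setNames(rep(kt$asc_allele, lengths(syn)), unlist(syn))
  } else {
    map <- setNames(vapply(syn, paste, "", collapse = ","), kt$asc_allele)
  }
  unknown <- character(0)
  out <- vapply(split_call(call), function(names_in) {
    hit <- map[names_in]
    miss <- names_in[is.na(hit)]
    if (length(miss)) {
      unknown <<- c(unknown, miss)
      hit[is.na(hit)] <- miss
    }
    paste(unique(unlist(strsplit(unname(hit), ",", fixed = TRUE))),
          collapse = ",")
  }, "")
  if (length(unknown)) {
    if (strict)
      abort_ascgeno(paste0("unknown allele names: ",
                           paste(unique(unknown), collapse = ", ")),
                    "ascgeno_unknown_allele_error")
    warning("unknown allele names passed through: ",
            paste(unique(unknown), collapse = ", "))
  }
  out
}

#' Key table of an ASC reference
#' @param asc_ref An `asc_reference`.
#' @return Tibble with columns `asc_allele`, `iuis_names`, `sequence`.
#' @export
as_key_table <- function(asc_ref) {
  tibble::tibble(asc_allele = asc_ref$asc_allele,
                 iuis_names = asc_ref$iuis_names,
                 sequence = asc_ref$sequence)
}

#' Read / write a key table TSV
#' @param path TSV path.
#' @rdname key_table_io
#' @export
read_key_table <- function(path) {
  kt <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("asc_allele", "iuis_names") %in% names(kt)))
    abort_ascgeno("key table needs asc_allele and iuis_names columns",
                  "ascgeno_schema_error")
  kt
}

#' @param key_table Tibble as from [as_key_table()].
#' @rdname key_table_io
#' @export
write_key_table <- function(key_table, path) {
  readr::write_tsv(tibble::as_tibble(key_table), path)
  invisible(path)
}

#' Export a clustering tree as Newick
#' @param tree An `hclust` tree.
#' @param path Output file.
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}
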