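# Deterministic simulator: toy germline sets with planted cluster
# structure, and repertoires drawn from a planted genotype.

#' Simulation configuration
#'
#' Describes a toy germline set with planted family/cluster structure and
#' a repertoire drawn from a planted genotype. All stochastic choices are
#' drawn from a single seeded stream in a fixed order, so outputs are
#' byte-stable for a given configuration.
#'
#' @param seed Integer RNG seed.
#' @param n_genes,alleles_per_gene Planted gene (cluster) structure.
#' @param within_cluster_similarity Minimum pairwise similarity among the
#'   alleles of one gene (default 0.97).
#' @param between_cluster_similarity Maximum pairwise similarity between
#'   alleles of different genes (default 0.80).
#' @param duplicated_allele_pairs Number of extra gene names ("D" genes)
#'   carrying a sequence identical to another gene's allele.
#' @param planted_genotype Character vector of allele names the simulated
#'   subject carries; defaults to two alleles of every gene.
#' @param planted_frequencies Named numeric vector of per-allele usage
#'   frequencies (summing to 1 over the planted genotype); defaults to
#'   uniform.
#' @param n_sequences Repertoire depth (default 10000, a typical AIRR-seq
#'   depth).
#' @param mutation_rate Per-base substitution probability (default 0).
#' @param ambiguity_rate Fraction of records emitted with the true allele
#'   plus its nearest reference neighbour in `v_call` (default 0).
#' @param anchor_alleles Two J anchor alleles for the heterozygous subject.
#' @param haplotype Optional named character vector allele -> anchor
#'   allele, pinning V alleles to chromosomes; unpinned alleles draw their
#'   anchor 50/50.
#' @param seq_length Germline V length in nucleotides (default 318).
#' @param genes_per_subgroup Genes sharing a subgroup-level ancestor
#'   (default 2), giving family-level structure above the clusters.
#' @return A validated `sim_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              n_genes = 4L,
                              alleles_per_gene = 3L,
                              within_cluster_similarity = 0.97,
                              between_cluster_similarity = 0.80,
                              duplicated_allele_pairs = 0L,
                              planted_genotype = NULL,
                              planted_frequencies = NULL,
                              n_sequences = 10000L,
                              mutation_rate = 0,
                              ambiguity_rate = 0,
                              anchor_alleles = c("IGHJ6*02", "IGHJ6*03"),
                              haplotype = NULL,
                              seq_length = 318L,
                              genes_per_subgroup = 2L) {
  if (within_cluster_similarity <= between_cluster_similarity)
    abort_ascgeno("within-cluster similarity must exceed between-cluster similarity",
                  "ascgeno_config_error")
  rates <- c(mutation_rate, ambiguity_rate)
  if (any(rates < 0 | rates > 1))
    abort_ascgeno("rates must lie in [0, 1]", "ascgeno_config_error")
  if (length(anchor_alleles) != 2L)
    abort_ascgeno("exactly two anchor alleles required", "ascgeno_config_error")
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              alleles_per_gene = as.integer(alleles_per_gene),
              within_cluster_similarity = within_cluster_similarity,
              between_cluster_similarity = between_cluster_similarity,
              duplicated_allele_pairs = as.integer(duplicated_allele_pairs),
              planted_genotype = planted_genotype,
              planted_frequencies = planted_frequencies,
              n_sequences = as.integer(n_sequences),
              mutation_rate = mutation_rate,
              ambiguity_rate = ambiguity_rate,
              anchor_alleles = anchor_alleles,
              haplotype = haplotype,
              seq_length = as.integer(seq_length),
              genes_per_subgroup = as.integer(genes_per_subgroup))
  if (is.null(cfg$planted_genotype)) {
    genes <- toy_gene_names(cfg)
    cfg$planted_genotype <- as.vector(vapply(genes$gene[!genes$duplicate],
      function(g) paste0(g, "*0", seq_len(min(2L, alleles_per_gene))),
      character(min(2L, alleles_per_gene))))
  }
  if (is.null(cfg$planted_frequencies)) {
    cfg$planted_frequencies <- setNames(
      rep(1 / length(cfg$planted_genotype), length(cfg$planted_genotype)),
      cfg$planted_genotype)
  }
  if (abs(sum(cfg$planted_frequencies) - 1) > 1e-8)
    abort_ascgeno("planted frequencies must sum to 1", "ascgeno_config_error")
  if (!all(names(cfg$planted_frequencies) %in% cfg$planted_genotype))
    abort_ascgeno("planted frequencies must cover the planted genotype",
                  "ascgeno_config_error")
  structure(cfg, class = "sim_config")
}

toy_gene_names <- function(cfg) {
  sg <- ceiling(seq_len(cfg$n_genes) / cfg$genes_per_subgroup)
  gene <- sprintf("IGHV%d-%d", sg, seq_len(cfg$n_genes))
  dup_of <- rep(NA_integer_, cfg$n_genes)
  if (cfg$duplicated_allele_pairs > 0L) {
    src <- seq_len(min(cfg$duplicated_allele_pairs, cfg$n_genes))
    gene <- c(gene, paste0(gene[src], "D"))
    sg <- c(sg, sg[src])
    dup_of <- c(dup_of, src)
  }
  tibble::tibble(gene = gene, subgroup = sg, duplicate = !is.na(dup_of),
                 dup_source = dup_of)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

mutate_at_positions <- function(seq, positions) {
  chars <- strsplit(seq, NULL)[[1L]]
  for (p in positions) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

#' Generate a toy germline reference with planted structure
#'
#' Genes within a subgroup share a common ancestor sequence; gene base
#' sequences are separated so that cross-gene similarity stays at or below
#' the configured bound, and the alleles of one gene are mutated copies of
#' its base kept within the within-cluster similarity. Duplicated gene
#' names ("D" genes) carry a sequence identical to the source gene's first
#' allele, so [collapse_identical()] merges them. The planted constraints
#' are verified on the realized distance matrix; violation is an error.
#'
#' @param cfg A [simulation_config()].
#' @return A `germline_ref` (functional alleles, gapless IMGT coordinates
#'   covering positions 1..`seq_length`).
#' @export
make_toy_germline <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  L <- cfg$seq_length
  genes <- toy_gene_names(cfg)
  n_sub <- max(genes$subgroup)
  # distances are planted via disjoint mutated position blocks:
  # cross-gene (same subgroup) hamming = 2 * d_gene, within-gene <= 2 * d_allele
  d_gene <- floor((1 - cfg$between_cluster_similarity) * L / 2) +
    ceiling(cfg$alleles_per_gene * (1 - cfg$within_cluster_similarity) * L)
  d_allele <- floor((1 - cfg$within_cluster_similarity) * L / 2)
  roots <- vapply(seq_len(n_sub), function(i) random_dna(L), "")
  all_pos <- seq_len(L)
  alleles <- character(0); seqs <- character(0)
  gene_seq_cache <- list()
  for (gi in seq_len(nrow(genes))) {
    g <- genes$gene[gi]
    if (genes$duplicate[gi]) {
      src <- genes$gene[genes$dup_source[gi]]
      alleles <- c(alleles, paste0(g, "*01"))
      seqs <- c(seqs, gene_seq_cache[[src]][1L])
      next
    }
    root <- roots[genes$subgroup[gi]]
    base <- mutate_at_positions(root, sample(all_pos, min(d_gene, L)))
    gene_alleles <- character(cfg$alleles_per_gene)
    for (ai in seq_len(cfg$alleles_per_gene)) {
      gene_alleles[ai] <- if (ai == 1L) base else
        mutate_at_positions(base, sample(all_pos, d_allele))
    }
    gene_seq_cache[[g]] <- gene_alleles
    alleles <- c(alleles, sprintf("%s*%02d", g, seq_len(cfg$alleles_per_gene)))
    seqs <- c(seqs, gene_alleles)
  }
  ref <- germline_reference(alleles, seqs, functionality = "functional",
                            amplicon_class = "S1",
                            coordinates = "aligned_from_1",
                            provenance = sprintf("simulated (seed %d)", cfg$seed))
  verify_planted_structure(ref, cfg)
  ref
}

verify_planted_structure <- function(ref, cfg) {
  D <- pairwise_distances(ref)
  gene <- ref$gene
  dup <- grepl("D$", gene)
  base_gene <- sub("D$", "", gene)
  same <- outer(base_gene, base_gene, "==")
  diag(D) <- NA
  within_max <- suppressWarnings(max(D[same], na.rm = TRUE))
  between_min <- suppressWarnings(min(D[!same], na.rm = TRUE))
  if (is.finite(within_max) && within_max > (1 - cfg$within_cluster_similarity) + 1e-9)
    abort_ascgeno("planted within-cluster similarity violated; adjust config",
                  "ascgeno_config_error")
  if (is.finite(between_min) && between_min < (1 - cfg$between_cluster_similarity) - 1e-9)
    abort_ascgeno("planted between-cluster similarity violated; adjust config",
                  "ascgeno_config_error")
  invisible(TRUE)
}

#' Simulate an annotated repertoire from a planted genotype
#'
#' Draws `n_sequences` records from the planted allele frequencies and
#' emits them as an annotated AIRR-style table (calls, mutation counts and
#' coverage fields -- not raw reads, since downstream analysis consumes
#' annotations). Mutations are injected per base at `mutation_rate`;
#' `v_mutation_count` records the mutations falling within positions
#' 1..316. A fraction `ambiguity_rate` of records lists the true allele
#' plus its nearest reference neighbour. The anchor J call is taken from
#' the planted haplotype when configured, otherwise drawn 50/50.
#'
#' @param cfg A [simulation_config()].
#' @param ref The `germline_ref` from [make_toy_germline()].
#' @param subject_id Subject label for the table.
#' @return An `airr_tbl`.
#' @export
simulate_repertoire <- function(cfg, ref, subject_id = "sim_subject") {
  stopifnot(inherits(cfg, "sim_config"))
  missing_alleles <- setdiff(cfg$planted_genotype, ref$allele)
  if (length(missing_alleles))
    abort_ascgeno(paste0("planted alleles missing from reference: ",
                         paste(missing_alleles, collapse = ", ")),
                  "ascgeno_config_error")
  set.seed(cfg$seed + 1L)
  n <- cfg$n_sequences
  L <- cfg$seq_length
  pf <- cfg$planted_frequencies[cfg$planted_genotype]
  pf[is.na(pf)] <- 0
  truth <- sample(cfg$planted_genotype, n, replace = TRUE, prob = pf)
  # nearest reference neighbour of every planted allele, for ambiguous calls
  D <- pairwise_distances(ref)
  diag(D) <- Inf
  nearest <- setNames(ref$allele[apply(D, 1L, which.min)], ref$allele)
  ambiguous <- stats::runif(n) < cfg$ambiguity_rate
  v_call <- ifelse(ambiguous,
                   paste(truth, nearest[truth], sep = ","),
                   truth)
  m_total <- rbinom(n, L, cfg$mutation_rate)
  m_window <- rhyper(n, 316L, L - 316L, m_total)
  j_call <- character(n)
  if (!is.null(cfg$haplotype)) {
    pinned <- truth %in% names(cfg$haplotype)
    j_call[pinned] <- cfg$haplotype[truth[pinned]]
    j_call[!pinned] <- sample(cfg$anchor_alleles, sum(!pinned), replace = TRUE)
  } else {
    j_call <- sample(cfg$anchor_alleles, n, replace = TRUE)
  }
  tbl <- tibble::tibble(
    sequence_id = sprintf("S%06d", seq_len(n)),
    v_call = v_call,
    j_call = j_call,
    clone_id = sprintf("C%06d", seq_len(n)),
    v_mutation_count = m_window,
    v_mutation_count_total = m_total,
    v_coverage_start = 1L,
    v_coverage_end = L,
    v_alignment_length = L
  )
  as_airr(tbl, subject_id = subject_id)
}

#' Snapshot a simulation configuration as YAML
#' @param cfg A `sim_config`.
#' @param path Output YAML file.
#' @export
write_simulation_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$planted_frequencies <- as.list(x$planted_frequencies)
  x$haplotype <- if (is.null(x$haplotype)) NULL else as.list(x$haplotype)
  yaml::write_yaml(x, path)
  invisible(path)
}
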