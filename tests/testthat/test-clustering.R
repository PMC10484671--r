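# Distances, the complete-linkage tree, threshold cuts, naming and
# clustering comparisons.

test_that("normalized Levenshtein matches hand values and the DP oracle", {
  expect_equal(normalized_levenshtein("ACGT", "ACGT"), 0)
  expect_equal(normalized_levenshtein("ACGT", "ACGA"), 0.25)
  expect_equal(normalized_levenshtein("AAAA", "AA"), 0.5)  # 2 deletions / 4
  expect_error(normalized_levenshtein("", "ACGT"), class = "ascgeno_empty_error")
  set.seed(11)
  for (i in 1:25) {
    ab <- random_sequences(2, c(5L, 15L))
    expect_equal(normalized_levenshtein(ab[1], ab[2]),
                 dp_levenshtein(ab[1], ab[2]) / max(nchar(ab)))
  }
})

test_that("pairwise distance matrices are symmetric, zero-diagonal and label-preserving", {
  set.seed(5)
  seqs <- random_sequences(6)
  ref <- germline_reference(sprintf("IGHV1-%d*01", 1:6), seqs)
  D <- pairwise_distances(ref)
  expect_equal(rownames(D), ref$allele)   # input order preserved
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
  expect_true(all(D >= 0 & D <= 1))
  # entry-by-entry agreement with the independent DP oracle
  for (i in 1:5) for (j in (i + 1):6) {
    expect_equal(D[i, j], dp_levenshtein(seqs[i], seqs[j]) /
                   max(nchar(seqs[i]), nchar(seqs[j])))
  }
  same <- germline_reference(c("A1*01", "A2*01", "A3*01"),
                             rep("ACGTACGT", 3))
  Ds <- pairwise_distances(same)
  expect_true(all(Ds == 0))
  expect_error(pairwise_distances(germline_reference("A1*01", "ACGT")),
               class = "ascgeno_size_error")
})

test_that("the tree merges a two-leaf matrix at its only distance", {
  D <- matrix(c(0, 0.3, 0.3, 0), 2, 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  tree <- build_tree(D)
  expect_s3_class(tree, "hclust")
  expect_equal(tree$height, 0.3)
  expect_equal(sort(tree$merge[1, ]), c(-2L, -1L))
})

test_that("the four-leaf toy produces the derived merge heights and cuts", {
  # {a,b}=0.02, {a,c}={b,c}=0.10, d at 0.30 from all
  labs <- c("a", "b", "c", "d")
  D <- matrix(0.30, 4, 4, dimnames = list(labs, labs))
  D["a", "b"] <- D["b", "a"] <- 0.02
  D["a", "c"] <- D["c", "a"] <- 0.10
  D["b", "c"] <- D["c", "b"] <- 0.10
  diag(D) <- 0
  tree <- build_tree(D)
  expect_equal(tree$height, c(0.02, 0.10, 0.30))
  cl <- cut_tree(tree, 0.95)
  expect_equal(partition_sets(cl),
               canonical_sets(list(c("a", "b"), "c", "d")))
  # complete-linkage cophenetic distances dominate the input distances
  cop <- as.matrix(stats::cophenetic(tree))[labs, labs]
  expect_true(all(cop >= D - 1e-12))
})

test_that("cut thresholds behave at the boundaries", {
  ref <- germline_reference(c("A1*01", "A2*01", "A3*01"),
                            c("AAAAAAAAAA", "AAAAAAAAAC", "GGGGGGGGGG"))
  tree <- build_tree(pairwise_distances(ref))
  expect_equal(max(cut_tree(tree, 1.0)), 3L)          # all distinct -> singletons
  expect_equal(max(cut_tree(tree, 0.9)), 2L)          # 1 mismatch / 10 joins at 0.9
  expect_error(cut_tree(tree, 0), class = "ascgeno_threshold_error")
  expect_error(cut_tree(tree, 1.2), class = "ascgeno_threshold_error")
  bad <- matrix(c(0, 0.2, 0.4, 0), 2, 2)
  expect_error(build_tree(bad), class = "ascgeno_matrix_error")
})

test_that("trees and cuts match the brute-force complete-linkage oracle on random sets", {
  for (seed in 1:40) {
    set.seed(seed)
    n <- sample(3:8, 1)
    seqs <- random_sequences(n, c(12L, 20L))
    ref <- germline_reference(sprintf("IGHV1-%d*01", seq_len(n)), unique(seqs))
    if (nrow(ref) < 3) next
    D <- pairwise_distances(ref)
    tree <- build_tree(D)
    oracle <- naive_complete_linkage(D)
    expect_equal(tree$height, oracle$heights, tolerance = 1e-12)
    for (s in c(0.99, 0.9, 0.75, 0.5)) {
      expect_equal(partition_sets(cut_tree(tree, s)),
                   canonical_sets(oracle$cut(s)))
    }
  }
})

test_that("clustering is invariant to input row order", {
  set.seed(99)
  seqs <- unique(random_sequences(7, c(15L, 22L)))
  ref <- germline_reference(sprintf("IGHV1-%d*01", seq_along(seqs)), seqs)
  cl1 <- cut_tree(build_tree(pairwise_distances(ref)), 0.8)
  perm <- sample(nrow(ref))
  ref2 <- germline_reference(ref$allele[perm], ref$sequence[perm])
  cl2 <- cut_tree(build_tree(pairwise_distances(ref2)), 0.8)
  expect_equal(partition_sets(cl1), partition_sets(cl2))
})

test_that("family cuts coarsen ASC cuts and names follow the F/G scheme", {
  setup <- toy_asc_setup()
  asc <- setup$asc
  # nesting: each 95% cluster lies in one 75% family
  expect_true(all(tapply(asc$family, asc$cluster,
                         function(f) length(unique(f))) == 1L))
  expect_match(asc$asc_allele, "^IGHVS1F\\d+-G\\d+\\*\\d{2}$")
  # name format example: family 2, cluster 15, allele 2 under amplicon S1
  ref1 <- germline_reference("IGHV1-1*01", "ACGTACGT")
  one <- build_asc_reference(collapse_identical(ref1 |> rbind_dummy()),
                             amplicon = "S1")
  expect_equal(one$asc_allele[1], "IGHVS1F1-G1*01")
})

test_that("assign_asc_names validates nesting and honours a pinning key table", {
  ref <- collapse_identical(germline_reference(
    c("IGHV1-1*01", "IGHV1-1*02", "IGHV2-2*01"),
    c("AAAAAAAAAA", "AAAAAAAAAC", "GGGGGGGGGG")))
  fam <- setNames(c(1L, 1L, 2L), ref$allele)
  cl <- setNames(c(1L, 2L, 3L), ref$allele)
  out <- assign_asc_names(ref, fam, cl, amplicon = "S1")
  expect_equal(out$asc_allele,
               c("IGHVS1F1-G1*01", "IGHVS1F1-G2*01", "IGHVS1F2-G3*01"))
  # a cluster straddling two families is rejected
  bad_cl <- setNames(c(1L, 1L, 1L), ref$allele)
  expect_error(assign_asc_names(ref, fam, bad_cl),
               class = "ascgeno_nesting_error")
  pin <- tibble::tibble(asc_allele = "IGHVS1F9-G99*01",
                        iuis_names = "IGHV2-2*01",
                        sequence = "GGGGGGGGGG")
  pinned <- assign_asc_names(ref, fam, cl, amplicon = "S1", key_table = pin)
  expect_true("IGHVS1F9-G99*01" %in% pinned$asc_allele)
})

test_that("cut-threshold metrics see perfect structure and shared-sequence mixing", {
  # two genes, internally >=95% similar, <75% similar across genes
  ref <- collapse_identical(germline_reference(
    c("IGHV1-1*01", "IGHV1-1*02", "IGHV2-2*01", "IGHV2-2*02"),
    c(strrep("A", 40), paste0(strrep("A", 39), "C"),
      strrep("G", 40), paste0(strrep("G", 39), "T"))))
  ev <- evaluate_cut_thresholds(ref, grid = 0.95)
  expect_equal(ev$gene_split, 0)
  expect_equal(ev$cluster_mixed, 0)
  expect_equal(nrow(evaluate_cut_thresholds(ref, grid = c(0.8, 0.9, 0.95))), 3L)
  expect_error(evaluate_cut_thresholds(ref, numeric(0)),
               class = "ascgeno_empty_error")
  # an identical sequence shared by two genes mixes its cluster at any threshold
  shared <- collapse_identical(germline_reference(
    c("IGHV1-1*01", "IGHV1-1D*01", "IGHV2-2*01"),
    c(strrep("A", 40), strrep("A", 40), strrep("G", 40))))
  ev2 <- evaluate_cut_thresholds(shared, grid = c(0.5, 0.75, 0.95, 1.0))
  expect_true(all(ev2$cluster_mixed > 0))
})

test_that("clustering comparisons classify unchanged, dropped and merged clusters", {
  setup <- toy_asc_setup()
  asc <- setup$asc
  same <- compare_clusterings(asc, asc)
  expect_true(all(same$status == "unchanged"))
  # removing every sequence of one cluster reports it dropped
  keep <- setup$collapsed[setup$collapsed$allele != "IGHV2-5*01", ]
  reduced <- build_asc_reference(rebuild_collapsed(keep), amplicon = "S1")
  dropped_row <- compare_clusterings(asc, reduced)
  dropped_cl <- asc$cluster[grepl("IGHV2-5", asc$iuis_names)]
  expect_equal(dropped_row$status[dropped_row$a_cluster == dropped_cl], "dropped")
  # removing a bridge allele merges two complete-linkage clusters
  labs <- c("IGHV1-1*01", "IGHV1-2*01", "IGHV1-3*01")
  set.seed(123)
  seq_a <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE), collapse = "")
  seq_b <- mutate_positions(seq_a, c(10, 30))    # d(a,b) = 0.02
  seq_c <- mutate_positions(seq_b, c(50, 70))    # d(b,c) = 0.02, d(a,c) = 0.04
  expect_equal(normalized_levenshtein(seq_a, seq_b), 0.02)
  expect_equal(normalized_levenshtein(seq_b, seq_c), 0.02)
  expect_equal(normalized_levenshtein(seq_a, seq_c), 0.04)
  full <- collapse_identical(germline_reference(labs, c(seq_a, seq_b, seq_c)))
  asc_full <- build_asc_reference(full, asc_sim = 0.97)
  expect_equal(max(asc_full$cluster), 2L)    # {a,b} and {c}
  wo_a <- collapse_identical(germline_reference(labs[2:3], c(seq_b, seq_c)))
  asc_wo <- build_asc_reference(wo_a, asc_sim = 0.97)
  cmp <- compare_clusterings(asc_full, asc_wo)
  expect_true("merged" %in% cmp$status)
  expect_error(compare_clusterings(asc_full, setup$asc),
               class = "ascgeno_disjoint_error")
})

test_that("call translation deduplicates, expands and round-trips", {
  key <- toy_asc_setup()$key
  merged_asc <- key$asc_allele[grepl(";", key$iuis_names)]
  # two IUIS alleles with one sequence collapse to a single ASC name
  tr <- translate_call("IGHV1-1*01,IGHV1-1D*01", key, "iuis_to_asc")
  expect_equal(tr, merged_asc)
  # asc -> iuis expands to all synonyms
  back <- translate_call(merged_asc, key, "asc_to_iuis")
  expect_setequal(strsplit(back, ",")[[1]], c("IGHV1-1*01", "IGHV1-1D*01"))
  # round trip yields a superset containing the original name
  rt <- translate_call(translate_call("IGHV1-1*01", key, "iuis_to_asc"),
                       key, "asc_to_iuis")
  expect_true("IGHV1-1*01" %in% strsplit(rt, ",")[[1]])
  expect_warning(translate_call("IGHV9-9*01", key), "unknown")
  expect_error(translate_call("IGHV9-9*01", key, strict = TRUE),
               class = "ascgeno_unknown_allele_error")
})

test_that("key tables and Newick trees survive a disk round trip", {
  setup <- toy_asc_setup()
  kt_path <- tempfile(fileext = ".tsv")
  write_key_table(setup$key, kt_path)
  expect_equal(as.data.frame(read_key_table(kt_path)),
               as.data.frame(setup$key))
  nwk <- tempfile(fileext = ".nwk")
  write_tree_newick(attr(setup$asc, "tree"), nwk)
  phy <- ape::read.tree(nwk)
  expect_setequal(phy$tip.label, setup$collapsed$allele)
})
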