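---
title: "Allele similarity clusters and absolute-usage genotype inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allele similarity clusters and absolute-usage genotype inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ascgeno)
```

## Why cluster alleles by similarity

Annotating adaptive immune receptor repertoire (AIRR-seq) reads requires
assigning each rearranged sequence to a germline V allele. The official
IUIS names organize IGHV alleles by subgroup and by gene position along
the locus, but the locus is riddled with duplications and structural
variation: distinct genes can carry identical allele sequences, and
partial-coverage sequencing protocols make even more alleles
indistinguishable. The result is pervasive multiple assignment, which in
turn biases clonal inference, genotype calling and usage reporting.

`ascgeno` replaces the gene level of the hierarchy with *allele
similarity clusters* (ASCs): groups of germline alleles defined purely by
sequence similarity of the portion of the V region the experiment can
actually observe. Identical sequences collapse to a single name, and
every name maps back to its IUIS synonyms through a key table, so results
remain reportable in standard nomenclature.

## The clustering procedure

1. **Filter.** Keep functional alleles whose sequence covers IMGT
   positions 1 through 318 (`filter_functional()`,
   `filter_complete_v()`). Position 318 is the last point at which
   repertoire reads can reliably resolve germline variation, because the
   3' end of the V is trimmed during rearrangement.
2. **Trim and collapse.** Truncate every allele at position 318
   (`trim_three_prime()`) and merge identical sequences
   (`collapse_identical()`). Allele pairs that differ only beyond the
   trim point (in human IGHV, IGHV3-66\*01/\*04 and IGHV4-28\*01/\*03 at
   position 319) collapse here; `extend_to_full_length()` restores both
   full-length sequences, under a shared cluster name, when exporting a
   reference for aligners.
3. **Distance.** Pairwise normalized Levenshtein dissimilarity
   \(d(a,b) = \mathrm{lev}(a,b) / \max(|a|,|b|)\) on ungapped trimmed
   sequences (`pairwise_distances()`). Levenshtein is used rather than a
   positional mismatch count so indels are modeled directly; max-length
   normalization keeps \(d \in [0,1]\) and symmetric.
4. **Tree and cuts.** Complete-linkage agglomeration (`build_tree()`)
   cut at two similarity thresholds (`cut_tree()`): **75%** defines
   allele *families* (the similarity logic historically used for
   subgroups) and **95%** defines the *ASCs*. Complete linkage
   guarantees that every pair inside a cluster meets the similarity
   bound. `evaluate_cut_thresholds()` reproduces the two diagnostics
   used to choose the ASC threshold for a given reference set: the
   fraction of genes split across clusters and the fraction of clusters
   mixing genes, as functions of the threshold; for the full-length
   human IGHV set their trade-off region lies around 94-96%. The right
   cut depends on the reference set, so both thresholds are plain
   arguments.
5. **Names.** `assign_asc_names()` emits
   `"{prefix}{amplicon}F{f}-G{g}*{aa}"`, e.g. `IGHVS1F2-G15*02`: family
   2, cluster 15 (clusters are numbered globally, not within families),
   allele 02, in a full-length (`S1`) reference.

### Determinism

Clustering output must not depend on row order in a FASTA file. Leaves
are canonicalized to natural-sort order of their names before
agglomeration; equal-height merge candidates resolve to the
earliest-created cluster pair; cut boundaries are inclusive
(cophenetic dissimilarity \(\le 1 - s\), with a `1e-9` epsilon guarding
float comparison); families, clusters and alleles are numbered by the
natural-sort-smallest member name. Collapsed records keep the
natural-sort-smallest IUIS name as representative. With these rules two
runs on permuted input are byte-identical. Published name sets can be
pinned by passing a previously exported key table, since any numbering
policy is otherwise only unique up to ordering.

### Amplicon classes

`S1` denotes full V coverage (positions 1-318). Partial protocols are
modeled by `amplicon_spec()` windows: a BIOMED-2-style `S2` (FW1 primer,
5' truncated) and an ImmunoSeq-style `S3` (3' fragment only). The exact
5' start positions of those commercial assays are not standardized in
print; the defaults used in this package's tests (27 for S2, 259 for S3)
are configurable approximations, and users emulating a specific protocol
should supply their own window.

## Genotyping by absolute usage

For each repertoire (after filtering; see below), every record
contributes weight 1, split `1/k` across the `k` distinct ASC alleles of
its call (`compute_allele_usage()`). The *absolute frequency* of an
allele is its fractional count divided by the total number of records in
the repertoire — not by its gene's total, which is the conventional
approach. An allele enters the genotype when its absolute frequency is
at least its allele-specific threshold (`infer_genotype_asc()`).

* The default threshold is \(10^{-4}\): at typical depths of 10-20K
  sequences it admits alleles observed once or twice.
* The comparison is inclusive (\(\ge\)). The boundary case matters for
  alleles expressed near detection; inclusion was chosen so that an
  allele observed exactly at threshold is kept.
* Thresholds are per-allele (`threshold_table()`), because alleles
  differ widely in their characteristic expression; a population-tuned
  table can be loaded with `read_threshold_table()` and audited with
  `audit_thresholds()`.

The conventional within-gene relative-frequency rule is provided as
`infer_genotype_gene_based()` (allele kept when it is at least 12.5% or
5% of its gene's assignments). It is a deliberate simplification of
fraction-based genotyping tools, used only as a comparison baseline: it
misses alleles expressed far below their gene-mates (false negatives)
and can admit spuriously dominant low-usage alleles (false positives),
the two failure modes the absolute-usage method addresses.

### Repertoire filters

`select_clone_representative()` keeps each clone's least-mutated record
(ties to the smallest `sequence_id`), `filter_unmutated()` removes
records with any V mutation in IMGT positions 1-316 (the final V codon
is left free to absorb sequencing error), `filter_five_prime_complete()`
requires coverage from position 1, and `filter_three_prime_coverage()`
requires at least 312 aligned nucleotides. Filters are idempotent and
commute; frequencies are computed on the filtered total, since filtering
precedes usage calculation in the genotyping workflow. Mutation counting
accepts either a precomputed windowed `v_mutation_count` or paired
`sequence_alignment`/`germline_alignment` strings, from which mismatches
over gapped positions 1-316 are counted; gapped IMGT coordinates are
assumed.

## Haplotype evidence and threshold tuning

When a subject is heterozygous at an anchor gene (typically IGHJ6),
`partition_by_anchor()` splits V-allele counts by the anchor allele each
record rearranged with, attributing V alleles to chromosomes. This
supports two uses:

* **Dominance testing.** If population data says allele A is used
  \(r\) times more than allele B, observing \(k\) B-reads out of \(n\)
  A-or-B reads has upper-tail probability
  \(P(X \ge k), X \sim \mathrm{Binom}(n, 1/(1+r))\)
  (`binomial_dominance_test()`, exact summation). The \(1/(1+r)\)
  parameterization treats \(r\) as the usage ratio between the two
  alleles; \(1/r\) is selectable for users who interpret the ratio
  differently.
* **Threshold tuning.** `suggest_threshold_adjustments()` implements a
  three-case curation guideline. Case 1: when every carrier expresses
  an allele far above its threshold, raise the threshold toward (but
  below) the lowest carrier frequency. "Far above" is operationalized
  as 10 times the threshold and the raise target as 0.9 times the
  minimum carrier frequency — both are arguments, since the underlying
  guideline is qualitative. Case 2: when sub-threshold expression has
  clean haplotype support (the allele sits on a chromosome with no
  same-IUIS-gene conflict), lower the threshold to include those
  subjects; conflicting haplotypes (two alleles of one gene on one
  chromosome) flag a contradiction and leave the threshold unchanged.
  Case 3: undocumented alleles are seeded with the threshold of their
  nearest reference allele (`novel_allele_threshold()`, ties resolved
  to the smallest threshold and flagged) and then re-evaluated under
  cases 1-2. Suggestions are advisory output; nothing is applied
  automatically, and `apply_threshold_suggestions()` exists for users
  iterating deliberately. Applying a round of suggestions and re-running
  produces no further changes.

## What the simulator emulates

`make_toy_germline()` and `simulate_repertoire()` generate the package's
test beds. The germline generator plants a known cluster structure:
genes within a subgroup descend from a shared ancestor, each gene's
alleles stay within a configured similarity of each other (default 97%),
genes stay below a configured cross-similarity (default 80%), and
optional "D" gene names duplicate an existing allele sequence exactly —
the duplication pattern that motivates ASC naming. Planted constraints
are verified on the realized distance matrix. The repertoire generator
draws records from planted per-allele frequencies at a configured depth
(default 10,000, a typical AIRR-seq depth), injects uniform per-base
mutations, emits a configurable fraction of calls ambiguous between the
true allele and its nearest neighbour, and assigns each record a J
anchor allele — 50/50, or according to a planted chromosome map. All
draws come from one seeded stream in a fixed order, so fixtures are
byte-stable.

The simulator produces annotation records, not nucleotide reads: the
package consumes annotated AIRR tables, so read-level realism (SHM
hotspots, junction diversity, alignment error structure) is out of
scope. Consequently, passing simulation tests demonstrates the
correctness of the counting, thresholding and clustering logic under the
stated statistical model — not robustness to aligner idiosyncrasies or
biological mutation structure in real repertoires.

## Problem sizes used in the test suite

The shipped tests exercise: brute-force oracle equivalence of distances,
trees and cuts on random sets of up to 8 sequences over 100 seeds;
planted-genotype recovery over 20 replicates at depth 10,000 with
planted frequencies between 0.002 and 0.35 (all at least 20 times the
default threshold); and the rare-allele discordance scenario (an allele
at absolute frequency \(2\times10^{-4}\) inside a cluster whose other
alleles carry half the repertoire) over 5 replicates at depth 20,000,
where the ASC rule detects it and the 12.5% gene-based rule cannot.
These sizes were chosen to make sampling noise negligible relative to
the assertions while keeping the default suite fast.

## Known limitations

* Clustering is reference-set dependent: adding or removing alleles can
  merge, split or drop clusters. `compare_clusterings()` quantifies the
  effect, but names are only stable across reference versions when
  pinned via a key table.
* The gene-based baseline is intentionally simplified and should not be
  read as a faithful reimplementation of any specific genotyping tool.
* Amino-acid distances, alignment-based (gapped Hamming) distances, and
  automatic threshold optimization beyond grid evaluation are not
  provided.
* D and J references are handled only as pass-through call strings;
  leader/UTR sequence and non-IMGT numbering schemes are unsupported.
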