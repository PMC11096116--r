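# cladescope

Comparative-genomics and network analyses for clade-partitioned genome
collections, built around questions that arise when new genomes of
streptophyte algae (the closest algal relatives of land plants) are
compared with land plants and other green lineages:

* Which protein domains, **domain combinations** (unordered sets of
  distinct Pfam families on one protein) and orthogroups are shared by
  all groups, and which are **exclusive** to a region of the partition —
  for example, found only in Zygnematophyceae + Embryophyta?
* Which domain families are significantly **expanded** in one group of
  genomes (say, multicellular vs unicellular species)?
* Which functional annotations are **enriched** in a foreground gene set?
* Which genes form **co-expression modules**, and which functional
  categories co-occur within modules?
* Do paralog **Ks / 4dtv distributions** carry the signature of a
  whole-genome duplication (WGD)?

Every analysis stage is paired with a synthetic-data generator that
plants known truth (exclusive families, expansions, co-expressed
modules, divergence mixtures), so the whole pipeline is testable on one
CPU without downloading any genome.

## The statistics at the core

* **Presence algebra.** A feature × genome count matrix plus a
  genome → group partition; a feature is present in a group iff present
  in ≥ 1 genome of the group (`any_genome`; the stricter `all_genomes`
  rule requires every genome). Venn regions are the exact presence sets
  over the 2^k − 1 non-empty group subsets; repertoire similarity is the
  Jaccard index of group-present feature sets.
* **Expansion tests.** Per-feature Wilcoxon rank-sum on per-genome copy
  counts, exact by enumeration of all rank splits for groups of ≤ 10
  genomes (midranks for ties), normal approximation with tie correction
  beyond; rank-biserial correlation as effect size;
  Benjamini–Hochberg FDR control.
* **Enrichment.** One-sided hypergeometric tail
  P(X ≥ a) for the 2×2 foreground/background × with/without table,
  odds ratio (ad)/(bc).
* **HRR network.** Edge weight `hrr(i,j) = max(rank_i(j), rank_j(i))`
  of mutual Pearson-correlation ranks (log2(x+1) scale); edge kept iff
  hrr ≤ cutoff (default 30). Modules by heuristic cluster chiseling
  (HCCA): stepwise neighborhood expansion with iterative removal of
  nodes more connected outside than inside, candidates scored by
  internal-edge fraction, accepted greedily without overlap.
* **WGD screen.** Reciprocal best hits (E ≤ 1e−6), codon alignments,
  NG86 Ks (pathway counting, Jukes–Cantor correction), 4dtv (transversed
  fraction of fourfold-degenerate third positions, with a
  composition-aware TN93-style correction), zero-filtered Gaussian KDE
  with peak calls.

## Worked example

Simulate 16 genomes in 4 super-groups with 12 domain families planted
exclusive to Zygnematophyceae + Embryophyta, then recover them:

```r
library(cladescope)

sc <- clade_scenario(
  planted_exclusives = list("Zygnematophyceae+Embryophyta" = 12L),
  dropout_rate = 0, seed = 42)
sim  <- simulate_clade_annotations(sc)
tabs <- genome_feature_tables(sim$hits)
tabs$domains
#> presence_matrix [domain]: 200 features x 16 genomes; 3104 present cells

vp <- venn_partition(group_presence(tabs$domains, sim$partition))
lengths(vp[c("Chlorophyta+Streptophyte_algae+Zygnematophyceae+Embryophyta",
             "Zygnematophyceae+Embryophyta")])
#> ...core: 188    Zygnematophyceae+Embryophyta: 12

head(exclusive_features(tabs$domains, sim$partition,
                        c("Zygnematophyceae", "Embryophyta")), 3)
#> [1] "EXC_ZygnematophyceaeEmbryophyta_001"
#> [2] "EXC_ZygnematophyceaeEmbryophyta_002"
#> [3] "EXC_ZygnematophyceaeEmbryophyta_003"

repertoire_similarity(tabs$domains, sim$partition)[1:2, ]
#>        group1             group2 similarity
#> 1 Chlorophyta Streptophyte_algae       1.00
#> 2 Chlorophyta   Zygnematophyceae       0.94
```

All 12 planted exclusives are recovered (188 background families form
the shared core; 188/200 = 0.94 Jaccard similarity between groups that
differ only by the planted families).

A WGD-style divergence screen on 300 simulated paralog pairs drawn at
Ks ≈ 0.5:

```r
ps <- simulate_paralog_pairs(
  paralog_scenario(300, 300, list(c(0.5, 0.05, 1)), seed = 7))
ks <- vapply(seq_len(300), function(p) {
  aln <- codon_alignment(as.character(ps$cds[[2 * p - 1]]),
                         as.character(ps$cds[[2 * p]]))
  compute_ks(aln)$ks
}, numeric(1))
distribution_summary(ks)$peaks
#> [1] 0.46
```

The KDE mode lands at 0.46 — the planted 0.5 minus the small downward
bias of the NG86 estimator under a transition-biased process (see the
methods vignette).

## Command line

A thin CLI wraps the main stages (`inst/scripts/cladescope`):

```sh
cladescope simulate  --out fixtures --seed 1
cladescope domains   --hits fixtures/*_hits.tsv --dialect tsv --out out
cladescope cladesets --features out/domain_counts.tsv \
                     --partition fixtures/partition.tsv --out out
cladescope expand    --features out/domain_counts.tsv \
                     --partition fixtures/partition.tsv --out out
cladescope coexpress --matrix fixtures/expression.tsv --cutoff 30 \
                     --categories fixtures/gene_categories.tsv --out out
cladescope wgd       --cds fixtures/paralogs.fasta --out out
```

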