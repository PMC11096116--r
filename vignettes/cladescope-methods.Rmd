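---
title: "Methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette records the models behind each analysis stage, the
defaults and why they were chosen, what the synthetic generators do and
do not emulate, and the places where the design was genuinely open.
No empirical claim is made here that the test suite does not itself
compute.

## Presence algebra over a clade partition

The substrate of the comparative stage is a feature × genome count
matrix (`presence_matrix`) — features are Pfam-style domain families,
unordered domain combinations, or orthogroups — together with a
`clade_partition` assigning each genome to exactly one group (a clade
super-group, or a body-plan class such as unicellular vs multicellular).
Presence is always derived as count ≥ 1 and never stored, so filtering
can never desynchronize counts and presence.

Group-level presence uses the *any-genome* rule: a feature is present in
a group iff it is present in at least one member genome. This is the
default everywhere because group repertoires are unions of member
repertoires. The Venn partition assigns each group-present feature to
its exact presence set among the 2^k − 1 non-empty subsets of groups;
features present nowhere (possible after upstream E-value filtering) are
reported in a separate `absent` attribute rather than silently dropped,
so region sizes plus absent features always sum to the matrix rows — an
invariant asserted in the tests.

`exclusive_features()` offers a second, stricter *all-genomes*
universality (present in every genome of every in-region group, zero
genomes outside). Both are provided because exclusivity statements about
domain repertoires are naturally made at group level, while statements
about combinations shared "by all studied genomes" are per-genome; the
choice is explicit in the API rather than hidden in a default.

Repertoire similarity is the Jaccard index of group-present feature
sets. Published similarity percentages of this kind rarely state their
metric (overlap coefficient and shared fraction are plausible
alternatives); Jaccard is our declared choice and we do not claim to
reproduce any specific published percentage.

## Domain architectures

Domain hits are read either from a plain 6-column TSV or from the
hmmscan per-domain (`domtblout`) dialect, taking envelope coordinates
and the per-domain independent E-value. Overlap resolution is greedy by
ascending E-value: a hit is discarded when it overlaps an
already-retained hit by more than half the shorter hit's length
(`overlap_fraction = 0.5`), after removing hits with E > 1e−5. Genome
papers typically do not state their Pfam post-processing; these two
knobs are therefore explicit parameters with documented defaults, not
reconstructions of any particular study. Resolution is idempotent and
leaves no pair overlapping beyond the bound (both property-tested).

A protein's *architecture* is its retained families in start order; its
*combination* is the unordered set of distinct families, emitted only
when ≥ 2 distinct families co-occur — repeats of one family are a repeat
expansion, not a new combination. Combination identifiers are the sorted
family names joined with `+`, making them stable across genomes.

## Two-group expansion tests

Per-feature copy counts are compared between the two groups with the
Wilcoxon rank-sum test. For group sizes up to 10 genomes per side the
null distribution is enumerated exactly over all `choose(n1+n2, n1)`
rank splits with midranks for ties; beyond that, a normal approximation
with tie correction and continuity correction is used. The effect size
is the rank-biserial correlation. Features with all-zero counts carry no
information and are flagged as skipped rather than tested; BH adjustment
runs over the tested features only.

Two calibration notes, both visible in the acceptance tests:

* With small counts (e.g. Poisson(3) per genome, 5 genomes per side) the
  exact test is **conservative**: ties coarsen the attainable p-value
  set, and the empirical size at α = 0.05 sits near 0.03 rather than
  0.05. This is a property of exact rank tests on discrete data, not an
  implementation artifact; the acceptance criterion is evaluated with
  the directional (expansion) alternative, which is both the analysis
  mode the pipeline actually runs for "expanded in group 2" questions
  and slightly less conservative than the symmetric two-sided
  enumeration.
* Power for 3-fold expansions (Poisson mean 3 vs 9) at 8 genomes per
  group exceeds 0.95 at BH 0.05, comfortably above the 0.8 bar.

Enrichment of annotations in a foreground gene set uses the one-sided
hypergeometric tail computed from log binomial coefficients, with the
sample odds ratio reported as-is (`Inf`/0 on zero cells, never imputed).
Terms are flat labels; no ontology graph propagation is attempted.

## HRR network and HCCA modules

Correlations are Pearson on log2(x + 1) values — the conventional scale
for expression; the transform is a parameter because source studies
rarely state theirs. Each gene ranks all others by descending
correlation, ties broken lexicographically by gene id so that ranking,
network and clustering are fully deterministic. The highest reciprocal
rank of a pair is `max(rank_i(j), rank_j(i))`; an edge exists iff that
value is at most the cutoff (default 30, the conventional setting for
HRR networks; step size 3 and maximum cluster size 100 likewise follow
the "standard settings" of the published chiseling framework).

HCCA grows each node's neighborhood one step at a time and, **after
every expansion**, repeatedly removes nodes with more edges leaving the
candidate set than inside it. Interleaving the chiseling with the
expansion is essential: module genes acquire occasional reciprocal-rank
edges to background genes, and if the neighborhood is grown to three
steps before any chiseling, those bridges pull a second module into the
same candidate, which then survives chiseling as one merged cluster.
With interleaved chiseling the bridge nodes are removed at radius one
and planted modules are recovered cleanly. Candidates within the size
bounds (default 3–100) are scored by internal-edge fraction and accepted
greedily without overlap; all remaining genes stay unassigned. The
`seed` argument is recorded for interface symmetry but unused — every
tie is broken by node id.

Module recovery in the acceptance suite is measured as the adjusted Rand
index between planted and recovered assignments **restricted to the
planted genes** (recovered "unassigned" counts as a singleton). The
background genes are not part of the recovery target: they are iid
noise, and whether spurious rank-reciprocity among them yields small
extra clusters is irrelevant to whether the planted modules were found.

Category co-occurrence reports, per unordered category pair, both the
raw number of multi-category modules containing the pair and the
fraction of multi-category modules — published heatmaps of this kind do
not always state their normalization, so both candidate definitions are
returned.

## WGD screening

Reciprocal best hits use highest score with ties broken by lower E-value
then id, E ≤ 1e−6 (the conventional threshold for this step). Ks is
estimated with NG86: synonymous site counts as the fraction of possible
changes preserving the amino acid (changes to stop codons count as
nonsynonymous), differences averaged over substitution orderings with
stop-crossing paths excluded, Jukes–Cantor correction of both
proportions. NG86 was chosen over YN00 deliberately: it is transparent,
exactly testable against hand-counted examples, and the simulation-based
acceptance checks are estimator-agnostic; the `method` slot leaves room
for alternatives. Under the transition-biased (κ = 2) simulation the
estimator shows the expected small bias (about −4% at Ks = 0.5, +5% at
1.2, from the interplay of Jukes–Cantor averaging with twofold-site
saturation), well inside the acceptance bands.

4dtv considers third positions of codon pairs whose first two positions
are identical and fourfold-degenerate — a conservative definition that
avoids ambiguous degeneracy classes. The corrected value applies the
TN93-style transversion distance `-2 gR gY log(1 − Q / (2 gR gY))` with
purine/pyrimidine frequencies estimated from the qualifying sites; with
balanced composition this reduces to the Kimura two-parameter
transversion distance. Undefined values (no qualifying sites, saturated
log argument) are flagged, never thrown.

Distribution summaries drop exact zeros (identical pairs; the
conventional filter for this analysis), cap Ks at a ceiling of 5 against
saturation artifacts, and fit a Gaussian KDE with Scott's-rule bandwidth
on a 512-point grid. Peak calling keeps local maxima above 5% of the
density maximum and then merges any maximum lying within two bandwidths
of a taller one: on a fixed grid the FFT-based density estimate can show
one-grid-step ripples near a mode, and two maxima closer than the kernel
scale are one mode, not two.

## What the generators emulate — and what they do not

* **Clade scenario.** Genomes per group, background families present in
  all groups, families planted exclusive to a region, per-group Poisson
  copy counts (mean 2 by default — a typical abundance for a present
  domain family — floored at 1 so planted presence is never lost to
  sampling), and per-genome-family annotation dropout. Proteins are
  single-domain; realistic multi-domain architectures, E-value score
  distributions and gene structure are *not* simulated, so green tests
  establish correctness of the set algebra and counting, not robustness
  to annotation noise beyond the dropout model. Orthogroups mirror the
  domain families one-to-one, giving them the same planted structure.
* **Expression scenario.** Module genes share a latent factor with the
  requested pairwise correlation on the log2 scale
  (`sqrt(r)·f + noise_sd·sqrt(1−r)·ε`; `noise_sd = 1` gives exactly r);
  values are exponentiated (`2^(8+z)`) so the emitted matrix is positive
  and roughly lognormal. Condition structure, library-size effects and
  count noise are not modeled.
* **Paralog scenario.** A stop-free random ancestor evolves along two
  branches of Ks/2 under a synonymous-only third-position process
  (fourfold/threefold/twofold families; jump probabilities κ : 1 for
  transitions : transversions; per-codon substitution intensity scaled
  by the codon's synonymous-site fraction). The drawn Ks is therefore
  the expected realized synonymous divergence by construction, and no
  internal stop can arise. First-position synonymous changes (Leu, Arg)
  are not simulated, which contributes the small downward NG86 bias
  noted above. Sequence lengths in the 4dtv grid check are large
  (4,000 codons) purely to push site-sampling noise below the grid
  increment — a power consideration, not a tuning of the statistic.

## Determinism

Every generator seeds a private RNG stream and restores the caller's
RNG state; reruns with equal seeds produce byte-identical files
(MD5-checked in the acceptance suite). All analysis-side tie-breaks
(ranks, candidate ordering, greedy acceptance) are lexicographic, so the
analysis layer is deterministic without any seed.

## Known limitations

* No ancestral-state reconstruction: exclusivity is set algebra on extant
  genomes, not a gain–loss inference on a tree.
* The Wilcoxon expansion test compares per-genome counts directly;
  phylogenetic non-independence of genomes is ignored (as it is in
  two-group repertoire comparisons generally).
* NG86 saturates above Ks ≈ 2–3; values near the ceiling of 5 are kept
  for the KDE but should not be interpreted individually.
* `alignment_scores()` is quadratic, for toy inputs only; real RBBH
  inputs should come from an external search tool's score table.
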