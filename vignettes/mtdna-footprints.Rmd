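---
title: "Detecting incipient population subdivision from mitochondrial footprints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting incipient population subdivision from mitochondrial footprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtfootprint)
```

## The problem

Marine species with pelagic larvae typically show so much gene flow — and so
much standing mitochondrial diversity — that conventional fixation indices
cannot resolve recently subdivided stocks: $\phi_{ST}$ sits at or below
zero even when ecological evidence says two stocks exist. The situation this
package targets is exactly that regime: two samples (here labelled *north*
and *south*), very high haplotype diversity ($h \approx 0.997$), moderate
nucleotide diversity ($\pi \approx 0.008$), and two deep mitochondrial
lineages nested in both samples.

The detectable signal of *incipient* subdivision under limited migration is
not a frequency shift across the whole genealogy. It is a **footprint**:
when migration has been restricted for a while, clades that arose during
that window fail to spread to both populations by chance. That leaves two
linked, testable observations:

1. **base-composition heterogeneity** between the samples at the few
   sites whose substitutions define those young clades, and
2. **convergence** of those sites' derived states on a shallow,
   population-biased clade of the tree.

The pipeline operationalises both: per-site Fisher exact tests between the
two samples at every variable site, then parsimony mapping (ACCTRAN) of the
significant sites along a neighbor-joining tree, then a scan for branches
where several of those derived substitutions co-occur.

## Pipeline stages and their models

### Diversity statistics

Haplotype diversity uses Nei's unbiased estimator
$h = n(1-\sum p_i^2)/(n-1)$ with the sampling variance of his eq. 8.12;
nucleotide diversity is the mean pairwise p-distance with the total
variance of eq. 10.5/10.7. Two deliberate conventions:

* $\pi$ uses **uncorrected p-distance**, not the TN93 model, because the
  diversity estimators are defined on observed differences; model
  corrections belong to tree building only. The two scales are therefore
  not directly comparable and the output labels them separately.
* Published tables often print "±" values without naming the formula;
  this package computes Nei's variances and labels the square roots `se`.
  If a source used a different dispersion convention, compare magnitudes,
  not labels.
* Missing data: pairwise deletion (sites missing in either member of a
  pair are dropped for that pair) — the least wasteful convention, and
  vacuous on gap-free data.

### Per-site exact tests

At every variable column the $2 \times K$ table of base counts
(populations × observed bases, missing excluded) is tested with a
two-sided Fisher exact test: for $2\times2$, the sum of hypergeometric
point probabilities not exceeding the observed one; for $K > 2$ the
Freeman–Halton extension by exhaustive enumeration over tables with fixed
margins (feasible because minor-allele column sums are small at these
sample sizes). Flagging uses a **raw** $\alpha = 0.01$ across sites — the
analysis this reproduces applied no multiplicity correction, and the
footprint logic treats the flagged set as candidates to be corroborated on
the tree, not as final discoveries. Benjamini–Hochberg q-values are always
emitted alongside, clearly non-default.

Each flagged site is annotated with its gene, gene-relative position and
codon position (from the gene map; default ND2 1046 bp + ND5 1839 bp,
concatenated in that order, frame 0, vertebrate mitochondrial code), and
with a synonymy flag assessed against the codon contexts actually observed
in the alignment: a column is synonymous iff swapping any observed base
into any observed codon at that position never changes the amino acid.
Neutral footprints are expected to be synonymous third-position
transitions; nonsynonymous heterogeneity would instead suggest selection.

### Distances and the tree

Distances are Tamura–Nei (1993) with optional invariant-sites and
gamma-rate corrections: observed proportions are divided by $1-p_{inv}$,
and each $-\log w$ term becomes $\alpha(w^{-1/\alpha}-1)$. Base
frequencies are pair-averaged (the model's original convention;
alignment-wide frequencies are one flag away). The gamma shape and
invariant proportion are **user configuration, not estimates** — model
selection and parameter estimation are explicitly out of scope, so the
defaults (0.5, 0.5) are placeholders to be replaced by values selected for
the data at hand. Saturated pairs (non-positive logarithm arguments) abort
with the pair named rather than returning infinities.

The tree is plain neighbor joining (Studier–Keppler $Q$ criterion).
Determinism matters more than speed here: $Q$ ties break on the smallest
index pair under the stable input ordering, and negative branch lengths
are clamped to zero with the deficit moved to the sibling branch (raw
values retained as an attribute). On additive matrices the implementation
recovers topology and branch lengths exactly, which is the calibration the
tests enforce.

### Rooting and character mapping

Parsimony polarity needs a root. The default is midpoint rooting — with
two deep lineages the midpoint falls on the deep split, which is the
natural orientation — and any tip can be named as outgroup instead, since
"derived" versus "ancestral" claims depend on this choice. Midpoint ties
are resolved by the deterministic behaviour of the underlying rooting
routine; for trees whose longest paths share a central edge (the usual
two-lineage case) every tied path gives the same physical midpoint. A
zero-length tree has no midpoint and is rooted on the first tip with a
warning.

Character mapping is small parsimony: a Hartigan-style counting downpass
(exact for polytomies, reducing to the Fitch intersect-else-union rule on
binary nodes) followed by an accelerated-transformation uppass — each node
keeps its parent's state when that state is in the node's downpass set and
otherwise switches immediately, placing every change on the most rootward
branch where it is forced, so reversals are preferred over parallel
terminal gains. Remaining ties (root state, entering state of a forced
change) break on the fixed A < C < G < T order. The number of placed
changes always equals the parsimony minimum; the tests verify this against
exhaustive enumeration.

A **footprint clade** is any branch carrying ACCTRAN changes at
`min_sites` or more of the heterogeneous sites (default 2: "convergence"
requires co-occurrence). Each is reported with tip membership, population
composition, the sister clade's membership and composition, and a per-site
apomorphy flag (the site's change occurs on exactly one branch tree-wide —
a clean synapomorphy). Only significant sites are mapped by default;
`map_all_sites = TRUE` maps everything.

### $\phi_{ST}$

The fixation index is the one-level AMOVA variance-component ratio on
squared pairwise distances (the convention of distance-matrix AMOVA; an
unsquared mode exists for matrices that are already squared-Euclidean).
Negative estimates are legitimate — they are the expected behaviour of the
estimator near zero differentiation — and are never clamped. Significance
is by permutation of individuals across populations with sizes fixed,
10 000 permutations by default, +1/+1 corrected, under a mandatory seed.

## The synthetic-data generator

`simulate_dataset()` exists so every stage is testable without any
external download. It emulates, by construction, the statistical structure
described above:

* **two demes** (91 + 60 samples by default) under a structured
  coalescent: within-deme coalescence at rate $k(k-1)/2$, per-lineage
  migration at `migration_rate`/2, demes merging into a common ancestral
  deme at `split_time` (0.25 by default — a recent split, i.e. incipient
  subdivision);
* **recent expansion**: coalescence is damped by 1/`expansion_factor`
  more recently than `expansion_time` (defaults 20 and 1.0). This is the
  feature that reconciles $h \approx 0.997$ with $\pi \approx 0.008$: an
  equilibrium coalescent with that $\pi$ would produce far too few
  haplotypes, whereas post-expansion genealogies have long terminal
  branches and nearly every individual carries private mutations — the
  regime high-diversity marine mtDNA actually sits in;
* **two deep ancestral lineages**, each sampled lineage assigned to one
  with probability `lineage_mix` per deme, joined by a basal split placed
  so the expected lineage-to-lineage divergence is `admixture_depth`
  substitutions/site;
* **finite-sites mutation** on the genealogy: Poisson at rate
  $\theta/2$ per site per unit time, transitions favoured `ti_tv`:1
  (default 10), third codon positions `third_pos_weight`× more mutable
  (default 5, weights renormalised to mean 1). Finite sites matter: the
  footprint logic is about identifiable columns, including homoplasy
  (the same substitution recurring on unrelated branches), which an
  infinite-sites model would define away.

Defaults were calibrated once, against the target summary statistics, to
$\theta = 0.0022$/site and `admixture_depth` = 0.005: over seeded
replicates at the default sample sizes this realises $h \approx 0.996$ and
$\pi \approx 0.0078$ in both demes, inside the intended bands
($h \in [0.98, 1]$, $\pi \in [0.005, 0.010]$). The calibration values are
implementation choices, not estimates of any real population.

What the generator does **not** emulate: selection, recombination
(irrelevant for mtDNA), more than two demes, sequencing error, and
base-compositional evolution. Passing tests on simulated data therefore
demonstrate correctness of the machinery and statistical behaviour under
the stated model — not robustness to artefacts real datasets may carry.

## Numerical and design choices

* Coordinates are 1-based inclusive everywhere a user sees them.
* Haplotype identity is exact string equality; ambiguity codes are not
  expanded.
* The exact-test comparison `p(table) <= p(observed)` uses a relative
  tolerance of 1e-7 to absorb floating-point noise in tied tables.
* Downstream two-sample statistics require exactly two populations;
  I/O does not.
* Degenerate inputs degrade explicitly: zero-variation data produce an
  empty scan, an empty footprint report and an `NA` $\phi_{ST}$ with a
  warning; saturated distance pairs and single-population inputs abort
  with named errors, and the pipeline leaves an error manifest naming the
  failed stage.
* Problem sizes in the test suite are chosen for a desk-scale run: the
  oracle batteries use 8-taxon trees (100 NJ cases, 200 parsimony cases),
  replicate simulation studies use 24+24 to 25+25 samples over 600–1000 bp
  (50 replicates for the footprint power study, 12 for the type-I study),
  and the full 91+60 × 2885 configuration is exercised directly by the
  fixture pipeline and the 6-replicate calibration check.

## Known limitations

* The gamma/invariant distance parameters are configuration; without the
  values selected for a given dataset, branch lengths are not
  reproducible even when the topology is.
* ACCTRAN polarity, and hence apomorphy claims, are root-dependent; both
  rooting modes are exposed and the report should be read with that in
  mind.
* The Freeman–Halton path enumerates tables; with four common bases *and*
  balanced large margins at one site it can be slow (this does not arise
  at realistic mitochondrial sites, where minor alleles are rare).
* $\phi_{ST}$ here is the two-population, one-level AMOVA; hierarchical
  designs and pairwise matrices over many populations are out of scope.
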