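# mtfootprint

Detecting incipient population subdivision from mitochondrial
phylogenetic footprints.

## The problem

High-gene-flow marine species routinely defeat conventional population
statistics: with haplotype diversity near 1 and two deep mitochondrial
lineages mixed across localities, F-statistics hover at zero
(ϕ_ST ≈ 0, nonsignificant) even where ecology says separate stocks exist.
Under *limited* migration, however, clades that arose recently fail to
reach both populations by chance, leaving a detectable footprint: a few
variable sites whose base composition differs between the samples, and —
crucially — convergence of those sites' derived substitutions on a
shallow, population-biased clade of the gene tree.

`mtfootprint` implements that analysis end to end for two population
samples of aligned mitochondrial haplotypes:

1. **Diversity** — Nei's haplotype diversity
   `h = n(1 − Σp_i²)/(n − 1)` and nucleotide diversity
   `π = mean pairwise p-distance`, each with Nei's sampling variances.
2. **Per-site exact tests** — a two-sided Fisher exact test on the
   2 × K base-count table at every variable site (Freeman–Halton by full
   enumeration for K > 2), with gene/codon-position mapping and a
   synonymy call under the vertebrate mitochondrial code.
3. **Tree** — Tamura–Nei (1993) distances with +I (invariant sites) and
   +G (gamma shape α, each −log w → α(w^(−1/α) − 1)) corrections,
   neighbor joining, midpoint or outgroup rooting.
4. **Character mapping** — small parsimony with accelerated
   transformation (ACCTRAN: changes placed as close to the root as
   possible), then detection of *footprint clades*: branches where ≥ 2
   heterogeneous sites change together, reported with population
   composition, sister clade, and per-site apomorphy flags.
5. **ϕ_ST** — one-level AMOVA variance components on squared pairwise
   distances, ϕ_ST = σ²_a/(σ²_a + σ²_w), permutation test.
6. **Simulator** — a two-deme structured coalescent (recent expansion,
   two deep ancestral lineages, finite-sites mutation with ti/tv bias and
   hot third codon positions) calibrated so defaults reproduce the
   regime above (h ≈ 0.996, π ≈ 0.008 over 91 + 60 samples × 2885 bp).

## Worked example

The package ships a deterministic 151-sequence benchmark alignment
(91 "north" + 60 "south", ND2 + ND5 = 2885 bp) engineered to contain the
canonical footprint situation:

```r
library(mtfootprint)

aln <- make_table1_fixture()
res <- run_pipeline(aln = aln, seed = 1, n_perm = 2000, quiet = TRUE)
summary(res)
```

```
151 samples (north:91, south:60); 27 variable sites, 3 heterogeneous
 column gene gene_position codon_position  p_value is_synonymous
    501  ND2           501              3 0.003363          TRUE
   2285  ND5          1239              3 0.003363          TRUE
   2858  ND5          1812              3 0.008926          TRUE
1 footprint clade(s); phi_ST = -0.01233 (p = 0.7176)
```

Reading this: of 27 variable sites, exactly three show base-composition
heterogeneity at α = 0.01 — all synonymous third-position transitions
(e.g. ND2 position 501: north 91 C / south 54 C + 6 T, p = 0.0034).
ϕ_ST is slightly *negative* and nonsignificant: frequency-based statistics
see nothing. The footprint report is where the signal lives:

```r
print(res$footprint)
```

```
Footprint report: 1 clade(s) with changes at >= 2 heterogeneous site(s)
 - clade of 5 tips (north:0, south:5); sister 3 tips (north:3, south:0); sites 501,2285,2858 [apomorphic: 2858]
```

All three heterogeneous sites converge on one shallow clade of five
southern individuals whose sister clade is three northern individuals —
and the ND5-1812 substitution maps *only* there (apomorphic), while the
other two recur once each elsewhere. That combination — nested deep
lineages, ϕ_ST ≈ 0, but convergent population-private substitutions — is
the signature of incipient subdivision under limited migration.

File-based inputs work the same way (`run_pipeline(fasta =, labels =,
gmap = read_gene_map(...))`), and `inst/exec/mtfootprint` is a thin CLI
over the same functions (`mtfootprint run --fasta F --pops P --seed 1 -o
out/`). Simulated datasets come from `simulate_dataset(sim_config(seed =
...))`, with the true genealogy and mutation record attached.

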