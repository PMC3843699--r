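# paraldiv

Paralogue-aware population genetics for duplicated genes.

## The problem

Tandemly duplicated genes such as the human steroid 21-hydroxylase gene
*CYP21A2* and its pseudogene *CYP21A1P* do not evolve independently:
non-allelic (ectopic) gene conversion shuttles sequence between the copies,
homogenizing them ("concerted evolution"). Standard single-locus diversity
and neutrality analyses are blind to this, and conversely the paralogue
structure offers extra signal — positions where the two copies carry
*different fixed alleles* mark subregions where conversion has stopped
working, and excesses of high-frequency derived variants point at selective
sweeps. `paraldiv` packages the full analysis chain for this setting, for
population geneticists working on duplicated loci:

- **Site classification across the paralogue pair.** Every position is
  classified as `FIXED` (different fixed alleles in the two copies),
  `SHARED` (polymorphic in both — the footprint of ongoing conversion),
  `SPECIFIC_A`/`SPECIFIC_B` (polymorphic in one copy only) or `INVARIANT`,
  tabulated per gene region, with Pearson chi-square contrasts and
  noncentral-chi-square power.
- **Diversity and neutrality statistics.** Per-region and sliding-window
  S, pi, haplotype heterozygosity, Watterson's theta, Tajima's *D*, Fu's
  *Fs*, Fay & Wu's *H*, Zeng's normalized *H*, and the Ewens–Watterson
  homozygosity test, with outgroup polarization for the unfolded spectrum:

  - θπ = Σ 2·i·(n−i)·ξᵢ / (n(n−1)),  θW = S/a₁,  θH = Σ 2·ξᵢ·i² / (n(n−1)),
    θL = Σ i·ξᵢ / (n−1)
  - D = (θπ − θW) / √(e₁S + e₂S(S−1)),  H = θπ − θH = 2(θπ − θL),
    nH = (θπ − θL) / √Var̂
  - Fs = ln(S′/(1−S′)) with S′ = P(K ≥ k | θ = θπ) from the Ewens sampling
    formula (unsigned Stirling numbers, computed in log space)

- **Coalescent null models.** An internal n-coalescent simulator with
  piecewise-constant/exponential demography (a European
  bottleneck-plus-expansion preset: Ne = 1861 between 51 and 21 kya,
  regrowth since), fixed-S conditioning, and one-tailed simulation-based
  rejection probabilities; reruns with published minimum gene-conversion
  tracts masked.
- **Concerted-evolution tree diagnostics.** Jukes–Cantor distances,
  neighbor-joining trees, bootstrap supports, a BootScan-style
  pair-monophyly signal scan along windows, normalized Robinson–Foulds
  topology distances with a random-topology baseline, and a MaxChi-style
  conversion breakpoint scan with permutation significance.
- **A synthetic-data generator** that emulates the studied gene's
  statistical structure (64 chromosomes, 3357 bp, 44 segregating sites
  partitioned 12/21/11 across intron 2 / other non-coding / coding, 33
  distinct haplotypes, 6 protein variants, per-region fixed/shared/specific
  counts, a conversion-suppressed intron, optional sweep-skewed spectra)
  with a known truth table, so the entire pipeline is testable offline.

## Worked example

```r
library(paraldiv)

# a synthetic paralogue pair with the study's structure and known truth
d <- generate_paralogue_dataset(synth_config(seed = 42))

sites  <- polarize_sites(call_segregating_sites(d$aln_A, regions = d$regions),
                         d$outgroup)
pseudo <- call_segregating_sites(d$aln_B, regions = d$regions)
cls <- classify_paralogue_sites(sites, consensus_seq(d$aln_A),
                                pseudo, consensus_seq(d$aln_B))
count_classes_by_region(cls, d$regions)
#>    region fixed shared specific_A specific_B
#> 1  noncds     5      3         18          8
#> 2     cds     5      6          5          5
#> 3 intron2    17      1         11          3
#> 4   total    27     10         34         16

diversity_summary(d$aln_A, sites)
#> S = 44  k = 33  HHe = 0.970 (sd 0.008)  pi = 0.00265  theta_w = 0.002772  (L = 3357, n = 64)

neutrality_stats(d$aln_A, sites)
#> n=64 S=44 k=33 | D=-0.146 Fs=-9.75 H=-4.46 nH=-0.77 EW=0.045

ct <- pearson_chi2(rbind(c(17, 1, 11), c(10, 9, 23)))
sprintf("intron2 vs rest: chi2 = %.2f, df = %d, p = %.4f", ct$chi2, ct$df, ct$p)
#> "intron2 vs rest: chi2 = 10.42, df = 2, p = 0.0055"
```

Reading the numbers: the 64 sampled chromosomes collapse to 33 distinct
haplotypes (haplotype heterozygosity 0.97 — a highly diverse gene); 44 sites
segregate, giving Watterson's θ ≈ 0.0028 per site against π ≈ 0.0027, hence
the mildly negative Tajima's *D*; the strongly negative Fu's *Fs* reflects
the excess of distinct haplotypes; and the class-count block shows the
hallmark of suppressed conversion — 17 of the 27 fixed differences crowd
into the 282-bp intron 2, a contrast whose chi-square p-value is 0.0055.

The end-to-end driver produces a full report bundle (per-region summary,
chi-square contrasts, 300/30-bp sliding-window tracks, rejection
probabilities under neutral and demographic nulls, masked reruns):

```r
cfg <- analysis_config(aln_A = d$aln_A, sites_B_table = pseudo,
                       consensus_B = consensus_seq(d$aln_B),
                       og = d$outgroup, regions = d$regions,
                       tracts = default_conversion_tracts(),
                       replicates = 10000, seed = 1)
report <- run_full_analysis(cfg, out_dir = "out/")
```

A shell entry point with the same surface lives in
`inst/scripts/report.R`. Small plain-text fixtures (a 33-haplotype-by-44-site
table, region map and tract files, all synthetic) ship under
`inst/extdata/`.

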