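---
title: "Methods: paralogue-aware diversity, neutrality tests and coalescent nulls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paralogue-aware diversity, neutrality tests and coalescent nulls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paraldiv)
```

This vignette explains the statistical machinery of `paraldiv`, the
assumptions behind it, the choices that were genuinely open when the package
was designed, and what the synthetic-data tests do and do not demonstrate
about real data.

## Setting and data model

The package targets a duplicated locus: a functional gene (here called gene
A) and a paralogous pseudogene (gene B) sharing a common alignment frame.
The central data objects are a `hap_alignment` — distinct haplotypes with
integer multiplicities, so a sample of n chromosomes collapsing to k
variants is represented without redundancy — and a `site_table` of
segregating sites with per-allele chromosome counts, region labels, and
(after outgroup polarization) ancestral states and derived counts.
Coordinates are 1-based and closed within the frame. Columns containing
gaps or `N` are excluded from all nucleotide statistics (`drop_column`
policy); for distance-based tree building the same complete-deletion rule
applies pairwise-globally. Sites whose minor-allele fraction falls below a
configurable cutoff (default 0.01, applied to both genes in the pipeline)
are treated as monomorphic, which protects the analysis from
sequencing-error singletons in externally sourced frequency tables; the
boundary case (frequency exactly at the cutoff) is retained.

## Site classification across the paralogue pair

With both genes on one frame, each position is classified by coexistence of
variation: polymorphic in both (`SHARED`), in one only
(`SPECIFIC_A`/`SPECIFIC_B`), monomorphic in both with different alleles
(`FIXED`), otherwise `INVARIANT`. Shared polymorphism is the footprint of
ongoing non-allelic conversion (the same variant circulating in both
copies); fixed inter-paralogue differences accumulate precisely where
effective conversion has ceased. Classification consumes site tables plus
consensus sequences rather than raw alignments because pseudogene data
often arrive as frequency tables only. Tri-allelic positions count as
polymorphic; downstream frequency-spectrum statistics use the two most
frequent alleles of such sites. Class-count contrasts between regions use
Pearson's chi-square without continuity correction on the asymptotic
distribution — the convention that reproduces the published footnote
p-values from printed tables — and power is the standard noncentral
formulation `P(chi2(df, n w^2) > q_alpha)`; no attempt is made to reproduce
any particular GUI tool's effect-size convention.

Spatial uniformity of site positions is tested two ways: a continuous
one-sample Kolmogorov–Smirnov test against Uniform(0, L) and a chi-square
over equal-width bins with expectations proportional to bin length. The
bin width defaults to 300 bp — the sliding-window width — which is a
package choice; the terminal short bin keeps a proportional expectation
rather than being dropped.

## Diversity and neutrality statistics

Per-region summaries report S, k, expected haplotype heterozygosity
`HHe = n/(n-1) (1 - sum p_i^2)` with Nei's sampling standard deviation,
per-site pi and Watterson's theta. All neutrality statistics are computed
on per-gene (length-unscaled) totals, matching the output scale of the
standard tool chain they mirror:

* **Tajima's D** contrasts θπ with S/a₁ using the usual
  a₁, a₂, b₁, b₂, c₁, c₂, e₁, e₂ constants.
* **Fu's Fs** is `ln(S'/(1-S'))` with `S' = P(K >= k | theta = theta_pi)`
  under the Ewens sampling formula. Both S′ and its complement are
  accumulated in log space over unsigned Stirling numbers of the first
  kind (computed by the log-space recurrence and cached per n), so extreme
  probabilities keep full precision.
* **Fay & Wu's H** is `theta_pi - theta_H` on the unfolded spectrum; the
  identity `H = 2 (theta_pi - theta_L)` is exploited as a cross-check in
  the test suite, never as the implementation.
* **Normalized H** follows the published variance of `theta_pi - theta_L`
  evaluated at `theta = S/a1` and `theta^2 = S(S-1)/(a1^2 + a2)`.
* **Ewens–Watterson** reports observed homozygosity `F = sum p_i^2` with a
  Monte-Carlo null conditional on (n, k): Chinese-restaurant draws at the
  theta solving `E[K] = k` (bisection), retained only when they produce
  exactly k classes — conditioning removes the theta dependence. The
  *lower* tail (too little homozygosity, i.e. too many, too even
  haplotypes) is the headline p-value, the convention under which an
  unusually flat haplotype spectrum rejects neutrality; the upper tail is
  emitted alongside. A seed is mandatory.

Polarization uses a single outgroup sequence on the same frame: a site is
polarizable when the outgroup carries one of the observed ingroup alleles;
otherwise it is flagged and excluded from unfolded-spectrum statistics but
retained for folded ones. H and nH are therefore undefined without an
outgroup.

Coding-sequence statistics use Nei–Gojobori (1986) pathway counting:
fractional synonymous site counts by brute-force enumeration of all nine
single-base mutants per codon (mutations to stop codons count as
nonsynonymous; each codon's synonymous + nonsynonymous sites sum to
exactly 3), pathway-averaged difference counting between codon pairs, and
complete deletion of codons containing gaps in any haplotype. Within-sample
πA/πS is left uncorrected; divergence-based Ka/Ks against an outgroup
coding sequence is reported both raw and Jukes–Cantor-corrected, because
the cited tool chain's correction setting is not documented — the
corrected value is the headline. The McDonald–Kreitman table counts
in-sample polymorphisms (each variant codon against the consensus) versus
positions monomorphic in-sample but different from the outgroup, with a
two-sided Fisher exact p-value and neutrality index `(Pn/Ps)/(Dn/Ds)`,
flagged undefined on zero margins.

## Coalescent nulls and rejection probabilities

The simulator is a standard n-coalescent with piecewise demography: epochs
are intervals of backward time in generations, each constant or exponential
in Ne, with closed-form integration of the pair-coalescence intensity and
inversion per epoch (no discretization). The packaged European preset
carries the bottleneck at Ne = 1861 between 51 and 21 thousand years before
present. The source model leaves the flanking sizes and the generation time
unstated; the package sets ancestral Ne = 10 000, present-day Ne = 10 000
(reached by exponential regrowth from the bottleneck) and a 25-year
generation time — values consistent with the demographic literature this
class of model descends from — giving epoch boundaries at 840 and 2040
generations. All four are arguments of `european_demography()`.

Mutation is infinite-sites. The default conditioning is **fixed-S**: exactly
the observed number of segregating sites is dropped on branches with
probability proportional to branch length, so the observed S drives the
null. A theta mode (Poisson mutation numbers at rate `theta/(4 Ne)` per
generation) exists for calibration, where `E[S] = theta a1` holds exactly.
Rejection probabilities are one-tailed add-one estimators
`(1 + #{replicates <= observed})/(R + 1)` — lower tail for D, Fs, H, nH,
where negative values are the selection signal — so p is never exactly
zero. No recombination is simulated within the locus (the studied region
has low crossover rates); conversion enters the analysis only through
masking: `masked_rerun()` drops sites inside supplied minimum-tract
intervals (the packaged defaults are the two published tracts, 624–634 and
3080 plus 3102–3186), recomputes the observed statistics, and re-simulates
the null conditioned on the reduced S.

Two calibration facts are worth knowing, both established with this
package's simulator and independently reproduced with a second coalescent
implementation during development. First, the finite-sample mean of
Tajima's D is *not* zero under neutrality — about −0.11 at n = 64 with
S = 44 fixed (and still about −0.1 in theta mode): D's denominator is an
estimate, and the statistic is left-skewed. The acceptance suite asserts
the idealized mean-zero property at 3 Monte-Carlo standard errors and is
expected to flag exactly this. Second, under the European preset the mean
of D shifts *positive* (≈ +0.43 at these parameters): the 30-thousand-year
bottleneck dominates the short 840-generation expansion and enriches
intermediate-frequency variants. Rejection probabilities, which compare an
observation against the simulated distribution rather than against zero,
are unaffected by either fact.

## Sliding windows and tree diagnostics

Windows are defined on the nucleotide frame (default 300 bp width, 30 bp
step — the geometry of the published figure tracks), not on segregating-site
indices. Partial terminal windows are dropped by default (`drop_partial`),
since the downstream tool this mirrors does not document its edge handling;
`truncate_last` is available. Windows without segregating sites report
S = 0 and π = 0 but *undefined* (empty-cell) D and H, to avoid spurious
zero-dips in plots.

Tree diagnostics are deliberately distance-based: Jukes–Cantor distances
(`d = -3/4 ln(1 - 4p/3)`, saturation at p ≥ 0.75 flagged with a sentinel),
neighbor joining (through `ape`, with negative branches clamped to zero and
the deficit moved to the adjacent branch), column-resampling bootstrap, a
BootScan-style scan reporting the percentage of bootstrap trees in which a
designated sequence pair is monophyletic per window (for a pair this is
cherry-hood of the unrooted tree), and the normalized Robinson–Foulds
distance (symmetric difference of non-trivial bipartitions over `2(t-3)`;
unresolved trees contribute only their present bipartitions against the
resolved-maximum denominator). Maximum-likelihood inference is out of
scope: the downstream use of the trees here is topology comparison via RF,
which NJ/JC serves, and the random-topology RF baseline
(`random_rf_baseline()`, uniform labelled topologies by random sequential
addition) calibrates what "dissimilar" means for a given tip count.

The MaxChi conversion scan follows the classical two-sequence formulation:
over the comparable (both-ACGT) columns of an aligned pair, a window of 2k
sites slides with its midpoint as candidate breakpoint, scoring the 2×2
chi-square of left/right half against match/mismatch; the null is the
permutation distribution of the *maximum* chi-square under shuffling of the
per-site match labels, which absorbs the scan's multiplicity. Nominated
minimum tracts span the implicated mismatching sites of the denser half.
Detection never gates masking — tracts can always be supplied externally.

## The synthetic-data generator

`generate_paralogue_dataset()` plants the studied structure directly rather
than simulating a two-locus conversion process mechanistically: per-region
counts of fixed, shared and gene-specific sites (defaults equal to the
published per-region class counts: intron 2 17/1/11, other non-coding
5/3/18, coding 5/6/5, i.e. 27/10/34 overall and S = 44 for gene A
partitioned 12/21/11), derived counts drawn from the neutral `P(i) ∝ 1/i`
spectrum or a sweep-skewed mixture concentrated near n−1 inside the
conversion-suppressed region, multiplicities arranged to hit 33 distinct
haplotypes of 64 chromosomes, and a coding-region design in which seven of
the eleven gene-A cds sites are synonymous third-position changes and four
are nonsynonymous with carrier sets arranged to yield exactly six protein
variants. Four gene-A sites are pinned at 624/628/630/634 and six at
3080–3186 so the packaged masking tracts remove exactly 4 and 10 sites.
The outgroup carries the ancestral allele at every planted site and its own
private substitutions elsewhere (30 synonymous plus 10 nonsynonymous codon
changes and 40 non-coding changes by default), giving synonymous-biased
divergence — so Ka/Ks and the McDonald–Kreitman path have realistic,
purifying-like inputs. Pseudogene-side quantities the source tables do not
print are package choices: n_B = 64 chromosomes, 20 distinct classes, and
specific-B targets (3, 8, 5).

The gene layout itself (10 exons totalling 1488 bp, a 282-bp intron 2 at
positions 496–777, flanks and remaining introns totalling 1587 bp over a
3357-bp frame) reproduces the published per-label totals; the exon
boundaries are approximate because only the totals are printed, and they
are placed so the published tract coordinates fall in the right region
labels (intron 2 and the 3′ UTR).

Because no two planted events share a position, the classifier recovers the
truth table exactly, and this recovery — plus the behavior of the
statistics on the planted spectra — is what the tests certify. What passing
does **not** show: realism of linkage disequilibrium between sites
(carriers are drawn independently per site), mechanistic conversion
dynamics, recombination, sequencing error, or diploid-phasing uncertainty.
`generate_neutral_dataset()` complements this with mechanistically neutral
data (coalescent haplotypes materialized as sequences), used for spectrum
calibration.

## Numerical choices and degenerate inputs

Log-sum-exp throughout the Ewens machinery; Stirling tables cached per
sample size; chi-square tests refuse zero marginals; Tajima's D requires
n ≥ 4 and is flagged undefined at S = 0; Fu's Fs is flagged infinite when
S′ reaches 0 or 1 at machine precision; normalized H is flagged when its
variance estimate is non-positive; JC distances at p ≥ 0.75 get a sentinel
of 5 substitutions/site and a saturation flag; collapse ordering and all
tie-breaks are lexicographic for deterministic output; every stochastic
routine takes an explicit seed, and the pipeline derives stage-specific
sub-seeds from one master seed so reruns are byte-identical.

Problem sizes in the packaged tests were chosen to keep a full run at a few
minutes on one core: 10 000 replicates for the headline simulator
calibration, 1 500–4 000 for module-level Monte-Carlo checks, 100 generator
seeds for the sweep-ordering property, and n ≤ 8 for exhaustive
set-partition enumeration against the Ewens formula.

## Known limitations

* The null simulator has no non-allelic conversion process; conversion is
  handled by masking observed tracts, which changes S but cannot model the
  correlation structure conversion induces.
* Fixed-S conditioning reproduces the standard tool chain but makes the
  finite-sample means of D and H slightly nonzero (see above); comparisons
  should always run through rejection probabilities.
* NJ/JC trees stand in for ML trees; figure-level topologies are
  qualitative diagnostics, not inference targets.
* The Ewens–Watterson conditional sampler is rejection-based and slows
  down when k is far from `E[K]` at any theta.
* Power calculations use the generic noncentral chi-square; published
  power figures from GUI tools with bespoke effect-size conventions are
  not reproducible and are not targeted.
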