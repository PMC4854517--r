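---
title: "Methods behind poolscan: models, estimators and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind poolscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolscan)
```

## The problem

Pool sequencing (pool-seq) estimates population allele frequencies from
read counts of pooled DNA rather than from individual genotypes.  It is
the standard economical design for scanning many natural populations for
loci under ecological selection: collect tens of population samples
spanning an environmental gradient (here, a salinity gradient and a
spawning-season contrast in a small marine fish), sequence each pool to
moderate depth (~30x), and compare allele frequencies SNP by SNP between
groups of pools ("superpools").  Species with very large effective
population sizes are ideal for this design: genetic drift is negligible,
so neutral differentiation between populations is tiny (mean F_ST near
0.04) and essentially any locus with a large, consistent frequency shift
between ecologically defined groups is a candidate target of selection.

`poolscan` implements that analysis stack end to end, together with a
synthetic metapopulation generator carrying a machine-readable truth
table, so that every stage can be validated against known ground truth
without any external data.

## Differentiation scan

For a contrast of two superpools, per-pool read counts are first
normalised against the genome-wide expected coverage
(`normalize_counts()`): at positions covered above the expected depth,
the minor allele count is scaled by `expected/total` and rounded (never
below one read for an allele that was observed), and the major allele
receives the remainder, so the site total equals the expected coverage.
Scaling down over-covered sites controls the otherwise systematic
inflation of chi-square statistics at high-depth positions, where read
counts carry more nominal information than the finite pool of
chromosomes that generated them.  Counts are then summed within each
superpool and tested with a Pearson chi-square on the 2x2
reference/alternate x group table, one degree of freedom, no continuity
correction (`chi2_contrast()`, `scan_contrast()`).  SNPs monomorphic
across the union are flagged and excluded from p-value accounting.

Two significance conventions are reported side by side: the Bonferroni
threshold 0.05/n (`bonferroni_threshold()`) and fixed stringent cutoffs
(`stringent_cutoffs`: 1e-10 for calling significant SNPs, 1e-20 for the
SNPs used in independent-locus counting).

**Calibration.**  The chi-square treats superpool counts as binomial
draws from a common frequency.  Two realistic features violate that:
(i) allele counts are sampled twice, chromosomes from the pool and then
reads from the chromosomes, which multiplies the variance by roughly
`1 + (c-1)/(2N)` per pool (c = read depth, N = fish per pool); and (ii)
any residual neutral differentiation among pools adds a component
proportional to F_ST.  Both push the genomic-control inflation factor
(`inflation_factor()`) above 1, which the package's tests assert under
default conditions (47-100 fish per pool, F_ST = 0.038) — a scan on such
data must therefore rely on the empirical null or the stringent cutoffs
rather than nominal chi-square tail areas.  Conversely, the calibration
tests that assert uniform p-values use the regime where the chi-square's
assumptions hold: no differentiation, pools large enough that read
sampling dominates, and the usual validity restriction to SNPs with
adequate expected cell counts (union minor-allele frequency >= 0.05).
Frequency filters in those tests use the generator's true frequencies,
because filtering on the observed counts selects on the test statistic
itself and distorts the null.

**F_ST.**  The per-SNP estimator is Nei's `(H_T - H_S)/H_T` with
`H_T = 2*pbar*qbar` and `H_S` the average per-pool `2*p*q`
(`pool_fst()`), algebraically equal to `2 Var(p)/H_T` and non-negative
per SNP.  Applied to raw pool-seq frequencies this estimator absorbs the
read- and chromosome-sampling variance, which inflates it upward by
roughly `1/c + 1/(2N)`; this is precisely why coverage filtering before
summarising F_ST distributions matters.  Recovery of the configured
baseline is therefore asserted on the generator's true frequencies
(restricted to ascertainable SNPs, overall MAF >= 0.01), where the mean
comes back within 10% of the 0.038 target.

## Independent loci

Significant SNPs (p below 1e-20 by default) are collapsed into
independent loci in two steps (`cluster_independent_loci()`): positions
are first rescaled by subtracting the cumulative length of assembly gaps
preceding them (`rescale_coordinates()`), then single-linkage clustered;
a new locus starts wherever consecutive significant SNPs are at least
20 kb apart on the rescaled axis.  Single linkage mirrors the defining
criterion — independence means a 20-kb stretch with no significant SNP —
and scaffolds never merge except through an explicit, manually curated
merge map.  Raising the separation distance can only reduce the locus
count (tested as a property); lowering the p cutoff can split clusters,
so no monotonicity is asserted in that direction.

## Environmental association and the spawning mixed model

The salinity arm is a per-SNP Pearson correlation between pool allele
frequency and salinity, flagged at |r| >= 0.8
(`salinity_correlation()`).  This arm alone does not correct for shared
population history and is anti-conservative under structure; the
accompanying null-rate test (flag rate under the generator null with 19
pools) quantifies that, and the Bayesian covariance-matrix correction of
a full environmental scan is deliberately out of scope.

The spawning contrast uses a binomial generalized linear mixed model per
SNP (`glmm_spawning()`): alternate-allele counts per pool, logit link, a
fixed spawning-group effect, and a Gaussian random intercept per
population — the random intercept absorbs the variability between
populations within a group that a plain chi-square would misattribute to
the group effect.  The marginal likelihood is maximised by adaptive
Gauss-Hermite quadrature with 10 nodes (the 1-node Laplace default is
insufficient when between-population differences within groups are
small), and the p-value is a 1-df likelihood-ratio test against the
model without the group effect.  The fit is delegated to `lme4::glmer`,
which is the field-standard implementation of exactly this model; its
correctness is cross-checked in the tests against an independent
brute-force trapezoid integration of the marginal likelihood (agreement
within 1e-4 log-likelihood units, in practice ~1e-6) and against
ordinary logistic regression whenever the variance component is
estimated at zero.  The binomial denominator per pool is
`min(2 x fish, normalised read depth)`: read counts cannot carry more
information than the chromosomes actually sampled.  The choice of
denominator is exposed because reads and chromosomes differ in real
data.

## Window and region diversity statistics

* **Pooled heterozygosity** (`pooled_heterozygosity()`, `hp_windows()`):
  `H_p = 2 * sum(n_MAJ) * sum(n_MIN) / (sum(n_MAJ) + sum(n_MIN))^2`,
  with major/minor read counts summed over the SNPs of a 5-kb window
  before the product.  Bounded by 0.5 and invariant to label swaps;
  depressed in swept regions.
* **Tajima's D** (`tajimas_d()`, `tajd_windows()`): the standard
  normalised difference between mean pairwise diversity and Watterson's
  estimator with the usual a1, a2, b1, b2, c1, c2, e1, e2 constants;
  undefined (missing) when a window has no segregating sites.  Windows
  simulated under the constant-size coalescent average to D near 0;
  under a recent expansion the mean drops well below 0 — the genome-wide
  negative shift expected for a species that expanded after
  deglaciation.
* **Regional nucleotide diversity** (`diversity_regions()`,
  `compare_region_diversity()`): mean pairwise difference per site
  within and between two populations for a set of differentiated regions
  and a matched set of control regions, compared by one-sided
  Mann-Whitney tests.  The scientific point: haplotype blocks maintained
  by selection keep diversity in differentiated regions as high as or
  higher than background even within populations, the opposite of a
  recent hard sweep's signature.
* **LD decay** (`ld_decay()`): composite (unphased genotype-correlation)
  r-squared per SNP pair, averaged in distance bins; pool data have no
  phase, so the composite measure is the honest choice.
* **Individual heterozygosity** (`het_rate()`): heterozygous sites per
  callable bp, by convention restricted to scaffolds of at least 1 Mb to
  avoid edge effects; one heterozygote per 309 bp equals 0.32%
  diversity.

## Population structure

`fit_statistic()` computes per-SNP `F_IT = 1 - H_obs/H_exp` and its mean
with a standard error over polymorphic loci (monomorphic SNPs carry no
information and are excluded; SNPs below 90% call rate are dropped).
`expected_mixture_fit()` gives the Wahlund expectation for a sample that
is secretly a mix of two populations — for an equal mixture of
populations at frequencies 0.1 and 0.9 the expected F_IT is 0.64, a
strong heterozygote deficiency — so comparing an observed near-zero (or
negative) F_IT against this expectation distinguishes a genuinely
distinct population from an admixed sample.

Trees are built by canonical neighbor-joining (`neighbor_joining()`, via
`ape`), from a pluggable pool distance (default: mean absolute
allele-frequency difference, `allele_freq_distance()`) or from Hamming
distances between phased haplotypes at a locus (`haplotype_tree()`).
Additive distances are recovered exactly; negative branch lengths on
noisy distances are clamped to zero with a warning.  `date_split()`
converts sequence divergence to time with a molecular-clock rate
expressed per lineage pair, avoiding the factor-of-two ambiguity of
per-lineage rates; both divergence and rate are parameters, not
constants.

## Annotation-category enrichment

`compute_daf_bins()` sorts SNPs into absolute allele-frequency
difference (dAF) bins of width 0.05 — left-closed, a value on an edge
goes right, the last bin closed so dAF = 1 is retained — and compares
each category's observed count with `p(category) x n(bin)`.  The
enrichment is the log2 observed/expected ratio (M-value); significance
is a 1-df chi-square on the 2x2 in-bin x in-category table, with
expected-below-5 cells flagged.  Genome-wide category proportions may be
supplied (in simulations they are known exactly; estimating them from
the analysed SNPs is supported but slightly dilutes a real enrichment
because the enriched SNPs contribute to the baseline).  The 5'/3' UTR
classes can be merged behind a flag.  SNPs with missing frequency in
either superpool must be removed upstream, mirroring the missing-call
rule for unbiased dAF.

## Read-depth CNV scan

Depth in 1-kb windows is normalised per pool against the highest-depth
reference pool (`normalize_depth()`, idempotent), windows whose all-pool
mean falls below a floor (default 20% of the overall mean; the rule is
configurable because only its outcome, not its form, is ever reported in
comparable studies) are excluded, and each remaining window is tested
with a two-group one-way ANOVA plus the log2 group depth ratio
(`window_anova()`, verified against `stats::aov`).  Windows passing
p < 0.001 and |M| > 0.6 merge into regions when separated by at most one
non-significant window (`call_cnv_regions()`), which lets multi-kb CNVs
emerge from 1-kb windows while keeping isolated windows apart; regions
with mean mappability below 0.5 are flagged rather than deleted, so the
mappability filter remains a reviewable annotation.

## Coalescent check of the allele-frequency spectrum

`simulate_site_frequencies()` draws one Kingman genealogy per locus —
exponential coalescence waiting times at rate k(k-1)/2, with times
beyond a single instantaneous size change at scaled time t stretched by
the ancestral/current ratio x — and returns the derived-allele count of
one segregating site per locus.  Conditioning on exactly one segregating
site is taken in the mutation-rate-to-zero limit: the epoch carrying the
mutation is sampled proportional to the *expected* branch length of that
epoch, and, topology being independent of coalescence times, the carrier
count is the leaf count of a uniformly chosen lineage at that level.
This choice is deliberate: placing the mutation uniformly on each
*realized* tree (the naive reading of fixed-S simulation) samples
E[L_i/L] instead of E[L_i]/E[L] and visibly distorts the spectrum (for
n = 32 the singleton probability becomes 0.264 instead of the analytic
(1/i)/H_31 value 0.248).  With the exact semantics the simulated
spectrum matches the 1/i law to goodness-of-fit, hypergeometric
subsampling (`subsample_spectrum()`) preserves it, and the
Kolmogorov-Smirnov comparison (`ks_compare()`) cleanly separates an
expansion-shaped spectrum from equilibrium.  The size-change defaults
(t = 0.1, x = 0.35) describe a recent expansion from a smaller ancestral
population; both are free parameters, since only the qualitative
excess-of-rare-alleles contrast is ever asserted.
`simulate_coalescent_windows()` keeps the per-tree Poisson placement,
which is the correct model when the number of mutations is itself
random.

## The synthetic metapopulation generator

`sim_config()` / `simulate_metapopulation()` generate:

* **Neutral SNPs** — ancestral frequencies from the configured spectrum
  (constant: probabilities proportional to 1/i; expansion: the coalsim
  size-change model, not an ad-hoc distortion), per-pool frequencies
  from a Balding-Nichols beta draw at `baseline_fst` (default 0.038):
  the standard one-parameter model reproducing a given mean F_ST.
* **Haplotype blocks** — each block is a two-haplogroup system:
  diagnostic SNPs have haplogroup allele frequencies `1-eps` vs `eps`
  (eps = 0.025), and each pool mixes the haplogroups with a proportion
  set by its contrast group so the superpool |dAF| matches the block's
  target (clamped, with a warning, if unreachable).  Within a pool, one
  haplogroup chromosome count is drawn per block, shared by all its
  SNPs, which creates the strong within-block LD that real
  differentiated haplotype blocks display.  Blocks default to 10-200 kb.
* **Reads** — double-binomial pool-seq sampling: chromosomes from
  2 x pool size (47-100 diploids), then reads at Poisson(30) (negative
  binomial behind an overdispersion knob, since per-pool depth variance
  is rarely reported).  Variants with zero alternate reads in every pool
  are dropped, as they would never enter a call set.
* **Genotypes** — phased haplotypes for a configurable subset of pools
  (default: one pool per superpool, 30 diploids each), consistent with
  the pool frequencies and haplogroup structure.
* **Depth windows and CNVs** — per-pool window depth Normal around a
  pool-specific scale, multiplied by the fold change inside CNV
  intervals (1-26 kb) for the affected group; mappability mostly 1 with
  a configurable low-mappability fraction.
* **Annotations** — one category per SNP from configurable genome
  proportions, with an optional fold bias of the non-synonymous class
  inside blocks (the device used to test enrichment recovery).
* **Truth table** — every injected block and CNV with its coordinates
  and effect size, written alongside the data.

The default SNP spacing of 40 bp makes the population data carry ~0.3%
nucleotide diversity (individual heterozygosity about 1 site per
350-400 bp) under the default expansion spectrum, the level typical of
a very large marine population.

What the generator does **not** emulate: recombination-realistic
chromosome-scale genealogies (neutral SNPs are exchangeable rather than
locally correlated, so background LD is flat instead of decaying over
~100 bp), base-level sequencing error, reference bias, indels and
multi-allelic sites, and callability variation.  Passing tests
demonstrate that the estimators and the pipeline logic are correct under
the stated sampling models; they do not certify performance under
alignment artefacts or miscalled variants, which is what the coverage
and mappability filters exist to blunt on real data.

## Problem sizes and tolerances used in the checks

The package's own validation experiments run at desk scale, chosen once:
a 20-Mb genome (10 scaffolds x 2 Mb) with 20 pools and 25 injected
blocks for scan recovery; ~17,000 qualifying SNPs and 10,000 depth
windows for the null-calibration Kolmogorov-Smirnov checks (criterion:
p > 0.01); 100,000 coalescent loci for the spectrum (goodness-of-fit
p > 0.01, singleton proportion within 0.02 of 0.248) and 500 windows for
Tajima's D (|mean| < 0.1 at equilibrium); 50 synthetic SNPs for the
mixed-model cross-check (1e-4 log-likelihood tolerance); 30 + 30 regions
with 16 individuals per population for the diversity contrast
(Mann-Whitney p < 0.01); and exact assertions for the closed-form
worked examples (Bonferroni 4.9e-6 at 10,195 tests, 0.32% diversity at
one heterozygote per 309 bp, Wahlund 0.64, NJ recovery, F_IT extremes).
The `scripts/acceptance.R` entry point re-runs all of these from scratch
with a user-supplied seed and writes the resulting numbers as JSON.

## Known limitations

* The salinity correlation arm is anti-conservative under population
  structure (by design, with the Bayesian correction out of scope).
* The raw-count F_ST estimator absorbs sampling variance; interpret its
  absolute level only after coverage filtering, or work with the
  truth/frequency level in simulations.
* Per-SNP GLMM fitting is comparatively slow (~50 ms per SNP);
  genome-wide use should pre-filter with the chi-square scan, as the
  analysis this package follows did.
* Locus counting depends on the 20-kb/1e-20 convention; with denser
  significant SNPs or different LD the "independent locus" unit changes
  meaning.
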