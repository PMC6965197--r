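---
title: "Models and methods behind eqpopgen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind eqpopgen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eqpopgen)
```

# Scope

`eqpopgen` implements the population-genetic toolkit needed to monitor a
closed domestic-animal population — the motivating system is the
Thoroughbred horse — from SNP-array genotypes: quality control and LD
pruning, two genomic inbreeding measures with temporal trend statistics,
reconstruction of an ungenotyped sire's genotype from its half-sib
progeny, a composite selection-signal scan, the LD method for effective
population size, and PCA of the genetic relatedness matrix. Every stage
can be exercised on synthetic genotypes with known ground truth, so the
whole pipeline is testable without any external data. This vignette
records the models, the defaults and why they were chosen, the numerical
decisions, and the limits of what the synthetic experiments demonstrate.

# Genotype representation

A `GenotypeDataset` stores a sample-by-SNP matrix of B-allele dosage
codes (0/1/2, `NA` for missing), a map (chromosome, 1-based bp position,
allele labels) and per-sample metadata (sire, dam, sex, year of birth,
region). Positions are strictly increasing within a chromosome. All
positions are 1-based base pairs throughout; BED input is converted at
the boundary (half-open 0-based `[start, end)` becomes closed
`[start + 1, end]`). Chromosome labels are opaque strings; numeric-looking
labels sort numerically. When PLINK input does not declare alleles, B is
the lexicographically later observed allele; a SNP showing a single
allele codes it as A (dosage 0). The orientation affects labelling only:
every downstream statistic is orientation-symmetric or defined per SNP.

# Quality control

`filter_call_rate()` removes SNPs first, then samples, keeping units with
genotyping rate strictly above the threshold (default 0.95 for both
passes). `filter_maf()` keeps SNPs with minor allele frequency strictly
above the threshold (default 0.05). Both filters are idempotent.

`vif_prune()` implements sliding-window variance-inflation pruning: in
each 50-SNP window (stepping by 5 within a chromosome) the SNP with the
highest VIF, `1/(1 - R^2)` with `R^2` the multiple correlation of its
dosage on the other window SNPs, is removed until all VIFs are at or
below 50. VIFs come from the diagonal of the inverse dosage-correlation
matrix; missing dosages are mean-imputed for the regression only, and a
singular window falls back to per-SNP least squares with `R^2` capped at
`1 - 1e-12`. Standard pruning tools leave tie-breaking unspecified; here
ties remove the lower-MAF SNP first, then the earlier SNP in map order,
so a run is exactly reproducible. SNP-level parity with any particular
tool is deliberately not claimed — the contract is that after pruning,
every window restricted to kept SNPs satisfies the VIF bound.

`ibd_pihat()` estimates genome-wide IBD sharing by the method of moments:
per SNP, the probabilities of IBS 0/1/2 given IBD 0/1/2 are computed from
sample allele frequencies with unbiased falling-factorial estimators of
the frequency powers (the small-sample correction), observed IBS counts
are decomposed sequentially into P(IBD = 0, 1, 2), the solution is
clipped to the probability simplex and renormalised, and
`pihat = P(IBD=2) + P(IBD=1)/2`. `remove_related()` then applies a greedy
rule: repeatedly drop the sample in the most pairs above the threshold
(default 0.25), ties broken by higher missingness then sample order. A
greedy rule removes at most one member of an isolated pair and two
members of a fully related triangle; the source method description does
not say whether one or both members were dropped, so the greedy
one-per-pair rule is this package's documented choice.

# Inbreeding

`f_is()` is the moment estimator of the individual inbreeding coefficient
relative to Hardy-Weinberg expectation in the sampled population. For SNP
$j$ with sample B-allele frequency $p_j$ over $n_j$ non-missing samples,
the expected-homozygosity contribution is
$1 - 2 p_j (1-p_j) \, n_j/(n_j - 1)$, and for an individual scored at $L$
SNPs, $F_{IS} = (O_{hom} - E_{hom})/(L - E_{hom})$. SNPs with fewer than
two calls are skipped; an individual with $L = E_{hom}$ gets `NA` with a
warning; results are clamped to $[-1, 1]$.

`detect_roh()` is a sliding-window scan for runs of homozygosity. A
window of 30 SNPs moves one SNP at a time; a window is homozygous if it
has at most 1 heterozygous and at most 2 missing calls; a SNP is a "hit"
if at least 5% of the windows containing it are homozygous; maximal hit
runs are split at inter-SNP gaps above 1,000 kb and kept when longer than
1,000 kb, containing at least 30 SNPs, and at most 1,000 kb per SNP.
The window hit threshold (5%) is the one scanning parameter the usual
parameter set leaves implicit; the established default is adopted and
exposed. Two defined edge behaviours: a chromosome with fewer SNPs than
the window is scanned with a single truncated window, and segment
coordinates are the positions of the first and last SNP of the run (not
midpoints between SNPs) — $F_{ROH}$ depends on this convention, so it is
fixed and documented. Rerunning with `min_kb = 5000` yields the long-ROH
call that reflects recent inbreeding.

`f_roh()` divides an individual's summed ROH length by the autosomal
genome length, by default 2,242,960 kb (the horse autosomes, EquCab2).
`roh_prevalence()` ranks SNPs by the percentage of individuals whose ROH
cover them — a selection-adjacent summary, since locally common
homozygous haplotypes produce high prevalence.

`annual_trend()` computes annual means, SD, SE and a normal 95% CI
(mean ± 1.96 SE — the CI construction is not dictated by the source
method, so the normal multiplier is used and documented), then regresses
the annual means on year by unweighted OLS, with the slope's two-sided P
from the t distribution on `n_years - 2` degrees of freedom. A
zero-variance series returns slope 0, `R^2 = 0`, `P = 1` rather than an
indeterminate fit. `region_ttest()` compares regions pairwise on
individual-level values with the pooled-variance Student's t-test
(Welch's variant behind a flag); individual-level input is the default
because annual means would discard within-year sampling variance.
`performance_correlation()` is the Pearson r between inbreeding and a
rating, with the t-transform P-value.

# Sire genotype reconstruction

For a sire with $n \ge 20$ genotyped half-sib offspring and a population
at Hardy-Weinberg equilibrium, the offspring genotype distribution under
each candidate sire genotype is (over offspring AA, AB, BB, with $p$ the
population A-allele frequency and $q = 1 - p$):
sire AA $\to (p, q, 0)$; AB $\to (p/2, 1/2, q/2)$; BB $\to (0, p, q)$.
Per locus the method (i) applies the hard Mendelian rule — both
homozygote classes among offspring force a heterozygous sire; (ii)
excludes any candidate that assigns probability zero to an observed
class (the hard rule is exactly this exclusion in the limit); (iii)
computes the goodness-of-fit statistic $X^2_G = \sum (O-E)^2/E$ over
classes with $E > 0$; (iv) converts to likelihood scores with the
chi-square density; (v) normalises and assigns the argmax, ties going to
the candidate with the higher Hardy-Weinberg genotype frequency, then to
the heterozygote.

Two decisions deserve note. First, the degrees of freedom of the density
are not dictated by the method description; `df = 2` is the default
because the density is then finite and monotone decreasing everywhere, so
a perfect fit ($X^2 = 0$) cannot produce an unbounded likelihood the way
`df = 1` would, and the argmax is simply the smallest $X^2$. Second, the
statistic is computed on genotype classes; an allele-count variant exists
in the literature of such procedures but enumerates to strictly worse
accuracy, and is not used.

The decision rule has a quantifiable error floor. Exact enumeration of
all offspring compositions at $n = 20$ (weighting sire genotypes by HWE
and offspring by the multinomial) gives an expected concordance of 98.8%
on a panel with folded-uniform MAF above 0.05; the residual errors are
almost all homozygous sires whose offspring show an upper-tail count of
heterozygotes. Concordance rises steeply with family size —
`reconstruction_concordance()` is exact at moderate MAF by a few hundred
offspring — which is why the minimum-offspring threshold matters and is
exposed.

# Composite selection signals

The scan contrasts a selected population against a reference on a shared
panel with three constituent statistics:

* `fst_per_snp()` — Wright's two-group variance ratio,
  $F_{ST} = \mathrm{Var}(p_1, p_2) / (\bar p (1 - \bar p))$ with divisor-2
  variance, i.e. $(p_1 - p_2)^2 / 4$ over $\bar p \bar q$. This estimator
  is used because its limiting cases are exact (0 at equal frequencies,
  1 at fixed differences); sample-size-corrected estimators exist but are
  out of contract here.
* `delta_saf()` — the frequency gain of the allele favoured in the
  selected population, $|p_{sel} - p_{ref}|$; the tracked-allele
  orientation (the allele higher in the selected population) resolves a
  sign convention the method family leaves open.
* `xp_ehh()` — cross-population extended haplotype homozygosity from
  phased haplotypes: EHH at a distance is the probability two haplotypes
  drawn without replacement are identical from the core to that point;
  each direction is truncated when EHH drops below 0.05; the statistic is
  the log-ratio of the two populations' trapezoidal EHH integrals,
  standardised genome-wide to mean 0, SD 1. Phased input is required;
  synthetic data are generated phased, and real-data use expects
  pre-phased haplotypes.

`composite_score()` combines the constituents by fractional ranks:
ranks $1..n$ (ascending, average on ties) become $r' = \mathrm{rank}/(n+1)$,
then $z = \Phi^{-1}(r')$, the mean $\bar z$ over the $m$ tests gets a
one-sided upper-tail P from $N(0, 1/m)$, and $CSS = -\log_{10} P$. SNPs
with any missing constituent are excluded from ranking. `smooth_css()`
averages CSS over SNPs within a centred 1 Mb window on the same
chromosome (bounds inclusive); the composite is what gets smoothed —
the alternative of smoothing each constituent is available behind a flag
of the workflow, but the region definitions downstream are stated in
terms of the smoothed composite. `call_regions()` takes the top 1% of
scored SNPs by smoothed CSS (tier size `floor(f n)`, ties at the cutoff
included — the printed "~48 SNPs" for a 0.1% tier of a 48,896-SNP panel
corresponds to truncation, so truncation is the tier rule), clusters
consecutive tier SNPs with gaps at most 1 Mb, and keeps clusters of at
least 5. `map_genes()` reports genes whose interval overlaps a region
extended by 0.5 Mb flanks, closed intervals on both sides, so touching
endpoints count.

## Calibration caveat

The composite P assumes the $m$ constituent tests are independent under
the null. They are not: $F_{ST}$ and $\Delta SAF$ are both deterministic
functions of the same pair of sample frequencies, and their rank-z
correlation under pure drift measures about 0.98 in this package's
two-population simulations. The variance of $\bar z$ is therefore about
0.55 rather than $1/3$, and the null distribution of the composite P is
measurably non-uniform (Kolmogorov-Smirnov distance around 0.065
regardless of panel size, so any panel above roughly 650 SNPs rejects
uniformity at the 1% level). The acceptance suite runs this check at the
package's CSS study scale and reports the failure rather than hiding it:
the composite is a *ranking* device — empirical top-percentile
thresholds, as used throughout this package, are unaffected — but its
nominal P-values must not be read as calibrated error rates.

# Population structure and effective population size

`grm()` builds the standardised-dosage relatedness matrix: codes centred
by $2p$ and scaled by $\sqrt{2p(1-p)}$, missing entries contributing 0
after centring, cross-products divided per pair by the number of SNPs
observed in both samples; fixed SNPs are excluded. `pca_outlier()`
eigendecomposes the GRM and iteratively removes samples lying more than
`sigma` SDs from the mean on any of the top 10 components (default
`sigma = 10`, the relaxed threshold that keeps genuinely diverged
founder-breed samples; 6 is the conventional strict default), recomputing
until stable or five iterations.

`ld_ne()` estimates effective population size from the association
between unlinked loci. Burrows' composite disequilibrium
$\hat\Delta = \mathrm{cov}(x, y)/2 \cdot n/(n-1)$ is computed from
unphased dosages for every eligible locus pair (pairwise-complete over
missing data), converted to
$r^2 = \hat\Delta^2 / ((p_j q_j + h_j)(p_k q_k + h_k))$ with $h$ the
homozygote excess, and averaged. The drift component subtracts the
sample-size expectation — $1/S + 3.19/S^2$ for $S \ge 30$, the
small-sample constants $0.0018 + 0.907/S + 4.44/S^2$ otherwise — and the
random-mating solution is
$N_e = (1/3 + \sqrt{1/9 - 2.76\, r^2{}'})/(2 r^2{}')$ (small-sample:
$0.308$ and $2.08$). A non-positive drift component means drift is
undetectable at that sample size and $N_e$ is reported infinite. Only
inter-chromosomal pairs enter by default, because physical linkage
inflates $r^2$ and biases $N_e$ downward; the same-chromosome option
exists for comparison with tools that use it and is flagged as biased.
The confidence interval treats the pair count as chi-square degrees of
freedom for the mean $r^2$ and maps the bounds through the same formula;
locus pairs are strongly dependent, so this parametric CI is an
optimistic lower bound on uncertainty and is documented as such rather
than presented as equivalent to any particular tool's CI.

# The synthetic-data generators

The generators define the study conditions the pipeline is tested under.

`simulate_wright_fisher()` draws a **common ancestral haplotype pool**
(default 60 distinct haplotypes — a founder-bottleneck scale typical of
closed domestic breeds) at linkage equilibrium, bootstraps two
populations from it, and lets them drift independently with
recombination (uniform 1 Morgan per 100 Mb — the horse-scale
approximation; configurable) for a configurable number of generations.
The finite pool supplies the background LD that a selective sweep rides
on: a standing variant at frequency 0.1 occupies only a handful of
founder backgrounds, so selection produces the haplotype structure
XP-EHH is designed to detect. Genic selection multiplies a parent's
sampling weight by $(1+s)$ per copy of the selected allele, in the
selected population only; a lost selected allele triggers a bounded
whole-simulation redraw. After the burn-in, loci below the MAF floor
(default 0.05 pooled) are thinned and the panel trimmed to the configured
size — the same screen every array panel has seen. The census population
(`n_per_pop`) and the genotyped cohort (`sample_per_pop`) are separate
knobs because a genotyped study sample is normally a small subset of the
breeding population; the sweep-power experiments use a census of 400
diploids with 100 genotyped per population (200 haplotypes), spanning 40
generations at $s = 0.1$ — roughly the age of the breed in generations —
over a 362 Mb, 5-chromosome genome carrying 5,000 SNPs, i.e. the marker
density of the motivating arrays preserved by scaling the genome down
with the panel. Density is the right invariant to preserve because both
EHH decay and region clustering operate on physical scale.

`simulate_half_sib_family()` gives each offspring one fair-coin sire
allele and one dam allele drawn Bernoulli(p) per SNP (dams random under
HWE), then applies a symmetric code-flip genotyping error and missingness
last. The symmetric flip is adequate for concordance testing and is not
an array-specific error model.

`simulate_temporal_cohorts()` breeds one cohort per year from the
previous cohort: dams uniform among females; sires drawn from a small
elite pool (default 4) with probability equal to that year's skew,
otherwise uniform. The default ramps the skew from 0 to 0.6 over
1996-2007 — the "big books" era pattern of mating concentration. The
census is large (4,000 foals/year from 400 founders) while only 60
animals per year are genotyped, mirroring a study that samples a large
breeding population. The census size matters for the null: a closed
population inbreeds under random mating at about $1/(2N_e)$ per
generation, so in a small census the zero-skew control would show a
genuine positive trend; at 4,000 per year the drift slope is an order of
magnitude below the sampling noise of 60 genotypes per year, and the
zero-skew control is statistically flat, isolating the effect of mating
skew. One year equals one generation here — real horse generation
intervals are 10+ years — so the simulated two-decade window compresses
what in the real population took most of a century; slopes are therefore
comparable in sign and significance, not in per-year magnitude.

`implant_roh()` forces an interval of one individual homozygous by
copying one allele of each het call over the other (fair coin), the
fixture generator for ROH detection round-trips.

`simulate_wf_unlinked()` is the ground-truth generator for the LD-Ne
method: free recombination at every locus, constant census equal to
$N_e$, 20 generations (enough for between-locus association to
equilibrate near $1/(3N_e)$), then a sample of individuals.

All generators are deterministic under `set.seed()`; the recombination
kernel draws from R's own RNG (including inside the compiled gamete
assembly), so a fixed seed reproduces byte-identical datasets across
platforms.

# Numerical choices and degenerate inputs

* VIF: `R^2` capped at `1 - 1e-12` (VIF at `1e12`); zero-variance SNPs
  get VIF 1 and never trigger removal.
* pi-hat: sequential moment solution clipped to the simplex and
  renormalised; SNPs with fewer than 2 called samples skipped.
* `f_is`: division guard when `L = E_hom`; clamping to `[-1, 1]`.
* Composite score: a constituent with zero variance contributes `z = 0`
  everywhere (with a warning) instead of undefined ranks; fractional
  ranks lie strictly inside (0, 1) by construction so `qnorm` is finite.
* XP-EHH: cores with a zero integral in either population are flagged
  `NA` and excluded from ranking and standardisation.
* `ne_from_r2`: the square-root argument is floored at 0 (very large
  `r^2` maps to the smallest solvable `Ne` rather than `NaN`).
* Ties: pruning (lower MAF first, then map order), sire assignment
  (higher HWE genotype frequency, then heterozygote), ROH prevalence and
  region ranking (map order) are all deterministic.

# Problem sizes used by the test suite

The acceptance experiments run at sizes chosen to exercise study-scale
behaviour on a single CPU: 200 fuzzed ROH instances up to 5,000 SNPs by
20 individuals against the exhaustive oracle; 20 replicate half-sib
families of 20 offspring at 5,000 SNPs; 20 drift-only and 20 sweep
replicates of the two-population simulation (2,000 and 5,000 SNPs); 20
replicates per level of the Ne recovery (2,000 unlinked SNPs, 50
samples); 20 rising-skew and 5 zero-skew cohort simulations. The
`scripts/acceptance.R` entry point re-runs the same computations at 10
replicates per quantity.

# Known limitations

* Composite-P calibration (above): ranking is sound, nominal P-values
  are anticonservative under correlated constituents.
* The sire-reconstruction decision rule has an irreducible ~1.2% error
  rate at exactly 20 offspring (exact enumeration); studies relying on
  reconstructed genotypes at that family size should treat per-locus
  calls as 98-99% accurate, not exact.
* The recombination map is uniform; real genomes have hotspots, so
  real-data EHH integrals decay less smoothly than simulated ones.
* The genotyping error model is a symmetric code flip; allele-intensity
  artefacts of real arrays (e.g. heterozygote undercalling, which
  inflates ROH) are not emulated, so passing tests do not certify
  robustness to platform-specific error structure.
* Cohort years are non-overlapping generations; overlapping generations
  and the long horse generation interval are not modelled, so simulated
  trend magnitudes are not per-year comparable to real populations.
* The LD-Ne parametric CI understates uncertainty because locus pairs
  are dependent.
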