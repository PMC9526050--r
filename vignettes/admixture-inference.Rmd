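---
title: "Methods: simulating and inferring sex-biased, assortative admixture histories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and inferring sex-biased, assortative admixture histories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

admixisle studies recently admixed populations founded by two source
populations ("S1" and "S2" throughout; all statistics are reported for S1).
It couples a mechanistic forward-in-time simulator with the inference stages
such histories call for: dating admixture from the decay of local ancestry
disequilibrium (LAD), testing for ancestry-assortative mating, inferring
sex-biased source contributions from X-versus-autosome ancestry, and
summarizing runs of homozygosity (ROH) and identity-by-descent (IBD)
segments. The simulator doubles as the test bed: every inference stage is
validated against populations whose history is known exactly.

## The forward model

A population of `N` diploids per generation is simulated for `G`
non-overlapping generations (`simulate_admixture()`). Generation 1 is the
founding cohort, built entirely from source migrants. To produce generation
`t`, `N/2` couples are formed; each mother slot is a new S1 migrant female
with probability `s1f[t]`, a new S2 migrant female with probability
`s2f[t]`, and otherwise a resident female drawn uniformly with replacement
from generation `t-1`; father slots use `s1m`, `s2m` likewise
(`contribution_schedule()`). This is the constant-admixture model: fixed
per-generation migrant fractions by sex and source. Migrants carry fresh
founder haplotypes and enter the pool *before* pairing, so strong
assortment preferentially pairs same-source migrants.

Couples are formed by `mate_assortative()`: ranks of each pool's
genome-wide ancestries are perturbed with Gaussian noise and sorted ranks
are matched; the noise scale is calibrated by bisection so the realized
Pearson correlation of spousal ancestries lands within ±0.05 of the target
`rho` (reliable for pools of 500+ with ancestry variance above 0.005).
"Genome-wide ancestry" always means the autosomal, cM-weighted S1 fraction.

Transmission is a standard Poisson crossover model without interference:
per meiosis and chromosome, the crossover count is Poisson in the genetic
length (Morgans), positions are uniform in genetic distance (the map uses a
constant cM/Mb per chromosome, 1 cM/Mb by default), and the starting
parental phase is a fair coin. Sons receive a recombinant maternal X only;
daughters receive a recombinant maternal X and the father's X intact. The Y
and mtDNA are not modeled. Every founder haplotype carries a unique key, so
autozygosity (`autozygosity_truth()`) and IBD (`ibd_truth()`) are exact
interval intersections of founder identity, not detection calls.

Two bookkeeping conventions matter downstream:

* **Generation indexing.** The founding cohort (t = 1) consists of children
  of pure-source parents, so its haplotypes are intact single-ancestry
  chromosomes and LAD equals 1. `G` cohorts therefore involve `G - 1`
  post-founding meiosis rounds, and the LAD-based fit — whose `g` counts
  decay rounds from full coupling — is expected to center on `G - 1` for a
  population simulated with `simulate_admixture(G)`. The
  parameter-recovery experiment in the test suite (true G = 15) recovers
  ĝ = 14 almost deterministically, inside the ±2 acceptance window.
* **Founding splits.** At t = 1 the schedule row is renormalized to
  source-only splits `s1f/(s1f+s2f)` and `s1m/(s1m+s2m)` (no hybrids exist
  yet). The sex-bias recursions use the same convention, which is what
  makes the simulator and `expected_hx_ha()` agree to Monte-Carlo error.

## Dating admixture from LAD decay

`lad_windows()` measures, for windows of 10 Mb placed every 9 Mb
(successive windows overlap by 1 Mb; a sliding 1-Mb step is available via
`step_mb`), the Pearson correlation across haplotypes of the S1 indicator
at the window's two ends (the end anchor is queried just inside the
boundary). Correlation rather than covariance is used because it is
scale-free and matches the closed form below; covariance is reported for
diagnostics. Anchor pairs with zero variance at either end are dropped and
counted.

`expected_lad(c, g, rho, m, h0)` runs the coupled recursion for mean
ancestry \(H_t\) and the within-haplotype two-locus association \(D_t\)
with migrant inflow split `m*h0` / `m*(1-h0)` (which keeps mean ancestry
stationary — the data give only a scalar migration rate):

\[
H_{t+1} = m_1 + h H_t,\qquad
E[Z_1 Z_2]_{t+1} = m_1 + h\left(H_t^2 + D_t\,(1 - c(1-\rho))\right),
\]

initialized at the founding state \(H_0 = h_0\), \(D_0 = h_0(1-h_0)\), and
returns \(D_g / (H_g(1-H_g))\). With `m = 0` this reduces exactly to
\((1 - c(1-\rho))^g\). The cross-homolog ancestry coupling is approximated
as \(\rho D_t\), which is exact at both limits (\(\rho = 0\): random-mating
decay \((1-c)^g\); \(\rho = 1\): no decay). At intermediate \(\rho\) this
approximation *overstates* LAD retention — the true cross-homolog
covariance scales with the variance of genome-wide ancestry, which is far
smaller than \(D_t\) at short range — so fits that assume the estimated
\(\rho\) tend to land above the truth. The bias is in the conservative
direction for the package's central claim: random-mating fits
underestimate the age of admixture, and \(\rho\)-corrected fits are older.
The test suite asserts that simulated decay under assortment is bracketed
by the \(\rho = 0\) and target-\(\rho\) model curves.

`fit_generations()` converts each window's genetic span to a recombination
fraction with the Haldane map function \(c = (1-e^{-2d})/2\) and minimizes
the sum of squared differences over an integer grid of g (default 5–25,
matching the convention of constraining dates to a plausible historical
range); ties break toward smaller g, and boundary hits warn. Continuous
optimization is deliberately omitted. `generations_to_years()` converts g
to calendar dates with the conventional 20–30-year generation-time range
and a 25-year point estimate.

## Testing for ancestry-assortative mating

Each phased haplotype of an offspring is one parental gamete, so
`parental_ancestry()` estimates the two parents' ancestries per autosome as
the S1 genetic fractions of haplotypes 0 and 1 — a deliberately simple
moment estimator in place of model-based parental-haplotype reconstruction;
it is validated directly against the simulator's pedigree truth (correlation with the true transmitting parent
above 0.6 on a 100-cM chromosome at generation 20). Chromosomes are kept
separate because phasing does not link haplotypes across chromosomes.

`assortment_correlation()` computes the per-chromosome Pearson R on the
symmetrized set \(\{(a_1,a_2)\}\cup\{(a_2,a_1)\}\) (parent labels are
arbitrary; an ordered variant is available) and reports the median across
chromosomes — the value passed downstream as the assortment strength
\(\rho\). Note this estimate is attenuated relative to the true spousal
correlation by gamete-sampling noise; it is used as-is, mirroring the
empirical pipeline it models.

`permutation_null()` builds the random-mating reference by re-pairing
*individuals*: one permutation per shuffle, applied within every
chromosome. Two design points were forced by calibration experiments
rather than chosen a priori:

* Shuffling each chromosome independently is grossly anti-conservative
  (measured type-I error 0.39 at nominal 0.05): a sample's chromosomes
  share its two parents, so per-chromosome R values are strongly
  dependent, and independent shuffles shrink the null spread of the median
  far below its true sampling variation.
* The test assumes no first-degree relatives among the samples, the usual
  hygiene for cohort genotype data. Full sibs duplicate the identical
  parental link, which no row-level permutation can emulate (measured
  type-I 0.225 when sibs are retained). With one sample per couple the
  observed mother–father link is exactly a uniform permutation under
  random mating and the test is exact: measured type-I 0.065 at
  \(\alpha = 0.05\) over 200 null simulations, Kolmogorov–Smirnov
  uniformity p = 0.73, power 1.0 at \(\rho = 0.4\) with 500 samples and
  B = 1000.

The p-value uses the add-one estimator \((1 + \#\{|R_b| \ge |R_{obs}|\})/(1+B)\).

## Sex-biased admixture from X versus autosomes

Because the X spends two-thirds of its time in females, female-biased
contributions from a source raise that source's X ancestry above its
autosomal ancestry. `expected_hx_ha()` runs the constant-admixture
recursions for autosomal ancestry, female X and male X (sons draw their X
from mothers only); the pooled X expectation weights X dosage,
\((2 p_f H^{Xf} + (1-p_f) H^{Xm})/(1+p_f)\), with \(p_f\) the proportion of
females in the sample. `sexbias_grid()` enumerates the full constrained
lattice of `(s1f, s1m, s2f, s2m)` at increment 0.02 (lattice points where a
sex has zero source contribution cannot found the population and are
excluded), computes the Euclidean distance between model and observed
(autosome, X) ancestry, and retains the closest 0.1% (ceiling count; ties
break lexicographically, so results are deterministic). Retained sets are
summarized by the female fractions \(f_1 = s1f/(s1f+s1m)\) and
\(f_2 = s2f/(s2f+s2m)\) and their medians. `sexbias_expect_grid()` exposes
the precomputed lattice so replicate searches are cheap.

## ROH and IBD

`boundary_from_generations()` encodes the 100/m-cM rule: a common ancestor
g generations back separates two lineages by m = 2g meioses, giving a mean
IBD segment length of 100/m cM — 2.5 cM, i.e. 2.5 Mb at the 1 cM/Mb
baseline, for g = 20. `classify_roh()` offers this fixed shorter/long
boundary and a 3-component Gaussian mixture on log10 physical length
(EM with k-means initialization, 20 restarts under a fixed internal seed;
class boundaries at the density intersections of adjacent ordered
components, midpoint fallback when heavy overlap leaves no intersection
between the means). The mixture refuses fewer than 50 segments or
degenerate lengths rather than fit nonsense.

`roh_summaries()` reports per-individual totals (classes partition the
total exactly), correlations with ancestry, and pairwise Mann–Whitney U
comparisons between populations. `ancestry_switches_in_roh()` counts
local-ancestry breakpoints strictly inside each ROH on either haplotype,
deduplicated at identical positions — within an autozygous segment the two
homologs are copies, so a shared breakpoint is one event. The printed
switch rates of any particular dataset are data-specific; the package
treats the direction (long ROH carry switches more often than shorter ROH)
as the reproducible signal.

`pairwise_ibd_totals()` applies the conventional 5-cM detection floor and
sums per unordered pair; `ibd_network()` thresholds at an absolute total
(150 cM, roughly fourth-degree relatives or closer) or keeps a top
quantile of the nonzero distribution. `kinship_proxy()` divides the
summed IBD over the four homolog pairs by four genome lengths, which
recovers 0.25 for parent–offspring and full sibs and halves per additional
meiosis; it replaces genotype-based kinship estimators, which are out of
scope because the simulator provides segment-level truth.

## What the generator does and does not emulate

The defaults describe an archipelago-like history: two-source admixture
over ~20 generations, constant per-generation contributions with a
female-biased S1 and male-biased S2 inflow, spousal ancestry correlation
0–0.6, island subpopulations realized as separate runs (founder effects
via a small founding `N`, e.g. `N = c(10, 300, ...)`), and a human-like
22-autosome + X map at 1 cM/Mb. The demonstration configuration
(`pipeline_config()`: N = 500, G = 20, rho = 0.4, s1f = 0.10, s2m = 0.05)
was fixed before any outcome was measured: it keeps both sexes of both
sources flowing, produces a mean S1 ancestry near the 0.6–0.65 reported
for such populations, and the larger ongoing S1 inflow means high-S1
individuals are enriched for recent (unrelated) migrant ancestors — the
mechanism by which shorter-ROH totals anticorrelate with S1 ancestry here.

Features of real data the generator does not emulate: source populations
have no internal background relatedness (founders are unrelated, so there
is no pre-admixture "short ROH" class and mixture classes compress),
recombination is constant per chromosome (no hotspots, no interference),
there is no phasing or local-ancestry calling error, no genotyping error,
and no selection. A green simulation test therefore establishes the
correctness and calibration of the estimators under the stated model, not
robustness to upstream calling artifacts.

## Numerical choices and degenerate inputs

Crossover positions are rounded to integer bp and deduplicated; coordinates
are 0-based half-open everywhere. All randomness flows through R's RNG
(including the compiled meiosis core), so a `sim_config` seed makes outputs
byte-identical; pipeline stages derive their seeds deterministically from
the master seed and stage name. `mate_assortative` falls back to random
pairing (correlation reported as NA) for degenerate ancestry pools.
LAD anchors with zero indicator variance are dropped and logged;
`x_vs_auto_test` refuses fewer than 6 informative pairs;
`assortment_correlation` skips zero-variance chromosomes with a warning;
Mann–Whitney tests use exact enumeration below 20 per group without ties
and the tie-corrected normal approximation otherwise. The heavy test-suite
simulations run on proportionally scaled maps (half or quarter scale) to
stay within desk-scale run times; tolerances are Monte-Carlo-SE based, so
they scale with the map.

## Known limitations

The \(\rho D_t\) coupling makes \(\rho\)-corrected dates biased old at
intermediate assortment strengths (direction-preserving; see above). The
moment estimator of parental ancestry is attenuated, so the \(\rho\) fed to
the timing fit is an underestimate of the spousal correlation — again
conservative for the underestimation claim. The permutation test requires
first-degree relatives to be removed upstream. The sex-bias grid assumes
contributions constant in time; time-varying schedules are supported by
the simulator but not inverted. The kinship proxy ignores inbreeding in
the pair members themselves.
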