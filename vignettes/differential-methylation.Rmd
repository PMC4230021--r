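---
title: "Beta-binomial regression for differential methylation: models and methods"
author: "methylBB"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Beta-binomial regression for differential methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylBB)
```

## The statistical model

A WGBS experiment observes, at each cytosine site and in each of $s$
samples, a read proportion $(m_i, n_i)$: $m_i$ reads indicating
methylation out of $n_i$ covering reads. With no replicate variability
$m_i \sim \mathrm{Binom}(p, n_i)$, but methylation levels genuinely vary
between replicates (library preparation, conversion efficiency,
inter-individual epigenetic variation). methylBB therefore models the
level of sample $i$ as a draw from a beta distribution and the count as
binomial given the level, which marginalises to the beta-binomial:

$$\Pr(M = m \mid n) = \binom{n}{m}
  \frac{B(m + \alpha,\; n - m + \beta)}{B(\alpha, \beta)}.$$

We use the mean/dispersion parameterisation
$\pi = \alpha/(\alpha+\beta)$, $\gamma = 1/(\alpha+\beta+1)$, under which

$$E(M) = n\pi, \qquad \mathrm{Var}(M) = n\pi(1-\pi)\,(1 + (n-1)\gamma),$$

so $\pi$ is the mean methylation level across replicates, $\gamma \in
[0, 1)$ is the dispersion, and $\gamma = 0$ recovers the binomial
exactly. Crucially, unlike fitting a beta distribution to the per-sample
ratios $m_i/n_i$, the beta-binomial keeps the coverage uncertainty: a
level estimated from 2 reads carries far less weight than one from 30.

Per site, the regression couples the samples through a logit link,

$$M_i \sim \mathrm{BetaBinomial}(n_i, \pi_i, \gamma), \qquad
  \mathrm{logit}(\pi_i) = \textstyle\sum_j X_{ij}\eta_j,$$

with $X$ an $s \times t$ binary model matrix (explicit intercept column
plus experimental factors or levels of multi-level factors) and a
*common* per-site dispersion $\gamma$. Effects $\eta_j$ are log-odds
ratios of mean methylation. The dispersion is estimated per site with no
genome-wide shrinkage or prior: sites with atypical replicate
variability are judged on their own data.

### Assumptions

* Counts at one site are independent across samples given the design.
* A single dispersion describes all samples at a site (no group-specific
  dispersion).
* Sites on opposite strands are independent rows; strand merging, if
  wanted, happens upstream during methylation counting.
* A sample with $n_i = 0$ carries no information at that site and is
  excluded from the likelihood.

## Testing a factor

For the factor of interest we fit the full model and the reduced model
without that factor's column(s), both by maximum likelihood, and refer

$$\Lambda = 2\,(\ell_{\text{full}} - \ell_{\text{reduced}})$$

to a $\chi^2$ distribution with one degree of freedom per dropped column
($\Lambda$ is clamped at 0; optimizers can return tiny negative values).
A site is *untestable* (p-value `NA`, propagated through every output)
when dropping zero-coverage samples leaves the design rank deficient or
leaves some level of the test factor with no coverage at all — the LRT
is simply undefined there.

The $\chi^2$ reference is asymptotic in the number of samples. The test
suite measures calibration directly on truly beta-binomial null data:
with 15 or 50 samples per group the empirical size at the 0.05 level is
nominal, while with 6 per group the likelihood-ratio test is measurably
anticonservative (the acceptance suite computes the 6+6 rate; readers
with small designs should expect raw p-values that are slightly liberal
and rely on the FDR-corrected, combined p-values, which the suite finds
consistent with the nominal level under the global null).

## Combining neighbouring p-values

Methylation is spatially organised, and DM regions are runs of sites
shifting together; a consensus test across neighbours both boosts power
at low coverage and suppresses isolated flukes. Raw p-values are mapped
to z-scores $z_i = \Phi^{-1}(1 - p_i)$ and combined over a window by the
weighted Z (Stouffer–Liptak) test,

$$p_z = 1 - \Phi\!\left(\frac{\sum_i z_i}
  {\sqrt{n + 2\sum_{i<j}\rho(d_{ij})}}\right),$$

which reduces to the classic Stouffer statistic $\sum z_i/\sqrt n$ under
independence (this limit fixes the placement of the square root and the
factor 2 in the variance). The Z form, rather than Fisher's product, is
deliberate: Fisher's method detects *one* significant test in a set,
whereas the Z statistic rewards consensus among all combined tests,
which is the right notion for a region "dominated by" DM sites.

The correlation $\rho(d)$ between tests $d$ bp apart is estimated
empirically, genome-wide, as the Pearson correlation over all pairs of
testable sites at exactly that distance (same chromosome), for every
integer $d$ up to `maxDist`. Distance bins with fewer than 50 pairs
inherit the nearest populated bin; with no populated bin at all the
profile is zero (independence). Estimates are clamped inside $(-1, 1)$.

Two numerical guards:

* **p-value clipping** at $10^{-15}$ before the quantile transform keeps
  z finite without materially moving any attainable p-value;
* **variance floor**: noisy negative correlation estimates could push
  $n + 2\sum\rho$ towards 0 and explode the statistic, so the variance
  term is floored at $0.1\,n$.

Combined p-values receive Benjamini–Hochberg correction (`NA`s excluded
from the ranking), and sites with adjusted p strictly below the cutoff
are DM.

## DM regions

DM sites at most `maxGap` bp apart (on one chromosome) merge into one
region spanning the first to last member; a lone DM site is a one-CpG
region. Tested-but-non-significant sites interior to the span count
toward `nCpGs` but do not break the run — only distance does — so
`nSig/nCpGs` measures how dominated a region is by DM sites. Each region
is summarised by:

* `logOdds` — pooled per-group counts over all member sites, Laplace
  smoothed (+0.5 methylated, +1 total per group, keeping proportions of
  0 or 1 finite):
  $\log\left[\hat p_A(1-\hat p_B)\,/\,\hat p_B(1-\hat p_A)\right]$.
  Pooled counts (not fitted $\eta$s) were chosen so the summary is
  well-defined even at sites where the fit did not converge, and so the
  staged CLI can compute it from the site table alone; swapping group
  labels exactly negates it.
* `minMethDiff` — the minimum over member sites of the absolute
  difference of the two groups' pooled site levels. Pooled
  (coverage-weighted) levels are robust at low coverage, unlike means of
  per-sample ratios. This is a deliberately conservative region effect
  size: every member site moved at least this much.

Filtering keeps regions with `nCpGs >= minCpgs` (default 10) and
`minMethDiff` strictly above `minDiff`.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `windowBp` | 200 | bp | combination window (±100 bp); matches the distance over which CpG test statistics are appreciably correlated |
| `maxDist` | 200 | bp | span of the correlation profile; independently configurable from the window |
| `fdrCutoff` | 0.01 | — | DM-site call on BH-adjusted combined p (strictly below) |
| `maxGap` | 200 | bp | region merge distance; mirrors the neighbour-gap constraint of dense CpG regions |
| `minCpgs` | 10 | CpGs | region size filter for downstream interpretation |
| `minDiff` | 0 | level | minimum methylation difference filter (e.g. 0.55 isolates strong, consistent shifts) |
| `clipEps` | 1e-15 | — | p-value clipping before the z-transform |
| `minPairs` | 50 | pairs | stabilises sparse correlation bins |

## Fitting: numerical choices

Maximisation is over $(\eta, \mathrm{logit}\,\gamma)$, keeping $\gamma$
in $[10^{-6}, 1-10^{-6}]$ so the beta shapes stay finite (the pmf
itself handles $\gamma = 0$ exactly; the optimizer approaches, never
hits, the binomial boundary, and boundary estimates are reported as-is).
Starts are deterministic — $\eta$ from a few IRLS steps of the pooled
binomial logistic fit (fallback zeros, clamped to ±8), $\gamma$ from
0.05 — so fitting involves no randomness. The optimizer is BFGS with
central-difference gradients (relative tolerance $10^{-8}$, max 500
iterations) followed always by a Nelder–Mead polish ($10^{-12}$): the
derivative-free polish removes the finite-difference gradient noise from
the endpoint, which is what makes p-values invariant (to $\sim 10^{-10}$)
under sample reordering. If BFGS fails outright, Nelder–Mead runs from
the original start. The full model is additionally restarted from the
reduced optimum (dropped effects at zero), which guarantees
$\ell_{\text{full}} \ge \ell_{\text{reduced}}$ up to optimizer
tolerance. The convergence flag reports the optimizer's own status; the
per-sample log-pmf is evaluated by a telescoping sum of logs for integer
counts (exact and fast at WGBS coverages) with an `lbeta` fallback for
very deep sites.

## What the simulator emulates — and what it does not

`simulateDataset()` reproduces the structure of the benchmark used to
evaluate this class of methods: sites on one chromosome with inter-site
gaps uniform on [2, 200] bp; DM regions of 10–100 CpGs placed as
non-overlapping site runs (uniformly, with at least one non-DM site
between regions); per-site, per-sample methylation levels drawn from
Beta(2, 2) at non-DM sites (variance 1/20; variants: Beta(1.5, 1.5),
variance 1/16, and a zero-dispersion constant 0.7), and at DM sites from
Beta(6, 1.5) in cases (mean 0.8) vs Beta(1.5, 6) in controls (mean 0.2);
coverage i.i.d. Poisson($\lambda$) with zeros kept (a zero-coverage draw
means the site is unobserved in that sample); methylated reads binomial
given level and coverage. One master seed drives four independent
streams (layout, levels, coverage, counts), so layout can be held fixed
while counts vary.

Real WGBS data differ in ways the generator deliberately ignores:
coverage is overdispersed and spatially structured rather than Poisson
(the original benchmark reused empirical mouse-brain coverages, which
are external data; Poisson keeps the package self-contained, and an
empirical-coverage file hook — `coverageFile` — accepts any coverage
pool to resample); methylation levels are spatially autocorrelated
*within* samples, not i.i.d. per site; null sites vastly outnumber DM
sites genome-wide; and bisulfite conversion errors, mapping artefacts
and strand effects are absent. Passing the simulation benchmark
therefore demonstrates the statistical machinery under its own model
assumptions, not performance on any particular real dataset.

### Benchmark scale

The shipped presets are desk-scale: `paper-main` (6+6 samples, 20,000
sites, 100 DM regions, Poisson(10) coverage — the stand-in for an
empirical mean coverage around 10–12) and `low-coverage` (50+50 samples,
mean coverage 1.5, 20,000 sites, 200 DM regions). The 20,000/200
configuration is the smallest that satisfies the layout invariant
`nRegions * max(regionSize) <= nSites` at 200 regions of up to 100
CpGs. Note what the scaling does to the operating point: roughly half
the simulated sites are truly DM, so the BH threshold at FDR 0.01 is far
more permissive than in a genome-scale analysis where DM CpGs are a
fraction of a percent of all sites. On this configuration the acceptance
script measures a Jaccard index of ~0.98 between called and true DM
CpGs, with errors concentrated at region flanks (null neighbours boosted
by the window combination, plus a few missed edge sites); a genome-scale
background would tighten the BH threshold and lower the index. The
acceptance script averages three seeds; a full run takes a few minutes
on one CPU.

## Degenerate inputs and tie-breaks

* Empty counts tables, empty region sets and header-only files are
  legal everywhere and round-trip through the text formats.
* Duplicate site keys and meth > total are rejected at parse time with
  the offending line number.
* Sites are ordered by (chromosome, position, strand) with `+` before
  `-`; chromosomes sort naturally (chr2 before chr10).
* A singleton combination window returns the raw p-value bit-for-bit.
* Correlation bins with tied nearest populated neighbours take the
  closer distance (ties resolve to the smaller `d` via `which.min`).
* `filterRegions` drops regions whose summaries are `NA` (a group with
  zero coverage across the whole region).

## Known limitations

* Raw per-site p-values are anticonservative for very small designs
  (6 or fewer replicates per group); interpretation should rest on the
  combined, FDR-corrected values.
* Dispersion is per-site with no information sharing; for 2–3 replicates
  per group, shrinkage-based methods may be preferable.
* The LRT compares nested binary-factor models only; continuous
  covariates are out of scope.
* Region log-odds uses pooled counts, so it reflects coverage-weighted
  group means, not the covariate-adjusted $\eta$ of the regression; in
  multifactor designs with strong confounders the two can differ.
* The correlation profile is pooled genome-wide; chromosome- or
  compartment-specific autocorrelation is averaged over.
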