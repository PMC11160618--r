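---
title: "Modelling crossover number and crossover interference in experimental crosses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling crossover number and crossover interference in experimental crosses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xointer)
```

## The scientific problem

Crossovers on the same chromosome are spaced more evenly than random
placement would produce: one crossover inhibits the formation of another
nearby. `xointer` implements a complete analysis chain for measuring the
strength of this *crossover interference* — and how it varies with genotype
and paternal age — from SNP-array genotypes of N2 offspring of F1 hybrid
males (an F1 male crossed to an unrelated inbred dam, so that each offspring
chromosome reveals the crossovers of one paternal meiosis).

The chain is: synthetic-cohort simulation → marker QC and two-array
harmonization → haplotype/crossover inference by a hidden Markov model →
gamma and gamma-escape interference likelihoods with maximum-likelihood
fitting, bootstrap and model comparison → a hierarchical Bayesian model of
group-specific interference. Every stage is exposed as ordinary functions;
the `analysis/` scripts in the source repository run them in sequence on a
bundled synthetic cohort.

## The gamma model and its thinned likelihood

Chiasmata along the four-strand bundle are modelled as a stationary renewal
process whose inter-event distances are gamma distributed with shape $\nu$
and rate $2\nu$ per Morgan, so the mean chiasma spacing is 0.5 Morgan.
Each chiasma involves two of four chromatids and is therefore transmitted
to a given gamete independently with probability 1/2. The thinned process
seen in a gamete is again a renewal process with inter-crossover density

$$f^*(y) = \sum_{k \ge 1} 2^{-k}\, g(y;\, k\nu,\, 2\nu),$$

a geometric mixture of gamma densities with mean exactly 1 Morgan (which is
what makes genetic map length equal expected crossover count). $\nu = 1$
gives exponential spacing — no interference; larger $\nu$ gives more regular
spacing. $\nu$ is unitless; the literature value for the house mouse male
germline is around 11.3. Note that the gap distribution's standard deviation
is $50/\sqrt{\nu}$ cM — the distribution itself, not any printed shorthand
for it, is what the package simulates and fits.

A chromosome of genetic length $L$ Morgans with ordered crossovers
$x_1 < \dots < x_n$ contributes the stationary renewal likelihood

$$h(x_1)\; \prod_{i} f^*(x_{i+1} - x_i)\; S^*(L - x_n),
\qquad h(x) = S^*(x)/\mu^*,\ \mu^* = 1,$$

with $S^*$ the mixture survival function; a crossover-free chromosome
contributes $\int_L^\infty S^*(x)\,dx$, evaluated termwise through the
closed-form partial expectation of each gamma component. Crossover-free
chromosomes are *included* by default (`include_zero = TRUE`): they carry
real information about $\nu$ through the void probability, and dropping
them materially shifts $\hat\nu$. At $\nu = 1$ the whole log-likelihood
collapses to $-\sum_c L_c$, a useful analytic anchor that the tests check
to the accuracy of the series truncation.

Numerically, the mixture series is truncated when its remaining mass bound
falls below $10^{-12}$ of the accumulated value (at most 60 terms); once
every gamma survival term is within $10^{-12}$ of 1 the remaining geometric
tail is added in closed form. Accumulation is in linear space — all
quantities at chromosome scale are far from underflow — and the escape-model
enumeration below uses streaming log-sum-exp.

## The gamma-escape (Housworth–Stahl) model

A proportion $p$ of crossovers escape interference: an independent Poisson
pathway of intensity $p$ per Morgan is superposed on the gamma pathway,
whose chiasma rate is scaled to $2\nu(1-p)$ so that total crossover
intensity stays at 1 per Morgan. The likelihood of a chromosome sums over
all $2^n$ assignments of its observed crossovers to the two pathways
(capped at 12 crossovers per chromosome, far beyond anything a real map
produces). At $p = 0$ it reduces exactly to the gamma likelihood, so the
models are nested and comparable by likelihood-ratio test.

The two parameters are only weakly identified: allowing more escape
crossovers lets the remaining gamma pathway look more regular, so profiled
$\hat\nu$ rises with fixed $p$ on the rising limb below the joint optimum,
and bootstrap replicate pairs $(\hat\nu, \hat p)$ are positively correlated.
Both behaviours are verified in the test suite; treat $\hat p$ with caution.

## Simulating cohorts

`simulate_cohort()` generates ground-truth meioses and array-like genotypes:

* **Chiasmata**: `simulate_chiasmata()` draws a *stationary* renewal stream;
  the first interval is sampled exactly as $U \cdot G$ with $G$ a
  length-biased gap (gamma with shape $\nu + 1$), avoiding any burn-in
  approximation. Events are thinned by `thin_to_crossovers()`.
* **Defaults emulate a realistic cross**: 19 autosomes scaled from ~90 down
  to ~40 cM summing to exactly 1230 cM (12.3 expected crossovers per
  meiosis); six reciprocal genotypes between three inbred strains split by
  two paternal age cohorts and two array platforms, 503 offspring in all;
  $\nu = 11.3$, $p = 0$; genotyping error
  1% per call; missingness 0.2%; dense/sparse marker spacing 0.5/2 cM
  emulating the harmonized array panels, with 30% of sparse markers shared.
* **Coding**: calls are the transmitted paternal allele, 0 for the allele
  of the founder strain listed first in the cross (grandparent A) and 2 for
  the alternate; the dam contributes a constant allele so heterozygous
  codes never arise. Segregation distortion is therefore assessed on the
  transmitted-allele frequency, whose Mendelian expectation is 0.5.
* **Reproducibility**: one global seed; each offspring's randomness comes
  from a derived substream, so enlarging a group leaves earlier individuals
  byte-identical.

What the generator does *not* emulate: recombination hotspots and distal
clustering of crossovers, platform-specific intensity artifacts, relatedness
among sires, X-chromosome transmission, female meiosis. Passing tests on
synthetic cohorts therefore validate the estimators under the gamma /
gamma-escape mechanism, not the biology of any particular cross.

## Marker QC and harmonization

Within each paternal genotype × platform partition, markers are kept only if
(1) missingness is strictly below 10%, (2) the two paternal grandparent
strains carry opposite alleles, and (3) the transmitted non-reference allele
frequency lies strictly inside (20%, 80%). Rules apply in that fixed order
and each removed marker is attributed to the first rule it fails, so the
`filter_report` categories are disjoint and sum to the input count. For
genotypes typed on both arrays, the dense panel is pruned to the nearest
dense marker (by physical position; ties to the more proximal) of each
sparse marker, and both panels are trimmed to the common physical span
(per chromosome, the maximum of the two proximal extremes to the minimum of
the distal extremes). No distance cap is imposed on the nearest-marker
pairing.

## Haplotype and crossover inference

Expected genotype frequencies in N2 offspring are 0.5/0.5, so each
chromosome is decoded as a backcross with a two-state HMM: emissions match
the state's allele with probability $1-\varepsilon$ (default
$\varepsilon = 1\%$, a conventional allowance for array calls); missing
calls are uninformative; transitions use the Haldane map function
$r = (1 - e^{-2d/100})/2$ — the map function is a documented, swappable
convention. Viterbi ties
prefer staying in the current state and the initial tie prefers state A, so
output is deterministic. A crossover is placed at the midpoint of the marker
interval flanking each state switch (the within-interval convention is not
observable; `left`/`right` alternatives are exposed), coordinates are shifted
so the first retained marker is 0, and $L$ is the retained-marker span —
the same censoring window the likelihood uses. Chromosomes with fewer than
two informative calls are flagged and excluded.

Two consequences worth knowing:

* A crossover in a *terminal* marker interval leaves a single discordant
  call, and at $\varepsilon = 1\%$ / 1 cM spacing the error explanation is
  marginally more likely than the switch, so such crossovers are absorbed
  (~1% of crossovers at that spacing). This is correct decoding, not a bug.
* Three consecutive miscalls (probability $\varepsilon^3$ per marker
  triple, ~0.5 expected occurrences in a 200-offspring cohort at 0.5 cM
  spacing) beat the error explanation and fabricate a tight double
  crossover. A single such doublet is essentially impossible under strong
  interference, so it can dominate the escape-model likelihood (shifting
  $\hat p$ off zero with a large likelihood gain) and drag the per-group
  gamma $\hat\nu$ down noticeably. The bundled demonstration cohort
  contains exactly one, kept deliberately as an illustration; bootstrap
  intervals (resampling individuals) convey the resulting instability.

## Fitting, bootstrap, and model comparison

`fit_gamma()` maximizes the likelihood over $\log\nu$ on the bracket
$[0.1, 100]$ (tolerance $10^{-6}$; estimates on the bracket boundary are
flagged). `fit_gamma_escape()` runs Nelder–Mead on
$(\log\nu,\ \mathrm{logit}\,p)$ from the five best points of a coarse
4 × 4 grid; bootstrap refits restart from the full-data optimum.
`bootstrap_ci()` resamples *individuals* (all their chromosomes together)
with replacement and reports percentile 95% and 50% intervals (percentile
rather than BCa throughout); replicates whose resample contains no
crossovers are counted and excluded. Model comparison uses
$\mathrm{AIC} = 2\,\mathrm{df} - 2\,\mathrm{LL}$ and likelihood-ratio tests
restricted to nested pairs (a pooled "null" fit is nested in per-group
"full" fits; gamma is nested in gamma-escape).

At desk scale the percentile intervals run slightly below nominal:
simulation at $\nu = 6$ with 80 individuals × 9 chromosomes per replicate
measures ~90% coverage for the 95% interval, because $\hat\nu$ is
upward-biased and right-skewed in small samples. The acceptance suite checks
coverage against a band of ±3 binomial standard errors.

## The hierarchical Bayesian model

For group $i$ (paternal genotype × age cohort),

$$\log \nu_i = \beta_0 + \beta_{g(i)} + \alpha\,[\text{old}],$$

with priors $\beta_0 \sim N(\mu, \sigma^2)$,
$\beta_g \sim N(0, \sigma^2)$, and $\alpha \sim N(0, \sigma^2)$ for old
males ($\alpha$ contributes nothing for young males). Defaults are
$\mu = 1$, $\sigma^2 = 0.5$ — deliberately weak, though note they put the
prior median of $\nu$ near $e \approx 2.7$, well below the fitted 8–15 —
and $\sigma^2$ is shared by $\alpha$. No sum-to-zero constraint is
placed on the $\beta_g$; the prior alone resolves the $\beta_0/\beta_g$
redundancy, which is why those coordinates mix more slowly than their sum
(watch the per-parameter R-hat).

Sampling is by component-wise random-walk Metropolis with $N(0, \tau^2)$
proposals, $\tau^2 = 0.005$; chains are plain independent replicate
Metropolis chains — no tempering (no Metropolis coupling) is implemented.
Group
log-likelihoods are cached so a genotype-effect proposal re-evaluates only
that genotype's groups; `run_mcmc(..., debug = TRUE)` revalidates the cache
against full recomputation every 1000 iterations. Full-scale settings are
25000 iterations, 5000 burn-in, 4 chains; the bundled demonstration uses
6000 × 2 and the tests use shorter runs still, sized so that Monte-Carlo
error is a few percent of posterior spread. Convergence is summarized by
the classic (non-split) Gelman–Rubin factor; every reported $\nu$ summary
(posterior mean, 95%/50% HPDI, genotype ratios, the young/old ratio
$e^{-\alpha}$) is computed on draws, never by transforming interval
endpoints. Escape proportion is not estimated in the Bayesian stage — the
$(\nu, p)$ ridge makes a random-walk sampler pathological there.

## Crossover-count summaries

`poisson_glm_deviance()` fits crossover counts with a Poisson log-link GLM
and reports the sequential (Type-I) analysis of deviance in the order
genotype, age, genotype × age, with chi-square p-values via `chisq_sf()`
(a thin wrapper over the log-space incomplete-gamma tail, accurate deep
into the far tail). `distance_summaries()` tabulates inter-crossover
distances on chromosomes with two or more crossovers; because a gap of
size $y$ can only be seen with rate proportional to $(L - y)f^*(y)$, the
observed mean lies *below* the unconditional 50 cM (about 43 cM on the
default map — the tests check the exact censored-renewal value by
quadrature). Map length is estimated as $100 \times$ mean crossover count
(expected crossovers per gamete equal map length in Morgans), with an
individual-level percentile bootstrap.

## A worked run

```{r demo, eval = FALSE}
cfg <- demo_config(seed = 1)
report <- run_pipeline(cfg, n_boot = 200)
report$identity      # segments - chromosomes = crossovers
report$comparison    # AIC / LRT table
report$posterior     # group-wise nu with HPDIs
posterior_contrasts(report$posterior)
```

With 50 offspring per genotype × age cell, group-level $\hat\nu$ carries
sampling noise of roughly ±25%, so demonstration-scale contrasts are
dominated by noise; the recovery properties of the estimators are
established in the test suite at larger simulated sizes (e.g. 1000 meioses
for the 10%-accuracy maximum-likelihood check, 70 individuals per group for
the 20%-accuracy hierarchical check).

## Known limitations

* The standard male genetic map is taken as true for all genotypes; a
  genotype whose true map is longer than assumed will look like weaker
  interference.
* Genotyping-error doublets can fabricate tight double crossovers (see
  above); with real arrays, error rates and clustering may differ from the
  1% independent-flip model.
* $(\nu, p)$ are weakly identified; escape estimates should be read
  together with the bootstrap cloud.
* Per-chromosome interference, female meiosis, X-linked transmission and
  diallel variance decomposition are out of scope.
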