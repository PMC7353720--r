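---
title: "Detecting fitness epistasis from local-ancestry correlations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting fitness epistasis from local-ancestry correlations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In a recently admixed population such as African Americans, each chromosome is
a mosaic of long ancestry tracts inherited from the two source populations.
Two loci whose joint ancestry configuration affects reproductive fitness
(fitness epistasis) leave a detectable signature: their local ancestries stay
correlated in the present-day population beyond what mixing history alone
explains. Between chromosomes this excess correlation can be tested directly.
On the *same* chromosome, however, admixture linkage disequilibrium (admixture
LD) dominates: a single admixture event `t` generations ago creates ancestry
correlation that decays with genetic distance `d` approximately as

    D = D0 (1 - d)^t  ~  D0 exp(-t d),     d in Morgans,

and this confound must be removed before any epistasis test. `admixepi`
implements that removal and the downstream testing machinery, working on
binned diploid local-ancestry dosages (0, 1 or 2 African alleles per bin,
typically 400-kb bins represented by their middle marker).

## The scan model

For bins `i`, `j` on one chromosome, let `beta_ij = cor(X_i, X_j)` be the
Pearson correlation of dosages over individuals. Per locus `i`, the expected
admixture-LD curve is fitted to all `beta_ij`, `j != i`, as

    f(d) = a0 + a1 exp(-a2 d),

where `a0` captures background LD between effectively unlinked loci, and
`a1, a2 >= 0` keep the curve a decaying exponential (`a0` is unconstrained
because background correlation can be slightly negative by sampling). The
directional residual is `beta_ij - f_i(d_ij)`; because the fit at locus `i`
and at locus `j` use different pair sets, the two directions differ slightly
and their average is the final departure. The test statistic is

    Z_ij = beta_res_ij / sigma_hat,   P_ij = 2 (1 - Phi(|Z_ij|)),

where `sigma_hat` is the standard deviation of ancestry correlations between
bins on *different* chromosomes — pairs at effectively infinite genetic
distance, which sample the null spread of the correlation estimate (dominated
by `1/sqrt(n - 1)` sampling noise at large `n`).

Multiplicity is handled with an effective number of independent tests:
per chromosome, the Li–Ji eigenvalue count
`k = floor(sum(I(lambda >= 1) + (lambda - floor(lambda))))` over the
eigenvalues of the bin-correlation matrix, with `sum_i k_i (k_i - 1) / 2`
total tests and a Bonferroni-corrected level. Pairs closer than 50 cM are
flagged out of the declaration set (they remain in every fit and in the
output for audit): at short range the decay fit removes admixture LD only
imperfectly, and the 50-cM bound restricts declarations to the regime where
the null model is reliable. Significant pairs are merged into region pairs as
connected components under a one-bin adjacency tolerance; components whose
regions approach annotated telomeres/centromeres are flagged, since
local-ancestry inference is error-prone there (such bins are normally already
excluded with a 2-Mb radius, and samples with genome-wide African proportion
at or below 5% or at or above 98% are removed — there is no ancestry contrast
to correlate in near-unadmixed genomes).

Cohorts are combined with the METAL-style weighted Z,
`z_meta = sum(sqrt(n_k) z_k) / sqrt(sum n_k)`. Heterogeneity uses Cochran's Q
on the residual-correlation scale with variances `sigma_hat_k^2` — Z-scores
have unit variance by construction, which would hide cross-cohort effect
heterogeneity, so Q is computed on effects, the standard fixed-effect
formulation. Diagnostics are the genomic-control factor
`lambda = median(z^2) / qchisq(0.5, 1)` (values at or below 1 indicate the
scan is conservative), the adjusted Fisher–Pearson skewness of the residual
distribution (positive skew is the qualitative epistasis signature), and
pairwise cohort Z correlations (positive under shared signal).

Two corroborating tests are included. The ancestry-crossover deficit test
(ANCAEC) counts, per individual, adjacent-bin dosage changes
`|dosage_{b+1} - dosage_b|` between a candidate region pair — a 0→2 change
counts two events, the minimal count consistent with unphased dosages — and
compares the per-cM rate against non-overlapping reference windows of the
same genetic length tiled over the rest of the genome, one-sided for a
deficit (epistasis disfavours recombinants between the loci). The positional
enrichment test tiles the chromosome minus a target region into windows of
the target's length and refers the observed hit count to the window-count
distribution; the denominator is the *SD of window counts*, not the standard
error of their mean, because one region is compared against the window
distribution rather than against its mean's uncertainty.

## The simulator

`simulate_population()` provides ground truth under the hybrid-isolation
model: one admixture pulse `t` generations ago (founder haplotypes entirely
African with probability `m`), then random mating at constant size `n` with
no further gene flow. Each meiosis places `Poisson(L)` crossovers uniformly
on the genetic map (Haldane's model, no interference), matching the
exponential-decay approximation the scan fits. Haplotypes are ancestry tract
lists; dosages are read at bin midpoints ("middle marker" convention) with a
linear cM–bp map per chromosome.

Epistatic selection had to be given a concrete generative form (the scan only
detects its signature, so any defensible choice is admissible): fitness acts
on offspring viability as `w = 1 + s * I(dosage_i = dosage_j)` on the
offspring's diploid dosages at the two chosen loci, implemented by rejection
sampling with acceptance probability `w / (1 + s)`. Matching-dosage selection
directly rewards concordant ancestry at the two loci, produces positive
excess correlation, and needs a single parameter. All randomness flows
through one seeded generator in a documented fixed order, so a run is
bit-reproducible from its config.

Two quantitative consequences of this design are worth stating because they
calibrate expectations for the tests:

* The simulator's true per-generation decay factor is `1 - r` with the
  Haldane recombination fraction `r = (1 - exp(-2d))/2`, so its correlation
  decay is `(1 - r)^t`. The fitted model `(1 - d)^t ~ exp(-t d)` treats
  distance as a recombination fraction and is exact only to first order in
  `d`; at 10 cM and `t = 8` the two differ by about 0.037. Tests therefore
  compare simulated decay against the exact Haldane form across the full
  range and against the approximation only at short range. One consequence:
  least-squares decay fits on a 200-cM chromosome recover `a2` about 9%
  *below* `t/100` per cM even on noise-free Haldane-decay data, which is why
  recovery of the admixture age is asserted at 15% rather than at
  Monte-Carlo precision.
* Visible ancestry junctions accumulate at about `2 m (1 - m) t` per Morgan
  (Poisson crossovers at rate `t` thinned by the probability that the joined
  segments differ in ancestry), not at `t` per Morgan; drift of the admixture
  proportion toward 0.5 raises the rate slightly above this
  infinite-population value.

## Numerical choices

* **Decay fit.** For fixed `a2` the model is linear in `(a0, a1)`, so the
  fit profiles them out in closed form (clamping `a1` at 0 when the
  unconstrained slope is negative) and minimises the one-dimensional profiled
  SSE over `a2` on a 61-point log-spaced grid (0 to 3 per cM) followed by
  Brent refinement in the bracketing interval (tolerance 1e-10). This is
  deterministic, insensitive to starting values, and has no iterative
  convergence failures; a grid-search oracle and an independent
  Levenberg–Marquardt solver confirm its optima in the tests. Loci with
  insufficient data (< 10 pairs or < 3 distinct distances) error out; pairs
  with an unusable endpoint fit are masked with a count rather than dropped
  silently.
* **Null scale.** When the number of cross-chromosome pairs exceeds
  `max_pairs` (default 2,000,000), a seeded uniform subsample is taken and
  the seed recorded. Zero-variance bins are excluded and reported; an
  all-equal cross-chromosome correlation set raises an error rather than
  returning `sigma_hat = 0`.
* **Effective tests.** Eigenvalues are rounded to 10 decimals before the
  Li–Ji sum and the final `k` is floored, so an identity-like matrix cannot
  lose a unit to floating-point jitter.
* **Determinism.** Scan outputs contain no timestamps; rerunning a config
  with the same seed is byte-identical.

## Simulation-study conditions used by the test suite

Calibration and power studies run at the admixture history relevant to
African Americans: `t = 8` generations, `m = 0.8` African proportion,
`n = 2000` diploid individuals, one 2-Morgan chromosome mapped linearly to
200 Mb and binned at 400 kb (500 bins). Because the cross-chromosome null
scale needs a second chromosome, null studies estimate `sigma_hat` from bin
pairs taken across two *independent replicates* — columns that are
independent over the same sample index, hence distributed exactly like
cross-chromosome pairs under the null — assembled through the package's own
`estimate_null_scale()`. Calibration (uncorrected rejection rate, genomic
control) is evaluated on the declaration set (pairs at or beyond 50 cM).
Power studies inject selection at 60 and 120 cM — a 60-cM separation, just
beyond the declaration bound — over `s` in {0, 0.05, 0.1, 0.2}, with `s = 1`
as the strong-selection setting for end-to-end region-recovery runs;
crossover-deficit calibration uses 200 replicates of `n = 250` over two
2-Morgan chromosomes with a 15-cM target interval. These sizes are the
package's chosen balance between Monte-Carlo resolution and a test suite
that runs in minutes.

## What the simulator does and does not emulate

The generator reproduces the features the scan actually consumes: long
ancestry tracts with the correct decay of ancestry correlation, drift in a
finite random-mating population, diploid dosages at bin midpoints, and a
tunable two-locus selection signal. It does **not** emulate continuous gene
flow (decay is then no longer a single exponential), three-way admixture,
assortative mating, local-ancestry inference error (real dosages are
probabilistic calls from models such as SABER+ and carry error concentrated
near telomeres/centromeres — the motivation for the 2-Mb exclusion), variable
recombination maps (the cM–bp map is linear per chromosome), or relatedness
between samples. Passing tests therefore demonstrate correctness and
calibration of the statistical machinery under the stated model, not
robustness to inference error or demographic misspecification in real
cohorts.

## Known limitations

* The method applies to recently admixed two-way populations; older or
  continuous admixture violates the single-exponential decay form.
* The 50-cM declaration bound means intra-chromosomal epistasis at shorter
  range is deliberately not declared, and the distance filter interacts with
  chromosome length: chromosomes shorter than 50 cM contribute no
  declarations.
* `sigma_hat` treats cross-chromosome correlations as pure null; pervasive
  cross-chromosome epistasis would inflate it and make the scan
  conservative.
* The viability-selection model in the simulator is one of several
  defensible generative forms of fitness epistasis (e.g. haplotype-level or
  multiplicative schemes); power numbers depend on that choice even though
  the detector does not.
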