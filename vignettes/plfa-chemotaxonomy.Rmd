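---
title: "PLFA chemotaxonomy: model, parameters and numerical choices"
author: "plfatax"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PLFA chemotaxonomy: model, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plfatax)
```

## The problem

Phospholipid-derived fatty acids (PLFA) are membrane lipids that degrade
within days of cell death, so the PLFA pool of pond seston is a snapshot of
the *living* microbial biomass. Because taxa differ in their fatty-acid
ratios — branched iso/anteiso acids in Gram-positive bacteria, cyclopropyl
and hydroxy acids in Gram-negatives, 18:1ω9c in fungi, C16/C18 PUFA in
algae, long-chain ω3 PUFA in diatoms — a sample's PLFA composition carries
quantitative information about how much of the community is bacterial,
fungal or algal. This package estimates those group abundances and follows
the group-specific fatty acids into the lipid fractions of the zooplankton
that eat the seston.

## The unmixing model

Let `R` be a taxa × FA ratio matrix with every row referenced to 16:0 = 1,
and `F(R)` its row-normalization (each taxon signature as proportions of its
total FA). A sample composition `s` (proportions of total measured FA) is
modelled as

$$ s \approx a^\top F(R), \qquad a \ge 0, \quad \textstyle\sum_k a_k = 1 . $$

Fitting proceeds by alternating optimization:

1. **Abundance step.** For each sample, `a` is the simplex-constrained
   non-negative least-squares solution. The sum-to-one constraint is folded
   into the NNLS system as a heavily weighted extra row (weight $10^4$, four
   orders above the data scale), then the solution is renormalized exactly.
   The augmented objective is convex, so the solver (a compiled
   Lawson–Hanson active-set kernel) returns the global optimum; the test
   suite checks it against an exhaustive simplex grid search at resolution
   $10^{-4}$.
2. **Ratio step.** The nonzero, non-reference elements of `R` take a
   projected steepest-descent step. The gradient is a finite-difference
   approximation with abundances held fixed (by the envelope argument this
   equals the gradient of the reduced objective at the current optimum
   abundances). A halving backtracking line search (at most 20 halvings)
   guarantees the RMSE never increases; once an improving step is found the
   step is doubled while the objective keeps dropping, which speeds crossing
   of the long flat valleys this objective has.

The objective is the unweighted RMSE between observed and reconstructed
compositions, both renormalized; a per-FA weight hook (`fa_weights`) is
exposed because abundance-weighted residuals are an equally defensible
choice and published implementations do not document theirs.

### The adjustment bound

Ratio matrices compiled from cultures or literature are only approximately
right for a local community, so each nonzero element may move within
**±50 % of its input value**, i.e. the band $[0.5\,r_0,\ 1.5\,r_0]$. Note
this is the symmetric-percentage reading, not the symmetric-multiplicative
one ($[r_0/1.5,\ 1.5\,r_0]$): published output matrices of this method
contain halvings of input elements (a factor 0.5 exactly), which only the
former allows. `bound_factor` generalizes the band to
$[(2-b)\,r_0,\ b\,r_0]$ with $1 \le b \le 2$; at `bound_factor = 1` the
matrix is frozen and the fit reduces to plain per-sample solving.

Two conventions are enforced throughout: **structural zeros stay zero** (an
FA a taxon does not make cannot be optimized into its signature), and the
**16:0 reference stays exactly 1**, preserving the "referred to 16:0"
semantics of the matrix.

### Stabilization protocols

Because the fit is sensitive to the input matrix, two standard protocols
wrap it. `successive_runs()` chains fits, each starting from the previous
optimized matrix (bounds taken relative to each run's own input) and returns
the best run. `randomized_starts()` perturbs every free element by a seeded
uniform factor inside the band, fits each start, averages the ratio matrices
of the best `best_fraction` of starts and refits once. Defaults are 8 runs
and 60 starts with `best_fraction = 0.1`. On the synthetic data used in the
tests the two protocols agree to well under 0.05 mean absolute abundance
difference.

### Convergence and non-convergence

Iteration stops when the relative RMSE improvement falls below `tol`
(default $10^{-8}$) or after `max_iter` (default 500) iterations; an RMSE
below $10^{-10}$ counts as a numerically exact fit. Non-convergence is
reported through the `converged` flag, never as an error — on noisy data the
descent typically keeps creeping at relative improvements just above the
tolerance, and the returned matrix is simply the best bounded matrix found.

### What can and cannot be recovered

Mixture factorizations have rotational ambiguity: different
(abundances, ratio-matrix) pairs inside the bounds can reconstruct the same
samples almost equally well. In closed-loop experiments the *abundances* are
recovered accurately (mean absolute error ≈ 0.03 at 10 % compositional
noise, 20 samples, 9 taxa), while individual perturbed ratio *elements* are
only partially recovered (more than half of an injected shift, in the right
direction). Interpreting optimized ratio elements as measurements of a
taxon's physiology is therefore not supported; they are nuisance parameters
that absorb local signature variation.

## Marker sums and retention ratios

The marker scheme maps each fatty acid to at most one group by an ordered
first-match rule list (fungi: 16:1ω5; bacteria: 15:0, all iso/anteiso FAs,
hydroxy FAs, cyclopropyl FAs, 18:1ω8; autotrophs: C16 and C18 PUFA). The
enumeration is deliberately exhaustive — straight-chain odd FAs other than
15:0 and PUFA outside C16/C18 are *not* markers. Explicit-name rules ignore
double-bond geometry (16:1ω5c satisfies the 16:1ω5 rule) since GC reports
are inconsistent about printing it. Group proportions are reported either
renormalized over the three groups (the default, scale-invariant) or as raw
summed weight percent, because both conventions appear in the literature.

Retention of essential fatty acids is the consumer:seston ratio of the
summed share of a fatty-acid set, by default EPA (20:5ω3) + DHA (22:6ω3).
A zero seston share is an explicit error, not an infinite ratio.

## The synthetic-data generator

No field data are deposited with the study this package operationalizes, so
every input is generated:

* **Seston samples** are exact mixtures `A F(R_true)` perturbed by
  multiplicative lognormal noise per FA and renormalized (default
  cv = 0.10), or by Dirichlet resampling. Noise factors have **mean one**
  (meanlog $=-\sigma^2/2$), so generated quantities are unbiased around
  their generating values. True abundances are flat-Dirichlet by default;
  presets pin the regimes observed in temporary ponds (heterotrophs at 0.90,
  green algae at 0.80, cyanobacteria at 0.50 of biomass) exactly, splitting
  the remainder within groups by a Dirichlet draw.
* **Isolate libraries** apply mean-one lognormal variation (default
  cv = 0.2, typical of repeated cultures) to each taxon's *ratios*, leaving
  the 16:0 reference untouched, so the per-taxon mean of normalized isolates
  is an unbiased estimate of the generating matrix.
* **Consumers** get FA shares proportional to seston share × retention
  factor, renormalized, plus an optional de-novo saturate fraction (added as
  16:0/18:0 in ratio 2:1), with PUFA retention in the phospholipid fraction
  boosted relative to reserve lipids (membranes conserve PUFA hardest).
  Because of the renormalization, a retention factor $f$ on a fatty acid
  with seston share $p$ yields a measured retention ratio $f/Z$ with
  $Z = 1 + (f-1)p$ — for the few-percent EPA shares of realistic seston this
  is within a few percent of $f$.

What the generator does **not** emulate: chromatographic co-elution and
peak-integration error, taxon signatures drifting with growth phase or
temperature (the noise is i.i.d. across samples), heterotrophic protists,
and any ecological dynamics. Passing closed-loop tests therefore shows the
estimators are correct under the stated statistical model, not that the
model captures every property of field data.

## Variable screening for ordination

`pca_screen()` applies, in order: (1) removal of fatty acids with fewer
than 14 carbons, which consumers synthesise de novo so they carry no dietary
signal; (2) iterative worst-first removal of variables with
Kaiser–Meyer–Olkin sampling adequacy ≤ 0.50 (KMO is computed from the
inverse-correlation-matrix partial correlations; a Moore–Penrose inverse
handles singular cases); (3) iterative removal of variables with communality
≤ 0.50 on the components retained by the Kaiser rule (eigenvalue > 1).
Variables are SD-scaled throughout (correlation-matrix PCA). Removal is
one-at-a-time and recomputed after every drop because both statistics change
when a variable leaves; simultaneous removal is a coarser alternative and
the thresholds are exposed as arguments. KMO screening runs before the
communality screen since adequacy is a property of the correlation structure
while communality depends on the retained-component solution. PCA signs are
fixed by making each component's largest-magnitude loading positive.

## Problem sizes and determinism

The shipped analyses and tests run at the study's own scale: 9 taxa ×
19 fatty acids, 20 samples per scenario, 10 seeds for replicated checks,
and the protocol comparison at 4 successive runs / 20 randomized starts.
Every stochastic routine takes an explicit seed and restores the caller's
RNG state, so pipelines rerun byte-identically; `run_pipeline()` records the
seed, config snapshot and input digests in a JSON manifest.

## Known limitations

* Group signatures of the three fungal phyla are similar, so their
  abundances trade off against each other more than bacterial vs algal ones.
* The ±50 % band is a convention, not an estimate of signature variability;
  communities whose local signatures deviate more will fit with biased
  abundances.
* Marker-based group proportions and unmixing-based abundances answer
  subtly different questions (share of marker mass vs share of biomass) and
  should not be compared numerically without the ratio matrix in hand.
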