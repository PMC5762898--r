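---
title: "Designing and analysing evenness-stratified synthetic communities"
author: "evenpanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and analysing evenness-stratified synthetic communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evenpanel)
```

## The scientific question

Synthetic microbial ecosystems let ecologists fix what nature confounds:
here, species **richness** is pinned at ten strains while initial
**evenness** — how equitably abundance is spread across those strains —
varies from strongly dominated to nearly uniform. The package implements
the complete computational chain for such an experiment: panel design,
serial-transfer dynamics, the two measurement modalities (single-cell flow
cytometry and amplicon-style sequencing counts), and the comparative
statistics that ask whether initial evenness shapes the temporal
trajectory of community structure and cell density.

Evenness is quantified by Pielou's index
$J = H'/\ln S$, with $H' = -\sum_i p_i \ln p_i$ the Shannon entropy of the
relative abundances $p_i$ and $S$ the richness; $J$ is 1 for a perfectly
even community and approaches 0 under extreme dominance. Communities are
stratified into Low ($J \in [0, 0.3]$), Medium ($J \in (0.4, 0.6]$) and
High ($J \in (0.6, 1]$) classes. The gap $(0.3, 0.4]$ is deliberately
unassigned — candidates falling there are generated but never sampled —
and the boundary $J = 0.6$ goes to Medium under the half-open reading.
These conventions are one defensible resolution of bin edges that are
often printed ambiguously in experimental protocols; both the edges and
the half-open convention sit in `evenness_bins()` and `classify_evenness()`.

## Panel design

The candidate pool is drawn from a **symmetric Dirichlet whose
concentration parameter is itself log-uniform on $[10^{-2}, 10^2]$** per
community. This one-knob family sweeps continuously from near-degenerate
($J \approx 0$) to near-uniform ($J \approx 1$) compositions, so all
three strata are well populated — at $10^4$ candidates the evenness range
already spans $[0.1, 0.99]$ and a $10^6$-candidate pool takes seconds.
Fractions below $10^{-6}$ are clipped up and the vector renormalized so
designed richness is exactly ten in every community; without the clip,
tiny Dirichlet draws underflow and would silently lower richness.

The default panel samples 40 Low, 20 Medium and 40 High communities
uniformly without replacement within class (100 total), and the plate
layout places the two biological replicates of each community in
column-adjacent wells of 96-well plates. Uniform within-class sampling is
the neutral choice where no selection scheme is prescribed; a
space-filling design over $J$ would be a reasonable alternative but is
out of scope.

## Serial-transfer dynamics

Growth between transfers follows generalized Lotka–Volterra competition

$$\frac{dN_i}{dt} = r_i N_i \Bigl(1 - \frac{\sum_j a_{ij} N_j}{K}\Bigr),$$

integrated per 48 h cycle with a fixed-step RK4 scheme (step 0.1 h); at
each transfer 5% of the community seeds fresh medium, five times, for
240 h total. Defaults are $r_i \sim U(0.2, 0.8)\ \mathrm{h}^{-1}$ drawn
once per run, $K = 10^9$ cells/mL, and $a_{ij} = 1$ (pure shared-resource
competition). With these rates every strain reaches stationary phase well
inside a cycle, so a stiff solver is unnecessary; the RK4 trajectory is
cross-checked against an adaptive LSODA oracle in the tests. Optional
transfer noise multiplies post-dilution densities by
$1 + \mathcal{N}(0, \mathrm{CV})$ with CV 0.05, emulating pipetting
variability — large enough to scatter replicates, small enough not to
drive stochastic extinction on its own.

Under pure competition with heterogeneous $r_i$, faster growers compound
their advantage across cycles, so initially even communities lose
evenness — the mechanism the analysis layer is designed to detect. The
neutral limit (identical parameters, zero noise) preserves composition to
$10^{-6}$, a symmetry test of the integrator.

## Synthetic measurements

**Flow cytometry.** Each sample yields a Poisson number of cell events
with expectation `density × volume / dilution`; each event carries
log-normal intensities in four channels (FL1-H, FL3-H, FSC-H, SSC-H)
around its species' fixed log10 signature (sd 0.12), plus a debris
cluster centred an order of magnitude below the dimmest cell cluster in
FL1, at 5% of events by default. Separated signatures make gating
meaningful and let fingerprint diversity track true community structure;
real instruments show more overlap, so the recovery correlation measured
here is an upper bound on what field data would give.

**Amplicon counts.** Reads are multinomial in the bias-distorted mixture
$q_i \propto p_i b_i$, where $b_i$ are multiplicative detection factors
(extraction/PCR bias; default 1). Sequencing depth is log-normal around
$10^4$ reads (sdlog 0.5), chosen so that a small fraction of the 200
samples falls below the rarefaction depth and the dropping path is
exercised; what the generator does **not** emulate — chimeras, spurious
phylotypes, overdispersion beyond multinomial — means passing tests
bound correctness of the pipeline, not realism of sequencing error.

## Fingerprinting

Raw intensities are mapped to $[0,1]$ by $x \mapsto
\mathrm{asinh}(x/c)$, min–max scaled by the fixed instrument range
(cofactor 1, range $10^{4.5}$); the polygon gate on transformed
FL1-H × FL3-H (vertices in config, default a half-plane at FL1 > 0.42)
removes debris by the boundary-inclusive even–odd rule, and samples with
fewer than 1000 gated cells are excluded. Fingerprints subsample 5000
events without replacement — after lexicographic canonicalization, so row
order can never change a result — and evaluate an **exact** Gaussian
product-kernel density (bandwidth 0.01) on 128 × 128 grids over all six
channel pairs, concatenated and normalized to unit mass. The exact sum is
computed as a rank-1 kernel-matrix product, $O(n \cdot \mathrm{nbin})$
memory and fast at these sizes, and keeps the estimator simple enough to
oracle-test; FFT approximations were deliberately avoided.

Diversity of a fingerprint (or of a count vector) uses Hill numbers
$D_q = (\sum_i p_i^q)^{1/(1-q)}$, with $D_1 = \exp(H')$ and $D_0$
counting entries above $10^{-10}$ of total mass — a Gaussian KDE is
nowhere exactly zero, so a threshold is needed to preserve the
"occupied bins" meaning of $D_0$. Bootstrap CIs repeat the
subsample-fingerprint-Hill chain with derived seeds; a single resample
reproduces the plain computation exactly, which pins the degenerate case.

## Taxonomic diversity

Phylotypes are kept when they exceed 0.1% relative abundance in at least
one sample or 0.001% in every sample — both thresholds read literally as
percentages (0.001 and 0.00001 as fractions) and both exposed as
arguments, since the stricter reading of "0.001" as a fraction is also
seen in practice. Counts are rarefied without replacement to 3317 reads;
samples below depth are dropped rather than retained unrarefied, matching
the "maximum depth" convention. Shannon, Simpson and inverse Simpson come
from vegan; Pielou's $J$ is `NA` for $S = 1$ (division by $\ln 1$), and
Fisher's $\alpha$ solves $S = \alpha \ln(1 + N/\alpha)$ by safeguarded
Newton with bisection fallback on $[10^{-6}, 10^6]$ to residual
$10^{-8}$ ($S = 1$ and $S \ge N$ reported missing). Expected rarefaction
curves use the analytic hypergeometric form, verified against Monte-Carlo
resampling.

## Statistics layer

All permutation engines share three conventions: the add-one estimator
$p = (1 + \#\{T^* \ge T\})/(1 + n_\mathrm{perm})$, two-sided where the
statistic is signed, and full seed determinism with the realized
permutation count reported.

- **PERMANOVA** partitions distance-based sums of squares
  (equivalently the Gower-centred trace) and permutes whole labels; at
  small $N$ it switches to exhaustive enumeration of all $N!$
  relabelings, which is also how the tests validate it. When every group
  is a singleton the within-group SS is zero and the pseudo-F is
  reported as infinite, making the two-sample case exactly enumerable.
- **PCoA** wraps classical metric scaling, drops negative eigenvalues
  and records their relative mass.
- **Dispersion** uses distances to group centroids (vegan's
  `betadisper`) with pairwise permutation contrasts and Holm correction —
  a small-sample-exact replacement for a studentized-range test.
- **MFA** standardizes each continuous block and divides by its first
  singular value, so every block's first singular value is exactly 1
  after weighting; the categorical block is indicator-coded with
  correspondence scaling. Category–axis association uses the v-test
  $v = \bar{x}_k \bigl/ \sqrt{\tfrac{N - n_k}{N - 1} \cdot
  \tfrac{s^2_\mathrm{dim}}{n_k}}$ on centred scores. When the v-test is
  to be *calibrated* (its p-values uniform under a random category), the
  category must enter as a **supplementary** variable
  (`categorical_active = FALSE`): an active indicator block pulls the
  axes toward the category structure and inflates $|v|$ even under the
  null. The active setting remains the default for descriptive use.
- **Trend testing** replaces repeated-measures mixed modelling with a
  permutation test on per-community least-squares slopes of diversity
  against transfer index, permuting transfer labels within community.
  This targets the same claim (monotone decline within a group) without
  REML machinery, and its null calibration is testable by construction.
  Note that with few time points the extreme ordering can be redrawn by
  chance, so the smallest achievable p-value exceeds
  $1/(1 + n_\mathrm{perm})$; the tests therefore validate against
  exhaustive enumeration rather than a nominal floor.

## Problem sizes and reproducibility

The test-suite and acceptance runs use the full 100-community panel with
a $2 \times 10^4$-candidate pool, one technical replicate, 1000-cell
fingerprints on 32-bin grids, and 199–999 permutations; the design stage
itself is always exercised at the full $10^6$ pool. These sizes keep a
complete end-to-end run in minutes on one core while preserving every
workflow constant (100 communities, 40/20/40 strata, five 48 h
transfers, 200 amplicon samples, depth 3317). The analysis scripts under
`analysis/` run the fingerprint stage at the full 128-bin, 5000-cell
settings. Every stochastic call receives a sub-seed derived from the
master seed and a stable stage/sample label (`derive_seed()`), so
re-running one stage never shifts another's draws and identical seeds
give byte-identical outputs.

## Known limitations

- The gLV competition model has no cross-feeding, spatial structure or
  lag phases; it generates the *direction* of evenness erosion, not
  quantitative dynamics of any particular consortium.
- Channel signatures are diagonal-covariance log-normals; real cytometry
  clusters are skewed and correlated, and gates would need tuning per
  instrument.
- The v-test treats ordination scores as approximately normal; with very
  small categories its normal calibration degrades.
- FCS binary input is not parsed; the CSV event-table contract is the
  canonical interchange format.
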