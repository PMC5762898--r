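# evenpanel

Design and analysis of synthetic microbial ecosystems of **fixed richness
and varying initial evenness**, followed through serial batch transfers
with two measurement modalities: flow-cytometric fingerprinting of
single-cell phenotypes and amplicon-style phylotype count tables.

The package is for microbial ecologists who assemble defined consortia
(here: ten strains spanning Alpha-, Beta-, Gammaproteobacteria and
Firmicutes) and need the full computational chain around such an
experiment:

1. **Panel design** — draw an in-silico pool of candidate compositions
   (symmetric Dirichlet with log-uniform concentration), quantify each by
   Pielou's evenness `J = H'/ln S`, and sample a stratified panel
   (default: 40 Low `[0,0.3]`, 20 Medium `(0.4,0.6]`, 40 High `(0.6,1]`)
   with adjacent-duplicate 96-well plate layout.
2. **Serial-transfer simulation** — generalized Lotka–Volterra
   competition `dN_i/dt = r_i N_i (1 − Σ_j a_ij N_j / K)`, five 48 h
   cycles with 5 % transfers, plus seeded generation of synthetic
   cytometry events (four channels, log-normal species signatures,
   debris cluster) and bias-distorted multinomial amplicon counts.
3. **Fingerprinting** — asinh transform, polygon gating (even–odd rule),
   <1000-cell QC, exact Gaussian kernel-density fingerprints on
   128×128 grids over all channel pairs, and Hill diversities
   `D_q = (Σ p_i^q)^{1/(1−q)}` with bootstrap CIs.
4. **Taxonomic diversity** — abundance filtering (>0.1 % in any sample
   or >0.001 % in all), rarefaction to 3317 reads, and the index battery:
   richness, Shannon, Pielou, Simpson, inverse Simpson, Fisher's alpha
   (safeguarded Newton on `S = α ln(1 + N/α)`), Hill `D0/D1/D2`, and
   analytic (hypergeometric) rarefaction curves.
5. **Comparative statistics** — Bray–Curtis PERMANOVA (seeded
   permutations, exhaustive enumeration at small N), PCoA, group
   dispersion contrasts with Holm correction, multiple factor analysis
   with category v-tests, a permutation trend test for diversity decline,
   and phenotypic–taxonomic diversity correlation.

## Worked example

```r
library(evenpanel)

pool  <- generate_pool(1e6, seed = derive_seed(777, "pool"))
panel <- sample_panel(pool, seed = derive_seed(777, "panel"))
panel$strata_counts
#>    Low Medium   High
#>     40     20     40

params <- growth_params(seed = derive_seed(777, "growth"))
traj <- simulate_transfers(panel$compositions[1, ], params,
                           noise_cv = 0.05, seed = 1)
traj$time_h
#> [1]  48  96 144 192 240
```

The numbered scripts under `analysis/` run the five stages end to end
(design → transfers → fingerprinting → diversity → statistics), writing
tables under `results/`. On the default seed (777) they print, among
other things:

```
mean phenotypic D2 by class and transfer:
            1      2      3      4      5
High   3724.2 2083.3 1484.7 1235.1 1100.2
Low    1287.3 1301.4 1162.4 1167.5 1180.4
Medium 2244.3 1842.5 1638.3 1307.5 1068.4

D2 trend Low:    mean slope  -34.77 per transfer, P = 0.043
D2 trend Medium: mean slope -288.70 per transfer, P = 0.001
D2 trend High:   mean slope -609.63 per transfer, P = 0.001

PERMANOVA (evenness, transfer 5): R2 = 0.14812, P = 0.001
```

Phenotypic diversity (Hill order 2 of the fingerprint, in effective
grid-bin units) declines sharply across transfers in the High- and
Medium-evenness groups and stays roughly flat in the Low group —
initially even communities lose diversity as faster-growing strains
compound their advantage, while already-dominated communities have little
left to lose. The PERMANOVA R² says how much of the Bray–Curtis
community-composition variance at the final transfer is attributable to
the initial evenness class.

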