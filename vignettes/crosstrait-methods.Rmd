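---
title: "Methods: quantifying cross-trait genetic overlap from summary statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying cross-trait genetic overlap from summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

Two complex traits can share genetic architecture even when their genetic
correlation is near zero: the same causal variants may act on both traits
with effect directions that mix positive and negative signs. `crosstrait`
quantifies such overlap from GWAS summary statistics alone, at two levels —
the overall architecture (how many causal variants are shared) and
individual loci (which genomic regions drive both traits) — and adds the
classical genetic-correlation view for comparison. This vignette describes
the models, the estimators, the tunable parameters, and the choices made
where the design was genuinely open.

## The generative model behind everything

All calibration and power statements in the package rest on a synthetic
two-trait GWAS generator with known ground truth. Each of `m` SNPs falls in
one of four causal components with probabilities `(pi0, pi_a, pi_b, pi_12)`:
null, causal for trait A only, for B only, or for both. Causal effects on
the standardized-genotype scale are Gaussian with per-SNP variances
`sigma_b2_a`, `sigma_b2_b`; within the shared component the two effects are
correlated with `rho12`. The marginal GWAS z-score of SNP `j` for a trait
with sample size `N` is

    z_j = sqrt(N) * sum_k r_jk * beta_k + eps_j,

where `r_jk` is the allelic correlation (LD) between SNPs `j` and `k` and
the residuals are bivariate normal with variances `sigma02` (1 = no
inflation) and cross-trait correlation `rho0` (nonzero only under sample
overlap; default 0, reflecting analyses that exclude overlapping cohorts).
Genotypes are never materialized — the z-scores are drawn directly from
this linear model, which is exactly the quantity every downstream stage
consumes.

LD is block-diagonal: exchangeable blocks of 50 SNPs spaced 5 kb apart
(a 245 kb span, the scale of one genomic locus), with per-block pairwise
correlations drawn once, uniformly in [0.2, 0.9], so that LD scores vary
across the genome — without that variation LD score regression would be
unidentified. Consecutive blocks on a chromosome sit 500 kb apart so that
distinct blocks normally become distinct loci. Defaults
(`m = 5e4`, `pi_a = pi_b = 1e-3`, `pi_12 = 2e-3`, `sigma_b2 = 1e-3`,
`N = 1e5`) give SNP heritabilities around 0.15 and per-causal-SNP
non-centrality `N * sigma_b2 = 100` — a moderately powered GWAS of a
polygenic behavioural trait.

What the generator does *not* emulate: realistic allele-frequency spectra
(effects are on the standardized scale, so MAF never enters), imputation
error, population stratification beyond a scalar inflation, long-range LD,
and the LD-block structure of real genomes (real blocks are neither
exchangeable nor disjoint). Passing tests therefore demonstrate correctness
of the estimators under the stated model, not robustness to every artefact
of real data; the harmonization and exclusion-mask machinery exists
precisely because real inputs violate the clean model.

## Conditional Q-Q tables

Cross-trait enrichment is visualized by conditioning: restrict to SNPs
whose secondary-trait p-value falls below a threshold (defaults 1, 0.1,
0.01, 0.001) and plot observed quantiles of the primary trait's
`-log10 p` against the uniform expectation. Successive deflection of the
curves with stricter conditioning is the qualitative signature of
pleiotropy. Curves use 1000 evenly spaced quantile levels and are capped at
`-log10 p = 20` for display. Strata below 100 SNPs are flagged rather than
dropped. LD-aware weighting of the curves, used in some conditional-FDR
pipelines, is deliberately omitted. A DKW-based 95% band
(`sqrt(log(2/alpha) / (2n))`) around the diagonal supports null checks;
the band presumes independent SNPs, so apply it to pruned or iid data.

## The bivariate causal mixture

The architecture-level estimator fits the four-component mixture to the
paired z-scores of an LD-pruned SNP set. Under component `c` the pair is
zero-mean bivariate normal with covariance built from the null covariance
(residual variances and `rho0`) plus `N * sigma_b2` terms on the diagonal
for the trait(s) the component affects, plus
`rho12 * sqrt(nA * nB * sigma_b2_a * sigma_b2_b)` off-diagonal in the
shared component. Pruned SNPs are treated as independent — a deliberate
simplification that replaces the full LD-convolution likelihood of the
original architecture method. The cost of that choice is that per-trait
polygenicity absorbs some LD-tagging; the benefit is a likelihood that
evaluates in milliseconds and needs no reference panel beyond the pruning
itself.

Fitting maximizes the likelihood over transformed parameters (softmax for
the weight simplex, log for variances, atanh for correlations) with
Nelder-Mead from 8 seeded starts. The two univariate margins (two-component
mixtures) are fitted first; their total polygenicities and variance
components anchor the bivariate starts, which vary the assumed shared
fraction (0.2-0.95 of the smaller total) and the sign of `rho12`. Starts
are explored on a 20,000-SNP subsample and the winner is polished on the
full data; tolerance is 1e-8 on the transformed scale. `rho0` is fixed at 0
by default (non-overlapping cohorts) and freed by flag.

Near the null the product `pi * sigma_b2` is only weakly identified: a
large weight with negligible variance fits as well as no component at all.
The fit therefore ends with a parsimony step: any causal component whose
removal costs less than one log-likelihood unit per freed parameter is
pruned to zero. Model-level diagnostics refit with the shared weight
constrained to zero (minimum overlap) and to the smaller trait's total
polygenicity (maximum overlap) and report AIC differences; positive
differences mean the data can tell the best fit from the boundary
scenario, mirroring the negative-AIC convention used to flag
indistinguishable fits.

Reported "causal variant" counts apply a 90%-of-SNP-heritability transform:
for iid Gaussian effects the heritability fraction above a squared-effect
threshold `t` is `P(chisq_3 > t)`, so solving `P(chisq_3 > t*) = 0.90`
retains the fraction `q* = P(chisq_1 > t*) ≈ 0.44` of causal variants. The
transform is applied per Venn component, so unique plus shared counts add
to each trait's total; whether the original method applies it per
component or per trait is not documented, and the additive convention was
chosen for internal consistency.

## Conditional and conjunctional FDR

The locus-level estimator re-ranks the primary trait's test statistics
within strata of the secondary trait. The lookup grid tabulates, over a
2D grid in `-log10 p` (step 0.1, range 0-20),

    condFDR(p1 | p2) = min(1, p1 * C2(p2) / C12(p1, p2)),

where `C2` counts SNPs passing the secondary threshold and `C12` counts
SNPs passing both. The null proportion is conservatively fixed at 1. To
undo LD's inflation of counts, both counts are averaged (as real numbers,
before the division) over 100 random greedy prunings at `r^2 < 0.1`;
published conditional-FDR analyses rarely state these two values, so both
follow common practice and are exposed as configuration. Cells whose averaged
joint count falls below one SNP inherit the nearest less-stringent defined
cell, and each column is made monotone by a running maximum toward
less-significant `p1`. Per-SNP values come from bilinear interpolation in
`-log10` space (which concentrates resolution where discoveries happen);
every SNP receives a value, not only pruned ones. The conjunctional FDR is
the maximum of the two reciprocal condFDR values, and the trio extension
takes the maximum of the three pairwise conjFDR values — so trio
significance at `tau` implies significance in all three pairs. No
published definition of a trio conjFDR exists; the max-of-three rule is
this package's documented choice.

Empirically (and by construction) the estimator controls the
false-discovery proportion at the SNP level. At the *locus* level the
picture is different: a true locus contributes many correlated SNPs that
collapse into one discovery while each false SNP tends to become its own
singleton locus, so the false fraction among loci exceeds the SNP-level
FDR, increasingly so in dense-signal simulations. This is a property of
the method, not a bug, and it is why effect-direction studies here use
sparse, overlap-only designs (below).

## Loci and effect-direction concordance

Scored SNPs collapse into loci by the FUMA convention with its published
defaults, all exposed as configuration: independent
significant SNPs (conjFDR < 0.05, mutually `r^2 < 0.6`, greedy by
ascending conjFDR with ties broken by chromosome then position), lead SNPs
(subset at `r^2 < 0.1`), candidate SNPs (conjFDR < 0.10 and `r^2 >= 0.6`
with an independent significant SNP), and positional envelopes merged
within 250 kb. Cross-block `r^2` is defined as 0. A locus is concordant
when the two traits' z-scores agree in sign at its lead SNP; loci with
zero or missing z are excluded from the percentage and counted separately.
Lead-SNP concordance is the default (one sign comparison per locus, at the
locus's most significant SNP); a majority vote over candidate SNPs is
available behind a flag.

The concordance recovery study plants an overlap-only architecture
(`pi_a = pi_b = 0`, `pi_12 = 2e-3`) with marginal per-SNP power
(`sigma_b2 = 3e-4`, `N = 1e5`) on iid SNPs: isolating the shared component
makes lead-sign agreement a direct read-out of `rho12`, and marginal power
puts discovery in the selection regime where conditioning on both traits'
magnitudes sharpens sign agreement — the regime real cross-trait scans
operate in. Trait-specific or null singleton loci would otherwise dilute
the percentage toward 50 regardless of `rho12`.

## LD score regression

Per-trait heritability comes from the weighted regression
`E[z^2] = intercept + N h2 l / m` and the cross-trait genetic covariance
from `E[zA zB] = intercept + sqrt(NA NB) rho_gcov l / m`, with weights
`1 / l` as a heteroskedasticity proxy; no two-step intercept constraint is
applied — the simplest defensible variant of the regression.
`rg = gcov / sqrt(h2A h2B)` is clamped to [-1, 1];
non-positive heritability makes it undefined and it is reported as missing
with the reason, never truncated silently. Uncertainty comes from a
delete-one block jackknife over 200 contiguous SNP blocks with a two-sided
normal p-value, and family-wise flags use `p < 0.05 / n_tests`. The
cross-trait intercept absorbs correlated residuals from sample overlap, so
planted `rho0` loads on the intercept while the slope-based `rg` stays at
zero.

## Numerical choices and degenerate inputs

p-values are floored at 1e-300 and z capped at the matching quantile;
strand-ambiguous SNPs (A/T, C/G) are dropped during harmonization because
the inputs carry no allele frequencies to orient them; region masks
default to the extended MHC (chr6:26-34 Mb) and the chr8p23.1 inversion
(7-13 Mb), applied to file inputs but not to simulated coordinates (which
do not live on the real genome); constant-p inputs make the FDR grid
degenerate and raise an error; empty significance sets yield empty locus
tables, not errors; greedy selections break conjFDR ties by chromosome
then position so results are invariant to input row order; all stochastic
stages (pruning draws, optimizer starts, simulation) derive their RNG
streams from explicit seeds, and rerunning any stage with the same seed
reproduces it bit for bit.

## Problem sizes

The bundled studies run at desk scale, chosen so the full test suite and
the acceptance script complete comfortably on one CPU: mixture recovery at
`m = 1e5` iid SNPs (10 replicates), FDR calibration and power at
`m = 5e4` (20 replicates), locus-definition equivalence on 200 randomized
20-SNP instances, and the demo pipeline at `m = 5e4`. These sizes are two
orders of magnitude below a real 1e7-SNP analysis; nothing in the
implementation depends on them, and the grid/pruning stages scale linearly
in SNP count.

## Known limitations

The mixture likelihood ignores residual LD among pruned SNPs and fixes
per-SNP effect variance within components (no MAF- or LD-dependent
architecture). The condFDR lookup inherits the self-counting bias of
empirical 2D cdfs in sparse tail cells; the sub-one-count inheritance rule
bounds but does not remove it. Locus definition uses the synthetic
block-LD notion of `r^2` when applied to simulations, and a user-supplied
triplet file otherwise — it never computes LD from genotypes. The 90%
transform assumes Gaussian effects within components. None of the
estimators model ascertainment or binary-trait liability scales.
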