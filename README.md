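# crosstrait

Cross-trait genetic overlap from GWAS summary statistics.

Two complex traits can share a large part of their genetic architecture
even when their genetic correlation is weak or zero, because shared causal
variants may act with mixed effect directions. `crosstrait` quantifies
such overlap from per-SNP summary statistics alone, at two complementary
levels:

- **Architecture level** — a bivariate Gaussian causal mixture fitted to
  LD-pruned z-score pairs. Each SNP belongs to one of four components
  (null, causal for trait A only, B only, or both) with weights
  `(pi0, piA, piB, pi12)`; causal effects are Gaussian with correlation
  `rho12` inside the shared component. The fit yields Venn counts of
  unique and shared causal variants (reported as the number explaining
  90% of SNP heritability), the model-implied genetic correlation
  `rg = rho12 * pi12 / sqrt((piA + pi12)(piB + pi12))`, and AIC
  comparisons against minimum- and maximum-overlap scenarios.
- **Locus level** — conditional and conjunctional false discovery rates.
  The condFDR re-ranks trait 1's statistics given trait 2,
  `condFDR(p1|p2) = p1 * C2(p2) / C12(p1, p2)`, with counts averaged over
  random LD prunings; the conjFDR is the maximum of the two reciprocal
  condFDRs (extended to trait trios by the max of the three pairwise
  values). Significant SNPs collapse into FUMA-style loci (independent
  significant SNPs at `r² < 0.6`, leads at `r² < 0.1`, candidates at
  conjFDR < 0.10, 250 kb merge) with effect-direction concordance at the
  lead SNPs.

Around these sit conditional Q–Q tables of pleiotropic enrichment,
cross-trait LD score regression (`E[zA zB] = intercept +
sqrt(NA NB) * rho_gcov * l / m`) with block-jackknife uncertainty and
Bonferroni flags, summary-statistics harmonization (allele alignment,
strand flips, ambiguous-SNP removal, region masks), and a synthetic
two/three-trait GWAS generator with block LD that provides ground truth
for every stage. See `vignettes/crosstrait-methods.Rmd` for the full
model description and design rationale.

## Worked example

Simulate a pair of traits with a planted shared component (100 shared
causal variants among 50,000 SNPs, effect correlation 0.9), score SNPs
with the conjunctional FDR, call shared loci, and estimate the genetic
correlation:

```r
library(crosstrait)

gp  <- generative_params(m = 5e4, pi_a = 1e-3, pi_b = 1e-3, pi_12 = 2e-3,
                         rho12 = 0.9, seed = 42)
sim <- simulate_gwas_pair(gp)

scored <- conjfdr_analysis(sim$pair, sim$ld, seed = 1)
loci   <- define_loci(scored, sim$ld)
cc     <- effect_concordance(loci)
cat(sprintf("%d shared loci at conjFDR < 0.05; %.1f%% concordant (%d/%d)\n",
            nrow(loci), cc$pct_concordant, cc$n_concordant, cc$n_evaluable))
#> 171 shared loci at conjFDR < 0.05; 74.9% concordant (128/171)

cross_trait_rg(sim$pair, ld_scores(sim$ld), m = 5e4)
#> rg = 0.584 (SE 0.100, p = 5.1e-09), h2: 0.114 / 0.146, cross intercept 0.521
```

The 171 loci are genomic intervals jointly associated with both traits at
conjFDR < 0.05; 74.9% of their lead SNPs have z-scores of the same sign in
both traits, reflecting the planted positive effect correlation diluted by
locus-level noise (the methods vignette discusses why locus-level false
fractions exceed the SNP-level FDR). The LD-score-regression `rg` of 0.58
(SE 0.10) sits near the generative value 0.6 implied by
`rho12 * pi12 / sqrt((piA + pi12)(piB + pi12))`. The first rows of the
locus table look like:

```
   chrom   start     end    lead_snp lead_conjfdr       z_a       z_b concordant
1:     1 3920001 3920001 snp_0005535 1.829140e-02  2.816537 -2.545176      FALSE
2:     1 7500001 7745001 snp_0011001 2.188142e-20 12.526213 12.276742       TRUE
3:     1 8345001 8480001 snp_0012128 2.351659e-03  3.463810  3.162367       TRUE
```

End-to-end runs (simulate/read → harmonize → Q–Q → mixture → conjFDR →
loci → concordance → rg) are driven by `run_pair_analysis()` /
`run_trio_analysis()` from a `run_config()` or a YAML file; a thin CLI
wrapper lives at `inst/cli/crosstrait-run.R`.

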