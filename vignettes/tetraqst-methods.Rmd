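---
title: "Methods: tetraploid genotype calling, half-sib variance components, and the QST-FST test"
author: "tetraqst"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tetraploid genotype calling, half-sib variance components, and the QST-FST test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetraqst)
```

`tetraqst` implements the statistical machinery used to ask whether
latitudinal trait differentiation in an autotetraploid, outcrossing grass
exceeds what genetic drift alone would produce. The study system is a
common-garden experiment: open-pollinated (half-sib) seed families from
populations along a latitudinal gradient, raised under simulated winter
scenarios, with genotyping-by-sequencing (GBS) read counts for one offspring
per family. This vignette explains each model, its assumptions, the tunable
parameters, and the design decisions taken where the methodology left
genuine choices.

## Tetraploid genotype calling from read depth

At a biallelic SNP, the number of reads $k$ carrying allele A out of $n$
total reads is modelled as $k \sim \mathrm{Binomial}(n, p)$, where $p$ is
the frequency of A in the tetraploid genotype and can only take the values
$0, \tfrac14, \tfrac12, \tfrac34, 1$ (zero to four copies). The caller:

1. finds the dosage $\hat p$ maximising the binomial likelihood;
2. tests every other dosage against $\hat p$ with the statistic
   $2(\ell_{\hat p} - \ell_p)$ against the $\chi^2_1$ critical value at
   $\alpha = 0.05$;
3. keeps the non-rejected set $S$ and claims only the allele copies that
   every member of $S$ supports: $\mathrm{minA} = 4\min(S)$,
   $\mathrm{minB} = 4(1 - \max(S))$, the remainder unknown.

A singleton $S$ yields a complete genotype (`AAAA`); otherwise the call is
incomplete (`AB00`, `ABB0`, ...). Cells with $n < 2$ support no call.

Numerical choices: ties in the likelihood maximum go to the smaller $p$
(they only arise in symmetric configurations and the rule exists for
determinism); impossible observations ($p = 0, k > 0$ or $p = 1, k < n$)
have log-likelihood $-\infty$, so those dosages are always rejected when not
themselves the maximum — the coherent reading of an infinite likelihood
ratio. The $\chi^2$ reference with 1 degree of freedom is a pragmatic
calibration for comparing two simple hypotheses; both $\alpha$ and the
degrees of freedom are arguments.

A consequence worth knowing: the error rate *among complete calls* at
moderate depth is governed by the tail probability of $k/n$ crossing the
midpoint between adjacent dosage grid points, not by $\alpha$. Exact
enumeration gives about a 2% error rate among complete calls at constant
depth 30, falling below 1% only around depth 50 and vanishing as depth
grows. The test suite asserts the >99% recovery property at depth 100 and
the monotone decline of the error with depth.

Locus retention follows the source protocol: polymorphic loci only
(both alleles observed among known copies, and not all calls identical),
minor allele frequency at least 0.01 computed from known allele copies
(unknown slots of incomplete genotypes are never imputed), and at least two
scored samples per population. "Per population" is read strictly (every
population); `mode = "any"` relaxes it. The MAF filter is applied after
calling; the original pipeline applied it at the read-processing stage,
which is out of scope here.

## Molecular diversity and differentiation

Gene diversity is Nei's sample-size-corrected estimator on known allele
copies: with $n_c$ copies and allele frequencies $p_i$ in a population,
$H_e = \frac{n_c}{n_c - 1}(1 - \sum p_i^2)$, averaged unweighted across
loci; a locus needs $n_c \ge 2$ in a population to contribute there.

FST is the Weir-Cockerham moment estimator with known allele copies as the
sampling units (four per complete genotype, fewer for incomplete calls).
Per locus, the among-population component $a$ and within-population
component $b$ come from the one-level ANOVA of allele indicators, and the
multi-locus estimate is the ratio of sums $\sum a / \sum(a + b)$. The
heterozygosity-correction terms of the diploid two-level estimator have no
agreed tetraploid analogue and are omitted; this "allele-frequency variant"
is well defined for any ploidy and is what the tests verify against a
brute-force oracle. Negative estimates are reported as computed. Pairwise
FST applies the same estimator to population pairs. The population-specific
value exported is the mean of the pairwise estimates involving each
population — a transparent substitute for a model-based population-specific
FST (the original used a Bayesian outlier-scan model, out of scope here);
output metadata labels it as such. Outlier loci are excluded from the
neutral estimate when a supplied q-value table puts them strictly below
`q_max = 0.05`.

Distances and matrix correlations: climatic distances are Euclidean on the
19 bioclimatic variables standardized to mean 0, sd 1 (sample sd) across
populations; geographic distances are haversine great circles on a
6371 km sphere. Mantel and partial Mantel tests use the Pearson correlation
of off-diagonal entries, a one-sided (positive-association) permutation
p-value over simultaneous row/column permutations of the second matrix,
with the $+1$ correction $(\#\{r^\ast \ge r\} + 1)/(n_\mathrm{perm} + 1)$;
the partial statistic is the correlation of residuals after regressing both
matrices' entries on the third. Residuals that are numerically zero (the
conditioning matrix explains a matrix exactly) define a partial correlation
of zero rather than propagating floating-point noise.

## Half-sib variance components by MCMC

The phenotypic model for the nested design (families in populations, blocks
in treatments) is, for a Gaussian trait,

$$y = X\beta + u_\mathrm{pop} + u_\mathrm{fam} + u_\mathrm{block}
      (+ u_{\mathrm{fam}\times t} + u_{\mathrm{pop}\times t}) + e,$$

each random vector i.i.d. normal with its own variance and
$e \sim N(0, V_\mathrm{err})$. Because open-pollinated seed families are
assumed half-sibs, the additive genetic variance is derived per posterior
draw as $V_A = 4 V_F$. The quantities of interest are

- heritability $h^2 = V_A / (V_A + V_R)$, with
  $V_R = V_\mathrm{err} + V_\mathrm{block}$ plus $V_{F \times T}$ in
  across-treatment fits, plus the logit link variance $\pi^2/3$ for the
  binary trait;
- evolvability $e = V_A / m^2$ with $m$ the observed trait mean;
- $Q_{ST} = V_P / (2 V_A + V_P)$, the diploid-derived definition, used for
  the autotetraploid with the explicit caveat that no exact tetraploid
  equivalent exists.

All three are computed per draw and summarized by the posterior mean and
central 95% interval, so the credible intervals are exact functionals of
the posterior rather than delta-method approximations.

Sampling: the Gaussian model uses a conjugate Gibbs sampler (closed-form
normal updates for fixed and random effects, inverse-gamma updates for
variances). The binary trait uses adaptive Metropolis-within-Gibbs on the
logit scale: all levels of a random factor are proposed jointly and
accepted per level, proposal scales adapt toward workable acceptance rates
during burn-in only (preserving detailed balance afterwards), and the
residual variance — not identifiable in a Bernoulli-logit model — is fixed
at 1 and reported as such, with $h^2$ denominators using that constant plus
$\pi^2/3$. A self-contained sampler was preferred over an external MCMC
engine to keep the variance-component arithmetic transparent and the
hundreds of replicate fits in the validation studies fast; the contract is
simply valid posterior draws, checked by parameter-recovery and
CI-coverage studies.

Priors default to inverse-gamma(0.001, 0.001) per variance, the
conventional weakly-informative choice for this model family; they are
configurable. Near-zero variance components therefore sit at a prior noise
floor of order $10^{-4}$ rather than exactly zero — degenerate-data tests
assert "near zero" at that floor. Defaults of 2 chains × 13,000 iterations
(3,000 burn-in, thinning 10) give 2,000 retained draws; a split-$\hat R$
diagnostic is reported per component and values at or above 1.1 raise a
warning flag rather than an error. Model-structure selection (AIC/DIC
ladders over random and fixed terms) is deliberately not implemented: fits
use the structure stated in the spec object, which is where the scientific
content lives.

Per-population heritability fits keep the block term as given (blocks are
crossed with populations in the design, so a single population's data still
spans all blocks). The across-treatment $h^2$ denominator includes
$V_{F\times T}$ but not $V_{P\times T}$, following the stated composition
of the residual variance.

### QST of plasticity and prior sensitivity

Plasticity differentiation uses the interaction variances:
$Q_{ST}^{plast} = V_{P\times T} / (2 \cdot 4 V_{F\times T} + V_{P\times T})$.
When the data carry no interaction signal this ratio is prior-driven. Under
inverse-Wishart-style priors such posteriors famously spread toward both
ends of the unit interval (dumbbell shapes); under this package's
inverse-gamma Gibbs prior they instead concentrate near the noise floor.
The `prior_sensitive` flag therefore fires on any of: a 95% interval wider
than 0.9, both tails (below 0.1, above 0.9) holding over 15% of mass, or a
lower credible bound of $V_{P\times T}$ below 1% of total variance — the
last being the operative signal that the data cannot distinguish the
numerator from zero. Flagged results should be reported but not
interpreted.

## The neutrality test

The test of adaptive differentiation compares the $Q_{ST}$ posterior with
a simulated neutral distribution: per simulation, a $V_A$ value is sampled
from the posterior, the neutral among-population variance is

$$V_{Pn} = \frac{2\,F_{ST}\,V_A}{1 - F_{ST}} \cdot \frac{r}{n_\mathrm{pop} - 1},
\qquad r \sim \chi^2_{n_\mathrm{pop} - 1},$$

and $Q_{STn} = V_{Pn} / (2 V_A + V_{Pn})$ with the same (index-paired)
$V_A$ draw in the denominator, so numerator and denominator are coherent
per draw (`va = "mean"` exposes the posterior-mean alternative). With the
$\chi^2$ factor at its expectation and a degenerate posterior,
$Q_{STn} = F_{ST}$ exactly — an identity the tests assert. The statistic is
the difference between $Q_{ST}$ posterior draws and $Q_{STn}$ simulations,
paired by index after an independent seed-controlled shuffle of both
vectors (the source describes subtracting two 1,000-length collections
without stating a pairing; shuffling makes the arbitrary pairing explicit
and reproducible). The verdict is read off the central 95% interval of the
difference: entirely positive = divergent selection, entirely negative =
homogenizing, otherwise compatible with drift. The global
outlier-excluded FST is the intended input.

## Plasticity and fitness

The family-level plasticity index is the coefficient of variation of
treatment-specific family means (sample sd over their mean; means
unweighted across treatments, which is robust to unbalanced survival — a
plant-level alternative is exposed as an option only through the underlying
means). Adaptive significance is tested by OLS of family fitness on the
CV with the family trait mean as covariate
(fitness ~ intercept + CV + mean); the binary fitness proxy uses the family
mean flowering probability. A significantly positive or negative CV slope
suggests adaptive or maladaptive plasticity respectively. Latitudinal
patterns of per-population estimates ($H_e$, population-specific FST,
$h^2$, $e$) use plain Pearson correlations with the two-sided t test.

## The synthetic study and what it does (not) show

`synthetic_config()` encodes the study conditions: 8 populations at
latitudes spanning 43.03-62.94°N, 5 half-sib families per population, 15
offspring per family (600 plants), treatments mild/frost/warmfrost with 4
blocks nested in each, one genotyped offspring per family, 500 loci at a
drift target of $F_{ST} = 0.09$, negative-binomial depth of mean 30
(dispersion 5; `Inf` gives constant depth). Allele frequencies follow the
Balding-Nichols model — population frequencies Beta-distributed around an
ancestral $p_0 \sim U(0.05, 0.95)$ with variance $\theta p_0 (1 - p_0)$ —
the simplest frequency model with a tunable FST. Trait architectures
default to the published mixed-model estimates of the source study
(random-effect SDs squared; treatment intercepts and latitude slopes as
published); traits whose best model carried no population term default to
the drift-coupled neutral expectation
$V_P = 2\theta\,(4 V_F)/(1 - \theta)$, which is also what the
`drift_coupled_vp` switch forces for type-I-error studies, with
`vp_inflation` scaling it for power studies. Family effects are drawn per
family, so $V_A = 4 V_F$ holds exactly in simulation and the analysis-side
identity is testable. Growth rate is derived as final minus initial height,
keeping that bookkeeping invariant exact.

The generator reproduces the statistical *structure* the models assume —
balanced nesting, normal random effects, binomial reads, Bernoulli
flowering. Real GBS data add allelic dropout, sequencing error, depth
correlated with genotype, and relatedness structure within families
(non-half-sib paternity, maternal effects); real phenotypes add
non-normality and unbalanced survival. Passing recovery tests therefore
validates the estimators under their own assumptions, not robustness to
those violations — the same caveat the source study makes for its
heritabilities possibly containing non-additive and maternal components.

## Validation study sizes

The replicate studies in the test suite and the acceptance script use
problem sizes chosen to give informative Monte-Carlo precision at desk
scale: 50 replicates of 500 loci for FST recovery (mean within 10% of the
0.09 target), 100 replicates of the 600-plant design for CI coverage
(expected at or above 85% for nominal 95% intervals) and $h^2$ bias (under
0.05 absolute), 200 drift-coupled replicates for the neutrality test's
size (accepted within [0.01, 0.12]) and 200 at tenfold $V_P$ inflation for
its power (at or above 0.8), with single-chain reduced-iteration MCMC
settings (1,300 iterations, 500 burn-in) whose adequacy the split-$\hat R$
and determinism tests support. The Mantel null-uniformity check uses 200
tests of 199 permutations each against the uniform by Kolmogorov-Smirnov.

## Known limitations

- The diploid-derived $Q_{ST}$ and $V_A = 4V_F$ identities are
  approximations for an autotetraploid; double reduction and polysomic
  segregation are not modelled.
- The population-specific FST substitute (mean pairwise) is not comparable
  to model-based population-specific estimates.
- The binary-trait sampler fixes the residual at 1; variance components for
  flowering are on the latent logit scale and not directly comparable to
  Gaussian-trait components.
- Incomplete genotypes contribute only guaranteed allele copies; this is
  conservative and slightly reduces effective sample size at low depth.
- No linkage, selection at individual loci, or pedigree structure beyond
  half-sib families is simulated.
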