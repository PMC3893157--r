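---
title: "Cryptic relatedness as a confounder of exposure regressions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cryptic relatedness as a confounder of exposure regressions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crconfound)
```

## The problem

Cohort studies recruited from small, closed populations routinely contain
*cryptic relatedness* (CR): pairs of participants who are close relatives —
duplicates or monozygotic twins (relationship degree $R = 0$), parent–offspring
or full sibs ($R = 1$), half-sibs, avuncular or grandparental pairs ($R = 2$) —
without the study knowing it. In genome-wide association studies CR is a
well-understood inflater of false positives. This package addresses the less
studied converse question: when a conventional epidemiological regression of a
quantitative trait (here systolic blood pressure, SBP, in mmHg) on
environmental exposures (BMI, smoking, alcohol, with age and gender as
covariates) is run on such a cohort, how much do the estimated exposure
effects change once the cryptic relatives are identified from genome-wide SNP
data and removed?

The package provides the complete chain as testable components:

1. **Relatedness detection.** Pairwise identity-by-state (IBS) and
   method-of-moments identity-by-descent (IBD) estimation from allele-dose
   genotypes, summarised per pair as $\hat\pi = Z_2 + Z_1/2$ (`PI_HAT`), with
   a pair called cryptically related when $\hat\pi > 1/4$ (strict).
2. **Paired regressions.** The same OLS specification fitted on the sample
   *with* CR and on the sample *without* CR.
3. **Parallel-regressions tests.** Chow-type F tests of coefficient equality
   between the two fits, both the full test and a per-term 1-df battery.
4. **Heritability of liability.** A Falconer-type estimator
   $h^2 = \{(x_p - x_q)/a_p\}/\rho$ contrasting the CR and CR-free
   subpopulations.
5. **A synthetic cohort generator** that plants relative pairs by real gamete
   dropping, so the detection step and the confounding mechanism operate on
   the same simulated genomes.

## The trait and liability model

For individual $i$ the generator produces

$$\mathrm{SBP}_i = \beta_0 + \boldsymbol\beta^\top \mathbf{c}_i
  + \sigma_u \ell_i, \qquad
  \ell_i = \sqrt{h^2}\, g_i + \sqrt{1 - h^2}\, e_i,$$

where $\mathbf{c}_i$ are the covariates, $g_i$ is the standardized polygenic
score over the causal SNPs (actual allele doses, centred and scaled), $e_i$ is
independent standard normal, and $\sigma_u = \sigma_e / \sqrt{1 - h^2}$ so
that the trait residual after covariates has variance $\sigma_u^2$ and
heritability $h^2$ on the standardized *liability* scale $\ell$. Hypertension
("affected") is the dichotomization $\ell_i > t$; thresholds are set per
subpopulation at the empirical quantile matching the configured prevalences,
which makes the three prevalence knobs (population, CR, CR-free)
independently controllable — the mixture identity
$K_{pop} = c\,K_{CR} + (1 - c)K_{\overline{CR}}$ (with $c$ the CR fraction)
is enforced at configuration time with a 0.02 tolerance.

Defaults are chosen for a realistic middle-aged rural cohort and are all
configurable: age $\sim U(40, 79)$ years, BMI $\sim N(23, 3^2)$ kg/m²,
smoking and alcohol as $\{1, 2\}$ codes with rates 0.25 and 0.5, balanced
gender, $\sigma_e = 14$ mmHg, and effect sizes
(intercept 82.52, BMI 1.31, alcohol $-0.80$, smoking $-0.66$, age 0.38,
gender $-3.09$) matching the magnitude regime of published SBP regressions;
with these settings the with-CR fit has adjusted $R^2 \approx 0.15$.

## How cryptic relatedness is made to confound

This is the one genuinely open design point, and the package takes a
deliberate position: **the structural difference between the CR and CR-free
subpopulations is realized genetically only.** Each planted pair consists of
a *proband* and a relative created from it by gamete dropping (degree 0: an
exact copy; degree 1: parent–offspring via a simulated mate; degree 2:
grandchild through an unobserved intermediate; the default degree mix is
0.05/0.60/0.35, since the relative classes are known but their proportions
are not). Two ascertainment modes shape the probands:

* `ascertainment = "gap"` (default). The prevalence gap between the CR-free
  and CR subpopulations implies, under a common liability threshold, a mean
  liability shift $\Delta = z_{\overline{CR}} - z_{CR}$ (upper-tail normal
  quantiles at the two prevalences). Probands receive a genetic mean shift
  $\delta_g = 2\Delta/(1 + \bar\rho)$ — so that the pair average works out to
  $\Delta$ — implemented by exponentially tilting the causal-allele sampling
  probabilities (a founder-lineage model: the CR families descend from
  ancestry with shifted causal-allele frequencies). Relatives inherit
  $\rho\,\delta_g$ of the shift through transmission.
* `ascertainment = "affected"`. Probands are rejection-sampled from the
  affected stratum of the base liability distribution — the classic Falconer
  proband design, under which the relatives' mean liability is
  $\bar\rho\, h^2 a_p$ and the heritability estimator below is consistent.
  This mode drives the estimator-recovery suites.

Because both mechanisms act through the genotypes, setting $h^2 = 0$ switches
the confounding off entirely: relatedness without genetic trait sharing
cannot move the regressions, and the parallel-regressions test must (and
does) hold its nominal level even with half the cohort cryptically related.
A purely environmental enrichment would break that property, which is why it
is not offered. A corollary worth stating: with equal subpopulation
prevalences (the baseline scenario) no shift is planted, so the baseline is a
true null of the parallel-regressions hypothesis; with a prevalence gap the
shift moves primarily the *intercept* of the with-CR fit, since covariates
are independent of pair membership. The published coefficient-level
differences in slopes are a feature of resampling a real cohort that the
simulation deliberately does not imitate.

## Relatedness estimation

For a pair observed at $n$ shared polymorphic SNPs, the observed counts of
IBS states 0/1/2 are set against their expectations under IBD states
$Z_0, Z_1, Z_2$, computed from panel allele frequencies. The moment equations
are solved in cascade ($z_0$ from IBS0, then $z_1$, then $z_2$), estimates
are bounded to $[0, 1]$ and renormalized to sum to one (the
bound-then-renormalize convention of the standard tooling), and
$\hat\pi = z_2 + z_1/2$. When the pairwise scan estimates frequencies itself,
the polynomial terms ($p^2q^2$, $p^3q$, ...) are replaced by unbiased
factorial-moment estimators built from the sample allele counts, which
removes the finite-panel bias that plug-in frequencies would induce.
Implementation notes:

* Frequencies are estimated from the full retained sample, relatives
  included — a known, small bias source, accepted because the alternative
  (iterative relative-free re-estimation) is circular.
* Monomorphic SNPs carry no IBD information and are excluded; pairs with
  fewer than `min_snps` (default 100) informative shared SNPs are flagged
  `low_confidence` rather than silently reported.
* No linkage-disequilibrium pruning is applied (simulated SNPs are unlinked);
  a `snp_subsample` argument stands in for thinning on real data.
* The strict `PI_HAT > 1/4` call makes second-degree detection intentionally
  seed-dependent: a degree-2 pair sits exactly at the threshold in
  expectation, so roughly half of them are called. First-degree and duplicate
  pairs are detected essentially always at 2000+ SNPs (the Monte-Carlo suite
  requires sensitivity ≥ 0.95 for degree ≤ 1 with false-positive rate
  ≤ 0.01).
* Pruning is `remove_all` (drop every member of a flagged pair, the
  conventional conservative cascade) or `keep_one` (a minimum vertex cover of
  the flagged-pair graph — exact up to 24-vertex components, greedy beyond).

## The parallel-regressions test

With groups 1 and 2 sharing a design specification, the unrestricted model
gives the `tested_terms` group-specific coefficients via interaction columns
on the stacked data; the restricted model forces them equal. Then
$F = \{(\mathrm{SSR}_r - \mathrm{SSR}_u)/q\} / \{\mathrm{SSR}_u/\mathrm{df}\}$.
Testing all terms is the classic Chow test; the per-term battery issues one
1-df test per coefficient (unadjusted for multiplicity, mirroring the usual
reporting of a single F and p per comparison — reverse-engineering published
(F, p) pairs such as $F = 0.35, p = 0.55$ is consistent with 1 numerator df,
not with a full multi-df test, so both are always reported).

One caution is built into the pipeline interface: the published comparison
contrasts the full sample with its own CR-free *subsample*. Those two samples
overlap, and treating them as independent makes the test conservative under
the null (empirically ~0 rejections at $\alpha = 0.05$). `run_once()`
therefore exposes `comparison = "overlapping"` (the published behaviour, the
default) and `comparison = "disjoint"` (CR vs CR-free individuals,
independent groups, correctly calibrated — verified by simulation at
$h^2 = 0$ with a uniformity check on the p values).

## Heritability of liability

The estimator is $h^2 = \{(x_p - x_q)/a_p\}/\rho$ with the CR-free
subpopulation as the reference ($p$) and the CR subpopulation as the
contrast ($q$):

* **Prevalence mode** maps prevalences to standard-normal deviates:
  $x_p = \Phi^{-1}(1 - K_{\overline{CR}})$,
  $x_q = \Phi^{-1}(1 - K_{CR})$, $a_p = \phi(x)/K_{pop}$ evaluated at the
  population prevalence. The numerator $x_p - x_q$ then equals the
  standardized mean-liability shift of the CR group — the Falconer
  convention. (The verbal definitions in the source analysis mix the signs
  of these differences; the package adopts the internally consistent
  threshold-minus-mean orientation in both modes and documents the choice.)
* **Observed mode** builds the same deviates from phenotype-scale
  quantities standardized by the phenotypic SD; the threshold cancels from
  the numerator, leaving
  $h^2 = (\bar y_{CR} - \bar y_{\overline{CR}})
  \big/ \{(\bar y_{aff} - \bar y_{\overline{CR}})\,\rho\}$.
  `falconer_inputs()` assembles these from a cohort table; given the
  simulation truth it contrasts the pairs' *relatives* (the configuration in
  which the estimator is consistent), otherwise the whole detected CR set,
  which mixes probands with relatives and is labelled as such.

The relationship weight $\rho$ is either the literal sum
$\sum_R 2^{-R}$ over the degrees present (1.75 when all of 0–2 occur — the
source analysis' stated definition, kept as the default even though a sum
over heterogeneous degrees exceeding 1 is statistically unconventional) or
the pair-count weighted mean $2^{-R}$ (the conventional choice; both are
always reported). In the pipeline, degrees are classified from
$\hat\pi$ bins ($> 0.75 \Rightarrow R = 0$; $(2^{-1.5}, 0.75] \Rightarrow
R = 1$; else $R = 2$). Estimates outside $[0, 1]$ are reported with a flag,
never clamped: on gap-ascertained cohorts with the CR group *less* affected
than the CR-free group the prevalence-mode estimate is legitimately
negative, and seeing that is informative.

A single observed-mode estimate is noisy by construction — it is a
group-mean contrast over a few hundred relatives, with sampling SD around
0.15 at $n = 1000$ — so recovery claims are about means over replicates: the
bundled suite checks that the 50-replicate mean lands within 0.05 of the
generating $h^2$ for $h^2 \in \{0.15, 0.25, 0.32\}$.

## Numerical and interface choices

* All randomness flows from the single `seed` field of a
  [`scenario_config()`]; identical configurations produce byte-identical
  cohorts, and `run_grid()` derives per-replicate seeds deterministically.
* The pairwise scan computes IBS-state tallies by dense indicator-matrix
  cross products; a 1000 × 5000 panel takes ~2 s on one core, so grids of
  hundreds of replicates are practical. The bundled scenario fixtures use
  2000 SNPs / 400 causal — detection power for degree ≤ 2 is saturated well
  below that, and nothing downstream depends on panel size beyond detection.
* Genotypes are exchanged as PLINK text PED/MAP (alleles `A`/`B`, missing
  `0 0`); cohort tables as CSV with a documented header. Round trips are
  exact, including missing calls.
* OLS goes through `stats::lm`; the test suite checks it against a
  hand-rolled normal-equations solve to 10⁻⁸. Rank-deficient designs raise
  an error naming the collinear columns. Heteroskedasticity-consistent (HC1)
  standard errors exist behind `robust = TRUE` but are off by default — the
  scientific object of study is precisely what naive OLS reports when
  relatedness-induced dependence is ignored.
* `{1, 2}`-coded covariates enter regressions untransformed as numeric,
  matching the published model form; missing model variables are handled by
  complete-case deletion with counts recorded.

## The scenario grid

`cr_scenarios()` encodes the five published scenario headers:

| scenario | n | CR ratio | $K_{pop}$ | $K_{\overline{CR}}$ | $K_{CR}$ | $h^2$ |
|---|---|---|---|---|---|---|
| `n1000_h14` | 1000 | 0.202 | 0.25 | 0.26 | 0.26 | 0.143 |
| `n400_h24` | 400 | 0.525 | 0.40 | 0.55 | 0.26 | 0.242 |
| `n400_h32` | 400 | 0.525 | 0.50 | 0.763 | 0.26 | 0.324 |
| `n500_h22` | 500 | 0.42 | 0.40 | 0.50 | 0.26 | 0.221 |
| `n500_h32` | 500 | 0.42 | 0.50 | 0.672 | 0.26 | 0.317 |

(The third setting's published caption and text disagree on the
heritability; the text value 32.4% is used, as it matches the caption's
other knobs.) At 50 replicates each, the baseline scenario rejects
parallelism at roughly the nominal level on every test, while the four
gap scenarios reject essentially always on the 1-df intercept test and
show mean intercept gaps of 3–11 mmHg between the with- and without-CR
fits. The original study draws these subsamples from one real cohort by
(presumably case-enriched) resampling; the generator controls prevalences
directly instead, which makes the mechanism explicit but means published
coefficient values are not reproduction targets.

## What the simulations do and do not show

The generator emulates: unlinked biallelic SNPs in Hardy–Weinberg
equilibrium, mixed-degree relative pairs with exact transmission, a polygenic
liability, independently drawn covariates, uniform genotype missingness and a
treated flag. It does **not** emulate linkage disequilibrium, population
stratification, X-linked loci, genotyping error beyond missingness,
covariate–relatedness correlation, or shared household environment. Passing
suites therefore demonstrate the internal consistency and calibration of the
estimators under the stated model — not that any particular real cohort is
free of, or quantitatively matches, these effects. In particular, because
shared environment is absent, the heritability estimator's recovery here is
an upper bound on its behaviour in data where relatives share households.

## Known limitations

* The degree classification bins misassign a borderline pair occasionally;
  only the $\rho$ weights consume it, and both $\rho$ conventions are
  reported.
* The observed-mode heritability estimator applied to the *detected* CR set
  (rather than known relatives of probands) mixes probands and relatives and
  is biased toward larger magnitudes; it is reported for completeness and
  labelled.
* `keep_one` pruning is exact only per component up to 24 vertices; larger
  components fall back to a greedy cover (and are rare at realistic CR
  fractions).
* EIGENSTRAT-style principal-component adjustment and mixed-model
  (kinship-matrix) alternatives are out of scope by design.
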