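# crconfound

Does undetected close kinship among cohort participants bias the exposure
effects a conventional regression reports? `crconfound` implements the full
analysis chain for that question on a quantitative trait such as systolic
blood pressure (SBP): detect *cryptic relatedness* (CR) from genome-wide SNP
genotypes via method-of-moments identity-by-descent, fit the exposure
regression on the cohort with and without the cryptic relatives, test whether
the two coefficient vectors are parallel, and estimate the heritability of
liability that drives the confounding — together with a synthetic-cohort
generator that plants relative pairs by real gamete dropping so every
estimator can be calibrated against known truth.

## The statistics at the core

* **Relatedness.** For each pair, observed identity-by-state (IBS) counts are
  matched to their expectations under IBD states to solve for
  (Z0, Z1, Z2); the summary is PI_HAT = Z2 + Z1/2, with expectation 2^-R for
  relationship degree R. A pair is called cryptically related when
  PI_HAT > 1/4 (strictly), and the flagged individuals are pruned.
* **Paired regressions.** OLS of
  `sbp ~ bmi + alcohol + smoking + age + gender` on the sample with CR and on
  the sample without it, reported as Estimated / Standard error / t-value /
  Pr(>|t|).
* **Parallel-regressions (Chow-type) test.** F test of b₁ = b₂ between the
  two samples from restricted vs unrestricted residual sums of squares; both
  the full test and a per-term 1-df battery.
* **Heritability of liability.** Falconer-type
  h² = {(x_p − x_q)/a_p}/ρ contrasting the CR-free (p) and CR (q)
  subpopulations, with ρ the relationship weight over the detected degrees
  (literal sum 2^-R, or the pair-count weighted mean; both reported).

See `vignettes/cryptic-relatedness-confounding.Rmd` for the models,
assumptions, design choices and limitations.

## Worked example

Simulate a 400-person cohort in which 52.5% of individuals belong to planted
relative pairs whose lineage carries an elevated polygenic liability
(prevalence 76.3% in the CR-free subpopulation vs 26% among the relatives,
heritability of liability 32.4%), then run the whole chain:

```r
library(crconfound)

cfg <- cr_scenarios()$n400_h32   # one of the five bundled scenario settings
cfg$seed <- 7L
cc  <- simulate_cohort(cfg)

fit <- cr_confound(sbp ~ bmi + alcohol + smoking + age + gender,
                   cc$cohort, genotypes = cc$genotypes)
fit
#> Cryptic-relatedness confounding analysis
#>   samples: with CR n = 400 | without CR n = 218 (removed 182 CR, 0 treated)
#>   detected 91 pair(s) with PI_HAT > 0.25 (182 individuals)
#>   parallel regressions: F = 5.735 (df 6, 606), p = 8.111e-06

round(coef(fit), 2)
#>             with_cr without_cr
#> (Intercept)   79.84      81.63
#> bmi            1.01       1.53
#> alcohol       -0.56      -1.58
#> smoking       -1.82       1.85
#> age            0.39       0.29
#> gender        -3.81      -4.68
```

The detector recovers the planted relatives (182 individuals flagged at
PI_HAT > 1/4), and the parallel-regressions hypothesis is firmly rejected
(p ≈ 8e-06): with a fifth of a standard deviation of genetic trait shift
concentrated in half the cohort, the with-CR and without-CR fits genuinely
disagree. Rerunning the same code on the baseline scenario
(`cr_scenarios()$n1000_h14`, equal subpopulation prevalences) leaves the test
at its nominal level — relatedness alone, without a prevalence gap or with
h² = 0, does not move the regression. `summary(fit)` prints both coefficient
tables and the per-term battery; `plot(fit)` draws the PI_HAT-vs-IBS-distance
diagnostic scatter.

The heritability estimator works from prevalence contrasts alone:

```r
estimate_h2_liability(list(prev_pop = 0.25, prev_nocr = 0.26, prev_cr = 0.35,
                           degrees = 0:2, weights = c(5, 60, 35)),
                      rho_mode = "weighted_mean")
#> Heritability of liability (prevalence mode, rho = 0.4375 [weighted_mean]):
#>   h2 = 0.4640   (x_p = 0.6433, x_q = 0.3853, a_p = 1.2711)
```

and `sample_accounting()` reproduces a quality-control cascade's arithmetic:

```r
sample_accounting(1622, 5, 326, 1039, 829)
#> enrolled 1622 -> post-QC 1617 (removed 5)
#> cryptic relatedness: 326 individuals (20.2%), 1291 CR-free remain
#> treated removed: 578 (with-CR partition), 462 (CR-free partition)
```

Scenario grids (`run_grid(cr_scenarios(), n_reps = 50, base_seed = 1)`)
aggregate coefficient gaps, parallel-test rejection rates and heritability
estimates over replicates with deterministic per-replicate seeds.

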