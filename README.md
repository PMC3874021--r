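# saxsgp

Automated statistical merging of buffer-subtracted small-angle X-ray (or
neutron) scattering profiles collected at different sample concentrations
and exposure times.

Higher concentration and longer exposure buy signal at wide angles but
distort the curve: interparticle interference suppresses the lowest angles,
radiation damage can perturb any region. `saxsgp` merges such profiles into
a single posterior curve while automatically excluding the regions where
they genuinely disagree, and reports the radius of gyration and Porod
exponent with uncertainties.

## Method in brief

Five sequential steps, the first three per profile:

1. **Clean-up** — one-sided one-sample t-tests of each point against zero
   intensity (`t = I√N/s`, Student-t with `N−1` df), Bonferroni-corrected
   at family level α = 0.05; zero-sd points and sd outliers
   (`s > 2 × median`) are dropped.
2. **Fitting** — a semi-parametric Gaussian process: squared-exponential
   kernel `τ² exp(−Δq²/2λ²)` around a nested parametric mean family (flat ⊂
   Guinier-with-offset ⊂ generalized Guinier–Porod with s = 0 ⊂ full
   generalized Guinier–Porod), noise covariance `σ·diag(s²)/N`.
   Hyperparameters by type-II maximum likelihood (Jeffreys prior on σ,
   bounded uniform priors otherwise); model selection by
   Laplace-approximated Bayes factors.
3. **Rescaling** — closed-form weighted least-squares scale factor γ (plus
   optional offset, or a lognormal variant) mapping each fitted profile
   onto a common reference.
4. **Classification** — profiles ranked by a concentration/dose proxy
   (Guinier `I(0) / median(s)`, ascending); each candidate point is
   Welch-tested (Satterthwaite df) against the fitted reference posterior
   at its `q`; incompatible points are excluded; wider profiles hand their
   tails over as the new reference.
5. **Merging** — compatible points are pooled (duplicates resolved by
   smallest sd), the GP is refitted, and the merged posterior with 95 %
   credible bands plus `Rg`/`d` estimates is written out.

See `vignettes/merging-methods.Rmd` for the full model, parameter
conventions, design decisions and limitations.

## Worked example

```r
library(saxsgp)

spec <- synthetic_spec(
  truth = mean_model("guinier", list(A = 20, G = 100, Rg = 20)),
  q_ranges = list(c(0.008, 0.12), c(0.008, 0.25), c(0.008, 0.4)),
  n_points = c(60, 90, 120), gammas = c(1, 2, 4),
  noise = 0.03, N = 10, seed = 1,
  gp_draw = list(tau2 = 13, lam = 0.02),
  perturbations = list(list(profile = 3, q = c(0.008, 0.015),
                            amplitude = -0.08)))
gen <- generate_profiles(spec)

res <- run_pipeline(gen$profiles,
                    run_config(mean = "guinier", reference = 1, seed = 1))
print(res)
```

```
<pipeline_result>  3 profile(s), reference 'synthetic-1'
  scale factors: synthetic-1=1 synthetic-2=0.499 synthetic-3=0.2519 
Merged profile summary
  selected mean model: guinier 
  Rg: 18.96 +- 0.788
  Porod exponent d: not estimable
  log evidence: -433.617
  duplicates dropped: 2
  retention by profile:
       label input cleaned_out incompatible extension kept
 synthetic-1    60           0            0         0   60
 synthetic-2    90           0            1        48   89
 synthetic-3   120           0            9        46  111
```

Three profiles at relative concentrations 1:2:4 were simulated from one
Guinier-type truth (`Rg = 20`, plus a smooth non-parametric deviation),
with an 8 % interference suppression injected at the lowest angles of the
most concentrated profile. The pipeline estimated the scale factors (true
values 0.5 and 0.25), excluded the perturbed low-`q` points of profile 3
while keeping its wide-angle tail (the `extension` column), and recovered
`Rg` — the smooth deviation on top of the ideal Guinier curve shifts the
best-fitting parametric `Rg` slightly, which the reported uncertainty
reflects.
`write_merged(res$merged, "merged.dat")` writes the annotated points and
the posterior curve with credible half-widths.

Real data enter the same way via three-column text files:
`run_pipeline(c("a.dat", "b.dat"), run_config(), N = c(10, 10))`, or from
the shell with the thin CLI in `inst/scripts/saxsgp.R`
(`merge`, `fit` and `simulate` subcommands).

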