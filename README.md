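# cenmediate

Causal mediation analysis when the **mediator is right-censored** and the
**exposure is categorical** — the situation of, say, a SNP genotype (rr /
Rr / RR) acting on type 2 diabetes risk partly through age at menopause,
which is censored for women who have not yet reached menopause.

For subject *i* we observe the outcome *y<sub>i</sub>* (continuous or
binary), the censored mediator *m<sub>i</sub>* = min(*t<sub>i</sub>*,
*c<sub>i</sub>*) with event indicator *δ<sub>i</sub>* =
I(*t<sub>i</sub>* ≤ *c<sub>i</sub>*), the exposure category, and optional
covariates *z<sub>i</sub>*. With dummy coding *X*₁, …, *X*<sub>k−1</sub>
against a reference category, the models are a semiparametric accelerated
failure time (AFT) model for the mediator and a linear or logistic model
for the outcome in the log-scale mediator:

    log t_i = a_0 + Σ_j a_j x_ji + γ̃' z_i + ε_i          (ε unspecified)
    g(E[y_i | t_i, x_i, z_i]) = b_0 + b log t_i + Σ_j c̃_j x_ji + γ' z_i

Estimation is two-stage:

1. **IPCW weighted least squares** for the AFT coefficients, with weights
   δ<sub>i</sub> w<sub>i</sub> / Ĝ(m<sub>i</sub>−) from the Kaplan–Meier
   censoring-survival curve Ĝ (closed form), followed by a Kaplan–Meier
   estimate η̂ of the AFT error distribution from the residuals.
2. **Pseudo-likelihood** for the outcome coefficients, where censored
   subjects integrate the outcome probability over η̂ beyond their
   censoring residual (trust-region Newton with analytic derivatives).

Per-category natural effects IE<sub>j</sub>, DE<sub>j</sub> (category
*d<sub>j</sub>* versus reference) are then combined into **overall**
measures with the exposure-category frequencies *f<sub>j</sub>*
(renormalized over the non-reference categories):

    IE = Σ_j f_j IE_j_versus_0,   DE = Σ_j f_j DE_j_versus_0,
    TE = IE + DE,                 PM = IE / TE.

Inference is by **BCa bootstrap** over the full pipeline (both Kaplan–Meier
curves and both stages re-estimated per replicate), stratified by outcome
class in case-control designs, which also support inverse-prevalence
sampling weights. A simulation engine generates Hardy–Weinberg genotypes,
AFT mediators, censoring calibrated to a target rate, and cohort or
case-control samples, and a replicate-study harness summarizes coefficient
and effect recovery.

## Worked example

Simulate one case-control study (MAF 0.3, per-allele a = b = 0.4, per-allele
c̃ = 0.5, ~20% censoring, ~30% prevalence, 500 cases / 500 controls) and
analyse it:

```r
library(cenmediate)

sc <- simulation_scenario(family = "binary", maf = 0.3, a0 = 6, a = 0.4,
                          b0 = -3.7, b = 0.4, c_tilde = 0.5, cp_target = 0.2,
                          n_case = 500, n_control = 500)
d <- simulate_mediation(sc, seed = 7)
fit <- mediate_censored(d, reference = "rr", prevalence = attr(d, "prevalence"))
fit
#> <censored_mediation> n = 1000, binary outcome, 22.7% censored mediator
#>
#> Stage 1 (AFT, log-time scale):
#> (Intercept)        x_Rr        x_RR
#>      6.0306      0.4466      0.8496
#>
#> Stage 2 (outcome model):
#>  (Intercept) log_mediator         x_Rr         x_RR
#>      -3.2961       0.3238       0.5471       0.9432
#>
#> Overall effects:
#>  term   estimate
#>    IE 0.03768359
#>    DE 0.11935660
#>    TE 0.15704020
#>    PM 0.23996145
```

The stage-1 coefficients recover the generating paths (a₁ = 0.4, a₂ = 0.8),
the stage-2 coefficients the outcome paths (b = 0.4, c̃₁ = 0.5, c̃₂ = 1)
up to single-replicate noise. The overall indirect effect 0.038 is the
frequency-weighted average change in disease probability attributable to
the mediator pathway (its theoretical value under these parameters is
0.0418); PM says about 24% of the total effect is mediated. BCa intervals:

```r
bt <- bootstrap_effects(fit, B = 200, seed = 7, accel = "none")
bt[bt$term %in% c("IE", "DE", "TE", "PM"), ]
#>  term estimate  lower  upper significant
#>    IE   0.0377 0.0220 0.0572        TRUE
#>    DE   0.1194 0.0751 0.1697        TRUE
#>    TE   0.1570 0.1142 0.2042        TRUE
#>    PM   0.2400 0.1267 0.3832        TRUE
```

`tidy()`, `glance()` and `autoplot()` methods are available on all fitted
objects; `run_simulation_study()` reruns whole scenario grids. A thin CLI
(`exec/cenmediate`, subcommands `fit`, `simulate`, `ci`) wraps the same
functions for shell use; see `?cli_run`.

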