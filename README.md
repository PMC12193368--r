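# twosexlt

Age-stage, two-sex life tables for insect cohort data, with bootstrap
inference and stage-structured population projection.

Classical female-only life tables ignore males and force every individual
through identical stage schedules. The age-stage, two-sex framework instead
follows every individual of a daily-censused cohort — both sexes, variable
developmental rates, preadult deaths included — through an age × stage grid.
`twosexlt` implements that framework end to end for rearing designs of the
kind used to evaluate population-level effects of a treatment (for example,
RNAi-based pest control trials on western flower thrips, *Frankliniella
occidentalis*, where cohorts of 40 eggs are reared on treated diet until the
last individual dies). It is aimed at entomologists and ecologists who want a
scriptable, reproducible alternative to spreadsheet-style life-table tools.

## The model

From per-individual records (stage entry ages, sex, death age, daily egg
counts) the package tabulates

- **s_xj** — probability a newborn is alive at age *x* (days) in stage *j*
  (egg, nymph, pupa, female adult, male adult),
- **f_xj** — eggs laid at age *x* per female-stage individual,
- **l_x = Σ_j s_xj**, **m_x = Σ_j s_xj f_xj / l_x**, and the net maternity
  **l_x m_x**,

and derives the scalar parameters

- net reproductive rate **R₀ = Σ_x l_x m_x**, which in the two-sex convention
  satisfies the exact identity **R₀ = F · N_f / N** (mean eggs per adult
  female times the female fraction of the whole cohort),
- intrinsic rate of increase **r** solving the Euler–Lotka equation
  **Σ_x e^(−r(x+1)) l_x m_x = 1** (daily age classes indexed from 0; solved by
  bisection to a residual below 1e−10),
- finite rate **λ = e^r** and mean generation time **T = ln(R₀)/r**,
- age-stage life expectancy **e_xj** and reproductive value **v_xj**, obtained
  by propagating virtual individuals through the cohort's observed daily
  transition kernel,
- the preadult mortality distribution (fraction of the original cohort dying
  in each stage).

Standard errors for every parameter come from resampling the N individuals
with replacement (the TWOSEX-style individual bootstrap); two treatments are
compared with a paired bootstrap test. A deterministic, TIMING-style
projection propagates any initial age-stage composition day by day under
unlimited growth. A calibrated generator simulates synthetic cohorts for both
treatment presets so the entire pipeline can be exercised without access to
raw rearing data.

## Worked example

```r
library(twosexlt)

coh <- simulate_cohort(cohort_preset("dsEGFP-like"), seed = 2)
coh
#> <cohort_table> 'dsEGFP-like': 40 individuals (18 female, 16 male, 6 preadult deaths)
#>   stages: egg > nymph > pupa > adult; daily census; max death age 126

lifetable_params(coh)
#> <life_table_params> 'dsEGFP-like' (N = 40: 18 female, 16 male)
#>   r = 0.1466 /d   lambda = 1.1578 /d   R0 = 90.9500   T = 30.7741 d
#>   F (eggs per adult female) = 202.1111
#>   preadult mortality: egg 0.000, nymph 0.050, pupa 0.100
#>   peak reproductive value 47.39 at age 23 d

bootstrap_params(coh, B = 2000, seed = 2, params = c("r", "lambda", "R0", "T"))
#> <bootstrap_result> B = 2000 resamples (0 degenerate, R0 = 0), seed = 2
#>  parameter estimate boot_mean   boot_se n_valid
#>          r   0.1466     0.146  0.007575    2000
#>     lambda   1.1578     1.157  0.008745    2000
#>         R0  90.9500    91.339 16.454330    2000
#>          T  30.7741    30.825  0.788247    2000
```

A cohort growing at r ≈ 0.147/day multiplies λ ≈ 1.16-fold per day; each
newborn leaves R₀ ≈ 91 offspring over a generation of T ≈ 31 days, and the
bootstrap SEs (± 0.0076 on r, ± 16.5 on R₀) quantify the cohort-sampling
uncertainty. Comparing against a knockdown-like cohort:

```r
tps <- simulate_cohort(cohort_preset("dsFoTPS-like"), seed = 3)
compare_cohorts(coh, tps, B = 2000, seed = 4,
                params = c("r", "R0", "fecundity", "TPOP"))
#>   parameter estimate_A  mean_A     se_A estimate_B mean_B    se_B difference p_value significant
#> 1         r      0.147   0.146  0.00754       0.12  0.119 0.00807     0.0269   0.021        TRUE
#> 2        R0     90.950  91.045 16.59767      24.50 24.634 4.57208    66.4117   0.001        TRUE
#> 3 fecundity    202.111 202.243 10.86182      54.44 54.495 3.42001   147.7479   0.001        TRUE
#> 4      TPOP     20.111  20.122  0.53732      19.11 19.128 0.79736     0.9934   0.299       FALSE
```

The knockdown-like cohort grows significantly more slowly (lower r, R₀ and
fecundity; paired bootstrap test at the 5% level). Projection and report
generation:

```r
sched <- build_schedule(coh)
proj <- project_population(sched, c(egg = 10), days = 100)
run_lifetable(coh, out_dir = "report", B = 1000, seed = 2)   # JSON + CSV + PDF
```

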