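# bnmmi

Bayesian-network-based identification of missing-data mechanisms for
categorical datasets with one incompletely observed variable.

## Why

The choice between complete-case analysis, multiple imputation and
everything in between hinges on the missing-data mechanism — MCAR
(missingness independent of everything), MAR (dependent only on observed
variables) or MNAR (dependent on the unobserved value). The usual
diagnostics are hypothesis tests of "the mechanism is MCAR", and a
non-rejection is not evidence for the null. `bnmmi` instead *learns the
structure* of the missingness:

1. **Prepare** — replace the incomplete variable by its dichotomous missing
   indicator (0 = observed, 1 = missing), giving a complete dataset.
2. **Learn** — estimate the Bayesian network over the indicator and the
   observed variables by score-based hill climbing (BIC by default),
   starting from the empty graph.
3. **Assess & identify** — bootstrap the data N times and re-learn; the
   structure is credible only if each of its relations recurs in ≥ 90% of
   replicates (an expert-specified structure can be compared in the same
   pass). If credible: no arc at the indicator ⇒ **MCAR**; any arc ⇒
   **not MCAR** (MAR or MNAR — indistinguishable, since the missing values
   are unobserved). If not credible: **inconclusive**.

The package also ships the clinical chain simulator
(`tumor_type -> operation -> twoweeks`, with MCAR or MAR missingness of a
fee variable) and the evaluation machinery (validity, simulation
consistency, robustness, a logistic-regression comparator, 2×2
contingency statistics) used to calibrate the method.

## Worked example

Simulate 2000 patient records with 15% MAR missingness of `fee` (missing
more often without an operation), then identify the mechanism:

```r
library(bnmmi)

d <- simulate_scenario("MAR", rate = 0.15, n = 2000, seed = 42)
fit <- bnmmi(d, indicator = "fee_missing", n_boot = 2000, seed = 1)
fit
#> Missing mechanism identification (2000 records, 4 variables, indicator 'fee_missing')
#> Learned structure: tumor_type -> operation; operation -> twoweeks; operation -> fee_missing
#> Credibility      : credible (threshold 90%, N = 2000)
#> Missing mechanism verdict for 'fee_missing': not MCAR; MAR or MNAR (indistinguishable without the missing values)
#>   evidence: fee_missing|operation

fit$credibility
#> Bootstrap credibility assessment (threshold 90%, N = 2000)
#>   fee_missing|operation          100.00%  ok
#>   operation|tumor_type           100.00%  ok
#>   operation|twoweeks              99.25%  ok
#> => credible
```

The learned structure recovers the generating chain, and the arc between
`operation` and `fee_missing` — reproduced in 100% of bootstrap
replicates, far above the 90% credibility threshold — rules out MCAR. On
raw data with `NA` cells, `bnmmi(data)` finds the incomplete variable
itself and builds the indicator; `summary()`, `coef()`, `plot()` and
`simulate()` methods expose the credibility table, the fitted conditional
probability tables, the graph and ancestral sampling from it.

Lower-level pieces are exported individually (`make_missing_indicator()`,
`hill_climb()`, `bootstrap_replicates()`, `assess_credibility()`,
`compare_with_expert()`, `identify_mechanism()`, `run_experiment()`, ...),
and `inst/cli/bnmmi.R` is a thin command-line front end with `identify`,
`simulate` and `evaluate` subcommands.

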