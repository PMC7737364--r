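# cs1decision

Decision analysis of chemotherapy exposure in clinical stage I (CS1)
pediatric testicular germ cell tumors: **surveillance** (observe everyone,
treat relapses) versus **risk-adapted treatment** (one adjuvant PEB cycle
for high-risk children, surveillance for the rest). Survival is ~100%
under both, so the strategies are compared on *expected toxicity-weighted
chemotherapy cycles* — salvage/primary PEB cycles count 1 each, second-line
VIP cycles count an elicited multiplier (1.3) each. The audience is anyone
building or auditing small decision-analytic models of treatment burden:
pediatric urologists/oncologists and health-decision scientists.

With $R = n_{salv} + p_{sc}\,n_{2nd}\,t$ the expected toxicity of the
salvage cascade, the two expectations are

$$E_{surv} = [\,p_{low}p_{rl} + (1-p_{low})p_{rh}\,]\,R,\qquad
E_{RA} = p_{low}p_{rl}R + (1-p_{low})(n_{prim} + p_{pc}R),$$

and their difference factorizes through the high-risk arm, so only the
high-risk relapse rate $p_{rh}$ and the post-primary-chemotherapy relapse
rate $p_{pc}$ can change which strategy is preferred.

The package provides:

* a small chance/terminal decision-tree engine with expected-value
  rollback, symbolic parameter-bound probabilities/payoffs, and an
  auditable JSON tree schema (`rollback()`, `serialize_tree()`);
* the two strategy trees and their closed-form oracles
  (`build_surveillance_tree()`, `closed_form_exposure()`,
  `compare_strategies()`);
* one-way/two-way deterministic sensitivity analysis with exact affine
  threshold solving cross-checked by bisection (`one_way_sweep()`,
  `find_threshold()`, `two_way_sweep()`);
* visual-analog-scale survey ingestion and aggregation, with the packaged
  24-respondent elicitation survey (`cs1_vas_survey()`,
  `summarize_survey()`, `derive_toxicity_ratio()`);
* synthetic-data generators — simulated surveys and Monte-Carlo patient
  cohorts — that make every stage testable and give the analytic results an
  independent stochastic cross-check (`generate_survey()`,
  `simulate_cohort()`);
* one-shot reporting (`run_base_case()`, `run_full_replication()`).

The `analysis/` directory holds the numbered drivers that walk through the
full analysis (survey → base case → one-way → two-way → microsimulation),
writing tables under `results/`.

## Worked example

```r
library(cs1decision)

compare_strategies(base_parameters())
#> Expected toxicity-weighted chemotherapy exposure
#>   surveillance : 1.3419 cycles
#>   risk-adapted : 0.8875 cycles
#>   difference   : 0.4543 (surveillance - risk-adapted)
#>   preferred    : risk_adapted

find_threshold("pRelapsePostPrimChemo")
#> Threshold analysis for pRelapsePostPrimChemo
#>   equal exposure at pRelapsePostPrimChemo = 0.287 (full precision 0.2870109546)
#>   preferred below: risk_adapted; above: surveillance

summarize_survey(cs1_vas_survey())
#> VAS elicitation survey: 24 respondents
#>   first_line   mean 0.841, SD 0.081, 95% CI 0.807-0.876
#>   second_line  mean 0.635, SD 0.151, 95% CI 0.571-0.699
#>   toxicity ratio (first/second line): 1.3244 (1.3 at 1 decimal)

simulate_cohort("surveillance", base_parameters(), n = 200000, seed = 1)
#> Simulated cohort (surveillance): n = 200000, mean exposure 1.3405 cycles (SE 0.0037)
#>   ...
```

Reading: under surveillance the average child receives 1.34
toxicity-weighted cycles versus 0.89 under risk-adapted treatment, so
risk stratification spares chemotherapy at the base case; that preference
holds until the relapse rate after one adjuvant cycle exceeds 0.287; the
survey says clinicians rate the second-line health state 0.635 versus
0.841 for first-line, making one VIP cycle as burdensome as 1.3 PEB
cycles; and a 200,000-patient microsimulation lands well within two standard
errors of the analytic 1.3419.

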