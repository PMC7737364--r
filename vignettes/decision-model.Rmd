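---
title: "A decision model of chemotherapy exposure in stage I pediatric testicular cancer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A decision model of chemotherapy exposure in stage I pediatric testicular cancer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cs1decision)
```

## The clinical question

Clinical stage I (CS1) pediatric testicular germ cell tumors — predominantly
yolk sac tumors confined to the testis — are almost universally cured:
overall survival approaches 100% whichever management strategy is chosen
after radical inguinal orchiectomy. What differs between strategies is how
much chemotherapy the average child receives, and chemotherapy in this
population carries life-long toxicity (ototoxicity, nephrotoxicity,
infertility). Two strategies are compared:

* **Surveillance**: every child is observed; a relapse (detected during
  follow-up) is treated with 3 salvage cycles of PEB (cisplatin, etoposide,
  bleomycin), and failure to reach a complete response is treated with 3
  second-line cycles of VIP (etoposide, ifosfamide, cisplatin).
* **Risk-adapted treatment**: children stratified as high-risk (e.g.
  lymphovascular invasion) receive 1 primary (adjuvant) cycle of PEB up
  front and low-risk children undergo surveillance; relapses in either
  group are treated with the same salvage-then-second-line cascade.

Because survival is equal, the payoff is not life-years but **expected
toxicity-weighted chemotherapy cycles**: each salvage/primary PEB cycle
counts 1, each second-line VIP cycle counts `tSecondChemo` (1.3 at the base
case), and the strategy with the *lower* expectation is preferred.

## The model

Each strategy is a finite chance/terminal decision tree over six
parameters (see `?parameter_set` for defaults and ranges). Writing
$p_{low}$ for the proportion of low-risk patients, $p_{rl}, p_{rh}$ for the
relapse rates of the low- and high-risk groups under surveillance, $p_{pc}$
for relapse after primary chemotherapy, $p_{sc}$ for progression after
salvage, and $t$ for the second-line toxicity multiplier, the expected
toxicity of the salvage cascade is

$$R = n_{salv} + p_{sc}\, n_{2nd}\, t = 3 + 0.05 \cdot 3 \cdot 1.3 = 3.195$$

and the strategy expectations reduce to

$$E_{surv} = \left[p_{low} p_{rl} + (1-p_{low}) p_{rh}\right] R, \qquad
E_{RA} = p_{low} p_{rl} R + (1-p_{low})\left(n_{prim} + p_{pc} R\right).$$

The package evaluates the trees two independent ways — symbolic-expression
rollback (`rollback()`) and these closed forms (`closed_form_exposure()`) —
and property-tests their agreement to within $10^{-12}$ over 1000 random
parameter sets; a Monte-Carlo microsimulation (`simulate_cohort()`), which
samples every branch event per virtual patient and is structurally
independent of both, provides a third, stochastic route.

```{r base-case}
compare_strategies(base_parameters())
```

The difference factorizes as

$$E_{surv} - E_{RA} = (1-p_{low})\left[p_{rh} R - n_{prim} - p_{pc} R\right],$$

so the *preferred* strategy depends only on $p_{rh}$ and $p_{pc}$ (and on
$R$ through magnitude, not sign, at base values): $p_{low}$, $p_{rl}$,
$p_{sc}$ and $t$ can never flip the decision, which is exactly what the
one-way sweeps show.

## Parameters and where they come from

| parameter | default | range | meaning |
|---|---|---|---|
| `pLowRisk` | 0.40 | 0–1 | proportion of low-risk patients |
| `pRelapseLowrisk` | 0.15 | 0.10–0.20 | relapse under surveillance, low risk |
| `pRelapseHighrisk` | 0.60 | 0.38–0.73 | relapse under surveillance, high risk |
| `pRelapsePostPrimChemo` | 0.05 | 0.01–0.10 | relapse after 1 primary PEB cycle |
| `pRelapsePostSalvChemo` | 0.05 | 0.01–0.22 | progression after 3 salvage PEB cycles |
| `tSecondChemo` | 1.3 | 1.0–2.0 | per-cycle toxicity, VIP vs PEB |

All defaults except `pLowRisk` are literature point estimates. **`pLowRisk`
has no published point estimate** (only the trivial 0–1 domain); 0.40 is
the unique value under which the surveillance expectation reproduces the
published base case of 1.3419 cycles, and it ships as a documented,
overridable default (`base_params.yaml` carries the same caveat). This
reconstruction is harmless for the decision itself because of the
factorization above.

`tSecondChemo` is not a literature value but an elicited one: 24
urological oncologists scored three health states on a 0–100 visual analog
scale (no chemotherapy, first-line, second-line). Each arm score is divided
by the respondent's no-chemotherapy anchor to give a relative value,
tabulated at 3 decimals; the arm means are 0.841 (SD 0.081) and 0.635
(SD 0.151), and their ratio, 0.841/0.635 = 1.3244, rounds to the 1.3 used
in the tree. Three deliberate conventions here:

* **sample (n−1) standard deviations** — these reproduce the published
  0.081/0.151; population SDs would give 0.080/0.148;
* **rounding half away from zero** for tabulation (`round_half_up()`):
  65/80 = 0.8125 tabulates as 0.813, as in the published table; banker's
  rounding would print 0.812;
* **aggregation of the 3-decimal tabulated values**, which is what makes
  the means exactly 0.841/0.635.

The 95% confidence intervals are Student-t on the mean (0.807–0.875 for
the first line). The originally published intervals (0.811–0.871 and an
asymmetric 0.578–0.697) match neither a t nor a normal formula; we compute
the t interval and document the discrepancy rather than reverse-fitting an
undisclosed method.

## Sensitivity analyses and thresholds

One-way sweeps (`one_way_sweep()`) evaluate both strategies on a uniform
grid (default 101 points — smooth plots at negligible cost) over a
parameter's full validity domain unless a narrower range is requested:
probabilities over \[0, 1\], `tSecondChemo` over its elicited analysis
range \[1, 2\].

Because each exposure is affine in any single parameter (holding the rest
fixed), the break-even point can be solved exactly from two endpoint
evaluations; `find_threshold()` does this after verifying affinity at the
midpoint (within $10^{-9}$), and a bisection solver (`stats::uniroot`)
serves as an independent cross-check in the test-suite (agreement within
$10^{-9}$). Displayed thresholds are rounded half-up to 3 decimals, full
precision is retained in the result:

```{r thresholds}
find_threshold("pRelapsePostPrimChemo")
find_threshold("pRelapseHighrisk")
```

Degenerate sweeps are reported, not raised: a parameter the difference does
not depend on (e.g. `pRelapseLowrisk`) returns no threshold with an
explanatory flag, as does an identically-zero difference (`pLowRisk = 1`,
where the two arms coincide).

Two-way sweeps (`two_way_sweep()`) classify the full factorial grid and
extract the preference boundary by linear interpolation between
sign-changing neighbours — exact here, since the difference is affine along
each grid line. Ties within $10^{-12}$ are labelled indifferent and counted
with neither strategy. In the `pRelapsePostPrimChemo` ×
`pRelapseHighrisk` plane the boundary is the line

$$p_{rh} = p_{pc} + \frac{n_{prim}}{R} = p_{pc} + 0.313,$$

with risk-adapted treatment preferred everywhere above it; the test-suite
checks this cell by cell.

## Reproducibility notes and known discrepancies

Three published figures are *not* reproduced by the canonical model, and
deliberately so:

1. **Risk-adapted base case 0.7965.** The canonical tree gives 0.88755 at
   `pLowRisk = 0.40`. The published figure is matched exactly by a variant
   in which the 0.05 progression probability is applied twice in the
   high-risk arm ($0.4 \cdot 0.15 \cdot 3.195 + 0.6(1 + 0.05^2 \cdot 3.195)
   = 0.7965$) — plausibly a wiring artifact in the original software model.
   We implement the canonical structure and surface the caveat in every
   base-case report.
2. **`pRelapseHighrisk` threshold 0.365.** The closed form
   $p_{pc} + 1/R = 0.363$; the 0.365 cannot be derived from the stated
   parameters. Both solvers here agree on 0.363.
3. **The two-way rule of thumb** "risk-adapted preferred when
   $p_{pc} \le 0.10$ and $p_{rh} \ge 0.40$" is a rounded reading of the
   boundary line: cells with $p_{pc} \in (0.087, 0.10]$ and
   $p_{rh} \in [0.40, p_{pc} + 0.313)$ — including the corner
   $(0.10, 0.40)$ itself, where the difference is $-0.0415$ — prefer
   surveillance. The corresponding end-to-end test asserts the rule as
   stated and is expected to fail; the cell-by-cell boundary-line property
   is what holds exactly.

## The synthetic-data generators

`generate_survey()` emulates the elicitation instrument: an integer anchor
score uniform on 85–100 (the typical anchor range), latent relative values
drawn from normals truncated to (0, 1\] at the target means/spreads
(defaults 0.841/0.081 and 0.635/0.151), then mapped back to integer VAS
scores. Integer mapping quantizes realized relative values by up to
0.5/anchor (≈ 0.006), so a zero-spread configuration pins values to the
target only within that resolution — the price of emulating how real
respondents mark an integer scale. What the generator does *not* emulate:
respondent-level correlation between the two arms beyond what the common
anchor induces, clustering by institution, or anchoring drift across the
interview; recovery of the configured means by `summarize_survey()` is
therefore a check of the pipeline's statistics, not evidence about real
elicitation behaviour.

`simulate_cohort()` walks virtual patients through a strategy
branch-by-branch (risk group, relapse, post-salvage progression as
independent Bernoulli draws) rather than sampling terminal paths from their
enumerated probabilities, so it cannot inherit an error in the rollback's
path algebra. It does not model relapse timing, calendar follow-up or
survival — the model compares toxicity burden only, on the premise that
survival is equivalent.

Seeds are explicit arguments everywhere; seeded calls restore the caller's
RNG state. Test-suite problem sizes: 1000 random parameter sets for the
oracle-equivalence property, 20 × 100,000 patients for the microsimulation
band (3 standard errors, with the expected rare excursion tolerated),
200,000 patients for the base-case cross-check, 2000 respondents for
generator recovery (±0.02).

## Limitations

The model inherits the simplifications of the original analysis: toxicity
is linear in weighted cycle counts (no per-agent side-effect profile);
second-line chemotherapy always succeeds; surgery or radiotherapy after
chemotherapy, relapse timing, and quality-adjusted life-years are out of
scope; and the parameter estimates come from small, partly adult,
literature series. The sensitivity machinery exploits that both exposures
are affine in each single parameter — user-built trees violating that
(e.g. with probability products of two swept parameters along one branch)
are handled by the grid/bisection paths but not by the closed-form
threshold solver, which verifies affinity before trusting itself.
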