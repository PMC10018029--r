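---
title: "Model structure and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model structure and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The decision problem

Acute decompensated heart failure (ADHF) carries a high risk of readmission
and cardiovascular death in the first months after discharge.
Sacubitril–valsartan reduces both risks relative to enalapril, but costs
more, and in China its price changed sharply when it entered the collective
purchasing list. `svcea` implements a lifetime cost-effectiveness comparison
of three treatment strategies for a cohort hospitalized with ADHF at age 60,
from the Chinese healthcare-system perspective:

* **enalapril** throughout;
* **early initiation** — sacubitril–valsartan started during the index
  admission and continued for life;
* **late initiation** — enalapril until the patient has gone three
  consecutive months without hospitalization, sacubitril–valsartan
  thereafter.

The primary endpoint is the incremental cost-effectiveness ratio (ICER),
incremental discounted cost over incremental discounted QALYs, judged
against a willingness-to-pay (WTP) threshold of three times the 2021
per-capita GDP of China (242,928 CNY, i.e. 37,654.5 USD at the 2021 average
exchange rate of 6.4515 CNY/USD).

## State space

The model is a Markov cohort with a one-month cycle. Clinically it has four
transition states — hospitalized HF, and the first, second, and
third-or-later non-hospitalized months — plus two absorbing states,
cardiovascular death and non-cardiovascular death. The two post-discharge
months are tunnel states: each can be occupied for at most one cycle per
visit, which encodes the elevated ("vulnerable-phase") risks of the first
two months after discharge. The third non-hospitalized month is the
self-looping **stable** state with lower ("stable-phase") risks. Deaths
within the two vulnerable months are counted as cardiovascular;
age-dependent background (non-cardiovascular) mortality applies only from
the stable state, via a six-band life table (ages 60–64 through 85+, both
arms share the table).

Internally every alive non-stable state carries a phase tag, *pre* or
*post* first stabilization, giving nine expanded states. The tag is what
lets the late-initiation strategy's switching history be expressed in a
memoryless transition matrix: the whole cohort starts in the pre-phase
hospitalized state, and the stable state routes its readmissions into the
post-phase hospitalized state.

## Strategies and the late-initiation switch

A strategy is a rule mapping expanded state to active drug
(`strategy_spec()`). Enalapril and early initiation are constant maps. Late
initiation uses enalapril in all pre-phase states and sacubitril–valsartan
in the stable state. For hospitalization episodes occurring *after* the
first stabilization the package's default is to parameterize the episode —
its risks, drug cost, and utility — with the reference (enalapril-arm)
vulnerable-phase values until the patient re-stabilizes
(`relapse_drug = "ena"`). The rationale is evidential rather than
pharmacological: the vulnerable-phase parameter pair contrasts in-hospital
initiation against control, so it describes patients whose
sacubitril–valsartan exposure begins with the episode, and in the
late-initiation philosophy a destabilized patient is back in the situation
in which the drug had not yet shown its vulnerable-phase benefit. This
choice also reproduces the published incremental results far more closely
than the alternative; the alternative reading — once switched, vulnerable-phase episodes keep the
treated parameters — is available as `strategy_spec("sv_late",
relapse_drug = "sv")` for comparison.

## Parameter derivations

All inputs ship as a flat YAML configuration
(`inst/extdata/base_case.yaml`) and load with `base_case_inputs()`.

* **Probabilities.** Trial event counts over a follow-up period are
  converted to monthly probabilities by the constant-rate identity
  `p = 1 - (1 - events/at_risk)^(1/period)` (`monthly_prob_from_period()`).
  Where a treated arm is only characterized by a hazard ratio, the ratio is
  applied to the reference event *count* before conversion
  (`monthly_prob_with_hazard_ratio()`); applying it after conversion would
  change the fourth decimal. The vulnerable-phase enalapril values have no
  printed count derivation and are terminal inputs.
* **Costs.** Historical CNY costs are inflated through the 2015–2021
  healthcare CPI chain and divided by the 2021 exchange rate
  (`inflate_and_convert_cost()`). The annual discount rate is the geometric
  mean of the CPI chain minus one (`derive_discount_rate()`, 0.0304),
  fixed at its working value 0.03 in the base case.
* **Utilities.** Annual utilities on treatment divide by 12 to monthly
  values (0.0698 and 0.0691 QALY/month); each hospitalization event costs a
  one-off 0.1 QALY.

## Accrual conventions

Three conventions matter and are deliberate:

1. **Costs accrue only in non-hospitalized alive months.** The background
   "enalapril + standard care" cost (37.9 USD/month) applies to every
   strategy; the sacubitril–valsartan acquisition cost (50.5 USD/month) is
   added in months where it is the active drug. Hospitalized months carry
   no monthly drug cost — the hospitalization itself is costed as an event.
   This additive treatment (treated arms pay the background *plus* the new
   drug) reproduces the published occupancy-cost decomposition to within
   about 1%.
2. **Events are dated, occupancy is half-cycle corrected.** Monthly
   cost/utility/life-year accruals use the trapezoidal average of
   consecutive trace rows and the mid-cycle discount factor
   `(1+r)^-(t+0.5)/12`. Hospitalization events (cost 2,361.5 USD, utility
   −0.1; the index admission at cycle 0 included) are counted at the inflow
   cycle's start-of-cycle factor `(1+r)^-t/12`. Utilities and life-years
   accrue in **all** alive months, including hospitalized ones.
3. **Horizon.** "Lifetime" is realized as 480 monthly cycles (age 60 to
   100). Under base-case mortality fewer than 0.7% of the cohort is alive
   at the horizon; residual mass is carried to the last cycle and dropped.
   Runs are exactly reproducible because the model is deterministic.

Competing risks within a cycle are additive: exit probabilities are summed
and the remainder goes to the progression target, mirroring the state
diagram. Every base-case sum is far below one and validation rejects any
parameter set where a sum reaches one.

## Sensitivity analyses

* **One-way (tornado).** Each parameter with a published range is set to
  its bounds, everything else held at base, and the early-initiation vs
  enalapril ICER recorded (`one_way()`, `tornado()`). The discount rate
  varies 0–0.06. Entries sort by bar width; under base inputs the
  sacubitril–valsartan price dominates.
* **Probabilistic.** `run_psa()` draws every parameter that carries an SD
  and distribution family — beta for probabilities and monthly utilities
  (moment-matched to the base value and SD), gamma for costs, and the
  hospitalization disutility as a beta on its magnitude, negated — runs
  both arms per draw, and reports acceptability as the fraction of draws
  with positive incremental net monetary benefit at the WTP threshold.
  Draws are independent across parameters (no correlation structure is
  published). Structurally invalid draws are rejected and redrawn with a
  logged count, rather than clamped, so the sampled moments stay unbiased;
  at base inputs rejections are a handful per 10,000 (utility draws above
  the 1/12 monthly ceiling). The default of 10,000 iterations gives a
  binomial standard error of about 0.2 percentage points on a 97%
  acceptability. `ceac()` evaluates the acceptability curve on a 0–50,000
  USD grid (100 USD steps) and `ceac_crossing()` bisects for the 0.5
  crossing to a 0.1 USD resolution.

## Verification strategy

The test suite cross-checks the cohort engine against an independent
individual-level micro-simulation (`micro_simulation_oracle()`), which
shares only the transition rows with the engine — its accrual arithmetic is
written separately — and agrees within three Monte Carlo standard errors on
cost, QALY and LY (10^6 simulated patients over a 60-cycle reduced horizon;
the reduction keeps the check to seconds while exercising every state).
Degenerate configurations (no transitions, zero discount) are checked
against closed forms. A synthetic parameter-set generator
(`synthetic_parameter_set()`) produces seeded, structurally valid inputs —
vulnerable-phase risk above stable-phase risk, treated risk below reference
risk — for property tests: mass conservation (row sums within 1e-12),
monotone absorption, the tunnel bound, and benefit monotonicity. Synthetic
sets emulate the *structure* of plausible inputs, not Chinese ADHF
epidemiology; passing them shows the machinery is sound, not that any
particular clinical claim transfers.

## Known limitations

* Adverse-event costs are excluded (their treatment costs were reported
  negligible in the source trial), and only direct drug and hospitalization
  costs enter; no societal-perspective indirect costs.
* PSA draws ignore parameter correlation; trial-level correlations between
  death and readmission effects are not published.
* The life table and starting age are fixed in all sensitivity analyses
  (no published ranges).
* Outcomes are reported in USD only, at the fixed 2021 exchange rate.

## A worked run

```{r, eval = FALSE}
library(svcea)
inputs <- base_case_inputs()
ena <- run_strategy(strategy_spec("enalapril"), inputs$params, inputs$lt)
sve <- run_strategy(strategy_spec("sv_early"), inputs$params, inputs$lt)
compute_icer(ena, sve)
#> sv_early vs enalapril: dC 4997.7 USD, dE 1.3921 QALY, ICER 3590.0 USD/QALY
```

The numbered scripts under `analysis/` run the full base case, the tornado
and the 10,000-draw PSA and write their tables under `results/`.
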