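---
title: "A decision-tree cost-minimisation model for POCUS in general practice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A decision-tree cost-minimisation model for POCUS in general practice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pocuscma)
```

## The question and the model

Spotting and light vaginal bleeding are common in early pregnancy and
usually harmless, but women seek reassurance of a viable pregnancy. In
gatekeeper systems such as Denmark's, a woman consults her GP, who —
without access to ultrasound — refers her onward to a private
gynaecologist or a hospital gynaecology department, where a conclusive
transvaginal scan is performed. If the GP has a point-of-care
ultrasonography (POCUS) device and suitable training, most of these
consultations can be completed in-house.

`pocuscma` implements a cost-minimisation analysis (CMA) of that choice.
A CMA presumes the compared strategies are clinically equivalent (here
supported by high inter-rater agreement between trained GPs and
specialists for intrauterine-pregnancy scans) and simply asks which is
cheaper. The model is a decision tree:

* the **decision node** chooses between `usual_practice` (GP without
  POCUS) and `intervention` (GP with POCUS);
* **chance nodes** encode the referral pattern: under usual practice the
  GP refers everyone, to a private gynaecologist (probability 0.23) or a
  hospital (0.77); a gynaecologist completes management (0.92) or refers
  on to hospital (0.08). Under the intervention the GP completes 73% of
  patients; the referred 27% split 0.16/0.84 between gynaecologist and
  hospital, with the same 0.92/0.08 split at the gynaecologist;
* **terminal nodes** mark where management is completed (GP,
  gynaecologist, hospital).

Costs accrue on branches: entering a location adds that location's visit
cost, so a patient who passes GP → gynaecologist → hospital accumulates
all three. The expected cost of an alternative is the probability-
weighted sum over its root-to-terminal paths, computed by bottom-up
roll-back (`expected_cost()`); `enumerate_paths()` recomputes the same
quantity by explicit path enumeration and serves as the engine's
internal oracle. The **incremental cost** is intervention minus usual
practice; negative values are savings.

```{r}
m <- build_paper_model()
evaluate_model(m)
```

## Costs, perspectives and annuitisation

Every cost component is `quantity x unit price`, tagged with a location,
a bearer (`healthcare` or `patient`) and the alternative(s) it applies
to. The default **societal perspective** counts all bearers; the
**healthcare-sector perspective** (`scenario_healthcare()`) keeps only
tariffs and the POCUS add-on, exactly decomposing the societal total
into healthcare plus patient-borne parts.

Unit-price semantics are fixed as: patient time EUR 0.408/min, GP
scanning time EUR 1.807/min, travel EUR 0.473/km — inferred from the
printed per-visit products. Transport times use a car speed of
50 km/h; the stored base values are the printed whole minutes
(11/47/47), since the printed per-visit products confirm those were
used rather than the unrounded 11.4/47.04.

Capital items are annuitised to an equivalent annual cost:
`annuity_factor(r, L) = (1 - (1+r)^-L)/r` (continuity limit `L` at
`r = 0`), and `per_use_capital_cost()` divides the annuitised capital by
the 2.4 scans per GP-year. The training course (EUR 2,008 across 6
course categories and 4 gynaecology subcategories, 7-year lifespan, 4%
interest) reconstructs the per-scan price of EUR 5.81. The scanner's
per-scan price of EUR 7.54 is stored directly: the fraction of scanner
use attributable to this indication is not observable, so the bundled
annuity spec carries a use fraction back-solved from 7.54 (about
0.70%), labelled synthetic.

The six intervention-only GP components — scanning time, scanner,
training, wet wipes, transducer cover, gel — form the proposed GP
remuneration (`remuneration()`, total EUR 31.98), and by construction
equal the add-on applied to the GP consultation in the intervention arm.

## Sensitivity analyses

**One-way DSA** (`one_way()`, `tornado()`) moves one parameter to each
end of its plausible range, everything else at base, and reports the
societal incremental cost at both endpoints plus the absolute swing,
ranked descending (stable in declaration order on ties, so a complement
pair's two mirrored bars keep their stated order). Probability ranges
are the lowest/highest questionnaire response; the two probabilities of
a binary chance node form a *complement group* and are co-varied so the
node still sums to 1, with the partner clamped to 0 when an endpoint of
1.0 annihilates the sibling branch. Whether the original analysis
co-varied or renormalised siblings is not stated; co-variation is this
package's choice, as it is the only option that keeps binary nodes
exactly normalised. Quantity-denominated ranges (consultation minutes,
km) are converted once to EUR ranges on the per-visit component cost by
the fixed unit prices. The utensil bundle (wet wipes + cover + gel,
base EUR 0.558) is varied as a single parameter over [0.34, 0.56],
scaling its members proportionally, because its range is stated for the
bundle. The scanner [1.30, 13.77] and training [3.35, 5.81] ranges are
ranges on the per-scan cost and override the annuity computation during
DSA. Transport time and distance are varied as separate parameters even
though time ranges derive from distance; this ignores their correlation
in one-way analysis, which only matters if they were varied jointly.

**PSA** (`run_psa()`) is a second-order Monte Carlo simulation: 10,000
independent joint draws, beta distributions for probabilities and gamma
for costs, re-evaluating the societal incremental cost per draw. The
original analysis does not state how distribution parameters were
derived, so the package uses a method-of-moments fit anchored at the
base value with `sd = (range width)/4`, treating the plausible range as
roughly a ±2 sd interval: it uses only published numbers and preserves
every parameter's mean exactly, which keeps the PSA centred on the base
case (the tree is multilinear in independent parameters, so the mean
incremental equals the deterministic incremental up to Monte Carlo
error). In each complement group exactly one member is sampled and the
partner set to its complement; parameters are otherwise independent, as
no correlation structure is reported. A zero-width range degenerates to
a point mass, and a range too wide for a beta's moment condition
(`v >= m(1-m)`) raises an error prescribing a narrower range. The three
unit prices named as held fixed (mileage, GP scanning time, patient
time) are constants of this parameterisation, not sampled parameters.
All draws flow from a single integer seed; identical configurations are
bitwise-reproducible.

```{r}
p <- run_psa(m, psa_config(n_draws = 2000, seed = 2019))
p
```

## Synthetic data

Two generators make every stage testable without external data.
`simulate_gp_responses()` emulates the questionnaire that produced the
referral probabilities: n independent beta-distributed per-GP
probability estimates with a requested mean and dispersion (the real
panel had 21 POCUS users among 22 respondents; the per-question response
counts are not published, so the simulated panel answers every
question). `aggregate_questionnaire()` reduces a panel the way the study
did — arithmetic mean as base value, min/max as the DSA range. Beta
responses are a modelling convenience (any distribution on [0, 1] would
do); real elicited probabilities show heaping on round values and
item non-response, which the generator does not emulate, so passing
recovery tests demonstrate correct aggregation arithmetic, not
elicitation realism.

`random_model()` generates seeded random valid trees (Dirichlet-
normalised chance nodes, random costbooks and bearer tags) for
property-based testing of the engine: roll-back versus path-enumeration
agreement to 1e-9, conservation of path probability, affinity of the
expected cost in any component's unit price, and invariance to branch
order. The test suite runs 200 such models; trees are kept to depth 3
and branching 3, deep enough to exercise nested chance nodes while
keeping enumeration exhaustive.

## Numerical choices

All arithmetic is double precision; euros are rounded (two decimals in
CSV, whole euros in the human-readable summary) only at the reporting
boundary. This matters for the headline figures: the full-precision
expected costs are 234.68 and 125.29, whose difference is a saving of
109.40, while the published saving of 110 is the difference of the
*rounded* averages 235 − 125. Both are reported
(`evaluation.json` carries full precision and the rounded block); the
rounded difference is treated as the headline because that is how the
published figure was formed. Chance-node normalisation is enforced to
1e-9; validation returns a complete list of named violations rather
than stopping at the first.

## Configuration and interface

Models are declared in a YAML file (`read_config()`/`write_config()`;
the bundled `inst/extdata/case_study.yaml` doubles as the format
reference). The reader rejects unknown keys with their location,
distinguishes schema errors from model-invariant violations, and
re-validates the assembled model. The `pocuscma` executable script
(`exec/pocuscma`, a thin wrapper over `cma_cli()`) offers `validate`,
`evaluate`, `tornado`, `psa` and `remunerate` subcommands with
`--config`/`--paper`, `--out`, `--perspective`, `--n-draws`, `--seed`,
`--quiet`/`--debug`; results are written as RFC-4180 CSV and JSON with
deterministic column order.

## Limitations

This is early-stage modelling: referral probabilities come from a small
convenience panel of POCUS-experienced GPs, specialist completion rates
from a non-specific national report, and several resource-use figures
from expert opinion. The model compares costs only — no QALYs,
cost-effectiveness ratios or Markov structure — and applies no
discounting, as the episode resolves within days. Results are specific
to Danish tariffs and travel patterns; the engine itself is generic for
any two-alternative decision tree declared in the configuration format.
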