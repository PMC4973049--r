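---
title: "A decision-analytic model for home safety interventions against childhood poisoning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A decision-analytic model for home safety interventions against childhood poisoning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poisoncea)
```

## The decision problem

Unintentional poisoning is one of the most common home injuries in children
under five. Health visitors and safety-equipment schemes can promote *safe
storage* of medicines and other household products — storage locked or above
adult eye level — through seven increasingly intensive strategies: usual
care (UC), education (E), provision of two low-cost cupboard locks (FE),
and combinations adding a home safety inspection (HSI) and fitting of the
equipment (F). `poisoncea` estimates, for a hypothetical cohort of 100,000
households each with one newborn child, the healthcare costs (2012 GBP, UK
NHS/PSS perspective) and health benefits of each strategy, as

* a **cost-effectiveness analysis** over the first five years of life, with
  benefits in poison cases averted, and
* a **cost-utility analysis** over a 100-year horizon, with benefits in
  quality-adjusted life years (QALYs),

propagating parameter uncertainty by Monte-Carlo probabilistic sensitivity
analysis (PSA) and summarising results as incremental cost-effectiveness
ratios (ICERs) with dominance classification, cost-effectiveness planes and
cost-effectiveness acceptability curves (CEACs).

## Model structure

The model couples three stages.

**Stage 1 — intervention decision tree.** Each arm converts the baseline
prevalence of safe storage `pSafe`, the acceptance probability `pAccept`
(0.90, fixed) and the arm's absolute effectiveness `pEff` (the probability
a household stores safely under that strategy, from a network
meta-analysis) into the initial share of households with safe storage, and
prices the intervention.

Two allocation rules are implemented (`allocate_states()`):

* **blend** — `propSafe = pAccept·pEff + (1 − pAccept)·pSafe`; and
* **convert** — `propSafe = pSafe + (1 − pSafe)·pAccept·pEff`: households
  that already store safely stay safe, and an accepted intervention
  converts an unsafe household with probability `pEff`.

The default pairs the *blend* rule for usual care (whose "effectiveness"
is the absolute control-arm safe-storage probability observed in the trial
network, 0.87 for medicines) with the *convert* rule for the six active
arms. This asymmetric pairing was chosen because it is the only
combination that reproduces the published per-arm expected case counts:
with posterior-mean effectiveness it gives 5.64 / 5.16 / 5.13 / 5.12 /
5.17 / 5.16 / 5.13 expected medicinal cases per 1,000 households across
the seven arms, against published values of 5.622 / 5.163 / 5.142 / 5.137
/ 5.176 / 5.168 / 5.148. Applying the blend rule to every arm compresses
the education-vs-usual-care incremental benefit roughly four-fold below
the published value; applying convert to every arm overstates the
usual-care caseload by ~8%. A consequence worth knowing: because usual
care loads on `pEff_UC` much more heavily than active arms load on their
own effectiveness, incremental-benefit *distributions* are wider than the
published credible intervals even under strong cross-arm correlation.

Intervention costing (default policy `target-unsafe`) charges, per
household: the scheme set-up cost `cFixed/100,000`, plus for the
`(1 − pSafe)` households targeted and the 90% accepting, the arm's offer
cost (built from components: education £3.67, equipment £7.45, inspection
£3.67, fitting £2.08, travel £4.99 when a dedicated visit is needed) and
the £0.40 acceptance cost. An `offer-all` policy is available; the
targeted policy was adopted because reverse-engineering the published
incremental costs (≈£1.32 per household for education against a £3.67
offer cost) shows offering to every household overshoots substantially.

**Stage 2 — preschool Markov model (ages 0–4).** Six states: safe (S1),
unsafe (S2), safe + chronic injury (S3), unsafe + chronic injury (S4),
poisoning death (S5) and other-cause death (S6); annual cycles; S5 and S6
absorbing. Each cycle applies background mortality, then the
stratum-specific annual ingestion risk. `pIngest` is interpreted as the
risk in the *no-safe-storage* stratum (0.001806/year for medicines); the
safe-stratum risk applies the signed log odds ratio on the odds scale,
`odds_safe = odds_unsafe · exp(logOR)` with logOR = −0.604 (SE 0.143) for
medicines (protective) and +0.2614 (SE 0.132) for other household
products (harmful). A data note: the source text quotes the corresponding
odds ratios with the reciprocal orientation (1.83 and 0.77 "safe versus
no safe storage"); the signed log odds ratios are the operative values —
they reproduce the published result directions — and are stored as
printed. The unsafe-stratum reading of `pIngest` was likewise selected
because a population-average reading inflates the usual-care medicinal
caseload to ≈9 per 1,000 (published: 5.622). Under this reading the
published non-medicinal usual-care count (5.820) is not reachable — it
lies below the non-medicinal model's own minimum of 6.02 — so the
non-medicinal analysis reproduces the published *pattern* (all active
arms dominated, north-west plane) rather than its exact caseload; one
consistent risk interpretation is kept for both variants.

Conditional on an event, the severity split is minor `1 − pAdmit`,
moderate `pAdmit(1 − pSevere)`, severe-surviving
`pAdmit·pSevere(1 − pFatal)` and fatal `pAdmit·pSevere·pFatal`. Severe
survivors move to the chronic state of their stratum (S3/S4) and remain
exposed to further ingestion events; at most one event per child-year
(annual probabilities, not rates). Acute unit costs rebuild the published
2012 figures exactly: minor £175.12 (0.24·cAmb + cED1), moderate £795.12
(+ short stay), severe £2670.12 (+ long stay); the ambulance *probability*
is stored as 0.242 but the weight 0.24 is used in cost arithmetic because
only 0.24 reproduces the printed unit costs. A £43 GP follow-up attaches
to every surviving medically attended case (the source lists the GP cost
without an attachment rule); fatalities follow the severe inpatient
pathway and add the £205.50 fatality cost instead.

**Stage 3 — long-term Markov model (ages 5–99).** Three states: alive
without chronic injury, alive with chronic injury (permanent; no recovery
transition and no excess mortality is parameterised), dead. The chronic
state accrues £386.42/year of care costs and loses `uChronic = 0.10`
utility per year. No poisoning events occur after age five.

## Utilities, discounting, and per-household scaling

Baseline utilities are age-band population norms (0.94 under 25, declining
to 0.73 at 75+; children use the under-25 band). These are treated as
**fixed** in the PSA: the reported dispersions (e.g. SD 0.12 at 0.94) are
population spreads, and sampling them as parameter uncertainty would both
place ~31% of draws above utility 1 and inflate the expected-QALY
intervals by two orders of magnitude relative to the published tables.
Event/chronic utility *decrements* are sampled, as Beta distributions
matched by moments to their means and SEs (SE = 10% of the mean for
minor 0.03, moderate 0.046 and severe 0.146 = 0.046 + 0.10; uChronic
0.10 with SE 0.025); scenarios SA11/SA12 scale these SEs.

Costs and QALYs are discounted at 3.5%/year, end-of-cycle, with no
half-cycle correction: the cycle at age *a* carries weight
`(1.035)^−(a+1)`. Intervention costs are charged undiscounted at time
zero. The `children_per_household` multiplier (1.0 base case, 1.8 in
SA8) scales the per-household *health* consequences — cases, healthcare
costs, QALYs — but not intervention costs, which are delivered once per
household.

## Effectiveness evidence and its joint distribution

Per-arm effectiveness is available only as posterior medians with 95%
credible intervals (e.g. education 0.90 (0.61, 0.98) for medicines). Each
arm is fitted as a **logit-normal** distribution — `mu = logit(median)`,
`sigma = (logit(u) − logit(l)) / (2·1.96)` — matching the logit-scale
geometry of a network-meta-analysis posterior (a quantile-matched Beta is
available as an option). Printed bounds of 0.00/1.00 (two non-medicinal
arms) are clamped to 0.005/0.995 before fitting.

The arms' *joint* posterior is not recoverable from printed marginals, yet
it drives every between-arm comparison. The package induces cross-arm
dependence through a shared latent factor: on the logit scale
`z_k = mu_k + sigma_k(√ρ·F + √(1−ρ)·e_k)`, which preserves every marginal
exactly for any `ρ ∈ [0, 1]`. The default `ρ = 0.9` expresses that the
trial network estimated all arms against a common baseline; it is a
configuration knob, not a constant. **Limitation:** quantities that hinge
on fine differences between arms — the probability education is optimal
at a threshold, or dominance flags between arms whose mean benefits
differ by less than the published rounding — inherit this approximation
and can differ materially from the published values even when all
marginal means match. No marginal-preserving correlation structure can
recover, for example, how often the equipment arm's effect exceeded the
education arm's by more than ~0.03 in the original joint posterior.
Scenario SA1 approximates a predictive distribution by inflating every
`sigma` by 1.5 (the source prints no predictive intervals; the factor is
documented as an approximation).

## Background mortality

The source cites national mortality statistics without printing them, so
the packaged lifetable is synthetic and labelled as such
(`inst/extdata/lifetable_synthetic.tsv`): a Gompertz–Makeham hazard
`q(a) = 1 − exp(−(A + B·e^{Ca}))` with `A = 2×10⁻⁴`, `B = 3×10⁻⁵`,
`C = 0.09`, chosen once for a UK-like life expectancy at birth of
81.7 years and low child mortality. Any two-column `age qx` text file can
be substituted (`read_lifetable()`). Lifetime discounted QALYs per person
are ≈24.3 under this fixture (the published figure is ≈25.06 per person;
the bracket 24–26 is what the synthetic lifetable supports asserting).

## Scenario ladder

`apply_scenario()` implements twelve one-change scenarios: SA1 predictive
effectiveness; SA2/SA3 baseline prevalence 0.93/0.50; SA4 acceptance
0.50; SA5 admission probability 0.833 (Beta rescaled to preserve its
coefficient of variation); SA6/SA7 equipment repriced as two pop-it
(2×£2.65) or two magnetic (2×£4.80) locks; SA8 1.8 children per
household; SA9/SA10 incidence 44.9/48.5 per 10,000 person-years
(deprivation quintiles; the ingestion probability is recomputed from the
new incidence while the admission/severity/fatality pathway probabilities
stay at base values); SA11/SA12 decrement SEs at 20%/50% of the mean.
Each scenario touches only its stated parameters (verified by a
configuration-diff test).

## Validation and numerical choices

* **Microsimulation oracle.** `simulate_households()` replays individual
  children with the same annual discretisation, event logic and
  end-of-cycle discounting as the cohort engine, so cohort outputs equal
  microsimulation expectations exactly, and the test suite checks
  agreement within 3 Monte-Carlo standard errors across ≥20 fuzzed
  parameter sets. The generator emulates the modelled process only: it
  has no within-year event timing, at most one event per child-year, no
  sibling correlation (SA8 is a deterministic multiplier), and no real
  secular trends — so passing tests certify internal consistency, not
  external validity against real injury data.
* **Conservation.** State occupancy must sum to 1 each cycle to 1e-12 or
  the engine aborts.
* **Dominance.** `incremental_analysis()` flags strict dominance, then
  removes extended dominance by iterative frontier-ICER inversion;
  results agree with an independent convex-hull enumeration on random
  problems. Exact effect ties break toward the cheaper arm. The
  published-layout `results_table()` classifies at the published tables'
  printed precision (1e-3 per 1,000 households), mirroring how those
  tables flag "the same QALY gain for a higher cost"; pass
  `effect_tol = 0` for exact classification.
* **ICER uncertainty.** Credible intervals for ICERs are 2.5/97.5
  percentiles of per-draw ratios restricted to draws with positive
  incremental effect (ratios are not sign-stable across plane quadrants);
  the restricted fraction is reported alongside.
* **CEAC ties** split equally across tied arms, so probabilities sum to
  one exactly.
* **Thresholds.** In the cost-effectiveness analysis the 30,000/50,000
  columns are per poison case averted; output metadata notes that the
  source's corresponding table heading reads "per QALY" while its text
  reads "per poison case avoided".

## Problem sizes

The default PSA uses 4,000 retained draws, matching the published
simulated-ICER cloud, and runs in well under a second per scenario (the
cohort engine is vectorised across draws). Unit tests use 200–500 draws;
the reproduction tests in `test-acceptance.R` use the full 4,000; the
microsimulation cross-checks use 3,000–30,000 children per parameter set,
sized so the 3-SE bands are a small fraction of the quantities checked.

## Worked example

```{r, eval = FALSE}
library(poisoncea)
cfg <- load_model_config("medicinal")
psa <- run_psa(cfg, n_draws = 4000, seed = 1)
results_table(psa, "cua")[, c("label", "benefit", "cost", "icer_display")]
ceac(psa, thresholds = 30000, effect_measure = "cases")
```

## Known limitations

Beyond the joint-posterior approximation and the synthetic lifetable
discussed above: the non-medicinal caseload level is structurally
irreproducible under the single consistent risk interpretation (pattern
reproduced, level ≈7.2 vs published 5.8 per 1,000); intervention-cost
reconstruction matches published incremental costs to ~10% (the exact
offered population was not stated); chronic survivors carry no excess
mortality or cost multiplier because none is parameterised; and no
equity, co-benefit or repeat-offer mechanisms are modelled.
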