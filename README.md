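# poisoncea

Probabilistic decision-analytic modelling of the cost-effectiveness of home
safety interventions for preventing unintentional poisoning in preschool
children (ages 0–4), from a UK NHS/PSS perspective in 2012 GBP.

## The problem and who this is for

Safe storage of medicines and household products — locked away or above
adult eye level — lowers a young child's chance of an unintentional
ingestion. Health visitors and safety-equipment schemes can promote it
with strategies of increasing intensity: usual care (UC), extra education
(E), provision of two low-cost cupboard locks (FE), and combinations
adding a home safety inspection (HSI) and fitting of the equipment (F),
seven strategies in all. `poisoncea` is for health-economic analysts who
need to compare these strategies on costs and health outcomes under full
parameter uncertainty, and for methodologists who want a compact,
fully-tested reference implementation of a decision-tree + Markov-cohort
cost-utility model with probabilistic sensitivity analysis.

## The model

Three linked stages, run separately for medicinal and non-medicinal
(other household products) poisonings:

1. **Intervention decision tree.** Baseline safe-storage prevalence
   *pSafe*, acceptance *pAccept* = 0.9 and per-arm effectiveness
   *pEff\_k* (network-meta-analysis posterior summaries) give the initial
   safe/unsafe split; usual care blends its absolute control-arm effect,
   active arms convert unsafe households
   (*propSafe* = *pSafe* + (1 − *pSafe*)·*pAccept*·*pEff\_k*).
   Intervention cost per household = *cFixed*/100,000 +
   (1 − *pSafe*)·*pAccept*·(offer cost + £0.40).
2. **Preschool Markov model**, six states
   {S1 safe, S2 unsafe, S3 safe+chronic, S4 unsafe+chronic, S5 poison
   death, S6 other death}, annual cycles, ages 0–4. Annual ingestion risk
   is *pIngest* in the unsafe stratum and
   invlogit(logit(*pIngest*) + logOR) in the safe stratum; events split
   into minor / moderate / severe / fatal via *pAdmit*, *pSevere*,
   *pFatal*, costed £175.12 / £795.12 / £2670.12 (+£43 GP follow-up;
   +£205.50 for fatalities), with QALY decrements 0.03 / 0.046 / 0.146.
3. **Long-term Markov model**, {alive, alive+chronic, dead}, ages 5–99:
   chronic survivors accrue £386.42/year and lose 0.10 utility/year.

Costs and QALYs discount at 3.5%/year end-of-cycle. The PSA samples every
uncertain parameter (Beta for probabilities from counts, Gamma for costs
by method of moments, Normal for the log odds ratio, correlated
logit-normals for the seven arm effects) with common random numbers
across arms, and the economics layer computes ICERs
(ΔCost/ΔEffect) with strict/extended dominance, cost-effectiveness
planes and acceptability curves. Twelve one-change sensitivity scenarios
(SA1–SA12) cover effectiveness-predictive sampling, baseline prevalence,
acceptance, admission probability, equipment prices, household size,
deprivation-quintile incidence and utility-decrement uncertainty.

## Worked example

```r
library(poisoncea)
cfg <- load_model_config("medicinal")      # packaged parameter file
psa <- run_psa(cfg, n_draws = 4000, seed = 1)
results_table(psa, "cua")                  # lifetime cost-utility table
```

which prints (per 1,000 households, lifetime horizon, seed 1):

```
        arm    qalys cost dQALY dCost      ICER  p30k
         UC 24259.83 3859 0.000     0           0.731
          E 24259.86 5239 0.033  1380     41302 0.269
         FE 24259.87 6068 0.035  2209     62894 0.000
       E+FE 24259.87 6878 0.036  3019     83131 0.000
   E+FE+HSI 24259.86 8854 0.033  4994 Dominated 0.000
     E+FE+F 24259.86 8490 0.033  4631 Dominated 0.000
 E+FE+HSI+F 24259.87 9294 0.035  5435 Dominated 0.000
```

Read: usual care yields ≈24,260 discounted QALYs and £3,859 per 1,000
households; education adds 0.033 QALYs for £1,380 more, i.e. ≈£41,300
per QALY gained — above the usual £20,000–£30,000 willingness-to-pay
range, so usual care remains most likely cost-effective (probability 0.73
at £30,000/QALY). The three inspection/fitting packages cost more than
more effective strategies and are dominated. The companion
cost-effectiveness view (`results_table(psa, "cea")`) counts poison cases
instead: education averts 0.483 cases per 1,000 households over five
years at ≈£2,960 per case averted. For non-medicinal products
(`run_variant("nonmedicinal")`) safe storage is associated with *higher*
ingestion risk (odds ratio direction as published), so every active arm
is dominated by usual care.

Other entry points: `ceac()`, `ce_plane()`, `incremental_analysis()`,
`apply_scenario()` / `scenario_ids()`, the microsimulation validator
`simulate_households()`, and `run_analysis()` which writes the full CSV
result bundle. A thin CLI wraps these:

```sh
Rscript scripts/run_model.R run --variant medicinal --analysis both \
    --draws 4000 --seed 1 --out results/base
Rscript scripts/run_model.R scenarios --variant medicinal
Rscript scripts/run_model.R validate
```

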