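---
title: "Deriving count-based clinical prediction rules with cprderive"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving count-based clinical prediction rules with cprderive}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cprderive)
```

## The problem

Exercise programs for non-acute low back pain help some patients much
more than others. A clinical prediction rule (CPR) of *treatment
success* is a short battery of baseline clinical tests whose count of
positive findings, compared against a threshold, moves the probability
that a given patient will respond. `cprderive` implements the
derivation stage of such rules: from a cohort with baseline candidate
predictors and longitudinal disability outcomes to a scored rule with
diagnostic performance statistics.

The pipeline assumes a one-arm design (every patient receives the
treatment), a primary outcome measured by the Oswestry Disability
Index (ODI, 0–100%), and candidate predictors tagged by *class*:
class A are treatment-specific (here, tests theoretically related to
lumbar segmental instability), class B are adherence-related, class C
are generic prognostic variables. This tagging drives the hierarchical
modeling order, so that the final rule is interpretable as specific to
the treatment rather than to recovery at large.

## Outcome classification

For each patient, ΔODI = ODI_T0 − ODI_Tx and
ΔODI% = ΔODI / ODI_T0 × 100. The trichotomy is

* **success**: ΔODI% ≥ 50;
* **clinically significant improvement**: ΔODI% < 50 and ΔODI ≥ 10;
* **failure**: otherwise,

with both boundaries inclusive exactly as written. The 10-point
absolute floor is the conventional minimal clinically important change
for the ODI and is a fixed constant here, not an estimated quantity.
Eligibility requires ODI_T0 ≥ 12%, which also guarantees ΔODI% is
well defined. Pain intensity (NPRS, 0–10) is summarized alongside but
never enters classification.

Group-level change is summarized by Cohen's d with the pooled pre/post
standard deviation,
d = (M_post − M_pre) / sqrt((SD_pre² + SD_post²)/2).
The literature uses several standardizers for pre/post designs; this
one was chosen because it reproduces, to two decimals, every published
whole-sample effect size of the study family this package emulates
when fed the corresponding printed means and SDs (the acceptance tests
assert exactly this).

## Cut-point selection

Continuous and ordinal predictors are dichotomized against the
success/failure contrast only — the improvement class is excluded from
every 2×2-based stage, mirroring the subgroup comparison that motivates
the rule. Candidate cuts are the midpoints between consecutive
distinct observed values plus ±∞ sentinels, so each criterion's result
depends only on the ranks of the data and any threshold between two
observed values is representable. Six criteria are available
(`select_cutpoint()`):

| method | objective |
|---|---|
| `ROC` | minimize (1−Se)² + (1−Sp)² (closest to the perfect corner) |
| `Md` | median split of the pooled values |
| `YI` | maximize J = Se + Sp − 1 |
| `dMinSnSp` | minimize \|Se − Sp\| |
| `LRmax` | maximize Se/(1−Sp) over cuts with ≥ 1 false positive |
| `KLfg`, `KLgf` | maximize D(f‖g) = Se·ln(Se/(1−Sp)) + (1−Se)·ln((1−Se)/Sp), resp. its mirror |

Numerical conventions: 0·ln 0 = 0; cuts producing an empty 2×2 cell
are excluded from the KL criteria; `LRmax` requires at least one false
positive so its objective is finite; ties (within 1e−12) are broken
toward the larger Youden index, then the smaller cut. If KL or LRmax
admit no cut at all (perfect separation leaves an empty cell
everywhere), the Youden optimum is returned with a `fallback` flag
rather than an error, so batch audits keep running. When a variable's
expected direction is unknown, the direction whose optimum yields
LR+ > 1 is chosen, so that a positive test always argues *for*
success — the semantics a count-based rule requires.

`cutpoint_audit()` tabulates all six criteria for every candidate; the
package deliberately does not pick among them automatically. Which
criterion's cut is clinically sensible is a judgment call (units,
feasibility, concordance with prior literature); the pipeline default
for unattended runs is `YI`, the most common convention.

## Screening and hierarchical modeling

Each dichotomous test is screened by an uncorrected Pearson chi-square
(success vs failure) at the liberal p < 0.20, or rescued by LR+ ≥ 2.
No Yates correction is applied: the screen is meant to be permissive,
and the correction only makes it more conservative (a `correct` switch
exists). When a zero false-positive cell makes LR+ undefined at the
screening stage, the Haldane–Anscombe 0.5-cell correction is applied
and flagged; the published-style donor substitution (below) is
reserved for rule-level reporting.

Modeling proceeds in three steps (`hierarchical_modeling()`), each a
backward-stepwise logistic regression driven by Wald p-values with
retention threshold `alpha_retain = 0.05` (the source procedure says
only "all statistically significant"; 0.05 is the standard reading and
is configurable). Step 1 pools the accepted class-A tests with the
adjustment covariates age, sex and BMI; the covariates are candidates
rather than forced terms, because none survive in the published final
models this package emulates — `force_confounders = TRUE` restores
epidemiological forcing. Step 2 adds accepted class-B variables to the
step-1 survivors and re-eliminates; step 3 likewise with class C. Wald
(not likelihood-ratio) tests drive elimination to match the per-term
confidence intervals reported; ties in p are broken alphabetically so
results are invariant to column order. Quasi-separation is detected
(IRLS non-convergence or |B| > 15) and halts elimination with a flag;
penalized fits are deliberately out of scope at the derivation stage.

Model summaries report Nagelkerke's
R² = [1 − exp((D − D₀)/n)] / [1 − exp(−D₀/n)], the trapezoidal AUC of
the fitted probabilities, the Hosmer–Lemeshow test, and per-predictor
*Adequacy* ranks. Two wordings of the Adequacy denominator circulate;
this package uses the share of the full model's deviance improvement
achieved by the predictor alone,
(D₀ − D_single)/(D₀ − D_full), which is bounded, comparable across
models, and gives rank 1 to the most influential predictor with equal
values sharing a rank. For Hosmer–Lemeshow, predicted risks are binned
into deciles with ties kept together, bins with an empty expected cell
are merged into a neighbor with the degrees of freedom (bins − 2)
adjusted, and the test is skipped with a flag when fewer than three
distinct predicted values exist — the normal situation for a model of
three or four binary tests, where the test is uninformative anyway.

## Rule evaluation

The non-covariate terms of a chosen step (default: the class-A-only
model) become a `cpr_rule`. For each threshold k, patients with ≥ k
positive component tests are rule-positive, giving nested 2×2 tables
(Se non-increasing, Sp non-decreasing in k). `diagnostic_stats()`
attaches Wald intervals on the proportion scale (truncated to [0,1])
for Se/Sp/PV± and log-method intervals for the likelihood ratios, with
SE(ln LR+) = sqrt(1/tp − 1/(tp+fn) + 1/fp − 1/(fp+tn)). These two
interval methods were fixed by verifying that they reproduce the
published intervals of the emulated study exactly at the printed
precision; that reproduction is a mandatory unit test.

The post-test probability of success is the algebraic Fagan nomogram,
odds_post = odds_pre × LR+. The pretest probability defaults to the
success fraction among *all* completers, improvement class included
(e.g. 54/110 = 49%), even though the 2×2 tables exclude that class —
this is the published convention; `pretest = "success_failure"`
switches to the 2×2-consistent denominator. The exact identity
"post-test at the table's own prevalence = PV+" holds by construction
and is asserted property-style.

When the failure-group cell at a high threshold is 0 or 1, the
specificity-side indicators are incalculable or unstable. The
reporting default is to flag them `NA`/degenerate.
`zero_cell_approximation()` implements, on explicit request only, the
published illustrative workaround of borrowing the failure-group split
from a lower threshold; its output is always flagged `approximated`
and should never support inference.

## The synthetic cohort

`simulate_cohort()` exists because the raw patient data of the study
family this package emulates are not public. Its defaults
(`default_paper_config()`) encode the study conditions: 134 enrolled;
18% in-program attrition and 10 further losses at follow-up (≈ 110
and 100 analyzable); baseline ODI ~ Normal(26.8, 10) truncated at the
12% eligibility floor; NPRS ~ Normal(5.0, 1.3); BMI ~ Normal(26.5,
4.7); age ~ Normal(43.5, 12) on 18–65; 55% female. Four planted
class-A tests mimic the published rule components — a continuous
performance ratio cut at 0.75, two binary provocation tests, and a 0–9
laxity score positive *below* 5 with a female shift (means 0.5 vs 2.2)
— with planted odds ratios equal to the exponentials of the published
coefficients (4.1–5.9). Six class-B/C noise variables are included.

Success is generated *first*: each patient's positive planted tests
contribute their log odds ratios to a logistic linear predictor whose
intercept is solved numerically (bisection on the mean predicted
probability) so the expected prevalence equals the target (0.49 at T8,
0.53 at T34); an unreachable target raises a configuration error. The
T8 and T34 success indicators share a Gaussian copula (ρ = 0.8) so
both marginals are exact while outcomes correlate over time. ODI at
follow-up is then generated conditional on the assigned class —
success draws ΔODI% uniformly in 55–95%, improvement draws an integer
drop of ≥ 10 points below the 50% line (possible only when baseline
ODI > 20), failure draws a small change — which guarantees that
`classify_outcome()` reproduces the intended class exactly. The
improvement class is assigned to 20% of non-successes, yielding ≈ 10%
of the cohort as published (11/110). Scores are stored at clinical
precision (integer ODI/NPRS/laxity, one-decimal BMI, three-decimal
ratios), which also makes file round-trips exact. Attrition is applied
after outcome generation and is independent of outcome by default; an
outcome-dependent switch exists for sensitivity studies.

What the generator does **not** emulate: correlations among predictors
(independence by default — no shared "instability" factor is asserted),
item-level questionnaire structure, adherence dynamics, measurement
error over repeated visits, and informative dropout. Passing the
pipeline-recovery tests therefore shows the *procedure* behaves
correctly under the stated generative model, not that the published
rule would validate on new patients.

## Problem sizes and reproducibility

The test suite runs the heavier simulation properties at sizes chosen
to keep the whole suite under half a minute while leaving comfortable
Monte-Carlo margins: prevalence calibration over 60 replicates of
n = 500; null screening over 400 replicates at n = 400; LR-interval
coverage over 2000 simulated tables; and the headline recovery
property — with all four planted odds ratios at 6 and n = 400, the
final class-A model contains at least three of the four planted tests
— over 100 full pipeline replicates (observed rate well above the 80%
bar). All randomness flows from explicit integer seeds; a cohort is
byte-reproducible through `write_cohort()` given the same
configuration.

## Known limitations

* Backward selection with a liberal screen inflates apparent
  performance at the derivation stage; nothing here replaces
  validation on an independent cohort.
* Optimal cut-points chosen on the same data as the model are a known
  source of optimism; the audit table exists precisely so that cuts
  can be fixed on external grounds.
* Firth or other penalized logistic fits are not provided; separation
  is reported, not repaired.
* The Hosmer–Lemeshow test is near-meaningless for models of a few
  binary predictors; it is reported for completeness and skipped when
  degenerate.
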