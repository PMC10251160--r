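---
title: "A Markov cohort model for FNAC-first triage of lymphadenopathy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort model for FNAC-first triage of lymphadenopathy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fnacost)
library(dplyr)
```

## The clinical question

Persistent, clinically suspicious lymphadenopathy needs a pathological
diagnosis. Two strategies compete: send every patient to excisional surgical
biopsy (SB) with histology — the traditional gold standard — or triage with
lymph-node fine-needle aspiration cytology (LN-FNAC) and reserve surgery for
the cases cytology cannot settle. FNAC is minimally invasive and cheap; the
question `fnacost` answers is *how much* the FNAC-first strategy saves, and
what diagnostic accuracy it delivers, when the two are compared on the same
cohort under a cost-minimization framework (the strategies are assumed
equally effective at eventually reaching a diagnosis, so they are compared on
cost alone; quality-of-life effects, complications and diagnostic delay are
outside the model).

## The model

Each lymphadenopathy is a row of a cohort table and moves through a
multistate transient (Markov cohort) process in discrete cycles:

* **Cycle 1** always starts with the first FNAC, which places the node in one
  of four Sydney-System states: `benign`, `alus` (atypical lymphoid cells of
  uncertain significance), `suspicious`, `malignant`.
* At the end of a cycle one **event** may occur — clinical follow-up, a
  repeat FNAC, or a surgical biopsy. Follow-up leaves the state unchanged;
  the two procedures move the node into the state they return
  (`advance_state()`).
* The process **concludes** when a definitive diagnosis is reached: by
  cytology alone, by a conclusive second FNAC, by histology, or when
  follow-up confirms benignity. All pathways conclude within three cycles.

Because the cohort records what actually happened to each node, the engine
(`run_model()`) is a *replay* over recorded events — transition rates are
empirical counts, not sampled probabilities. The sampling counterpart lives
in the generator (`simulate_cohort()`).

### When does a trajectory conclude?

A trajectory normally concludes at the cycle of its last recorded event.
One clinically grounded exception: a first FNAC that reads *malignant with a
metastasis (or lymphoma-relapse) subtype* is diagnostically definitive on its
own — cytology plus immunocytochemistry established the malignancy — so such
a pathway concludes at cycle 1 with mode `fnac_sufficient` even when a biopsy
follows, because that biopsy serves primary-site identification rather than
diagnosis. Primary NHL and HL, by contrast, always require histological
confirmation, so those pathways conclude at the biopsy. On the reference
cohort this rule yields the cycle progression 403 / 130 / 2: the 403
first-cycle conclusions are 174 cytology-sufficient malignancies, 220 benign
nodes that regressed under follow-up, 2 ALUS nodes managed clinically, and
the 7 metastases biopsied only to locate the primary.

A pathway with events beyond the cycle horizon raises an error rather than
being silently truncated: the data promise that every work-up concluded
within `max_cycles`, and a violation is a data problem the user must see.

## The reference cohort

`reference_cohort()` ships a 535-lymphadenopathy consecutive series (545
FNACs: 535 first aspirations + 10 repeats; 131 biopsies on distinct nodes,
132 biopsy procedures) reconstructed as disaggregated pathway records from
published stratum counts. Encoding *individual pathways* rather than
marginal totals means the same table drives the cycle model, the cost
accumulation and the accuracy analysis, and the disaggregation is uniquely
determined by the narrative counts (see `?reference_cohort` for the full
composition). The unit of analysis is the lymphadenopathy, not the person:
the procedure arithmetic (545 FNACs on 535 nodes, 131/535 biopsied) only
closes at node level.

Two internal inconsistencies of the source counts are worth knowing about:

* the strata enumerate **396** nodes needing neither a biopsy nor a repeat
  aspiration (174 + 220 + 2, also 535 − 131 − 10 + 2 overlapping), although
  the figure is elsewhere printed as 395; the package reports the
  reproducible 396 (74.0% of the cohort);
* the replayed final states count 294 malignancies (275 + 15 + 3 + 1), while
  a printed percentage implies 292; the tally reports the replayed counts.

```{r}
tally_cohort(reference_cohort())
```

## Costs

Costs are Italian-NHS reimbursements treated as plain configuration
(`cost_schedule()`): EUR 129.50 per FNAC and EUR 1666.64 per surgical
biopsy. Follow-up visits and ancillary techniques are deliberately
cost-free: follow-up reimbursement is hard to estimate, and ancillary
techniques are assumed equally distributed across the two strategies, so
they cancel out of the comparison.

The FNAC-first strategy accumulates, over the cohort, the first FNAC in
every case plus any repeat FNAC plus any biopsy; the comparator simply
prices a biopsy for everyone. Two counting rules are exposed as flags
because the published accounting is asymmetric: repeat FNACs are billed
(545 aspirations), while the single biopsy repeated after excision of the
wrong node is not billed twice (131 biopsy costs, not 132). Defaults
reproduce that accounting; both flags can be flipped.

All arithmetic is carried unrounded; `round_half_up()` is applied only at
presentation, because reimbursement figures use commercial rounding while
base R rounds half to even. Derived shares (e.g. the biopsy component's
share of the total) are computed on unrounded values.

```{r}
cost_fnac_first(reference_cohort())
compare_strategies(reference_cohort())
```

Per-patient cost stratified by the first-FNAC result attaches repeat
aspirations to the patient's *initial* state. Computed from the counts, the
suspicious stratum (one FNAC and one biopsy each) costs EUR 1796.14 per
patient and the ALUS stratum (5 FNACs + 3 biopsies over 5 patients)
EUR 1129.48 — the source text attributes these two figures to the opposite
strata, but the stratum counts force this assignment, so the package
computes from counts rather than hard-coding the printed ordering.

`one_way_sensitivity()` varies one parameter (either unit cost, or the
biopsy rate) over a grid while holding the cohort's empirical procedure mix
fixed; the saving is linear in each parameter, so the break-even point is
solved exactly and appended to the table. At the default FNAC tariff the
FNAC-first strategy stays cheaper until the biopsy tariff falls below about
EUR 175 — an order of magnitude under any realistic excision reimbursement.

## Diagnostic accuracy

The cytology call of a pathway is its **final** FNAC category — the repeat
result when a repeat was done, otherwise the first result — with
`suspicious`/`malignant` counting as positive and `benign`/`alus` as
negative (the indeterminate category is managed conservatively, like a
negative, by follow-up). Using the final rather than the first cytology is
forced by the published metrics themselves: only that choice reproduces all
eight of them simultaneously (the node whose benign first FNAC turned
suspicious on repeat and benign at biopsy is the series' single false
positive).

Truth comes from histology wherever a biopsy was performed. For the rest,
two reference standards are offered:

* **composite** (all 535 nodes): clinical follow-up adjudicates the
  unbiopsied — the standard mitigation of partial-verification bias;
* **histology_only** (the 131 biopsied): the traditional gold standard,
  which conditions on having been selected for surgery and therefore
  overestimates the false-negative rate (NPV 71.4% versus 98.4% composite —
  the false-negative rate falls from 3.3% to 1.4% once follow-up-confirmed
  negatives are admissible evidence).

```{r}
confusion_matrix(reference_cohort(), "composite")
confusion_matrix(reference_cohort(), "histology_only")
```

Metrics with a zero denominator are reported as `NA` (undefined), never as
0. Presentation rounding follows the mixed precision of the published
figures (one decimal for the composite metrics, two for the biopsy-subset
PPV/NPV); internal values are unrounded fractions.

## The synthetic-cohort generator

`simulate_cohort()` exists so every stage of the pipeline is testable
without the reference cohort, at any size, with known ground truth. It
emulates the statistical structure the analysis assumes:

1. initial states are multinomial with configurable probabilities
   (defaults: the reference cohort's 0.5140 / 0.4486 / 0.0281 / 0.0093 for
   malignant / benign / suspicious / ALUS);
2. the post-initial event is drawn from a per-state conditional table
   (default: the empirical conditionals, e.g. after a benign first FNAC
   follow-up 220/240, repeat FNAC 10/240, biopsy 10/240);
3. repeat-FNAC results come from a configurable cytology table (default
   9/10 benign, 1/10 suspicious after benign), with a configurable
   probability that a biopsy follows the repeat;
4. ground truth is *planted* from the final cytology call through two
   mislabel rates — the probability that a negative call is truly malignant
   (default 4/244) and that a positive call is truly benign (1/291) — and
   every biopsy then reveals the planted truth, because histology is the
   gold standard in the simulation.

Planting truth for unbiopsied cases is the point: the simulator knows the
truth the composite reference only sees through follow-up, which is what
lets tests measure reference-standard bias (the histology-only reference
overestimates false negatives) and lets `estimate_params()` demonstrate
parameter recovery — at n = 50,000 the initial probabilities are recovered
within 0.01 and the mislabel rates within three binomial standard errors
(under the composite reference, 1 − NPV estimates the planted
false-negative rate and 1 − PPV the false-positive rate).

Reproducibility: a `seed` in `generator_params()` makes the draw
deterministic and leaves the caller's RNG stream untouched (the seed is
applied in a scoped, restored RNG context rather than via global state).

What the generator does **not** emulate — so what passing tests do not show
about real data: selection for biopsy is independent of the planted truth
given cytology (in reality clinicians biopsy the nodes they distrust, so
real biopsied subsets are enriched for discordance); the repeated-biopsy
mishap is not simulated (`n_sb_procedures` equals the biopsy events);
mislabel rates do not depend on covariates such as node size or
ultrasound features; and person-level correlation between nodes of the same
patient is absent.

## Numerical and design choices

* **Sizes used in the shipped checks.** The property suite exercises 1,000
  simulated cohorts of 10–60 nodes against a per-pathway brute-force cost
  oracle, and parameter recovery uses one cohort of 50,000 — large enough
  that a 0.01 band on the initial probabilities is ~4.5 standard errors for
  the largest one.
* **Sparse strata.** A fixed 0.01 recovery band is not a sound guarantee for
  event tables of the ALUS/suspicious strata (expected a few hundred rows at
  n = 50,000), so those are checked within three binomial standard errors of
  their realised stratum size.
* **Degenerate inputs.** Empty cohorts: tallies and confusion matrices
  return zeros; cost functions error (a per-patient cost over zero patients
  is meaningless). States absent from a cohort get `NA` per-patient cost and
  a degenerate `none` event estimate.
* **Validation is front-loaded.** `as_cohort()` enforces every structural
  rule the downstream modules rely on (vocabulary, event/result pairing,
  binary histology, truth-source/biopsy consistency) with row-level
  diagnostics, so the engine, cost and accuracy code can assume clean data.

## Limitations

The model is a replay of one retrospective series: it has no discounting,
half-cycle correction or utilities (a cost-minimization, not a
cost-effectiveness, analysis), assumes the published reimbursement tariffs,
and ignores core-needle biopsy as a third strategy. The generator's
independence assumptions above mean synthetic results validate the
*machinery*, not the clinical generalisability of the accuracy figures.
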