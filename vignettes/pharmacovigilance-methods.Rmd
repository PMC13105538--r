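---
title: "Disproportionality signal detection and cross-drug similarity analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection and cross-drug similarity analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvatlas)
```

pvatlas analyzes spontaneous adverse-event reports in the FAERS dialect:
quarterly `$`-delimited ASCII tables (DEMO, DRUG, REAC, INDI, OUTC, THER,
RPSR) joined on the report identifier. This vignette documents the
statistical models, the conventions and tunable parameters behind each
stage, what the synthetic-data generator does and does not emulate, and
the numerical choices that make runs reproducible.

## Report normalization and de-duplication

One analysis unit is the de-duplicated report. Parsing is deliberately
forgiving: rows with the wrong field count (stray delimiters occur in
real quarters) are rejected and counted in a provenance table, join
orphans (DRUG/REAC rows without a DEMO row) are counted and dropped, and
unit normalization is total — every `(value, code)` pair either maps
through the documented FAERS unit tables (ages in decades, years,
months, weeks, days or hours; weights in kg, lb or g) or becomes
missing, never an error. Normalized ages outside [0, 150] years and
weights outside (0, 650] kg are treated as implausible and set missing.
A blank unit code is deliberately *not* assumed to mean years: an
undocumented unit leaves the field missing rather than guessing.

FAERS cases accumulate versions: the same `CASEID` reappears under new
`PRIMARYID`s as reports are amended. Following FDA guidance, one version
survives per case: the one with the most recent `FDA_DT`, ties broken by
the numerically larger `PRIMARYID`. A missing date sorts earliest, so a
dated version always beats an undated one (the more complete record
wins). The operation is idempotent and invariant to input row order, and
a consistency check asserts case uniqueness afterwards.

## Cohorts

Exposure to a study drug is established by exact matching of normalized
verbatim names — uppercased, whitespace-collapsed, trailing salt and
formulation tokens stripped — against a user-editable dictionary of
generic and brand synonyms (both `drugname` and the active-ingredient
field are consulted; the default dictionary covers 14 targeted agents
used in NSCLC across the EGFR, ALK, ROS1, RET and KRAS-G12C classes).
Fuzzy matching is intentionally out of scope: silent approximate matches
are a larger pharmacovigilance risk than missed spelling variants, and
the dictionary is the transparent place to add variants.

The primary analysis keeps only reports in which the study drug is coded
*primary suspect*, the most specific of the four FAERS role codes.
Indication filtering is optional: when enabled, a qualifying indication
term (default: common FAERS codings of non-small cell lung cancer, fully
overrideable) must attach to the matched drug's `drug_seq`; a
report-level fallback is available because real INDI linkage is
imperfect. A report naming two study drugs as primary suspect
contributes to both cohorts; with the default generator each report has
exactly one primary suspect, so synthetic cohorts are disjoint.

Descriptive summaries report counts/percentages for sex, reporter type
and outcome (multi-outcome reports count once per category), mean/SD and
median/quartiles for age and weight, and the conventional bins
(<18, 18–64.9, 65–85, >85 years; <50, 50–100, >100 kg). Missingness is
profiled per field and never imputed — multiple imputation is a
deliberate non-goal, replaced by the transparent missingness report.

## The four disproportionality methods

Every drug–event pair is summarized by the 2×2 table `a` (drug and
event), `b` (drug, no event), `c` (event, no drug), `d` (neither), with
`N = a+b+c+d` and expected count `E = (a+b)(a+c)/N`. The comparator
defaults to the entire de-duplicated corpus; a flag restricts it to the
indication-defined population instead, which answers a subtly different
question (excess reporting relative to the disease population rather
than the whole database).

**PRR.** `PRR = [a/(a+b)] / [c/(c+d)]`, flagged with the chi-square
statistic `N(|ad − bc| − y)² / [(a+b)(c+d)(a+c)(b+d)]`. The continuity
correction `y = N/2` (Yates, numerator floored at zero) is the default,
being the dominant convention in the FAERS disproportionality
literature; `y = 0` (Pearson) is an option. Signal rule: `PRR ≥ 2`,
`χ² ≥ 4`, `a ≥ 3`. The three-report minimum is housed inside the PRR
flag; because the key-signal call is a conjunction, it gates the final
call either way.

**ROR.** `ROR = ad/(bc)` with the Wald interval
`exp(ln ROR ± 1.96·sqrt(1/a + 1/b + 1/c + 1/d))`; signal when the lower
bound `ROR025 > 1`. Any zero cell makes the statistic undefined; this is
carried as a soft `NA` whose flag is false, so sparse terms can never
crash a pipeline — they simply cannot signal.

**BCPNN information component.** The relative reporting rate is given the
shrinkage posterior `Gamma(a + ½, E + ½)` (shape, rate), so
`IC = log2[(a + ½)/(E + ½)]` and `IC025` is the log2 of the exact 2.5th
posterior percentile; signal when `IC025 > 0`. The add-½ shrinkage keeps
every table defined and pulls sparse cells toward independence. A
"two-sigma" approximation (`IC − 2·SD[log2 λ]`, via the trigamma
function) is available for compatibility with normal-approximation
implementations. On fully symmetric tables `IC = 0` exactly, and
`IC025 < IC` always.

**MGPS.** The multi-item gamma–Poisson shrinker places a two-component
gamma mixture prior `p·Gamma(α₁, β₁) + (1−p)·Gamma(α₂, β₂)` on the
relative reporting rate; marginally each count is a mixture of negative
binomials with `NB(a; α, β, E)` having size `α` and success probability
`β/(β+E)`. The five hyperparameters are fitted by marginal maximum
likelihood over all pairs in scope (default: pairs with `a ≥ 1`,
matching the scan scope; a flag includes the zero-count grid).
Optimization runs in unconstrained space (log shapes/rates, logit
weight), Nelder–Mead followed by a BFGS polish, multi-started from the
conventional start `(0.2, 0.1, 2.0, 4.0, 1/3)` plus deterministic
perturbations — no random restarts, so the fit needs no seed. The
posterior for a pair is again a two-component gamma mixture;
`EBGM = 2^{E[log2 λ]}` follows from the digamma function and `EB05` is
located by bracketed root-finding on the mixture CDF between the two
component quantiles, to absolute tolerance 1e−8. Signal when
`EB05 ≥ 2`.

A note on fitting scope: when the *data themselves* are a complete
simulated grid, the `a ≥ 1` restriction is a truncated likelihood and
noticeably biases the implied prior mean upward; hyperparameter-recovery
checks therefore fit with `include_zeros = TRUE`. On a real scan the
zero cells are not enumerable without fixing a PT universe, which is why
the truncated scope is the operational default — a documented,
conventional compromise.

**Key signals.** A pair is a *key signal* only when all four criteria
hold simultaneously. No further multiplicity adjustment is applied: the
four-way concordance is itself the false-positive control, and the
package's null synthetic corpora measure its realized false-positive
proportion (≤ 1% at the default study conditions). Rankings (top 10 by
report count, top 5 by EBGM) break ties by the respective other field
descending, then PT lexicographically, so outputs are deterministic.

## Atlas and shared-PT structure

Key-signal PTs are grouped per drug by System Organ Class through a
user-supplied two-column mapping (MedDRA content is licensed and never
bundled; the generator emits a mock map). MedDRA's multiaxiality is
collapsed to one primary SOC per PT — redistributing a PT across SOCs
would break the conservation law that per-drug SOC counts sum to the
drug's key-signal count, which the tests enforce. Unmapped PTs fall
under an explicit `UNMAPPED` sentinel rather than disappearing.
"Marker–organ concordance" (laboratory-abnormality signals co-occurring
with an organ-specific SOC) has no established quantitative criterion;
the package flags joint enrichment when both the Investigations SOC and
the organ SOC hold at least `min_pt` signal PTs (default 2) — a
package convention, clearly labelled as such.

## Similarity network and MDS

Each drug is represented by its key-signal PT set; pairwise similarity
is the Jaccard coefficient `J = |∩|/|∪|` (0 when both sets are empty,
with a warning), and `D = 1 − J` is a metric. The network backbone keeps
edges at or above the linear-interpolation (type 7) quantile of the
upper-triangle similarities at the chosen percentile (default 80th,
sensitivity 70th/90th). Ties at the threshold are kept — "at or above" —
so slightly more than the nominal share of edges can survive, and
backbones nest across percentiles by construction. Drugs with empty
signal sets stay as isolated nodes so the node set always equals the
panel.

The 2-D embedding is classical (Torgerson) multidimensional scaling:
double-center the squared distances, `B = −½·C·D²·C`, and take the top
two eigenpairs. Jaccard distances need not be Euclidean, so negative
eigenvalues can occur; they are clamped to zero and their relative mass
reported. Axis signs are fixed by making each axis's largest-magnitude
coordinate positive, and heatmap leaf ordering uses average-linkage
clustering on `D` with label-sorted input, so both outputs are exactly
reproducible. One caveat found while validating: *rank* correlations
between embedded and input distances degenerate on class-structured
Jaccard matrices because between-class distances are exactly tied (an
exact 2-D embedding can show Spearman ≈ 0.75 with Pearson = 1.0), so
embedding fidelity is checked via the linear correlation, the
within-closer-than-between separation, and the bound that embedded
distances never exceed inputs beyond the clamped eigenvalue
contribution.

## The synthetic corpus: what it emulates, and what it does not

The generator is first-class, tested code. Each report draws one
primary-suspect drug by exposure probability, then every vocabulary PT
independently with its background probability, multiplied by `rho`
(capped at 0.99) for planted drug–PT pairs. Duplicates mimic FAERS
versioning — same case, larger primaryid, later date — rather than exact
row copies, so the real de-duplication rule is exercised. Demographics
come with unit-code variety (some ages in months/decades, some weights
in pounds) and configurable per-field missingness; panel reports always
carry a qualifying indication so ground-truth accounting is exact
whether indication filtering is on or off.

The reference study conditions are: 50 000 reports; the 14-agent panel
with exposure probabilities 0.015–0.03 (cohorts of ~750–1500, echoing
the several-fold volume differences between agents in real spontaneous
data); 200 PTs over ten SOCs with background probabilities cycling over
{0.002, …, 0.012} (~1.3 events per report); per class five shared
planted PTs plus three drug-unique PTs per drug, all at `rho = 5` on
terms with background probability ≥ 0.006 so every planted pair expects
at least 20 co-reports; 5% duplicate versions; missingness of 3% (sex),
15% (age), 30% (weight), 20% (country), 10% (reporter type). Under
these conditions the pipeline's sensitivity for planted pairs is ≥ 0.9
with false-positive proportion ≤ 1%, the backbone's connected
components recover the planted classes (adjusted Rand index ≥ 0.8), and
no PT signals across all 14 drugs (disjoint unique blocks), the
structural analogue of finding no universal class effect.

Deliberate simplifications: events are conditionally independent given
the drug (the simplest structure under which the 2×2 model is
well-specified), with no PT–PT dependence, no reporting dynamics over
time, no drug–drug interaction effects, and exactly one suspect drug
per report. Passing recovery tests therefore demonstrates correctness
of the machinery under a well-specified model — not performance on real
FAERS data, where duplicates are messier, names dirtier, and
co-reporting correlated.

## Reproducibility and problem sizes

All randomness flows from a single configured seed; the MGPS fitter and
every ordering rule are deterministic, so a rerun with the same seed and
configuration is byte-identical — the run manifest deliberately omits
wall-clock timestamps for this reason. The test suite and the
reproduction script work at the reference size of 50 000 reports for
the end-to-end properties (a scale at which binomial noise on planted
counts is a few percent), 1 000 random tables for closed-form oracle
agreement, and 5 000 simulated pairs for hyperparameter recovery; these
sizes were chosen so each check's sampling error is far from its
decision boundary.

## Known limitations

Only the post-2012 FAERS schema is read (the legacy ISR-keyed dialect is
refused with a clear error). Exact-match drug identification will miss
unlisted misspellings. The BCPNN point estimate follows the
gamma-posterior shrinkage formulation; published analyses vary in which
BCPNN variant they use, so absolute IC values may differ slightly across
implementations even when signal calls agree. Disproportionality
statistics are reporting-rate contrasts, not incidence estimates: the
package measures signal structure, and its outputs should be read as
hypothesis-generating.
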