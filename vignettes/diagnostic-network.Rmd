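---
title: "An augmented BN2O network for cluster-B personality disorders: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An augmented BN2O network for cluster-B personality disorders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdnet)
```

## The model

`pdnet` implements a three-layer Bayesian network for the five dramatic
and emotional personality disorders. The first two layers form a BN2O
architecture, the standard shape of probabilistic diagnostic expert
systems: independent binary disease roots above, conditionally independent
finding nodes below. The third layer is the distinctive extension: binary
*psychological distress* nodes, one per symptom cluster plus one general
node, that aggregate the capacity of a cluster to cause clinically
significant distress. Their purpose is clinical: when enough symptoms are
absent to keep every categorical diagnosis negative, the distress layer
can still flag maladaptive clusters and rank therapeutic targets.

Three structural assumptions keep the model tractable and elicitable:

* no disorder–disorder edges — comorbidity is expressed through shared
  symptom children, not direct dependence;
* no symptom–symptom edges — correlated symptoms were avoided at the
  variable-selection stage, and a clamped finding is unaffected by its
  parents anyway;
* independence of causal influence within each symptom's CPT — each
  disorder's effect on a symptom does not depend on the other disorders,
  their order, or interactions. This is what lets a 5-parent CPT be built
  from 5 elicited numbers instead of 32.

### State spaces

DSM criteria and defense mechanisms are binary (absent/present). The four
level-of-personality-functioning (LPF) scales are graded low/medium/high
with *low* as the neutral state. Five-factor (FFM) traits and biosocial
polarities are graded with *medium* neutral: a medium score is
statistically unremarkable, and either tail may be the deviant one
depending on the disorder (e.g. antisocial pushes Anxiety *down* while
borderline pushes it *up*).

### Canonical CPT models

All three models are calibrated against two kinds of elicited numbers:
the single-cause probability $q_i$ of the target state given disorder
$D_i$ alone, and the baseline (leak) $l$, the prevalence of that state in
the absence of any disorder. The package treats exact single-cause
calibration as the binding contract: in every model, the CPT row with
exactly one parent present reproduces $q_i$ to machine precision, and the
all-absent row reproduces the baseline.

**Leaky noisy-OR** (binary symptoms). Link strengths are
$c_i = (q_i - l)/(1 - l)$ — the unique calibration consistent with both
the leak and the single-cause marginals — and
$P(S^+ \mid \mathit{pa}) = 1 - (1-l)\prod_{i \in \text{present}} (1-c_i)$.
Arcs weaker than the leak ($q_i < l$) are a calibration error; the
validator rejects them before any CPT is built.

**Leaky noisy-MAX** (graded, neutral low; all arcs point at *high*). Each
cause contributes an independent graded effect and the child takes the
ordinal maximum of the effects and the leak. Only one number per arc was
elicited, so the per-state effect distribution is underdetermined; the
package uses two-point effects (mass $c_i$ on *high*, remainder on *low*)
with a `medium_split` option (default 0) that diverts a fraction of the
non-high mass to *medium*. With the default, the MAX reduces to a
noisy-OR on the top state; calibration holds for any split.

**Evidence-weighting model** (graded, neutral medium). The published
description of this model — a "logistic-Gaussian" canonical model in which
the probability of the effect depends on the weighting of evidence for and
against — does not include its functional form, so the package
reconstructs it as additive log-odds evidence against a population
baseline. Each arc toward tail $t$ carries weight
$w_i = \mathrm{logit}(q_i) - \mathrm{logit}(b_t)$; for a parent
configuration the raw tails are
$p_{\text{high}} = \sigma(\mathrm{logit}(b_{\text{high}}) + \sum_\uparrow w_i - \sum_\downarrow w_i)$
and symmetrically for $p_{\text{low}}$, so evidence toward one tail counts
*against* the other — the "for and against" semantics. Because "Gaussian"
may equally refer to a latent-normal threshold reading, a probit link is
provided as an option (`link = "probit"`); the logit link is the default
and both satisfy the same single-cause calibration. When many strong
causes push both tails at once the two raw tails can exceed 1; they are
then rescaled proportionally so that the medium state keeps a floor
$\varepsilon$ (default 0.01). Whether the original model rescales the
neutral state instead is unknowable from its description; the proportional
rescue keeps every row a proper distribution under arbitrarily many
simultaneous causes, and it never triggers in any single-cause row of the
shipped knowledge base, so the calibration contract is unaffected.

### The distress layer

Each of the 13 cluster distress nodes is a *zero-leak* noisy-OR child of
its cluster's symptoms, with link strength equal to that symptom's
elicited distress probability. Zero leak is deliberate: no
spontaneous-distress baseline was elicited, and with leak 0 the elicited
number is exactly P(distress | that symptom alone in its deviant state),
matching the elicitation wording. A graded parent activates its link from
any deviant state targeted by one of its arcs (both tails for traits with
arcs to both tails). The 14th node aggregates the five disorders directly,
using the disorder-level distress probabilities; the alternative reading
(aggregating the 13 cluster nodes) has no elicited parameters and was
rejected. One consequence worth knowing: because graded traits have
substantial baseline tail mass, cluster distress nodes carry non-trivial
probability even with no findings — that is faithful to the elicited
semantics, not an artifact.

The mapping of the four LPF scales onto three distress nodes is not
published; the package uses the self/interpersonal split of the LPF
framework — {Identity, Self-direction}, {Empathy}, {Intimacy} — and keeps
the grouping data-driven (a column in the parameter tables), so any other
partition is a one-line edit. The four FFM distress nodes follow standard
NEO domain membership of the retained traits; the three openness traits
and the six biosocial polarities carry no distress link, as elicited.

### Priors and populations

Disorder roots take their priors from the prevalence table: the clinical
column for confirmatory use, the general-population column for screening.
`build_network(ps, population =)` selects the column; with empty evidence
the posteriors reproduce the chosen column exactly, which doubles as an
end-to-end sanity check.

## Inference

The BN2O layering admits simple exact inference: enumerate the $2^5 = 32$
disorder configurations, multiply each configuration's prior by the
likelihood of the evidence factored over the conditionally independent
symptom children, and normalize. Observed distress nodes contribute an
exact factor without enumerating their parents: the zero-leak noisy-OR
"absent" probability is a product of independent per-parent terms, so
unobserved parents enter through their marginal activation probability
given the configuration. Likelihoods are accumulated in log space (86
factors can underflow) with one final normalization. Contradictory
evidence (total mass zero) raises an error rather than returning NaNs.

A symptom query whose own distress child is observed is the one coupled
case; it is handled by clamping the queried symptom state inside the
distress factor and renormalizing per configuration. Everything is exact —
there is no sampling anywhere in the package — and the engine is verified
against an independently written full-joint enumeration oracle on seeded
random networks.

## Likelihood-ratio diagnostics

For each arc, $LR^+ = q/l$ and $LR^- = (1-q)/(1-l)$, computed from the
stored unrounded fractions and only rounded for display (two decimals,
matching the published convention). Thresholding uses unrounded values
with inclusive boundaries; this is what places the two borderline items
whose $LR^+$ recomputes to 5.01 (printed 5.00) inside the confirmatory
panel. For graded symptoms "test positive" is the arc's target tail and
"test negative" any other state. Panels sort by strength with ties broken
by symptom id for determinism. Two reproduction notes, recorded rather
than corrected: a few published ratios differ in the second decimal
(e.g. 7.08 recomputed vs 7.06 printed) because the authors rounded their
expert means before publishing them; and one borderline screening item
(DSM-BDL-06, recomputed $LR^- = 0.174$) satisfies the published threshold
but is absent from the published listing.

## Delphi machinery

Rounds are expert × item matrices on a 0–100 scale. Aggregation uses the
sample (n−1) standard deviation — with seven experts the distinction from
the population SD matters, and the elicitation protocol does not specify —
and an *inclusive* consensus bound: a response exactly one SD from the
mean counts as consensus, reading "more than one standard deviation away"
literally. Missing responses are excluded per item, never imputed; items
with fewer than two responses are flagged insufficient and excluded from
the consensus rate. Second-round questionnaires contain, per expert,
exactly the items on which that expert dissented, bundled with the item
mean and SD (the feedback shown between rounds); consensus answers are
frozen. Final parameters are last-round means divided by 100.

One subtlety the test suite makes explicit: "dissenters move toward the
mean, therefore the consensus rate rises" is *not* a theorem when the rate
is recomputed with the new round's own mean and SD — convergence shrinks
the SD too, and under Gaussian dispersion the recomputed rate typically
*falls*. What is guaranteed, and tested per seed, is improvement against
the previous round's feedback band. The between-round rise in the
recomputed rate is a property of flat (roughly uniform) expert dispersion
— the regime indicated by a first-round consensus rate near two thirds —
and is tested as an average over twenty seeded synthetic elicitations of
270 items with dissenters adopting the mean.

## Sensitivity analyses

Strength of influence of an arc is defined explicitly (the published
analyses relied on a third-party tool whose metric is undocumented): for
each configuration of the child's other parents, the distance between the
child's conditional distributions across the arc parent's states (maximum
over state pairs), aggregated by unweighted average (default) or maximum,
with Euclidean (default), Hellinger or maximum-absolute distance.
Unweighted aggregation is the default because the third-party weighting
is unknown; a prior-weighted variant would be easy but would no longer be
comparable across populations. Finding impact ranks candidate observables
by the maximum absolute change any single finding on them induces in the
target's deviant-state posterior, computed by exact inference on top of
the current evidence — the quantity used for therapeutic-target ranking.

## The synthetic-data generator

`generate_fixture()` draws random valid knowledge bases for
property-based testing: baselines 0.05–0.45, arc strengths uniform between
baseline + 0.05 and 0.95, distress links 0.2–0.9, clinical prevalences
0.05–0.25 with general prevalences a 10–50% fraction of them. These ranges
mirror the elicited cluster-B tables, so the fixtures stress the same
numerical regime as the real model, including mixed canonical models and
both graded neutral conventions. What they deliberately do *not* emulate:
correlated expert noise, the heaped rounding of real elicited values
(multiples of ~0.7 from seven-expert means), or realistic comorbidity
structure. Passing the fixture-based properties therefore demonstrates
algorithmic correctness (calibration, normalization, exact inference,
round-trips), not clinical validity — which, as for the original model,
would require patient data.

## Numerical and testing choices

* All probabilities are converted from the percent scale at load time;
  every internal computation is on [0, 1].
* Fixture-based oracle comparisons use networks of at most 12 nodes
  (2 disorders, 4 symptoms, up to 4 distress nodes) so the full joint
  table stays small; the suite runs 100 such seeded networks in the
  acceptance properties and ~12 in the unit tests.
* CPT row order enumerates parent configurations with the last parent
  varying fastest; the XMLBIF writer flattens tables in that order with
  child outcomes innermost and serializes with 17 significant digits, so
  an export/import cycle reproduces every double exactly.
* The evidence model's tail rescue uses $\varepsilon = 0.01$; the value is
  inert for the shipped knowledge base (no single-cause row overflows) and
  only shapes extreme multi-cause configurations.
* Zero-probability evidence raises; validators report instead of raising
  and return every violation, not just the first.

## Known limitations

* The evidence-weighting model is a reconstruction constrained by the
  published description and exact single-cause calibration; other
  functional forms satisfy the same constraints, and multi-cause rows may
  differ from the original implementation's.
* The published summary statistics of the elicitation cannot all be
  reproduced exactly from the published (rounded) cells; the package
  computes its summaries from the shipped tables and documents the
  residual drift where it occurs.
* Expert-elicited parameters encode the panel's beliefs, not measured
  frequencies; posteriors should be read comparatively (across disorders
  for one patient), not as calibrated risks.
* The model is diagnostic-support machinery. It has not been validated on
  a clinical sample, and nothing in this package changes that.
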