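---
title: "Prioritizing natural extracts by bioactivity and structural novelty"
author: "extractprio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing natural extracts by bioactivity and structural novelty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Large collections of crude natural extracts (NEs) are screened against a
reporter assay faster than their constituents can be isolated and
identified. Most hits turn out to contain well-known compounds, so a
triage step has to combine two orthogonal pieces of evidence before any
isolation work starts: *is the extract active, and is that activity
specific?* and *is the extract likely to contain chemistry nobody has
described yet?* `extractprio` implements that triage as a reproducible
pipeline: dual-luciferase dose-response classification, four
structural-novelty component scores computed from untargeted LC-MS2
metabolite profiling and taxon literature counts, a combined Priority
Score, and a sequential selection cascade that reduces the collection to
a ranked shortlist.

Because the raw screening tables of a real campaign are not available at
desk scale, the package ships a synthetic-collection generator with
planted ground truth. Every claim the test suite makes about recovery
rates is a claim about these synthetic conditions, not about any
particular wet-lab data set.

## Dose-response model

Extracts are screened in single repeats at five concentrations (50, 25,
12.5, 6 and 3 µg/mL) against two luciferase channels: TopFlash (firefly,
reporting Wnt/β-catenin transcriptional activity) and Renilla
(constitutive, reporting cell viability). Raw luminescence is normalized
to the stimulated vehicle control, and each channel is fitted with a
four-parameter logistic

$$r(c) = r_\infty + \frac{r_0 - r_\infty}{1 + (c/\mathrm{IC}_{50})^h},$$

where $r_0$ is the zero-dose asymptote, $r_\infty$ the infinite-dose
asymptote and $h$ the Hill slope. Fitting is bounded Levenberg–Marquardt
least squares with a multi-start grid over IC50 (six log-spaced starts
spanning the tested range) and Hill slope (0.7, 1.5, 3), with a
Nelder–Mead fallback when no start converges.

IC50 recovery under these conditions is evaluated where the true value
lies inside the tested range; an IC50 beyond 50 µg/mL is not a number
five points can estimate, and the pipeline treats it as the bound it is.

Two numerical choices matter with only five single-replicate points:

* **The control anchor.** Normalization *defines* the zero-dose response
  as 1, so the vehicle control enters the fit as an observation at
  concentration 0. Without it the top plateau is unidentifiable whenever
  the response is already falling at 3 µg/mL, and the fitted IC50 drifts
  upward by 50% or more for potent extracts. With the anchor, the median
  relative IC50 error at 10% multiplicative noise is about 10% for
  IC50s below 5 µg/mL and about 20% across the 8–45 µg/mL range.
* **Bounded asymptotes.** Normalized luminescence cannot be negative, so
  both asymptotes are constrained to be ≥ 0. This removes a family of
  shallow-slope, negative-plateau solutions that otherwise win on noise.

IC50s fitted beyond the highest tested concentration are reported as the
bound `">max_tested"`, never as extrapolated numbers; flat curves give
`"not_estimable"`.

### Activity classification

An extract is called **toxic** when its Renilla IC50 is estimable and
less than 1.7 times its TopFlash IC50 — the TopFlash drop is then
attributed to cytotoxicity rather than to specific pathway inhibition.
Modulation is called only when the magnitude of the fitted response
change from zero dose to the highest tested concentration,
$|r(c_\max) - r_0|$, reaches the effect floor of 0.3 (fraction of
control; configurable). The floor is applied to this fitted span rather
than to the asymptotic amplitude $|r_0 - r_\infty|$ because the
unconstrained asymptotic amplitude of a five-point fit can lie far
outside the observed window; the sign of the span gives the direction
(down = inhibitor, up = potentiator). Categories: *inhibitor* (TopFlash
down, not toxic), *potentiator* (TopFlash up), *cytotoxic_only* (Renilla
down without specific TopFlash modulation, or TopFlash down but toxic),
*inactive* otherwise. Inhibitors get nested potency tiers at ≤ 5, < 10
and < 50 µg/mL.

## MEMO fingerprints and the Similarity Component

Each extract's MS2 spectra are summarized alignment-free as counts of
binned fragment peaks (`peak@m/z`) and neutral losses (`loss@m/z`,
precursor minus fragment, restricted to 10–200 Da). The bin width
defaults to 0.01 Da; neither value is prescribed by the screening
protocol, both follow common practice for this kind of fingerprint and
are configurable. Counts, not intensities, populate the matrix, and one
token is recorded per occurrence (per fragment, per spectrum), which
makes the fingerprint additive over spectrum lists.

The Similarity Component (SC) flags extracts whose fingerprint is
substantially dissimilar from the rest of the collection. The count
matrix is row-normalized to relative frequencies and reduced by PCA to
at most 10 components before scoring. The compact ordination matters: in
a fingerprint matrix most trailing components carry only token-sampling
noise, and retaining them dilutes isolation- and density-based detectors
until genuine outliers can score *less* anomalous than inliers. Three
detectors score the reduced matrix: a k-nearest-neighbour local outlier
factor (k = 10), an isolation forest (100 trees, subsample 256), and a
one-class SVM with a deliberately wide radial kernel (γ two orders of
magnitude below the median-distance heuristic, ν = 0.1) — with a tight
kernel the decision values of far-away rows saturate at the margin and
exactly the extracts of interest become indistinguishable from one
another. Each detector flags rows whose anomaly score exceeds its
median + 3 MAD; SC = 1 when at least 2 of the 3 detectors agree. All detectors are seeded, so SC is
deterministic given the seed. With fewer than 10 extracts the component
is undefined and reported as 0 with a warning; an all-identical matrix
yields no outliers.

## The other component scores and the Priority Score

* **Feature Component (FC)** — the fraction of the extract's features
  that are both *specific* (detected in at most 10% of the collection's
  extracts; configurable) and *unannotated* (no structural annotation at
  or above the score threshold). Ranges over [0, 1].
* **Literature Component (LC)** — taxon-level novelty from reported-
  compound counts: $\mathrm{LC} = \sum_r w_r \max(0, 1 - n_r/\kappa_r)$
  over ranks species/genus/family with weights 0.5/0.35/0.15 and caps
  20/100/500. LC is exactly 1 for a taxon with no reports and 0 once
  every rank reaches its cap. The linear-ramp form and its caps are this
  package's choice; only the direction (fewer reports → closer to 1) is
  prescribed by the original scoring idea, and the selection cascade
  uses the strict `< 10 reports at species and genus` rule, not an LC
  threshold, as the normative literature filter.
* **Class Component (CC)** — 1 when some predicted chemical class
  (confidence ≥ 0.5) has never been reported for the taxon at species or
  genus level; matching is exact-string on normalized names, fuzzy
  ontology matching is out of scope.
* **Priority Score** — $\mathrm{PS} = \mathrm{FC} + w_L \mathrm{LC} +
  w_C \mathrm{CC} + w_S \mathrm{SC}$ with unit default weights; the
  ranking is invariant to a joint positive rescaling of the weights.

## The selection cascade

Filters are applied in the screening campaign's order — (1) non-toxic
inhibitors with IC50 ≤ 5 µg/mL, (2) SC = 1, (3) fewer than 10 reported
compounds at both species and genus level, (4) CC = 1 — with each
stage's surviving set recorded, and the final set ranked by PS
(descending), ties broken by FC then extract id (the original ranking is
informal; the tie-break makes it total and deterministic). Because the
filters are conjunctive the final set is invariant to stage order, which
the tests assert on randomized inputs; the order only shapes the
intermediate funnel counts. A manual post-hoc literature review (e.g.
excluding taxa whose actives are already known) is modelled as an
optional exclusion-list stage, not as text mining.

## Mass calculus

Monoisotopic masses come from an embedded CHNOPS isotope table (≥ 9
decimals). Theoretical adduct m/z is (neutral mass + delta)/charge with
registered adducts [M+H]+, [M+Na]+, [M+K]+, [M+NH4]+ and [M+2H]2+. The
[M+H]+ delta is the proton mass 1.007276466 Da — the hydrogen-atom mass
minus the electron mass — because the electron's 0.00055 Da matters at
sub-ppm scale: with this convention the worked example (observed
479.2793 vs protonated C30H38O5) reproduces a +0.21 ppm error at
two-decimal rounding, matching dereplication practice. Printed ion
formulas such as C30H39O5 are read as protonated ions whose neutral has
one H fewer. ppm errors are reported rounded half-away-from-zero to two
decimals. Formula assignment enumerates compositions within per-element
bounds depth-first with a residual-mass window, returns all candidates
within tolerance sorted by |ppm error| (ties by formula string), and is
validated against round-tripping randomly drawn formulas through their
own computed [M+H]+ m/z.

## What the synthetic generator emulates

`generate_collection()` produces, under one seed, everything the
pipeline consumes. Its defaults are the study conditions the tests refer
to:

* **Activity**: 497/1600 ≈ 31% of extracts active, split 148:241:108
  into potentiators, inhibitors and solely cytotoxic extracts. Inhibitor
  IC50s follow the campaign's reported tier mix — of 241 inhibitors, 30
  at ≤ 5 µg/mL (drawn uniform 1.5–4.5), 23 more below 10, 79 more below
  50, and the remainder beyond the tested range (55–120) — so a
  realistic fraction of inhibitors is only callable by its fitted span,
  with the IC50 reported as the ">=50" tier. Cytotoxic extracts get a
  Renilla IC50 at 0.6–1.2 times their TopFlash IC50, i.e. within the
  toxic regime of the 1.7× rule. Hill slopes are uniform 0.8–2.
* **Plates**: the five screening concentrations, single replicate,
  lognormal multiplicative noise with CV 10% (unit mean) — plate readers
  are heteroscedastic and responses positive.
* **Features**: ~80 per extract (Poisson), 60% drawn from a shared pool
  of 300, m/z uniform in 100–1000 Da, retention time 0.5–7.0 min
  (the acquisition window), 40% annotation rate (planted survivors 10%,
  with their private features essentially unannotated).
* **Spectra**: 20 spectra per extract, 6–12 fragments each, drawn from a
  shared 400-token vocabulary; planted outliers (5% of the collection)
  draw ≥ 80% of fragments from per-extract private slices of a disjoint
  vocabulary, so outliers are dissimilar from the bulk *and* from each
  other (mutually similar outliers would mask one another in
  density-based detection).
* **Taxa**: negative-binomial literature counts (typical extracts:
  mean 30 at species, +60 at genus); planted survivors get 0–5 species
  and < 9 genus reports and carry one predicted class never reported for
  their taxon.
* **Planted truth**: 4 extracts are forced to satisfy every cascade
  stage; their ids are shuffled into the collection.

What it does **not** emulate: real fragmentation chemistry, correlated
annotation errors, retention-time structure, plate edge effects,
taxonomic synonymy, or the long-tailed feature-sharing structure of real
collections. Passing recovery tests therefore demonstrates that the
machinery is correct and well-calibrated under these idealized
conditions, not that the same numerical recovery rates would hold on a
real campaign.

## Problem sizes and reproducibility

The reference scenario is 200 extracts; the dose-response recovery study
uses 500 simulated extracts; the end-to-end recovery property is
averaged over 20 seeds of the 200-extract scenario; funnel-order
invariance is fuzzed over 1,000 random inputs. These sizes give stable
estimates of the recovery rates while keeping a full run of the analysis
scripts and test suite in the minutes range on one CPU. All randomness
flows from explicit integer seeds; identical seeds give byte-identical
scenario files and reports.

## Known limitations

* Single-replicate five-point curves fundamentally limit IC50 precision;
  values below the lowest tested concentration (3 µg/mL) rest on the
  control anchor and the curve shape, and should be read as "potent"
  rather than as precise numbers.
* The 1.7× toxicity rule compares two noisy IC50s; near the boundary the
  toxic flag is unstable under noise, which is inherent to the rule.
* SC depends on the collection context: the same extract can be an
  outlier in one collection and unremarkable in a larger, more diverse
  one. The MAD thresholds assume outliers are a minority.
* LC and CC inherit whatever inconsistencies the literature table has
  (species counts exceeding genus counts are warned about, not fixed).
* Several printed HRMS errors in the source data are internally
  inconsistent with their four-decimal observed m/z; the package
  reproduces the one self-consistent worked example and otherwise
  reports what it computes.
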