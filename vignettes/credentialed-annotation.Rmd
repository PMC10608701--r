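---
title: "Isotope-credentialed metabolite annotation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isotope-credentialed metabolite annotation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(credmet)
```

## The problem

Untargeted LC-MS metabolomics produces thousands of features per run, most
of which are not metabolites: media components, solvent clusters, adducts,
and chemical noise. Even for genuine metabolites, a measured accurate mass
alone rarely determines a molecular formula — at 5 ppm, a mass above
300 Da is typically consistent with dozens of CHNOPS compositions.

A reference culture grown on stable-isotope-labeled nutrients solves both
problems at once. A microbial culture (e.g. yeast) is grown to full
isotopic enrichment in four media: unlabeled, U-13C, U-15N, and U-13C+15N.
Every biosynthesized metabolite then appears as a *quartet* of peaks, one
per condition, whose mass shifts are exact functions of its elemental
composition:

* 13C condition: shift = `c` × (m(13C) − m(12C)) = `c` × 1.0033548 Da
* 15N condition: shift = `n` × (m(15N) − m(14N)) = `n` × 0.9970349 Da
* dual condition: the sum of both

where `c` and `n` are the metabolite's carbon and nitrogen atom counts.
Observing all four peaks *credentials* the feature as biological (a media
contaminant cannot shift, because it was never biosynthesized from the
labeled nutrients) and simultaneously measures `c` and `n`, which
collapses the formula search space. `credmet` implements this workflow:
quartet matching, atom-count inference, constrained formula enumeration,
tiered library annotation, and merging of results across ESI/APCI ion
sources and both polarities into one metabolite database.

## Quartet matching

For each unlabeled feature with observed m/z and retention time, the
matcher converts m/z to a neutral mass `M` (assuming [M−H]⁻ in negative
mode, [M+H]⁺ in positive; the 0.00055 Da electron term is included because
at m/z 70 it alone is ~8 ppm) and searches candidate carbon counts
`c ∈ [0, min(c_max, ⌊M/12⌋)]` and nitrogen counts
`n ∈ [0, min(n_max, ⌊M/14⌋)]`. A partner peak supports a candidate if it
lies within `mz_tol_ppm` of the predicted shifted m/z, co-elutes within
`rt_tol`, and has a labeled/unlabeled intensity ratio inside
`intensity_ratio_bounds` (full enrichment means the labeled culture
produces the same metabolite at a comparable level).

Candidate `(c, n)` pairs are scored by **support** — `full` (partners in
all three labeled conditions), `triad` (two), `pair` (one) — then by the
worst partner ppm error. Ties on both are flagged `ambiguous`.
`credential()` keeps only full-support, unambiguous quartets; this is the
set passed downstream. Two deliberate consequences:

* A feature present only in the unlabeled condition (the background class
  credentialing exists to remove) can never reach full support.
* A feature with a single labeled partner cannot pin down both atom
  counts; it is emitted with `pair` support and the ambiguity flag, and
  never credentialed.

Conflicts — two unlabeled features claiming the same labeled peak — are
resolved greedily in order of descending unlabeled intensity. Greedy
claiming is deterministic and reproducible; a global assignment
(e.g. Hungarian) could in principle rescue the weaker feature, but the
conflict rate at realistic feature densities is far too low to justify
the added machinery, and determinism is worth more here.

Key defaults (all exposed in `match_config()` and the YAML config):

| parameter | default | unit | rationale |
|---|---|---|---|
| `mz_tol_ppm` | 5 | ppm | routine accuracy of a 120k-resolution Orbitrap |
| `rt_tol` | 0.5 | min | co-elution window for one HILIC method |
| `intensity_ratio_bounds` | (0.2, 5) | — | biological variation between cultures, without admitting unrelated peaks |
| `c_max`, `n_max` | 40, 10 | atoms | covers water-soluble primary metabolites below m/z 1000 |

The m/z windows these tolerances imply are what limit accuracy: with
~2 ppm scan-to-scan mass noise on both members of a pair, the *relative*
error of an observed shift has an SD near 3 ppm, so a 5 ppm window
excludes a few percent of true partners. That trade-off is intentional —
widening the window admits background peaks faster than it recovers
partners.

## Formula enumeration under the labeling constraint

`decompose()` enumerates formulas for a neutral mass with `(c, n)` fixed.
Only O, P and S are looped over their bounds; the hydrogen count is
*solved* from the mass residual (`h = round(residual / m(H))`), which
reduces the enumeration from O(H·O·P·S) to O(O·P·S). Correctness of the
shortcut is guaranteed by test-suite equivalence against a full
nested-loop oracle: solving for `h` can only miss a composition whose
rounded hydrogen count is wrong, in which case its mass error exceeds
half a hydrogen mass and the full loop would reject it too.

Accepted candidates must satisfy, in addition to the ppm tolerance:

* **RDBE** = C + 1 + (N+P)/2 − H/2 within `rdbe_range` ([0, 25]) and
  integer-valued — for neutral even-electron molecules RDBE is an
  integer, which subsumes the classical nitrogen rule.
* **H/C ratio** within `hc_ratio_range` when C > 0. The default is
  **[0.1, 4]**, deliberately wider than the common [0.2, 3.1] heuristic:
  urea (CH₄N₂O, H/C = 4) and similar heavily hydrogenated one-carbon
  metabolites are real, abundant, and central to nitrogen metabolism; a
  bound that rejects urea is miscalibrated for this compound class.
* element bounds H ≤ 80, O ≤ 20, P ≤ 4, S ≤ 4 (golden-rules-style caps
  for small water-soluble metabolites; all configurable).

`constrained_gain()` quantifies what the labeling buys: the candidate set
with `(c, n)` fixed versus C and N free. The constrained set is a subset
by construction; the test suite measures the strict-shrink fraction and
the acceptance script reports the median fold reduction.

## Annotation tiers

Credentialed quartets are matched against a user-supplied reference
library (a TSV of names and formulas with optional RTs, plus an optional
MSP spectral file). A library entry is eligible only if its formula's C
and N counts equal the quartet's `(c, n)` **and** its neutral mass is
within `mass_tol_ppm` — library evidence never overrides the labeling.
Eligible entries are tiered:

1. `standard_confirmed` — RT within `rt_tol` (0.5 min) of an
   authenticated standard's library RT;
2. `ms2_matched` — MS2 cosine ≥ `ms2_threshold` (0.7);
3. `putative_formula` — mass + formula agreement only (also the tier for
   quartets with formula candidates but no library hit);
4. `unannotated` — no formula candidate at all.

The MS2 score is a cosine over square-root-scaled intensities with greedy
closest-first one-to-one fragment pairing within `frag_tol_mz` (0.01 Th).
Square-root scaling is the standard compromise that keeps base peaks from
dominating; the score is symmetric, lies in [0, 1], and equals 1 exactly
for spectra identical up to global scaling. Precursor-mass agreement is
already enforced upstream by the mass/formula eligibility filter, so the
cosine only ever compares spectra of mass-consistent candidates.

## Merging across ion sources

ESI and APCI ionize complementary compound classes, and each polarity
sees a different subset again, so the same metabolite may be annotated in
up to four channels. `merge_annotations()` collapses entries with the
same identity key — best-tier name if annotated, otherwise the Hill
formula string — whose RTs fall in the same single-linkage cluster
(`rt_tol` 0.5 min). The merged entry records the union of detecting
channels, the best tier, and per-channel intensities (kept separate, not
averaged, so source-coverage heat maps remain reconstructable). Input
tables are canonically sorted before clustering, making the merge
order-independent; conflicting names at the same mass and RT are kept as
separate entries rather than guessed at.

## The synthetic study

No public raw data exists for a four-condition labeled reference culture
at this scale, so the package ships a generator that is itself first-class,
tested code. `sample_library()` draws plausible CHNOPS formulas by picking
an integer RDBE first and solving H from it — every sampled formula is
even-electron by construction — with masses in 75–990 Da (both ion forms
inside a 70–1000 scan range), H/C in [0.2, 3.1], RT uniform on the 1–20 min
span of a typical HILIC gradient, and a random fragment spectrum.
`simulate_quartets()` plants each compound's quartet at the exact labeling
shifts and then corrupts it with the study conditions:

* multiplicative m/z noise, SD 2 ppm — Orbitrap-like scan-to-scan error;
* RT jitter, SD 0.05 min — well inside one chromatographic peak width;
* partner dropout, 10% per labeled partner, independently — detection
  failures of the labeled forms (the unlabeled anchor is always planted,
  since recovery is measured from observed unlabeled features);
* one unlabeled-only decoy per compound — the media-background class;
* log-normal intensities with condition-to-condition ratio spread well
  inside the default ratio bounds;
* source design: 40% of compounds ESI-exclusive, 25% APCI-exclusive, the
  rest seen by both; 60% ionize in negative mode — chosen to mirror the
  qualitative coverage asymmetry of a two-source HILIC study.

**What recovery means here.** A planted compound is *recovered* when its
matched quartet reports the correct `(c, n)` unambiguously, at any
support level. With 10% independent dropout of three partners, all four
peaks survive only ~73% of the time, so full-quartet credentialing can
never reach 90%; but the correct `(c, n)` survives any *single* missing
partner (two of the three shifts determine both counts), giving an
expected correct-inference rate near 92% once the ~3 ppm effective shift
noise against the 5 ppm window is folded in. The test suite requires
≥90% recovery and — absolutely — zero credentialed decoys.

What the generator does **not** emulate: partial isotopic enrichment and
isotopologue envelopes (the workflow assumes cultures labeled for many
generations, i.e. fully enriched), adducts other than [M±H], in-source
fragments, chromatographic peak shapes, and cross-run RT drift. Passing
tests therefore demonstrate the matching, inference and merging logic
under realistic noise — not robustness to incomplete labeling or adduct
confusion, which are out of scope.

## Numerical and testing choices

* All randomness flows from a single integer seed; identical
  configurations produce byte-identical peak tables and pipeline outputs
  (asserted in the suite).
* Candidate ranking tie-breaks are total and deterministic (support,
  ppm residual, then `c`, `n`; formula candidates by |ppm|, then fewer
  heteroatoms, then O, P, S counts).
* The S/N filter is strictly `>` (a peak at exactly the threshold is
  rejected), matching S/N > 5 peak picking.
* Oracle tests run quartet matching against an exhaustive brute-force
  search on 100 random ≤20-peak instances, and formula enumeration
  against a full nested-loop grid on 100 random formulas ≤500 Da. The
  study-scale recovery harness uses 1,000 compounds across four channels
  (~5,300 planted peaks plus ~1,350 decoys); these sizes give binomial
  standard errors below one percentage point on the reported rates.

## Known limitations

* Fixed CHNOPS alphabet; halogenated or metal-containing metabolites are
  invisible (extension is a config option on `element_bounds()` only for
  the CHNOPS subset bounds, not new elements).
* One adduct per polarity by default; a metabolite ionizing only as, say,
  [M+NH₄]⁺ will be missed or mis-massed.
* RT identity across sources assumes one chromatographic method; merging
  data acquired with different gradients would need an RT mapping first.
* The MS2 score ignores neutral losses and fragment annotation; it is a
  spectral similarity, not a structure elucidation tool.
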