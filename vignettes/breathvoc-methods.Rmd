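---
title: "Methods: cross-platform annotation of breath VOCs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-platform annotation of breath VOCs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breathvoc)
```

## Scope and model

`breathvoc` annotates oxygenated VOCs in exhaled breath by combining
predicted diagnostic ions from three ionisation techniques with gas
chromatographic retention indices. The underlying model is deliberately
simple and transparent: for each chemical class (ketone, saturated and
unsaturated aldehyde, carboxylic acid, primary alcohol, phenol, other
aromatic) a small declarative rule table states which ions the class
produces on each platform and at what qualitative intensity (`base`,
`major`, `minor`, or `absent` for suppressed ions). Ion m/z values are
computed from the nominal molecular mass with integer transforms
(`M+H` = +1, `M-17`, `M-29`, `M-33`, `M-73`, `M+NO` = +30, the
proton-bound dimer `2M+H`, and hydrates `M+H+nH2O` = +1+18n).

**Nominal masses only.** All instruments modelled are unit-resolution
quadrupoles; every diagnostic m/z is an integer, the electron mass
(sub-mDa) is ignored and all ions are treated as singly charged.
Accurate-mass and isotope-pattern support are out of scope — at masses
below 50 Da even high-resolution analysers struggle with VOCs, and the
unit-mass arithmetic is exactly what the workflow's decisions rest on.

One deliberate internal inconsistency is preserved: the unsaturated-aldehyde
beta-cleavage fragment is encoded as the fixed literal m/z 41, although the
ketene-type formula usually drawn for it (C2H2O) has nominal mass 42. The
diagnostic value in use is 41; the rule table records the number actually
matched against spectra rather than silently "correcting" either side.

## Rule tables

EI and water-PCI rules ship as plain CSV under
`system.file("extdata", ...)` with columns
`chem_class, c_min, c_max, kind, value, intensity_class, mechanism,
requires_flag`; users can extend classes by editing a copy and passing it
to the predictors. Serialising and reloading a table reproduces identical
predictions (tested). Two readings of chain-length boundaries are fixed
here once:

* "short-chain" acids are C ≤ 3 and "long-chain" C ≥ 4 (acetic and
  propanoic acid behave alike; butanoic and longer switch to the
  McLafferty-60-plus-acylium pattern). For the short branch both the
  molecular ion and `[M-17]+` are emitted: for acetic acid these are the
  observed 60/43 pair, and for a C ≤ 3 acid the McLafferty product *is*
  the molecular ion, so no separate fragment is invented.
* under PCI, ">C4" saturated aldehydes means carbon count ≥ 5 and ">C3"
  alcohols means ≥ 4 (strict inequalities).

SIFT-MS channels are a fixed code table because they are few and uniform:
H3O+ protonates everything, with water adducts (capped at n = 2, matching
the observed two-adduct series such as 61/79/97 for acetic acid;
configurable) for phenols, alcohols and acids and an additional dehydration
channel for alcohols; NO+ performs electron transfer on phenols/aromatics,
nitrosonium addition on ketones, unsaturated aldehydes and acids, and
hydride abstraction on saturated aldehydes. Two conventions in this table
are the package's own choices where the channel lists are silent:
saturated aldehydes with H3O+ default to plain protonation, and aromatics
(benzaldehyde-type) are treated like phenols under NO+ and like generic
VOCs (protonation) under H3O+ and PCI. Acid/NO+ dissociative ionisation is
flagged on the result but its fragment list is *not* predicted from
structure — those fragments are kinetic-library knowledge supplied by the
user, and inventing them would fabricate evidence. Alcohols have no NO+
channel: prediction raises an unsupported-channel error and the simulator
simply emits no signal for them on that platform.

Multi-ion-monitoring quantitation uses standard flow-tube kinetics,
`ppbv = 1e9 * (product counts / precursor counts) / (k t N)` with the rate
coefficient `k` (cm^3/s), reaction time `t` (s) and carrier number density
`N` (cm^-3) taken from the user's kinetic library; precursor counts are
summed over the full hydrate series.

## Matching, tiers and thresholds

* **m/z tolerance ± 0.3** — a unit-resolution quadrupole bins to integers;
  0.3 absorbs centroiding error without ever bridging adjacent nominal
  masses.
* **RI tolerance ± 15 index units** — wide enough for run-to-run drift on
  a 60 m column, narrow enough to separate the closest isomer pair the
  workflow must resolve (ethylphenols at RI 1286 vs 1323). Retention is
  compared *as index*, never as raw time: retention times are not aligned
  between the EI and PCI runs, so cross-platform grouping must go through
  the alkane ladder (C5–C20, linear temperature-programmed interpolation;
  requests outside the ladder span are refused rather than extrapolated).
* **Library-score gate 800** — NIST-style match and reverse-match scores
  (0–1000) below 800 do not permit standalone annotation; the gate is
  strict at the boundary and simply flags that cross-platform evidence is
  required.
* A platform supports a candidate when **every** predicted base-peak ion
  is found and at least one base/major ion matched; whether the base
  prediction is also the most intense matched peak is recorded but not
  required (co-eluting compounds legitimately distort ratios).
* **Contradiction** requires a rich spectrum: at least 3 observed peaks
  above the intensity floor with zero base/major predictions matching.
  Absence of evidence on a sparse spectrum never rejects.

Tiers (`confirmed` > `probable` > `tentative` > `rejected`) are this
package's vocabulary for graded annotation confidence; the mapping from
evidence counts is fixed in `screen_candidates()` and documented there.
Adding a matched platform can never lower a tier (tested property). The
two SIFT precursors are treated as two independent evidence records — the
alternative (one combined SIFT platform) would make a single technique
count twice differently; this is an interpretation choice, stated here
once. Candidates with identical SIFT prediction sets (e.g. positional
isomers) carry each other in an explicit ambiguity set until the observed
RI resolves exactly one of them, so downstream logic can demand GC
evidence. Ties in the final ranking are broken by matched-ion count and
then candidate name, making screening invariant under candidate
permutation.

## Intercomparison statistics

Paired platform responses are fitted by ordinary least squares
(`stats::lm`); precision is the percent relative standard deviation; the
detection limit uses the ICH-style `3.3 * blank SD / slope`, converted to
ppbv through the series' loading-to-mixing-ratio factor — the underlying
study reports LODs without stating a method, so the convention is
documented here and isolated in one function for easy substitution.
Cohort class composition normalises summed peak areas to 100% per sample
and summarises across samples by median and quartiles, matching
box-and-whisker presentation.

## The synthetic generator

The generator exists so the entire pipeline can be exercised with known
ground truth. Its defaults are the study conditions the workflow assumes:

* multiplicative lognormal intensity noise with CV 0.09 (the replicate
  RSD regime of flow-tube quantitation);
* intensity bands base = 100, major uniform in [30, 100), minor below 30
  (the "< 30% relative intensity" convention);
* m/z jitter SD 0.1, RI drift SD 5 index units;
* Poisson decoy background (mean 5 peaks per spectrum) uniform over the
  20–250 m/z acquisition range — deliberately chemistry-free background;
* cohort composition medians ketone 77, aldehyde 10, acid 9, phenol 3,
  alcohol 1 percent (renormalised), scattered per sample by a Dirichlet
  draw with concentration 60. The alcohol figure is set to 1 because the
  published composition list is internally inconsistent about alcohols;
  the value chosen keeps the remaining classes at their stated medians.

Everything is a pure function of (configuration, seed). What the generator
does **not** emulate — chromatographic peak shapes, co-elution,
deconvolution artefacts, sorbent-tube breakthrough, humidity effects on
SIFT-MS — bounds what a passing recovery test shows: it validates the
matching and consensus logic, not peak picking on real chromatograms.

Problem sizes used throughout the tests: the 17-compound example library
across all four platforms for annotation recovery (top-1 ≥ 90% demanded,
typically 100% at default noise), 10-point calibration curves, 300
replicate triplicates for RSD recovery, and 200-sample cohorts for
composition-median recovery; each run completes in seconds on one CPU.

## Degenerate inputs and numerical choices

Transforms that would produce non-positive m/z (e.g. `M-73` on a light
molecule) raise a domain error naming the compound; regression refuses
zero-variance x; RSD refuses zero means; LOD refuses non-positive slopes;
composition refuses all-zero areas; readers reject truncated files,
negative intensities, duplicate library names and retention columns on
SIFT tables (no chromatography there). Proton-transfer feasibility with an
unknown analyte proton affinity returns `NA`, never a silent default.

## Known limitations

Bifunctional compounds must be assigned a single class by the caller — no
multi-class merging. Only the water reagent is parameterised for PCI
(methanol's dimer/trimer-forming behaviour is carried as metadata only,
since no ion list exists for it here). No in-silico bond-enumeration
fragmentation, no isotope patterns, no spectral similarity scoring
(library scores are consumed, not computed), and no vendor raw-file or
mzML parsing — peak tables arrive as delimited text.
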