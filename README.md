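# breathvoc

Cross-platform mass-spectrometry annotation of oxygenated volatile organic
compounds (VOCs) in exhaled breath.

## The problem

Breath VOC profiling is a promising non-invasive route to early cancer
detection, but single-platform peak annotation is unreliable: spectral-library
hits are often weak (match scores below 800), SIFT-MS cannot separate isomers,
and EI spectra of small carbonyl compounds look alike within a chemical class.
`breathvoc` implements a consensus workflow that treats three ionisation
techniques as orthogonal witnesses:

* **GC-EI-MS** (70 eV): class-characteristic fragments — alpha-cleavage m/z 43
  for ketones, McLafferty m/z 44 (aldehydes) and m/z 60 (acids), `[M-29]+` for
  C3 aldehydes, `[M-H2O]+`/`[M-33]+`/m/z 31 for primary alcohols, the phenyl
  fragment m/z 77 for substituted benzenes;
* **GC-PCI-MS with water reagent** (proton affinity 697 kJ/mol): soft
  protonation to `[M+H]+` for most classes, `[M-17]+`/`[M-73]+` for long-chain
  saturated aldehydes, hydride abstraction for alcohols;
* **SIFT-MS** (H3O+ precursors at m/z 19/37/55/73, NO+ at 30/48/66):
  class-specific reaction channels — protonation and water adducts,
  electron transfer, nitrosonium adduct `[M+NO]+`, hydride abstraction.

All ion arithmetic is nominal (unit) mass: `m/z = scale * M + delta` for a
transform such as `M+H` (delta +1), `M-17`, `M+NO` (+30), `2M+H` (scale 2) or
`M+H+nH2O` (1 + 18n). Predicted ions are matched against observed peak tables
(±0.3 m/z) together with Kovats retention indices on a C5–C20 alkane ladder
(±15 index units), and each candidate receives a consensus tier:

| tier | evidence |
|---|---|
| confirmed | RI match **and** ≥ 2 MS platforms matched |
| probable | ≥ 2 platforms (no RI), or RI + 1 platform |
| tentative | exactly 1 platform, no contradiction |
| rejected | a rich spectrum contradicts every base/major prediction |

The package also provides platform intercomparison statistics (paired
response regression, relative standard deviation, ICH-style detection limits,
class-composition profiles) and a synthetic-data generator for end-to-end
validation with decoy peaks.

## Worked example

A chromatographic peak at RI ≈ 676 shows EI fragments m/z 60 and 43, and the
PCI run shows a protonated ion at m/z 61. Weak library hits suggest either
acetic acid or ammonium acetate (both MW-compatible at nominal resolution):

```r
library(breathvoc)
lib <- example_library()
peaks <- list(
  EI  = peak_table(c(60, 43), c(80, 100), platform = "EI"),
  PCI = peak_table(61, 100, platform = "PCI"),
  SIFT_H3O = peak_table(c(61, 79, 97), c(100, 60, 35), platform = "SIFT_H3O"))
amm <- compound_record("ammonium acetate", "C2H7NO2", "acid")
screen_candidates(peaks, c(lib["acetic acid"], list(amm)), observed_ri = 676)
```

```
         candidate chem_class      tier n_platforms_matched    platforms_matched n_ions_matched ri_match ambiguity_set
1      acetic acid       acid confirmed                   3      EI;PCI;SIFT_H3O              6     TRUE
2 ammonium acetate       acid  rejected                   1                   EI              1    FALSE
```

Acetic acid (M = 60) explains every observation — EI `[M]+.` 60 and `[M-17]+`
43, PCI `[M+H]+` 61, the SIFT-MS H3O+ series 61/79/97 — and its reference RI
matches, so it is confirmed. Ammonium acetate (MW 77) predicts `[M+H]+` 78,
which matches nothing in the three-peak SIFT-H3O+ spectrum: that platform
contradicts it and it is screened out.

The same machinery runs from a shell:

```sh
$(Rscript -e 'cat(system.file("cli","breathvoc",package="breathvoc"))') \
  annotate --library LIB.csv --ei EI.csv --pci PCI.csv --ri 676 --out report.csv
```

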