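# massdivide

Dry-mass partitioning during cytokinesis, measured from quantitative
phase imaging (QPI) time lapses.

When a cell divides, how evenly does it split its biomass between the
two daughters? QPI answers this directly: the optical path difference
(OPD) light accumulates through a cell is proportional to dry mass per
area, so integrating OPD over a segmented cell footprint and dividing
by the specific refractive increment α = 1.8×10⁻⁴ m³/kg yields the
cell's dry mass — independent of the drastic shape changes of mitosis.
`massdivide` is for cell biologists and microscopists who want to turn
phase-image stacks of dividing adherent or non-adherent cells into
per-division partitioning statistics:

- **Phase unwrapping** — a linear pixel classifier (16 image-statistic
  channels, trained by linear discriminant analysis) plus random-walker
  segmentation finds phase-wrapped regions (tall rounded mitotic cells
  exceed one wavelength of OPD) and applies single positive wavelength
  corrections.
- **Segmentation & mass** — Gaussian low-pass, Otsu thresholding and
  the watershed transform split touching cells along OPD ridges; each
  region is measured (mass, area, perimeter, mean phase shift, shape
  factor 4πA/P², confluence).
- **Tracking** — minimum-cost frame linking (squared centroid
  displacement, Jonker–Volgenant assignment).
- **Division detection** — a parent splitting into two ~50%-mass
  daughters, confirmed in adherent mode by sigmoid matched-filter fits
  of the mean-phase rise at mitotic entry and fall at daughter
  respreading.
- **Partitioning statistics** — the pair-normalized asymmetry
  Δm = 2|m_d1 − m_d2|/(m_d1 + m_d2), its rate of change r, heatmap
  ordering by atan2(r, Δm₀), population mean |Δm| vs time, the mass
  coefficient of variation, binned growth rates, Welch's t test and a
  regression F test.
- **Synthetic movies** — a seeded generator (`simulateMovie()`) renders
  growing, rounding, dividing cells with programmable split fractions,
  post-furrow mass redistribution and phase wrapping, plus a complete
  ground-truth ledger, so the whole pipeline is verifiable without a
  microscope.

## Worked example

Simulate one adherent cell that rounds up, divides 55/45 at t = 75 min
and respreads, then run the full pipeline:

```r
library(massdivide)

scn <- cellScenario("cell1", center = c(60, 60), initialMass = 350,
                    growthRate = 0.2, tEntryMid = 45, tFurrow = 75,
                    tExitMid = c(100, 100), splitFraction = 0.55)
mv  <- simulateMovie(scn, frames = 48, dim = c(120, 120), seed = 1)
res <- runPipeline(mv, pipelineConfig(seed = 1), outDir = "results")

res$events[, c("furrow_frame", "t_furrow_min", "m_d1_pg", "m_d2_pg",
               "delta_m0_signed")]
#>   furrow_frame t_furrow_min  m_d1_pg  m_d2_pg delta_m0_signed
#> 1           26           75 201.8821 163.2361       0.2116907
measureDivisionTimes(res$events)
#>   event_id time_in_mitosis time_rounded_post defined
#> 1        1              33                27    TRUE
res$records
#>   event_id  delta_m0          rate        theta n_frames usable
#> 1        1 0.2116907 -0.0003723694 -0.001759024       21   TRUE
```

Reading the output: the watershed first separates the daughter pair at
frame 26 (t = 75 min, defining t = 0 for the event); the daughters
carry 202 and 163 pg, a signed asymmetry Δm₀ = 0.21 — close to the
programmed 2|2·0.55 − 1| = 0.20. The parent spent 33 min rounded up
before the furrow (programmed entry midpoint 30 min before, recovered
to one 3-min frame) and the first daughter flattened 27 min after
(programmed 25). The asymmetry rate is near zero — no redistribution
was programmed — so θ = atan2(r, Δm₀) ≈ 0, placing this event among
the "asymmetric, stable" group in the population heatmap ordering.
`results/` holds the per-frame region table, tracks, events, asymmetry
records, population curves, both heatmap matrices and a manifest.

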