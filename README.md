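# cardioflux

Quantification of cardiomyocyte Ca²⁺ handling and mitochondrial function
from fluorescence recordings, respirometry and super-resolution images —
with seeded synthetic-data generators so that every analysis stage is
verifiable by parameter recovery, without any experimental download.

The package targets the measurements used to characterise right-ventricular
cardiomyocytes in pulmonary-hypertension models (monocrotaline-treated rats
vs saline controls), but the analyses are generic:

* **Paced Ca²⁺ transients** — Fura-2 340/380 ratio (cytosolic) or Rhod-2
  ΔF/F₀ (mitochondrial) traces, segmented into beats; per beat the package
  reports the diastolic level, amplitude, maximum rate of rise
  (a.u. ms⁻¹), time to peak, and the decay time constant τ from a
  monoexponential fit *y(t) = A·e^(−(t−t_p)/τ) + C*, plus fit quality;
  steady-state summaries average the last *n* accepted beats.
* **Caffeine-bolus assay** — amplitude of the caffeine-induced transient
  (total SR Ca²⁺ store) and the efflux time constant of its decay in the
  continued presence of caffeine (trans-sarcolemmal extrusion, chiefly NCX).
* **Respirometry + membrane potential** — event-marked oxygraph recordings
  segmented into respiratory states (CI Leak, CI OXPHOS, Ca²⁺ titrations,
  FCCP); mass-specific O₂ flux = −slope × V_chamber × 1000 / mass
  (pmol s⁻¹ mg⁻¹); membrane potential from safranine-O partitioning via the
  Nernst equation, ΔΨ = (RT/zF)·ln(C_out/C_in) with
  C_in = (C_FCCP − C_RB)·V_RB/V_mito.
* **Cluster quantification** — Otsu (or fixed) thresholding, 8-connected
  labelling, cluster areas (µm²), density per 1 µm² tile, fractional
  labelled area within an ROI, and nearest-neighbour distances between
  cluster centroids (e.g. RyR2 vs TOM20).
* **Synthetic data** — generators for all three input classes with exact,
  analytically known ground truth, plus a two-group (CON vs MCT) study
  generator and a pipeline runner that checks recovered group-effect
  directions against the generated manifest.

## Worked example

```r
library(cardioflux)

## a 1 Hz paced ratiometric recording with known ground truth
tr    <- genTransientTrace(n_beats = 10, stim_freq = 1, diastolic = 1,
                           amplitude = 0.5, ttp = 0.15, tau_decay = 0.27,
                           noise_sd = 0.01, mode = "ratiometric", seed = 101)
ratio <- computeRatio(tr)
beats <- analyzeBeats(ratio)
steadyStateSummary(beats, n_last = 5)$summary
#>      parameter   mean      sem
#>      amplitude 0.5041 0.004684
#>   time_to_peak 0.1445 0.002000
#>      tau_decay 0.2704 0.002123

## caffeine-bolus assay (SR store content + efflux tau)
caf <- genCaffeineTrace(store_amplitude = 0.78, tau_efflux = 4.75,
                        noise_sd = 0.02, post_s = 30, seed = 7)
analyzeCaffeine(caffeineRatioTrace(caf))
#> Caffeine-bolus transient (event at 10 s)
#>   SR store amplitude: 0.7595 (peak 1.76 - diastolic 1)
#>   efflux tau: 4.722 s (rmse 0.0205, r2 0.9878)
#>   recovered to baseline: TRUE

## safranine-O Nernst conversion (2 mL buffer, 2 mg tissue, 37 C)
calib <- psiCalibration(tissueMass_mg = 2, cTotal_uM = 2, cFCCP_uM = 2)
safranineToPsi(0.5, calib)
#> [1] -183.7353        # mV

## STED-like TOM20 frame at the hypertrophic operating point
img <- genClusterImage(density_um2 = 14.9, mean_area_um2 = 0.027, seed = 3)
cs  <- segmentClusters(img)
c(n = nClusters(cs), per_um2 = clusterDensity(cs)$mean_per_tile,
  mean_area = mean(clusters(cs)$area_um2))
#>        n  per_um2  mean_area
#>     3296    14.65     0.0273
```

The generator amplitudes, time constants and cluster statistics above are
set to the values reported for control and hypertrophic right-ventricular
myocytes, and the analysis recovers each of them from the simulated raw
data: amplitude 0.504 vs 0.5 configured, τ 0.270 vs 0.27, store 0.76 vs
0.78, efflux τ 4.72 vs 4.75, density 14.65 vs 14.9 µm⁻², mean cluster area
0.0273 vs 0.027 µm².

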