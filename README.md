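# ferrotrace

Analysis of single-molecule transmission time traces from plasmonic
nanotweezer (double-nanohole, DNH) trapping experiments on ferritin, plus a
physics-based synthetic trace generator that makes the whole analysis chain
testable without experimental data.

## The scientific problem

When a single protein enters the optical hot spot of a DNH aperture, the
transmitted intensity steps up by a fraction ΔT/T₀ (*dielectric loading*)
and then fluctuates with the protein's Brownian motion and conformational
dynamics. Two signatures separate the iron-free (apo) and iron-loaded
(holo) isoforms of ferritin:

1. **Step contrast.** The holo form is larger and carries a conductive
   ferrihydrite core, so its Clausius–Mossotti polarizability
   α = 4πε₀r³(ε̃ₚ − εₘ)/(ε̃ₚ + 2εₘ), with ε̃ₚ = εₚ + iσ/(ωε₀),
   is higher — trapping a holo-ferritin produces a ~41% larger ΔT/T₀.
2. **Fluctuation magnitude.** The apo shell is floppy: its unfolded 3-fold
   channels produce low-frequency (3–150 Hz) conformational fluctuations,
   giving a larger normalized RMS (NRMS = sd/median of the trapped,
   1 kHz-filtered signal) than the rigid holo form.

During Fe²⁺ loading the 3-fold channels fold and unfold as ions are
transported, switching the fluctuation amplitude between a high ("on") and
a low ("off") state with dwell times of seconds, while progressive
mineralization slowly damps the fluctuations (median sliding RMS falling
from 6.8 to 5.4 mV at the package's calibrated detector scale). ferrotrace
implements the full chain: Gaussian low-pass filtering, decimation, mode
normalization, change-point trap/release detection, sliding-RMS/NRMS/KDE/
PSD metrics, two-state segmentation with dwell-time kinetics, and seeded
permutation tests — all tidyverse-style (traces are tibbles, results are
tibbles, plots are ggplots).

## Worked example

```r
library(ferrotrace)

# one 60 s apo-ferritin trapping run at 10 kHz (T0 = 1 V, trap at 5 s)
tr <- simulate_trap_experiment(preset_apo(), seed = 1)
ev <- detect_trap_event(tr)
ev[, c("t_trap", "T0", "deltaT", "ratio")]
#> # A tibble: 1 × 4
#>   t_trap    T0 deltaT  ratio
#>    <dbl> <dbl>  <dbl>  <dbl>
#> 1  5.00   1.00 0.0500 0.0500

# fluctuation metrics of the trapped segment
f   <- gaussian_lowpass(tr, cutoff = 1000)
seg <- dplyr::filter(f, time > ev$t_trap + 0.5)
nrms(seg$value)
#> [1] 0.006554698

# classify from the two features
classify_isoform(list(nrms = nrms(seg$value), ratio = ev$ratio))$label
#> [1] "apo"
```

The step ratio recovers the preset contrast δ = 0.05 and the NRMS sits in
the apo population (≈ 6.8 mV fluctuation on a 1.05 V trapped level); the
same call on `preset_holo()` traces yields ratio ≈ 0.0705 (41% higher) and
a smaller NRMS, which is what the classifier keys on.

For an iron-loading experiment:

```r
lt <- simulate_loading_experiment(seed = 7)      # trap 5 s, loading 65 s
fl <- gaussian_lowpass(lt, 1000)
rs <- sliding_rms(fl, window = 0.1, hop = 0.05)
sg <- segment_states(rs[rs$time > 65, ])         # on/off gating states
dw <- dwell_statistics(sg); tidy(dw)
mineralization_trend(fl, c(5, 25), 65 + 22 * 60 + c(0, 20))
#> # A tibble: 1 × 3
#>   median_rms_pre median_rms_post relative_change
#>            <dbl>           <dbl>           <dbl>
#> 1           6.85            5.41           0.210
```

`autoplot(rs, segments = sg)` draws the colour-coded on/off RMS trace;
`plot_trace()` and `autoplot()` methods exist for traces, PDFs and
segmentations, and `run_pipeline()` executes the whole chain from a
YAML/JSON config, writing JSON/CSV/PNG outputs and a log.

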