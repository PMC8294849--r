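# mitodyn

Quantification of mitochondrial dynamics in parvalbumin-positive (PV+)
interneurons — and of its physiological consequences — for R.

PV+ interneurons are fast-spiking GABAergic cells whose high energy
demand makes them unusually dependent on mitochondrial positioning.
When Miro1 (Rhot1), the Ca²⁺-sensing adaptor that couples mitochondria
to microtubule motors, is removed from these cells, mitochondrial
trafficking collapses, mitochondria cluster in the soma and near axonal
branch points, axons branch more, hippocampal gamma oscillations speed
up, and anxiety-related behavior changes. Measuring any link in that
chain requires a set of small bespoke analyses that are usually scripted
ad hoc per lab. `mitodyn` packages them as tested, parameterized
functions:

| Module | What it computes |
|---|---|
| trafficking | mobility by the 2 µm / 300 s path-length rule, pause-excluding velocity (pauses > 10 s omitted), path length, percent moving per movie |
| morphometry | SWC I/O, branch points, process counts, compartment lengths, analytic 3D Sholl profiles |
| voxel analysis | capsule-based volume masks, MitoSholl (rolling ball → median → binarize → AND mask → 1 µm shells), branch-point-to-mitochondrion minimum distances, reference-normalized distances, P(mito within 1 µm) |
| image quantification | rolling-ball background subtraction, masked intensities, soma mitochondrial area % and cluster detection, bouton detection / occupancy / mitochondrial content, 33–100 % object-overlap synapse colocalization |
| electrophysiology | normalized-FFT power spectra (Parseval-scaled, 50 Hz mains excluded), gamma (20–80 Hz) peak/area, Gaussian 50 %-width, autocorrelograms, sPSC detection (3 pA and 5×SD floors), train recovery, intrinsic properties, fEPSP slopes |
| behavior | EPM/open-field zone occupancy, trajectory kinematics, rotarod RPM = (end−start)/300 × s + start, T-maze alternation with NO-GO exclusion |
| synthetic data | seedable generators for every input above, each returning its ground truth |

Because the raw microscopy and electrophysiology behind such studies are
rarely shareable, the package ships a first-class synthetic-data module:
every generator is a pure function of its parameters and a seed and
returns ground truth alongside the data, so every estimator is testable
end to end — parameter in, parameter out.

## Worked example: trafficking and gamma oscillations

Generate a 100-track movie (5-s frames, 500 s) in which 23 % of
mitochondria are mobile at 0.17 µm/s, then recover both numbers:

```r
library(mitodyn)

g  <- gen_tracks(100, mobile_fraction = 0.23, speed = 0.17, seed = 1)
st <- track_stats(g$tracks)   # 2 µm / 300 s rule, 10 s pause exclusion
head(st, 3)
#>   track_id path_length_um velocity_um_s is_mobile excluded_time_s
#> 1        1           85.0          0.17      TRUE               0
#> 2        2           85.0          0.17      TRUE               0
#> 3        3           71.4          0.17      TRUE              80

movie_mobile_fraction(st, n_total_mito = 100)
#> [1] 23
median(st$velocity_um_s[st$is_mobile])
#> [1] 0.17
```

Track 3 paused for 80 s; its velocity is still exactly the ground-truth
speed because paused path and paused time are excluded together. The
mobile percentage is the percentage of *all* mitochondria in the movie,
mobile or not, that pass the 2 µm / 300 s rule.

The same round trip for a carbachol-style gamma oscillation — a 300-s
LFP at 5 kHz oscillating at 31 Hz (0.1 mV) in 0.05 mV noise:

```r
lfp  <- gen_lfp(frequency = 31, amplitude = 0.1, noise_sd = 0.05,
                duration = 300, sample_rate = 5000, seed = 1)
spec <- power_spectrum(lfp)        # Welch, 0.5 Hz bins, 49-51 Hz excluded
gamma_metrics(spec, band = c(20, 80))
#> gamma metrics: peak 0.00334 at 31 Hz, area 0.00254
```

The peak frequency lands on the generating 31 Hz bin; peak power and
power area are on the Parseval scale (power summed over all bins equals
the signal variance).

`run_pipeline()` chains every module on synthetic inputs from a single
config (R list or YAML) and writes per-module CSVs plus a JSON run
report that echoes every effective parameter.

## Documentation

The methods vignette (`vignettes/mitodyn-methods.Rmd`) describes each
model and its assumptions, the defaults and their provenance, what the
synthetic generators do and do not emulate, and the package's numerical
conventions. Function-level documentation lives in the roxygen comments
in `R/`.
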