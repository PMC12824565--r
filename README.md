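# fretspt

Combined single-molecule FRET (smFRET) and single-particle tracking (SPT)
analysis of ligand-induced membrane-receptor dimers in two-channel TIRF
movies — together with a ground-truthed synthetic movie generator so that
every stage of the pipeline can be validated quantitatively without any
external data.

## The science

A receptor tyrosine kinase such as MET is activated when a dimerizing
ligand (internalin B) crosslinks two receptors into a 2:2 complex. If the
two ligand copies carry a donor (Cy3B-like) and an acceptor (ATTO
647N-like) fluorophore, the dimer produces FRET: under donor excitation a
spot appears in the acceptor emission channel. Tracking that spot and its
donor counterpart through time yields, per molecule:

* **the dimer lifetime** — the duration of the FRET signal, exponentially
  distributed with the dissociation rate `k_off`; fitted as
  `A·exp(−t/τ)` to the duration histogram (durations > 10 s excluded),
* **corrected FRET efficiency** — with the standard crosstalk algebra
  `F_corr = I_AD − α·I_DD − δ·I_AA` and
  `E = F_corr / (γ·I_DD + F_corr)`, histogrammed and fit with a Gaussian,
* **mobility of dimer vs monomer** — time-averaged MSD per trajectory
  segment, `MSD(t) = 4Dt + 4σ²` fit to the first four lags; FRET-active
  segments (dimers) diffuse more slowly than the donor-only segments that
  continue after acceptor loss (monomers); segments are additionally
  classified free/confined and summarized by jump-angle distributions,
* **the termination pathway** — donor fluorescence persisting after
  acceptor loss indicates dimer dissociation (pathway 1); simultaneous
  loss of both signals indicates the complex left the TIRF field
  (pathway 2).

Traces are vetted the way the field does it: only traces with
single-step photobleaching in both channels and anti-correlated
donor/acceptor intensity at the acceptor loss (or a joint simultaneous
loss) are accepted; multi-complex endocytic puncta are rejected by their
multi-step bleaching.

The pipeline stages are `simulate_movie()` →
`localize_movie()` / `register_channels()` → `link_trajectories()` /
`filter_trajectories()` → `pair_trajectories()` / `vet_fret_trace()` /
`estimate_correction_factors()` / `compute_fret_efficiency()` →
`segment_trajectory()` → `compute_msd()` / `fit_msd()` /
`classify_motion()` / `compute_jump_angles()` / `fit_lifetime()` /
`compare_groups()`, with `simulate_and_analyze()` and `pool_analyses()`
wrapping the whole chain. See the methods vignette
(`vignettes/fretspt-methods.Rmd`) for the models, defaults and design
choices.

## Worked example

```r
library(fretspt)

cfg <- sim_config(n_frames = 800, seed = 61)   # live-cell defaults
res <- simulate_and_analyze(cfg)               # render -> localize -> analyze
print(res$analysis)
st <- pool_analyses(list(res$analysis))
print(st)
```

```
smFRET/SPT analysis
  16133 localizations -> 65 donor + 16 acceptor trajectories
  16 FRET candidates, 16 accepted
  median D: FRET 0.046, donor-only 0.105 um^2/s
  pathway-1 fraction 0.38
smFRET/SPT study: 1 movies, 16 accepted FRET traces
  FRET efficiency peak: 0.893 +/- 0.022 (Gaussian fit, n=457 frames)
  median D: FRET 0.0457 (confined 69%), donor-only 0.1048 (confined 0%) um^2/s
  Mann-Whitney FRET vs donor-only: p = 0.0135 (*)
  pathway-1 fraction: 0.38
```

Reading the output: from a single 32-second synthetic movie the pipeline
found 16 FRET traces (all passed vetting), recovered the simulated FRET
efficiency (0.89 fitted vs 0.90 simulated), and already resolves the
mobility difference between dimer (FRET segment) and monomer (donor-only
segment) at p ≈ 0.01. One movie is deliberately small: per-segment
diffusion medians and confined fractions are noisy at n = 16, which is
why the study-level interface pools many movies.

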