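---
title: "Methods: combined smFRET and single-particle tracking of receptor dimers"
author: "fretspt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: combined smFRET and single-particle tracking of receptor dimers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fretspt)
```

## The problem

Membrane receptors such as the MET receptor tyrosine kinase are activated
by ligand-induced dimerization. In a live-cell TIRF experiment, each
ligand carries either a donor (Cy3B-like) or an acceptor (ATTO 647N-like)
fluorophore; a 2:2 ligand–receptor dimer brings the two dyes within FRET
range, so a dimer appears as a spot in the acceptor emission channel under
donor excitation. Two quantities of biological interest fall out of a
combined smFRET + single-particle-tracking analysis:

* the **dimer lifetime**, from the duration of the FRET signal in each
  single-molecule trajectory, and
* the **mobility change upon dissociation**, from diffusion coefficients
  of the FRET-active segment (dimer) versus the donor-only segment that
  follows acceptor loss (monomer).

`fretspt` implements the full analysis chain — sub-pixel localization,
channel registration, trajectory linking, FRET-trace vetting, crosstalk
correction, trajectory segmentation, MSD/lifetime/jump-angle statistics —
together with a ground-truthed synthetic movie generator, so that every
stage is testable quantitatively without any external data.

## The synthetic experiment

`sim_config()` collects the acquisition and kinetic parameters. The
defaults are the live-cell operating point of the emulated experiment:

| parameter | default | meaning |
|---|---|---|
| `pixel_size` | 159 nm | effective camera pixel |
| `frame_interval` | 0.040 s | integration time per frame |
| `field_size` | 256 × 256 px | one channel; the full frame is 256 × 512 with donor left, acceptor right |
| `n_frames` | 2000 | movie length |
| `emitter_density` | 0.05 /µm² | sparse post-photobleaching-recovery density |
| `D_dimer`, `D_monomer` | 0.066, 0.109 µm²/s | 2-D diffusion coefficients |
| `k_off` | 1/1.13 s⁻¹ | dimer dissociation rate (dwell ~ Exp(k_off)) |
| `p_internalize` | 0.7 | probability that a dissociation removes both signals (pathway 2) |
| `E_true` | 0.90 | FRET efficiency of the dimer |
| `photons_donor` | 600 /frame | unquenched donor photon budget |
| `leak_alpha_true`, `direct_delta_true`, `gamma_true` | 0.05, 0, 1 | crosstalk and detection-imbalance ground truth |
| `bleach_rate_donor`, `bleach_rate_acceptor` | 0.05 s⁻¹ | single-step photobleaching rates |
| `background_mean` | 2 photons/px | autofluorescence + readout background |
| `psf_sigma` | 150 nm | Gaussian PSF width |

Emitters are born monomeric or dimeric (`f_dimer`); association events are
not simulated because the lifetime analysis starts at FRET appearance.
Birth frames are staggered uniformly over the movie, emulating the steady
influx of labelled receptors returning to the basal membrane after the
photobleaching/recovery step. Dimer dwell times are exponential in
continuous time and discretised to whole frames. At dissociation the
emitter either continues as a donor-labelled monomer (pathway 1) or
disappears entirely (pathway 2, internalization or escape from the TIRF
field). The acceptor-labelled partner monomer after a pathway-1 event is
not rendered: under donor excitation it would emit only through direct
excitation (δ), far below the detection threshold.

Rendering distributes each emitter's expected photons as a
pixel-integrated 2-D Gaussian, draws per-pixel Poisson counts of signal
plus background, and applies a linear camera gain and baseline. This
keeps the photon bookkeeping exact — the sum of background-subtracted
pixel values around an emitter is an unbiased estimate of its emitted
photons — which the localization and photometry tests exploit. An
explicit EM-register excess-noise factor is not modelled; it would scale
all variances without changing any of the logic under test.

Features of real data the generator does **not** emulate: motion blur
within a frame (positions are rendered at one instant), spatially varying
background, dye blinking (off by default), z-dependence of the TIRF
evanescent field, and non-Poisson camera noise. Passing tests therefore
validate the algorithmic chain under idealized photon statistics, not
robustness to every instrumental artifact.

## Localization and registration

Candidates are found per frame by a difference-of-Gaussians band-pass
(σ and 2σ of the nominal PSF) followed by 8-connected local maxima above
`median + k·MAD` of the filtered frame (`k_sd = 4` by default). The
robust threshold matters: with a mean/sd threshold, bright emitters
accumulating over the movie would progressively raise the threshold and
silently drop the FRET-quenched donor spots.

Each candidate is refined by a Levenberg–Marquardt least-squares fit of a
pixel-integrated symmetric Gaussian plus constant background. The PSF
radius is data-driven: σ is fit freely until 200 bright (≥ 100 photons)
fits have accumulated, then fixed at their median. Overlapping candidate
pairs (closer than one fit window) are fit jointly as a two-Gaussian
mixture by default; fit windows are shifted inside the frame near the
borders rather than discarded. Per-localization precision uses the
standard Mortensen-style least-squares formula from photons, background,
PSF width and pixel size.

During FRET the donor is quenched to `(1 − E)·photons_donor` (≈ 60
photons at E = 0.9) and is often below the detection threshold. The
donor intensity of a FRET trace is therefore measured by **guided
photometry**: for every acceptor detection, the donor channel is read out
at the registered donor position by a two-parameter linear least-squares
fit (amplitude + background at fixed position and width). Symmetrically,
the acceptor channel is read out at every donor-only position, which
calibrates the donor leakage α.

Channel registration fits a full 2-D affine transform to mutual
nearest-neighbour bead pairs localized in both halves of a fiducial
movie, reporting the rms residual (warning above 20 nm).

## Tracking

Per-frame-pair assignment is a linear assignment problem on squared
displacements with birth/death dummy costs of `max_disp²`, solved by a
Hungarian algorithm; track ends and starts within 3 frames and
`max_disp·√(gap+1)` are then merged (gap closing), and trajectories
spanning fewer than 20 frames are discarded — the standard tracking
parameterization for this acquisition regime (3-frame gap closure,
20-frame minimum length). `max_disp` defaults to 1.1 µm
(≈ 4·√(4·D_max·Δt) at D_max = 0.5 µm²/s), a configurable choice: tracking
software in this field derives its search radius internally from the
observed motion. Gap frames carry no interpolated coordinates: MSD and jump-angle
statistics skip pairs that span a gap.

## FRET traces: pairing, vetting, correction

Acceptor trajectories are mapped into donor coordinates and paired
one-to-one with time-overlapping donor trajectories within 250 nm (mean
distance, nearest wins). Donor trajectories that never co-move with any
acceptor are the donor-only class used for α calibration — note "never":
a donor that loses its pairing to a closer competitor must still be
excluded, or its FRET-sensitized neighbourhood contaminates α upward.

Change points in each intensity series are found by binary segmentation
with penalty `pen_mult·σ²·log n` (σ from the median absolute first
difference, so a constant-plus-noise series yields no change points;
`pen_mult = 3`). Because photobleaching steps are quantal, detected mean
shifts smaller than 25% of the series' peak level are ignored as drift.
A trace is accepted iff the acceptor series shows exactly one downward
step to background (the acceptor loss frame), the donor series shows at
most one downward step, and one of three anti-correlation signatures
holds at the loss: the donor rises by ≥ k·σ (window W = 5 frames, k = 2),
a donor decrease coincides with an acceptor increase at FRET onset, or
donor and acceptor vanish together (the pathway-2 termination). Endocytic
puncta carrying several complexes fail through their multi-step
photobleaching. Near-simultaneous double losses (< 3 frames apart, the
change-point minimum segment) are physically indistinguishable from a
single step; the vetting specificity is therefore quantified on
observably multi-step puncta.

After acceptor loss the donor trajectory is concatenated: among donor
trajectories *active* within 3 frames of the loss and within 250 nm of
the last FRET position, the nearest is appended. Activity rather than a
fresh start is required because the quenched donor is sometimes detected
intermittently during FRET, so its trajectory can begin before the loss.

Correction factors follow the standard corrected-FRET convention:
α and δ as tracewise intensity ratios of donor-only and acceptor-only
(ALEX) calibration traces, γ from the ratio of the acceptor drop to the
donor rise across the acceptor-bleach step of accepted traces, β (ALEX)
such that dual-labelled traces sit at stoichiometry 0.5. Then

$$F_{corr} = I_{AD} - \alpha I_{DD} - \delta I_{AA}, \qquad
  E = \frac{F_{corr}}{\gamma I_{DD} + F_{corr}}, \qquad
  S = \frac{\gamma I_{DD} + F_{corr}}{\gamma I_{DD} + F_{corr} + I_{AA}/\beta}.$$

Live-cell movies carry a single excitation line, so δ cannot be
calibrated natively; it is imported from an ALEX calibration or set to 0.
E values are reported unclipped; frames with a non-positive denominator
are flagged invalid and excluded from histograms, which are fit with a
least-squares Gaussian.

## Segmentation and dynamics

Donor and acceptor localizations of the same molecule are merged per
frame by inverse-variance weighting (merge radius 250 nm, reusing the
concatenation radius rather than introducing a second spatial-overlap
parameter). Frames before the acceptor loss form the FRET segment, donor
frames after it the donor-only segment; where the spatial support and the
intensity change point disagree by ≤ 3 frames, the intensity change point
wins, being the primary acceptance signal. Pathway 1 requires the donor
to persist more than 3 frames past the loss; otherwise the trace is
pathway 2 and its donor-only segment is empty. The FRET duration is the
spanned FRET-frame count × Δt (interior gap frames flanked by FRET frames
count; trailing gaps do not).

The time-averaged MSD is computed per lag over all frame pairs with both
endpoints localized. The free model `MSD(t) = 4Dt + 4σ²` is fit by
weighted least squares to **lags 1–4 only** (weights = pair counts), and
D is always reported from this fit; a negative intercept leaves D
reported but the dynamic localization precision "not estimable". The
confined model `MSD(t) = L²(1 − e^{−t/τ_c}) + 4σ²` is fit over a longer
range (default: up to half the available lags).

**Motion classification.** There is no community-standard threshold rule
for calling a short trajectory confined, so the rule here is an explicit,
documented choice. Free diffusion grows
proportionally with lag, so the long-lag MSD (lags 5–10) is predicted by
scaling the lag-1 MSD; the pair-count-weighted relative shortfall below
that prediction is the confinement deviation, and a segment is confined
when it exceeds θ = 0.6. The lag-1 MSD is used as the mobility reference
because under strong confinement even the first-four-lag fit is already
saturated and extrapolates no deviation at all. The localization-noise
intercept inflates the lag-1 prediction, biasing the deviation upward by
roughly `4σ²(n−1)/(n·MSD(1))` for free motion (≈ 0.1 at the default
operating point), which the θ = 0.6 default accommodates; on simulated
ensembles the rule classifies ≥ 98% of strongly disk-confined segments
confined at < 7% false-confinement on 20-frame free segments. θ and the
attained deviation are reported with every classification, and the
confined fraction should always be quoted alongside θ.

Jump angles are the direction differences of consecutive displacement
vectors, folded to [0°, 180°], histogrammed in 18 bins of 10° and
normalized to relative frequencies; they are uniform for free diffusion
and biased toward 180° under confinement.

Dimer lifetimes are fit by least squares of `A·exp(−t/τ)` to the
histogram of FRET-segment durations (bin width 2 frames), after removing
durations above 10 s; the first populated bin is excluded by default to
mitigate the left-censoring imposed by the 20-frame minimum trajectory
length (the exponential's memorylessness makes the fit insensitive to
this truncation). FRET vs donor-only diffusion coefficients are compared
with a two-sided Mann–Whitney test with the usual n.s./*/**/***
significance bands.

## Numerical and design choices worth knowing

* Observed lifetime: the fitted τ estimates `1/(k_off + k_bleach,acceptor)`.
  At the defaults (k_off = 1/1.13, bleach 0.05 s⁻¹) the apparent lifetime
  is ≈ 5% below 1/k_off — the same photobleaching confound the real
  experiment quantifies with fixed-cell controls.
* Ambiguous pairings and concatenations are broken deterministically by
  distance, then lower trajectory id.
* All coordinates are in µm with the origin at the top-left corner of
  each channel, x rightward, y downward; pixel (i, j) spans
  `[j, j+1) × [i, i+1)` pixel units (half-open, 0-based).
* Determinism: `seed` drives every random draw; rendering derives its
  stream from the seed and the first frame of the rendered block, so a
  movie rendered in chunks equals the same chunking re-rendered, and all
  exported CSVs are byte-identical across runs with the same seed.
* Emitters that leave the field are marked lost in the truth; rendering
  refuses out-of-field positions rather than clipping them.

## Problem sizes used in validation

The packaged tests validate parameter recovery end-to-end on 20 synthetic
movies of 2000 frames (256 × 256 px per channel) at 0.05 emitters/µm²
with the generator set to the measured values of the emulated experiment
(D 0.066/0.109 µm²/s, k_off = 1/1.13 s⁻¹, E = 0.90); trace-level vetting
and segmentation are validated on 500-trace ensembles at acceptor-channel
SNR 8, and statistical nulls on 10⁴ jump angles and 1000 Mann–Whitney
replicates. These sizes give standard errors comfortably inside the
tolerances being checked while keeping a full run on a single CPU
practical.

## Known limitations

* Association (monomer→dimer) events and repeated FRET episodes within
  one trajectory are not modelled or analysed.
* The vetting cannot reject a punctum whose acceptors bleach
  near-simultaneously, nor can any intensity-based method.
* Fitted-σ spot detection assumes an isotropic Gaussian PSF; no
  astigmatism or 3-D localization.
* The confined/free rule is a heuristic with an explicit threshold, not
  a likelihood-ratio test; absolute confined fractions shift with θ and
  should be compared only at fixed θ.
* No hidden-Markov modelling of within-trace FRET states, and no
  FRET-to-distance conversion.
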