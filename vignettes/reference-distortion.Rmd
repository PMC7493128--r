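---
title: "How the EEG reference distorts scalp functional networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How the EEG reference distorts scalp functional networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Scalp EEG never measures a potential; it measures potential *differences*
against a reference electrode that has its own, generally active, potential.
Every functional-connectivity estimate computed from referenced signals
therefore mixes genuine source coupling with the reference site's signal,
which is subtracted from every channel simultaneously. Two offline remedies
are standard: the common average reference (CAR), which subtracts the
instantaneous mean over all channels, and the reference electrode
standardization technique (REST), which uses a volume-conductor model to map
the recorded data back towards potentials against a point at infinity.

`scalpnet` implements the full comparison pipeline for self-paced hand
movement experiments: EMG-based movement-onset detection, beta-band (13--30
Hz) epoching around onset, construction of coherence (COH), phase-locking
value (PLV) and phase lag index (PLI) adjacency matrices per movement stage
(idle, movement preparation MP, movement execution ME), weighted graph
metrics, and the edge-wise significance procedure (candidate threshold on
the group-mean difference, one-tailed paired t-tests over subjects,
Benjamini--Hochberg FDR). Because raw recordings of this kind are not
publicly deposited, the package ships a forward-model simulator with known
ground-truth source coupling; every claim the pipeline makes can be checked
against what was actually generated.

## The head model and REST

The volume conductor is the classic three-shell concentric sphere (brain,
skull, scalp), radii `(0.87, 0.92, 1)` relative to the scalp and relative
conductivities `(1, 0.0125, 1)` — the conventional values used by REST
implementations; the source paper for this pipeline does not state the
model its REST call used, so these are declared assumptions, not
reconstructions. Potentials are computed analytically: for each Legendre
order the radial two-point boundary problem across the shells is solved
with per-shell rescaled unknowns (all matrix entries bounded, so the system
stays well conditioned at high order), and dipoles of arbitrary orientation
are handled by the analytic gradient of the expansion. Terms decay like
$b^n$ with $b \approx 0.86$ the source radius, so the default truncation at
200 terms leaves a tail below $10^{-12}$; a 60-term truncation, sometimes
seen elsewhere, still carries a $\sim 10^{-4}$ tail, which is why the
default here is higher. The implementation is validated against the
closed-form solution for a radial dipole in a homogeneous sphere.

REST forms the transfer matrix $T = G \, G_{\mathrm{avg}}^{+}$, where $G$
is the infinity-referenced gain of an equivalent source layer (300 radial
dipoles, Fibonacci-spaced at radius 0.86) and $G_{\mathrm{avg}}$ its
average-referenced counterpart; $T$ is applied to average-referenced data,
which makes the operation invariant to the input reference. The
pseudoinverse discards singular values below $10^{-4}$ of the largest.

**Identifiability.** With $C$ channels and $M > C - 1$ layer dipoles,
$G_{\mathrm{avg}}$ has rank at most $C-1$, and the component of the data
lying in its null space — which is exactly the spatially constant potential
— cannot be recovered: REST then reconstructs the infinity-referenced
potentials *up to a common offset shared by all channels* (the residual is
constant across channels to machine precision). When the layer has at most
$C-1$ dipoles, all visible to the cap, recovery is exact for any source in
the layer; the package's recovery tests exercise this determined regime
(e.g. 48--62 upper-hemisphere dipoles at 63 channels), and verify the
pattern-exactness property for the 300-dipole default. Connectivity
measures are insensitive to a common offset, so this limitation does not
touch the pipeline's conclusions.

**Noise floors.** With spatially white sensor noise at a global
signal-to-noise ratio $s$ (linear), the correlation between a noisy channel
and its noiseless truth cannot exceed $\sqrt{s/(1+s)}$ — about 0.95 at 10
dB for a channel of exactly average power, and less for weak channels at
the cap edge. Any per-channel fidelity statement about REST at 10 dB
therefore has to be read against this floor; the package's robustness test
evaluates fidelity in the analysis band (where the band-limited sources
live and the white-noise floor is roughly 9 dB more favourable) and checks
a median per-channel correlation of at least 0.95 with no channel below
0.90.

## The synthetic cohort

The generator emulates the study conditions: 17 subjects, 250 Hz, 10-10
montage (62 scalp channels plus the physical recording-reference site
midway between CZ and CPZ; a 19-channel 10-20 variant for fast tests),
self-paced movements of both hands more than 5 s apart, bipolar EMG with
bursts at each onset.

* **Sources.** Active cortical dipoles sit at radius 0.78 (a realistic
  cortical depth giving skull-smoothed, broadly overlapping scalp
  topographies) under named electrodes; each source is unit-RMS white
  noise filtered to 13--30 Hz. Orientations are tilted 40 degrees away
  from radial with deterministic azimuths: folded cortex produces
  orientation-diverse generators, and the tangential components have
  near-zero mean over the electrode cap, which keeps the common-mode
  signal (and hence what the common average reference subtracts) at a
  realistic size. An all-radial layout over an upper-hemisphere cap
  maximises the common-mode and makes CAR look far worse than real data
  shows.
* **Coupling.** Coupled pairs share a band-limited noise carrier with
  mixing weight $a$ (`strength`), crossfaded into the active stage windows
  with 50 ms raised-cosine ramps; a lagged pair receives the
  analytic-signal copy rotated by the specified phase. A stochastic
  carrier, not a sinusoid, is essential: a pure tone's phase difference
  has unbounded memory, so the sign of the phase difference persists
  across whole 1 s windows and PLI acquires a large finite-sample bias
  that real beta oscillations (and hence the PLI literature) do not show.
* **Heterogeneity.** Coupling strengths jitter log-normally across
  subjects (sd 0.1) and each source's amplitude jitters log-normally per
  subject (sd 0.15): real cohorts differ in how strongly each generator
  expresses itself, and without heterogeneity paired tests across
  subjects resolve arbitrarily small systematic reference offsets that no
  real study would detect. The amplitude sd is kept moderate because
  coupling strengths are mixing fractions within a source, so amplitude
  jitter also scales the carrier-to-background ratio at the sensors;
  large values push entire cohorts between effect-size regimes and make
  significant-edge counts bimodal.
* **Sensor chain.** Spatially white Gaussian noise at a configurable SNR
  (default 10 dB) is added at all electrodes including the reference site;
  the recording then subtracts the reference electrode's row and drops it,
  exactly as an amplifier does. Analyses re-insert that channel as zeros.
* **EMG.** Bursts are 0.5 s, with an abrupt onset (a movement marker needs
  a well-defined start), an equal-power mixture dominated by a 35 Hz tone
  with band-limited noise, at 8 times the baseline RMS by default.
* **ERD hook.** An optional amplitude scale on all sources during MP/ME
  (`erd_scale`) emulates movement-related beta desynchronisation for the
  time-frequency check; it defaults to off.

The default coupling scenario strengthens a zero-lag mesh over the lateral
sensorimotor sources (C3, C4, F3, F4, P3, P4 anchors; the source under the
vertex stays background) during MP and ME of either hand. Zero-lag dominance reflects the empirical observation the
pipeline is designed to reproduce: scalp-level beta synchronisation changes
are dominated by components PLI discards. Strengths (0.3--0.5) were chosen
so subject-level connectivity increases at coupled edges land roughly an
order of magnitude above the 0.02 candidate threshold without letting the
shared carrier dominate the whole scalp; a carrier that saturates every
channel also saturates the reference site and flips the reference
comparison into a regime no real recording shows.

What the generator does **not** emulate: eye-blink and muscle artifacts,
handedness asymmetries, individual head geometry (a single sphere model
serves the whole cohort), and 1/f broadband background. Passing tests on
this cohort show the pipeline's operations and statistics behave as
designed under known ground truth — not that any particular neuroscientific
conclusion transfers to real recordings.

## Signal processing choices

* FIR filters are windowed-sinc (Hamming) designs, order
  $3.3 f_s / \Delta f$ with transition width $\Delta f$ defaulting to a
  quarter of the lower band edge, applied forward-backward (zero phase).
  The zero-phase pass is implemented in the frequency domain (squared
  magnitude response with odd-reflection padding), vectorised across
  channels, and agrees with the reference implementation away from the
  padded edges. EMG onset detection uses a wider 8 Hz transition: a long
  filter's step response smears burst energy backwards and forwards, which
  costs onset timing accuracy far more than the extra stop-band attenuation
  is worth (2 Hz content still loses well over 20 dB after the double
  pass).
* Filtering precedes epoching, so filter transients never sit inside the
  1 s stage windows; band-pass filtering and re-referencing commute (both
  linear), and the pipeline exploits this by filtering once per subject.
* Instantaneous phases come from the FFT-based analytic signal computed on
  the full 5 s epoch and then windowed to the stage, avoiding boundary bias
  inside 250-sample windows.
* Per-trial coherence uses Welch spectra on the 250-sample stage window:
  125-sample segments, 50% overlap, Hanning taper (3 segments, 2 Hz
  resolution), with the magnitude-squared coherence averaged over the bins
  inside [13, 30] Hz. Three segments leave a substantial small-sample bias
  (null mean near 1/3); the bias is common to both stages being compared,
  but it compresses observable stage differences — worth remembering when
  comparing COH and PLV sensitivity.
* A channel that is flat inside a window (notably the re-inserted
  reference row under the recording reference) carries no phase or
  spectral information; its edges are set to 0 rather than left as 0/0.
  Degree comparisons "near the reference" therefore read the nearest scalp
  channel (CPZ, or CZ in the 10-20 variant), not the reference row itself.

## Statistics

The edge procedure follows the published recipe exactly: group-mean
difference matrices (movement stage minus idle), candidate edges where the
difference strictly exceeds 0.02, a one-tailed paired t-test per edge
across subjects (df = n − 1), BH-FDR correction, and significance =
candidate AND q < 0.05. The FDR family defaults to all upper-triangle
edges — the conservative reading, since the source text does not restrict
the family — with the candidate mask applied afterwards as a conjunction
(`fdr_family = "candidates"` switches to the other reading). Zero-variance
paired differences are guarded (p = 0.5 for all-zero differences, 0/1 by
sign otherwise) and logged. Node-degree contrasts between references are
paired two-tailed t-tests per node, uncorrected, as in the original
tables; path-length contrasts likewise. "Two-sample paired t-test", as the
source text prints, is contradictory; the data are paired by subject, so a
paired test is what runs.

Characteristic path length uses the reciprocal weight-to-length rule
($\ell = 1/w$, the standard brain-connectivity choice; `one_minus` is
available), all-pairs shortest paths on the weighted graph, and the mean
over ordered pairs; disconnected pairs make the strict value infinite, and
a finite-pair variant is reported alongside.

## Problem sizes

The shipped tests and the acceptance script run at deliberately modest
sizes chosen to exercise every code path at full statistical fidelity
where it matters: cohort-level checks use the 19-channel montage with 17
subjects and 10-20 trials per hand, FDR calibration uses 50 null cohorts
at reduced trial counts, and estimator-level oracles (closed-form dipole
potentials, direct-summation PLV/PLI, Floyd-Warshall path lengths,
brute-force BH-FDR) run at small n where exhaustive computation is exact.

## Known limitations

* REST's unidentifiable constant offset (above) in the overdetermined
  layer regime.
* The 19-channel montage concentrates the common-average and
  reference-injection effects into fewer channels than a 62-channel cap,
  which strengthens systematic reference offsets on global measures such
  as the characteristic path length relative to what dense montages show.
* The simulator's subject heterogeneity is statistical (amplitudes,
  strengths), not anatomical; all subjects share one head model and
  montage geometry.
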