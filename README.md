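# scalpnet

Reference-aware scalp EEG functional networks for hand-movement tasks.

Scalp EEG measures potential differences against a reference electrode
whose own potential is active, so every connectivity estimate computed from
referenced signals mixes genuine source coupling with the reference
signal's footprint. `scalpnet` implements the full pipeline for studying
this distortion in self-paced hand-movement experiments: it compares the
original recording reference (an electrode between CZ and CPZ), the common
average reference (CAR), and the reference electrode standardization
technique (REST) on beta-band (13–30 Hz) functional networks built with
three coupling measures,

- magnitude-squared coherence
  `COH_xy(f) = |S_xy(f)|^2 / (S_xx(f) S_yy(f))`, averaged over beta bins,
- phase-locking value `PLV = |K^-1 Σ_k exp(i θ(t_k))|`, and
- phase lag index `PLI = |⟨sign Δφ(t_k)⟩|`, which discards couplings whose
  phase difference centres on 0 mod π (volume-conduction-like),

followed by weighted graph metrics (node degree `D_i = Σ_{j≠i} A_ij`,
characteristic path length `L = (N(N−1))^-1 Σ_{i≠j} d_ij`) and an
edge-wise significance procedure: candidate edges where the group-mean
stage-minus-idle difference exceeds 0.02, one-tailed paired t-tests across
subjects, Benjamini–Hochberg FDR at 0.05.

Because recordings of this kind are not publicly deposited, the package
ships a forward-model simulator — a three-shell spherical head model with
analytic lead fields, beta-band cortical sources with configurable
zero-lag/lagged coupling, a physical recording reference, sensor noise, and
EMG bursts at movement onsets — so the entire pipeline is testable against
known ground truth. EMG onset detection (6–50 Hz FIR, energy envelope,
robust threshold), (−3000, 2000) ms epoching with idle/MP/ME stage windows,
and a multitaper-style ERD check complete the chain.

## Worked example

```r
library(scalpnet)
library(dplyr)

# a small synthetic cohort: 8 subjects, 19-channel montage, zero-lag
# coupling over the lateral sensorimotor sources during movement
cfg <- pipeline_config(
  n_subjects = 8, n_trials_per_hand = 12, n_channels = 19,
  stages = c("idle", "ME"), hands = "left", seed = 42
)
res <- run_pipeline(cfg)
res$edge_counts
#> # A tibble: 9 × 5
#>   method stage hand  reference n_significant
#>   <chr>  <chr> <chr> <chr>             <int>
#> 1 COH    ME    left  REF                   0
#> 2 COH    ME    left  CAR                   0
#> 3 COH    ME    left  REST                  8
#> 4 PLV    ME    left  REF                   0
#> 5 PLV    ME    left  CAR                   0
#> 6 PLV    ME    left  REST                  6
#> 7 PLI    ME    left  REF                   0
#> 8 PLI    ME    left  CAR                   0
#> 9 PLI    ME    left  REST                  0

res$edge_tests |>
  filter(method == "PLV", chan_i == "C3", chan_j == "C4") |>
  select(reference, diff, t, p, q, significant)
#> # A tibble: 3 × 6
#>   reference    diff      t       p      q significant
#>   <chr>       <dbl>  <dbl>   <dbl>  <dbl> <lgl>
#> 1 REF        0.0182  0.754 0.238   0.957  FALSE
#> 2 CAR       -0.0470 -2.72  0.985   0.997  FALSE
#> 3 REST       0.0376  3.60  0.00440 0.0597 FALSE
```

Each `edge_counts` row is one cell of the comparison: how many edges
increased their connectivity significantly from idle to movement execution
under that reference. Even in this small cohort the pattern the package
exists to study is visible: only REST, which undoes the reference
distortion, recovers the movement-locked network (8 coherence and 6
phase-locking edges), while the recording reference and CAR bury it — the
hand-area edge C3–C4 carries a genuine +0.038 phase-locking increase under
REST, halved under the recording reference and inverted in sign under CAR.
The empty PLI rows are expected for zero-lag coupling: PLI discards
phase-difference distributions centred on zero. `res$node_tests`, `res$path_length`,
and `res$networks` hold the node-degree contrasts, path-length comparison,
and the subject-level adjacency matrices (tibbles with `tidy()`/`glance()`
methods; `autoplot()` a `conn_matrix`, or `plot_degree_topo()` a degree
vector, for figures).

Lower-level entry points mirror each pipeline stage: `simulate_cohort()`,
`detect_onsets()`, `to_car()` / `to_rest()`, `beta_bandpass()`,
`epoch_record()`, `connectivity_trials()`, `node_degree()`,
`char_path_length()`, `edge_tests()`.

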