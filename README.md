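# wristemg

Simultaneous and proportional estimation of the three wrist degrees of
freedom — flexion/extension, radial/ulnar deviation, pronation/supination —
from multichannel forearm surface EMG, and quantification of how the
estimator degrades when the arm is held in a different position than it
was trained in.

The package is aimed at myoelectric-control researchers who want a
reproducible, fully tested implementation of this analysis chain:

1. **Conditioning** — 10–450 Hz second-order Butterworth band-pass on the
   7-channel EMG (2048 Hz), resampling to a common 1024 Hz analysis rate,
   and alignment of the EMG and motion-capture streams through a shared
   20 Hz synchronization square wave.
2. **Features** — the TDAR set on 100 ms windows with 60 ms overlap: mean
   absolute value, MAV slope, zero crossings, slope sign changes, and
   6th-order autoregressive coefficients from an LMS adaptive linear
   predictor (7 channels × 10 features = 70 per window).
3. **Kinematics** — wrist joint angles from seven anatomical markers
   (256 Hz): with the wrist-centered frame (origin between the styloids,
   z along the forearm axis, x mediolateral, y dorsopalmar),

   α₁ = atan(H_y / H_z),  α₂ = atan(H_x / H_z),  α₃ = ∠(ω, l),

   where H is the metacarpal midpoint, ω the inter-styloid vector and l
   the inter-epicondyle vector; 6 Hz low-pass, 1024 Hz, per-window mean
   angles as regression targets.
4. **Regression** — contralateral training: one small MLP (3 hidden
   units) per DoF maps the control side's EMG features to the opposite
   side's measured angle.
5. **Evaluation** — the multivariate R²

   R² = 1 − [Σ_i Σ_t (α̂_i(t) − α_i(t))²] / [Σ_i Σ_t (α_i(t) − ᾱ_i)²]

   over a grid of analysis scenarios (DoF12, DoF13, DoF23, DoF123) ×
   training position(s) × testing position × 5 cross-validation folds,
   with inter-position scores normalized to their intra-position
   baselines and a one-tailed paired t test for the benefit of pooling
   training data across arm positions.
6. **Synthetic sessions** — a generator that emulates a full recording
   session (3 arm positions × 7 movement runs, bilateral mirrored wrist
   movement, forward-modelled markers, envelope-modulated band-limited
   noise as EMG, and a parametric arm-position effect), so the entire
   pipeline runs and is verified without human data.

## Worked example

```r
library(wristemg)

# a synthetic session with a moderate arm-position effect
cfg <- with_position_effect(emg_synth_config(), sigma_g = 0.3, seed = 101)
ses <- simulate_session(master_seed = 7, duration_s = 30, config = cfg)

res <- run_pipeline(ses, seed = 5)
res
#> <wrist_eval>
#>   DoF12   inter 92.7 +/- 4.1%, intra 98.4 +/- 0.3%
#>   DoF123  inter 51.9 +/- 31.1%, intra 95.0 +/- 2.0%
#>   DoF13   inter 85.2 +/- 8.4%, intra 97.8 +/- 1.0%
#>   DoF23   inter 85.9 +/- 9.1%, intra 98.3 +/- 0.6%

res$pooling
#> # A tibble: 4 x 6
#>   scenario n_pairs mean_single_pct mean_pooled_pct mean_diff_pct       p_value
#>   <chr>      <int>           <dbl>           <dbl>         <dbl>         <dbl>
#> 1 DoF12         30            92.7            98.9          6.12 0.00000000345
#> 2 DoF123        30            51.9            94.8         42.9  0.0000000113
#> 3 DoF13         30            85.2            97.7         12.5  0.00000000224
#> 4 DoF23         30            85.9            94.6          8.64 0.0000130
```

Reading the output: training and testing in the same arm position
("intra") scores substantially higher than testing in a different
position ("inter") — the position effect the analysis is designed to
expose — and pooling the three positions' training data recovers most of
the loss (the one-tailed paired t test is significant in every scenario).
`autoplot(res)` draws the normalized training × testing position matrix;
`plot_pooling_comparison(res)` the pooling bar chart. On-disk sessions
work the same way: `generate_session()` writes TSV streams plus a
manifest, `load_session()` reads them back.

Numbers from synthetic sessions characterize the pipeline, not human
muscle; see the methods vignette (`vignettes/`) for the generator's
scope and every numerical design choice.

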