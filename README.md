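# ttswing

Biomechanical quantification of table tennis forehand strokes from
single-camera pose landmarks.

Marker-based optical motion capture tells you which body movements drive
ball speed, but it needs a lab. `ttswing` implements the lightweight
alternative end to end: it takes 33-landmark pose time series (MediaPipe
Pose topology, 100 Hz) plus per-stroke annotations (impact frame, six-frame
ball trajectory), and produces interpretable correlation tables linking
kinematic summaries to the speed of the returned ball. It is aimed at sports
scientists and movement analysts who have pose-tracker output and want
defensible statistics, not video processing.

## What it computes

* **Ball speed** from the annotated six-frame ball track via an RBF
  support-vector regression (grid-searched C and gamma, 5-fold CV, 80/20
  split), trained against acoustic ground truth
  (`speed = distance / (interval − Δd/343)`, in km/h), and validated by
  Bland–Altman agreement.
* **Preprocessing**: 31-tap Hamming windowed-sinc low-pass at 4 Hz;
  two-factor scaling to meters (measured body-chain length + per-frame
  apparent-size compensation); origin at the time-averaged ankle midpoint
  with y up; left-handed strokes mirrored into the right-handed frame.
* **Kinematics**: central-difference landmark velocities; unwrapped plane
  orientation angles and angular velocities for 19 body segments; included
  joint angles `acos(BA·BC/|BA||BC|)` for 12 joints.
* **Forward-swing segmentation** from the inflection points (zero crossings
  of the second derivative) of the re-filtered wrist resultant velocity,
  bracketing the impact frame.
* **Statistics**: per-stroke summaries over the forward swing — range,
  mean/peak/impact absolute (angular) velocity; Tukey-fence speed outlier
  removal; fastest/slowest stroke pairing; within-subject (repeated-measures
  ANCOVA) correlation
  `r_ws = sign(β)·sqrt(SS_measure/(SS_measure+SS_error))`;
  measurement-weighted between-subject correlation of age/height with speed,
  stratified at 14.3 years; ICC / normalized-DTW / cosine reliability
  metrics; 18-feature curve comparison with Bonferroni correction; a
  Monte-Carlo power calculator for the Pearson test.
* **A synthetic cohort generator** with closed-form ground truth (Gaussian
  wrist-velocity bump, rigid trunk rotation, planted speed effects through a
  latent swing-vigor factor) so that every stage is testable without any
  recordings.

## A worked example

```r
library(ttswing)

spec <- synth_cohort_spec(
  n_players = 10, strokes_per_player = 6,
  speed_effects = c(elbow_MV_R = 0.7), seed = 11
)
cohort <- generate_cohort(spec)
res <- run_pipeline(cohort, landmarks = c(14, 16), segments = NULL, joints = NULL)
res
#> <pipeline_result> 56 of 60 strokes retained across 10 players; 32 correlation cells

dplyr::filter(tidy(res$result, "within"),
              entity == "14", component == "R", summary == "MV")
#>   entity_type entity component summary  r_ws        p df n_obs sig
#> 1    landmark     14         R      MV 0.933 2.69e-05  9    20   b
```

Four of sixty strokes were dropped as per-player speed outliers. The planted
within-player effect (0.7 between swing vigor and ball speed) is recovered
on the playing-side elbow's mean resultant velocity (`r_ws = 0.93`,
p < 0.01 across the ten fastest/slowest stroke pairs; extreme-pair selection
inflates the magnitude, which is why the pipeline reports significance, not
effect sizes, at this scale). Phase detection against the generator's
analytic boundaries shows a −11.5 ms start bias (the filter widens the
velocity bump slightly), 1.2–1.3 frames MAE, and 96% of differences within
the Bland–Altman limits of agreement:

```r
res$phase_validation
#>   boundary mean_diff within_loa_pct mae_frames
#> 1    start     -11.5           96.4        1.2
#> 2      end      13.1           96.4        1.3
```

Between subjects, ball speed correlates with age only below 14.3 years
(here `r_bs = 0.91`, p = 0.005 young vs `r_bs = −0.18` old), the
developmental pattern the generator plants.

`plot_forward_swing()`, `plot_correlation_heatmap()` and
`autoplot()` on Bland–Altman objects provide the standard figures; `tidy()`
and `glance()` methods cover the fitted objects. See the methods vignette
(`vignettes/ttswing-methods.Rmd`) for the model, its assumptions, and every
numerical convention.

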