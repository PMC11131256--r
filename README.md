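# skelvar

Movement quantification from 2-D skeleton keypoint sequences, for screening
hyperactivity in seated children.

A fixed consulting-room camera and a pose estimator (OpenPose, BODY_25
model) reduce a video to 25 keypoints per frame. skelvar turns those
keypoint sequences into a small set of interpretable movement descriptors
and asks how well they separate children with ADHD from children without:

1. **Kinematics** — six bone vectors (shoulders, hips, right thigh, trunk)
   give 11 per-frame skeleton parameters: five bone lengths
   ℓ<sub>i,j</sub> = ‖(Δx, Δy)‖ (pixels) and six bone angles, with
   θ<sub>i,j</sub> = |atan(Δy/Δx)|·180/π ∈ [0°, 90°] for the non-trunk
   bones and a signed trunk angle mapped to [0°, 180°).
2. **Features** — each parameter series is summarized by its *windowed
   averaged variance*: the mean, over K = ⌊T/R⌋ disjoint R-frame windows,
   of the within-window sample variance (denominator R − 1). Restless
   subjects have large within-window dispersion in many bones at once.
3. **Discriminability** — on the cohort's 96 × 12 dataset matrix
   (11 descriptors + label for 48 + 48 subjects): per-descriptor Welch
   t-tests; a 100-repetition bootstrap optimal-cutpoint analysis (cutpoint
   chosen in-bag by the Youden index J = sensitivity + specificity − 1,
   evaluated out-of-bag); and a classification analysis of 17 descriptor
   subsets across six tuned classifier families (AdaBoost, CART, kNN,
   random forest, RBF SVM, gradient-boosted trees) under three resampling
   strategies, summarized by averaged ranks.

Because clinical videos cannot be shipped, the package includes a seeded
two-tier synthetic generator: skeleton-level cohorts (a seated posture with
joint jitter and swivel-chair "fidget events") that exercise the whole
pipeline, and feature-table cohorts with exact distributional control for
testing the statistical machinery.

## Worked example

```r
library(skelvar)

ft <- generate_feature_table(seed = 1)   # 48 + 48 subjects, 96 x 12
compare_groups(ft)
```

```
  descriptor adhd_mean adhd_sd non_adhd_mean non_adhd_sd p_value significance
   var_l_1_2     40.42    6.07          9.81        1.49 1.9e-37          ***
   ...
 var_th_9_10    155.01   36.10         15.14        6.51 4.7e-31          ***
  var_th_8_1     48.97   21.37          8.71        2.42 2.5e-17          ***
```

Every movement-variance descriptor is far larger in the ADHD group (here by
construction of the reference scenario; `***` marks p < 0.001, Welch test).
The bootstrap cutoff analysis then quantifies each single descriptor's
diagnostic value:

```r
cutoff_analysis(ft, reps = 100, seed = 2)
```

```
     feature optimal_cutpoint accuracy sensitivity specificity   auc
  var_l_9_10           52.883    0.990       0.980       1.000 1.000
 var_th_9_10           68.333    0.986       0.971       1.000 1.000
  var_th_8_1           18.928    0.972       0.944       1.000 0.984
  ...
```

Each row is the mean over 100 bootstrap repetitions: the Youden-optimal
cutpoint found in-bag and the four indices of that cutpoint applied
out-of-bag. A subject whose thigh-angle variance exceeds ~68 degrees² is
classified as ADHD with ~99% out-of-bag accuracy in this synthetic cohort.
The thigh parameters dominate because the generator makes body spin on the
swivel chair the loudest group difference.

For a single descriptor in detail, with per-repetition records:

```r
bootstrap_cutoff(ft$var_th_9_10, ft$label, reps = 100, seed = 3,
                 feature = "thigh angle")
#> <cutoff_result> thigh angle (100 bootstrap repetitions)
#>   mean optimal cutpoint: 70.00
#>   out-of-bag means: accuracy 98.26%, sensitivity 96.53%, specificity 100.00%, AUC 100.00%
```

Multi-feature classification and ranking (the full 17 × 6 × 3 grid; long):

```r
res <- run_classification(ft, seed = 4)
averaged_ranking(res[res$strategy == "cv10x10", ])
```

Skeleton-level cohorts run the same pipeline from raw keypoints:

```r
cohort  <- generate_cohort(cohort_config(), seed = 5)  # 96 skeleton sequences
dataset <- cohort_features(cohort)                     # 96 x 12
```

Real OpenPose output is read per-frame-JSON directory at a time with
`read_openpose_sequence()` (with nearest-neighbor person tracking and
`repair_missing_joints()` for detection dropouts), or via the long-format
CSV interchange (`read_sequence_csv()` / `write_sequence_csv()`).

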