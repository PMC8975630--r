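---
title: "Multimodal hybrid fusion for ASD detection: models and methods"
author: "neurofuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal hybrid fusion for ASD detection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurofuse)
```

## The problem

Children with autism spectrum disorder (ASD) differ from typically
developing (TD) children in how they attend to social stimuli. While a
child watches a short video containing social content (performers with
happy expressions) and nonsocial content (spinning wheels, background),
three signals can be recorded simultaneously: where the child's gaze
rests (eye fixation coordinates), whether the child imitates the target
facial expression (per-frame expression labels), and cortical activity
(14-channel EEG). Each modality carries partial, complementary
information about diagnosis. This package implements a two-level fusion
classifier over these modalities, together with a synthetic cohort
generator that makes the full pipeline testable end to end.

## Per-modality features

### Eye fixation: AOI distribution frequencies

Fixation points pooled over the training subjects are clustered into $K$
areas of interest (AOIs) by minimizing

$$J = \sum_{n=1}^N \sum_{k=1}^K r_{nk}\,\lVert x_n - \mu_k \rVert^2,$$

with $r_{nk}$ the hard assignment of point $n$ to cluster $k$ and
$\mu_k$ the cluster center. `aoi_kmeans()` implements Lloyd's
alternation (nearest-center assignment, then center update by the
cluster mean) with:

* k-means++ probabilistic seeding and `n_init = 10` restarts, keeping
  the best restart by final loss;
* deterministic tie-breaking (lowest cluster index wins);
* reseeding of an emptied cluster at the currently worst-fit point;
* a first-variation polish after Lloyd converges: single-point
  reassignments, applied one at a time with their exact size-corrected
  loss change $\frac{n_b}{n_b+1}\lVert x-\mu_b\rVert^2 -
  \frac{n_a}{n_a-1}\lVert x-\mu_a\rVert^2$, accepted only while they
  strictly lower $J$. Lloyd's iteration is assignment-stable at many
  partitions that a single-point move can still improve; on small point
  sets this polish is what makes the best-of-restarts loss reliably
  attain the global optimum (the test suite verifies equality with an
  exhaustive-partition oracle at $n \le 10$, $K = 2$). The loss remains
  non-increasing throughout a run.

A subject's feature vector is their AOI *distribution frequency*: the
fraction of the subject's fixation points assigned to each fitted AOI —
region count over total count, a probability vector over the $K$ AOIs.
$K$ defaults to 8 (the grid 8, 12, 16, 20 is the studied range;
`fusion_config(gaze_K = ...)` exposes it). Within cross-validation the
clustering is refit on training subjects only and held-out subjects are
projected onto the trained centers.

### Facial expression: windowed target-expression counts

The stimulus defines a target expression. Given per-frame categorical
expression labels (produced upstream — any frame labeler can be plugged
in via `frame_labeler()`; the synthetic generator emits labels
directly), `count_target_frames()` counts target frames in consecutive
40-frame windows. Trailing frames that do not fill a window are dropped
so every count lives on the common $[0, 40]$ scale; with the default
25 fps and a 40 s stimulus this yields 25 windows. Counts are conserved
(window sums equal the target total over retained frames) and invariant
to frame order within a window.

### EEG: region-by-band spectral power

The pathway in `region_band_features()` is:

1. **Band-pass 0.2–45 Hz.** Zero-phase 4th-order Butterworth response.
   The squared-magnitude response — what a forward-backward pass
   realizes — is applied spectrally (two FFTs per recording across all
   channels), which introduces no phase distortion or startup
   transients; on interior samples it matches forward-backward IIR
   filtering to five decimal places.
2. **Epoching and artifact rejection.** Non-overlapping 2 s epochs; an
   epoch is rejected if any channel exceeds 100 µV peak absolute
   amplitude (the blink/movement/muscle amplitude criterion). Both
   parameters are configurable; a recording with no retained epoch is
   an error.
3. **Band power.** Hann-windowed periodogram per epoch; band power is
   the sum of periodogram mass over bins in the half-open interval
   $[f_{\text{low}}, f_{\text{high}})$ for the five bands theta
   [4, 6), alpha [6, 13), low beta [13, 20), high beta [20, 30), gamma
   [30, 45) Hz. Half-open edges ensure a bin on a shared boundary is
   counted exactly once; the band layout (no delta band, theta ending
   at 6 Hz) is kept exactly as specified rather than "corrected" to
   textbook bands.
4. **Region aggregation.** Powers are averaged over retained epochs and
   over the channels of six scalp regions of the Emotiv 10–20 montage:
   LF = {AF3, F3, F7, FC5}, RF = {AF4, F4, F8, FC6}, LT = {T7},
   RT = {T8}, P = {P7, P8}, O = {O1, O2}. The montage lists only
   channel names, so this grouping follows standard 10–20 topography.

`ttest_screen()` compares the 30 region × band features between groups
at the subject level (one value per subject: the subject's epoch-mean
power). Levene's test on absolute deviations from group means gates the
choice between the pooled-variance Student t-test and Welch's t-test
(Welch when Levene's $p < 0.05$); features with two-sided $p < \alpha =
0.05$ are selected. `eeg_features()` offers the fixed 12-feature panel
found discriminative in the cohort analysis (theta in LF, RF, RT, P, O;
alpha in P, O; low beta in LF, RF, P, O; gamma in LF) or data-driven
screening refit on each training fold.

## The attribute-weighted naive Bayes decision layer

Decision fusion consumes one categorical subdecision per branch. For a
subdecision vector $(d_1, \dots, d_n)$ and class $c_i$, the fused
posterior is the naive Bayes factorization with each conditional
multiplied by a weighting coefficient:

$$P(c_i \mid d_1, \dots, d_n) \propto P(c_i) \prod_{j=1}^{n}
P(d_j \mid c_i)\, W(d_j \mid c_i),$$

$$W(d_m = v \mid c_i) = \frac{n(m) + n(d_m = v \wedge c_i)/n(d_m = v)}
{n(m)},$$

where $n(m)$ is the number of attributes, $n(d_m = v \wedge c_i)$ the
count of training rows with value $v$ and class $c_i$, and $n(d_m = v)$
the count with value $v$. The weight of an attribute value is largest
when the value is perfectly predictive of the class (upper bound
$(n(m)+1)/n(m)$) and exactly 1 when the value never co-occurs with the
class, so weighting never zeroes a probability. Conditionals are
Laplace-smoothed ($\lambda = 1$); the weights use raw counts, since the
$n(m)$ term already guards zeros. Scores are computed in log space and
normalized over classes (the evidence term is never estimated).
Prediction is the posterior argmax; an exact tie goes to the larger
prior, then to the first class in canonical order (ASD). Attribute
values unseen in training fall back to the smoothed zero-count
conditional with weight 1.

Design notes: the source presentation of the posterior uses a joint
notation without an explicit prior; the factorization above is the
reading under which "the product of the probabilities of each
attribute" is well-formed, and weights *multiply* conditionals (rather
than exponentiate them) following the description of "weighting the
conditional probability". $n(m)$ is read globally as the number of
decisions.

## The two-level hybrid fusion framework

* **Level 1.** The behavioral features (expression windows ‖ AOI
  frequencies, concatenated per subject) train one base classifier; the
  physiological (EEG) features independently train another. Supported
  base classifiers: random forest (500 trees), RBF support-vector
  machine ($C = 1$), and $K$-nearest neighbors ($k = 5$); features are
  z-scored with training-fold statistics before SVM/KNN. Each branch
  emits a categorical subdecision per subject.
* **Level 2.** The two subdecisions form a decision table on which the
  weighted naive Bayes is fit; the fused decision is its posterior
  argmax.

`fusion_loocv()` evaluates the pipeline by leave-one-out
cross-validation. In every fold *all* fitted components see only the
$n-1$ training subjects: the AOI clustering is refit on training
fixations (held-out subjects are projected), EEG screening (in
`"screened"` mode) is refit on training subjects, base classifiers are
trained on the training fold, and the decision table for the weighted
naive Bayes is built from *inner leave-one-out* subdecisions over the
training fold. Resubstitution subdecisions would be optimistically
correct and would drive the learned weights toward full confidence in
whichever branch happens to overfit hardest; the inner LOO gives the
decision layer honest estimates of each branch's reliability. Within an
outer fold the inner loop refits only the base classifiers — feature
extraction never sees labels, so refitting it inside the inner loop
would add an $O(n^2)$ clustering cost without affecting the held-out
subject. The no-leakage property is tested directly: corrupting a
held-out subject's label never changes that subject's own prediction.

Reports are column-normalized confusion matrices (element $(i, j)$ = %
of true class $j$ predicted as class $i$; columns sum to 100), plus the
off-diagonal percentages as directed confusion-graph edges for
comparing modality complementarity.

## The synthetic cohort generator

The study cohort (40 ASD + 40 TD children, 3–6 years) is not publicly
deposited, so `generate_cohort()` emulates its statistical structure;
all downstream code is exercised against it. Per subject:

* **Gaze** — fixation points from a 2-D Gaussian mixture over
  configurable AOI centers (default: 4 social + 4 nonsocial centers on
  a 1280 × 1024 screen, SD 40 px, 100 points/subject). A subject's
  mixture weight on social AOIs is a Beta draw around the group mean:
  TD 0.70, ASD 0.45 by default (effect sizes for gaze are free
  parameters of the generator — chosen as a clear but imperfect
  separation — not values estimated from any cohort).
* **Expression** — frame labels drawn independently per frame; target
  probability a Beta draw around TD 0.55 / ASD 0.35 (same caveat);
  1000 frames at 25 fps.
* **EEG** — per channel, a sum over the five bands of band-limited
  noise: random-phase Fourier components confined to the band (an
  exact band-pass of white noise, synthesized spectrally), plus white
  measurement noise. Band component RMS defaults to (4, 4, 2, 2, 1)
  for (theta, alpha, low beta, high beta, gamma). For ASD subjects the
  theta amplitude in the channels of the configured regions (default
  LF, RF, RT, P, O — the regions reported with significant theta
  elevation) is multiplied by `theta_gain_asd` times a per-subject
  log-normal factor. 40 s at 128 Hz.

Heterogeneity is first-class: Beta concentrations and log-normal SDs
control within-group spread, and `modality_coupling` imposes a
Gaussian-copula correlation between a subject's EEG effect strength
and behavioral effect strength. Defaults are symmetric across groups,
so a configuration with `theta_gain_asd = 1` and equal biases makes the
two groups generatively identical — the null configuration used to
verify that the t-test screen's false-positive rate matches its nominal
level. All randomness flows from the single integer `seed` through
per-subject derived seeds; identical specs produce byte-identical
cohorts.

What the generator does **not** emulate: saccade dynamics and fixation
durations, facial video (labels are generated directly, standing in for
an upstream expression-recognition model), volume conduction or any
waveform realism beyond band power, drift/artifact segments, and
recording-session nonstationarity. Tests passing on synthetic cohorts
therefore validate the pipeline's statistical machinery and its
leakage-safety, not clinical performance on real recordings.

### The complementary-strengths scenario

`complementary_cohort_spec()` is the configuration used to study what
decision fusion adds. With only two subdecisions, the fused rule is a
function of four patterns; if the branches' error profiles are
mirror-symmetric, the disagreement patterns are population-level ties
and no fusion rule can beat the better branch. Fusion has headroom
precisely when the branches fail on *different subjects*. The scenario
therefore makes ASD presentation heterogeneous (broad ASD effect
distributions against tight TD ones, so each branch misses its
least-affected ASD children while staying specific for TD), gives the
EEG effect slightly more strength than the behavioral one, and sets
`modality_coupling = -0.9` so the children with the weakest EEG
signature tend to carry the clearest behavioral signature and vice
versa. Cohorts are 25 + 25; the parameters were fixed by targeting
branch operating points (EEG branch more sensitive to ASD, behavioral
branch highly specific for TD, disjoint misses) before evaluating the
fusion property across seeds. Under this scenario the hybrid pipeline's
LOOCV accuracy exceeds the better single branch in the large majority
of seeds (the acceptance suite measures this over 20 seeds).

## Numerical and evaluation choices

* Problem sizes used by the test suite: oracle equivalence at
  $n \le 10$ points; weighted-NB enumeration at $\le 12$ rows;
  screening calibration over 200 null cohorts of 20 + 20 subjects;
  pipeline integrity on one 80-subject cohort; the complementarity
  study over 20 seeds of 25 + 25 subjects with the KNN base classifier
  (whose inner leave-one-out is essentially free to refit).
* K-means convergence: largest center displacement below `tol = 1e-8`
  or 100 iterations; polish moves accepted while the improvement
  exceeds $10^{-6} J$.
* Posterior ties are detected at $10^{-12}$; weighted-NB scores are
  accumulated in log space.
* The Hann periodogram is normalized so band powers ratio exactly as
  squared amplitudes for in-band tones; absolute units cancel in every
  downstream comparison.
* Degenerate screen inputs (zero variance in both groups with equal
  means) report $t = 0$, $p = 1$, not selected, rather than NaN.
* `fusion_loocv()` derives one seed per fold from the config seed;
  fixed seed ⇒ byte-identical evaluation reports.

## Limitations

* The decision layer fuses exactly two subdecisions; gains over the
  better branch require genuinely complementary errors and are modest
  when branches err on the same subjects.
* Accuracy on synthetic cohorts says nothing quantitative about real
  cohorts; the generator's effect sizes are free parameters.
* The screened EEG mode selects features marginally (per-feature
  tests), not jointly; correlated features can enter together.
* Expression analysis starts at frame labels; errors of an upstream
  recognition model are outside the evaluated pipeline.
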