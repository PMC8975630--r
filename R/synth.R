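#' Specification of a synthetic multimodal cohort
#'
#' Describes a two-group (ASD / TD) cohort of children for which the three
#' modalities are simulated with plantable group effects:
#' \itemize{
#' \item \strong{Eye fixation}: each subject's fixation points are drawn
#'   from a 2-D Gaussian mixture over the configured AOI centers. A
#'   subject's total mixture weight on the social AOIs is their social
#'   attention bias, drawn from a Beta distribution around the group mean
#'   (`gaze_social_bias_td` / `gaze_social_bias_asd`); TD children are
#'   biased toward social regions, ASD children toward nonsocial ones.
#' \item \strong{Facial expression}: per-frame labels are independent
#'   draws; a frame shows the target expression with the subject's
#'   probability, drawn from a Beta distribution around the group mean
#'   (`p_target_td` higher than `p_target_asd`).
#' \item \strong{EEG}: each channel is a sum over the five analysis bands
#'   of band-limited noise (random-phase Fourier components confined to
#'   the band) plus white noise of sd `noise_sd`. For ASD subjects, the
#'   theta-band component amplitude in the channels of `theta_regions` is
#'   multiplied by `theta_gain_asd` (times a per-subject log-normal
#'   factor), planting the elevated theta power reported for ASD in
#'   frontal, temporal, parietal and occipital regions.
#' }
#' Per-subject heterogeneity (Beta concentrations `kappa`, log-normal
#' `theta_gain_sd` and `subject_amp_sd`) defaults to the same values in
#' both groups, so a configuration with `theta_gain_asd = 1` and equal
#' biases and target probabilities makes the two groups' generative
#' distributions identical.
#'
#' @param n_asd,n_td group sizes (default 40 + 40, the study design).
#' @param seed integer seed; all randomness derives from it.
#' @param screen screen size in pixels, `c(width, height)`.
#' @param aoi_centers data.frame with columns `x`, `y`, `social`
#'   (logical): the stimulus regions generating fixations.
#' @param aoi_sd_px Gaussian spread of fixations around an AOI center (px).
#' @param n_fixations fixation points recorded per subject.
#' @param gaze_social_bias_td,gaze_social_bias_asd group-mean probability
#'   that a fixation falls in a social AOI.
#' @param gaze_bias_kappa_td,gaze_bias_kappa_asd Beta concentration of the
#'   per-subject social bias (larger = more homogeneous group).
#' @param fps video frame rate (default 25).
#' @param video_duration_s stimulus length in seconds (default 40; with
#'   `fps = 25` this yields 1000 frames = 25 windows of 40 frames).
#' @param target_label,other_labels the expression vocabulary; `target_label`
#'   is the stimulus' target expression.
#' @param p_target_td,p_target_asd group-mean per-frame probability of the
#'   target expression.
#' @param p_target_kappa_td,p_target_kappa_asd Beta concentration of the
#'   per-subject target probability.
#' @param eeg_fs EEG sampling rate in Hz (default 128).
#' @param eeg_duration_s EEG length in seconds (default 40).
#' @param band_amp named amplitudes (RMS, amplitude units) of the five
#'   band-limited components.
#' @param theta_gain_asd multiplicative factor (>= 1) on the theta
#'   component amplitude of ASD subjects in `theta_regions`.
#' @param theta_gain_sd_asd,theta_gain_sd_td per-subject log-normal sd of
#'   the theta gain.
#' @param theta_regions regions (names of [emotiv_region_map()]) whose
#'   channels receive the theta gain.
#' @param subject_amp_sd log-normal sd of a per-subject global EEG
#'   amplitude factor (inter-subject power variability).
#' @param modality_coupling correlation in `[-1, 1]` between a subject's
#'   EEG effect strength (theta-gain quantile) and their behavioral effect
#'   strength (gaze-bias and target-expression quantiles), imposed through
#'   a Gaussian copula. 0 (default) draws the modalities independently;
#'   negative values make children whose EEG is most atypical tend to show
#'   the least atypical behavior and vice versa — modalities informative
#'   about different children, the regime where decision fusion has the
#'   most to add.
#' @param noise_sd sd of the additive white measurement noise.
#' @return An object of class `"cohort_spec"` (a validated list).
#' @seealso [generate_cohort()], [null_cohort_spec()],
#'   [complementary_cohort_spec()]
#' @export
cohort_spec <- function(n_asd = 40L, n_td = 40L, seed = 1L,
                        screen = c(1280L, 1024L),
                        aoi_centers = default_aoi_centers(),
                        aoi_sd_px = 40,
                        n_fixations = 100L,
                        gaze_social_bias_td = 0.70,
                        gaze_social_bias_asd = 0.45,
                        gaze_bias_kappa_td = 20,
                        gaze_bias_kappa_asd = 20,
                        fps = 25L,
                        video_duration_s = 40,
                        target_label = "happy",
                        other_labels = c("neutral", "sad", "surprise"),
                        p_target_td = 0.55,
                        p_target_asd = 0.35,
                        p_target_kappa_td = 20,
                        p_target_kappa_asd = 20,
                        eeg_fs = 128,
                        eeg_duration_s = 40,
                        band_amp = c(theta = 4, alpha = 4, low_beta = 2,
                                     high_beta = 2, gamma = 1),
                        theta_gain_asd = 1.5,
                        theta_gain_sd_asd = 0.15,
                        theta_gain_sd_td = 0.15,
                        theta_regions = c("LF", "RF", "RT", "P", "O"),
                        subject_amp_sd = 0.15,
                        modality_coupling = 0,
                        noise_sd = 1) {
  spec <- structure(as.list(environment()), class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}

#' @rdname cohort_spec
#' @export
default_aoi_centers <- function() {
  data.frame(
    x = c(420, 600, 510, 860, 1060, 1130, 160, 210),
    y = c(300, 300, 520, 380, 700, 330, 820, 160),
    social = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
}

validate_cohort_spec <- function(spec) {
  check_that(is_count(spec$n_asd), "n_asd", "must be a positive integer")
  check_that(is_count(spec$n_td), "n_td", "must be a positive integer")
  check_that(is_count(spec$seed, min = 0L), "seed",
             "must be a nonnegative integer")
  check_that(length(spec$screen) == 2L && all(spec$screen > 0), "screen",
             "must be positive (width, height)")
  ac <- spec$aoi_centers
  check_that(is.data.frame(ac) && all(c("x", "y", "social") %in% names(ac)) &&
               nrow(ac) >= 2L && any(ac$social) && any(!ac$social),
             "aoi_centers",
             "must contain social and nonsocial centers with x, y columns")
  check_that(spec$aoi_sd_px > 0, "aoi_sd_px", "must be positive")
  check_that(is_count(spec$n_fixations), "n_fixations",
             "must be a positive integer")
  for (f in c("gaze_social_bias_td", "gaze_social_bias_asd",
              "p_target_td", "p_target_asd"))
    check_that(is_prob(spec[[f]]), f, "must be a probability in [0, 1]")
  for (f in c("gaze_bias_kappa_td", "gaze_bias_kappa_asd",
              "p_target_kappa_td", "p_target_kappa_asd"))
    check_that(spec[[f]] > 0, f, "must be positive")
  check_that(spec$fps > 0, "fps", "must be positive")
  check_that(spec$video_duration_s > 0, "video_duration_s",
             "must be positive")
  check_that(is.character(spec$target_label) &&
               length(spec$target_label) == 1L,
             "target_label", "must be a single label")
  check_that(length(spec$other_labels) >= 1L &&
               !(spec$target_label %in% spec$other_labels),
             "other_labels", "must be non-target labels")
  check_that(spec$eeg_fs > 90, "eeg_fs",
             "must exceed 90 Hz (gamma band up to 45 Hz)")
  check_that(spec$eeg_duration_s > 0, "eeg_duration_s", "must be positive")
  check_that(all(band_definitions()$name %in% names(spec$band_amp)),
             "band_amp", "must name all five bands")
  check_that(all(spec$band_amp >= 0), "band_amp", "must be nonnegative")
  check_that(spec$theta_gain_asd >= 1, "theta_gain_asd", "must be >= 1")
  check_that(spec$theta_gain_sd_asd >= 0 && spec$theta_gain_sd_td >= 0,
             "theta_gain_sd_asd", "must be nonnegative")
  check_that(all(spec$theta_regions %in% names(emotiv_region_map())),
             "theta_regions", "must be region names (LF, RF, LT, RT, P, O)")
  check_that(spec$subject_amp_sd >= 0, "subject_amp_sd",
             "must be nonnegative")
  check_that(is.numeric(spec$modality_coupling) &&
               abs(spec$modality_coupling) <= 1, "modality_coupling",
             "must be a correlation in [-1, 1]")
  check_that(spec$noise_sd >= 0, "noise_sd", "must be nonnegative")
  invisible(spec)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("Synthetic cohort spec: %d ASD + %d TD (seed %d)\n",
              x$n_asd, x$n_td, x$seed))
  cat(sprintf("  gaze social bias ASD/TD: %.2f / %.2f; p(target) ASD/TD: %.2f / %.2f\n",
              x$gaze_social_bias_asd, x$gaze_social_bias_td,
              x$p_target_asd, x$p_target_td))
  cat(sprintf("  theta gain ASD: %.2f in %s\n", x$theta_gain_asd,
              paste(x$theta_regions, collapse = ",")))
  invisible(x)
}

# Beta quantile parameterized by mean and concentration
qbeta_mk <- function(q, mean, kappa) {
  if (mean <= 0 || mean >= 1) return(mean)
  stats::qbeta(q, mean * kappa, (1 - mean) * kappa)
}

# Per-subject effect-strength quantiles through a Gaussian copula: z_eeg
# drives the theta gain, z_gaze / z_expr the behavioral abnormality, with
# corr(z_eeg, behavioral latent) = rho (0 = independent draws).
subject_effect_z <- function(rho) {
  a <- sqrt(abs(rho))
  b <- sqrt(1 - abs(rho))
  u <- stats::rnorm(1)
  e <- stats::rnorm(4)
  z_eeg <- a * u + b * e[1]
  z_beh <- sign(rho) * a * u + b * e[2]
  list(eeg = z_eeg,
       gaze = sqrt(0.8) * z_beh + sqrt(0.2) * e[3],
       expr = sqrt(0.8) * z_beh + sqrt(0.2) * e[4])
}

# Band-limited noise for all channels of one subject: spectrum with
# random-phase components confined to each band, scaled so a band's
# component has RMS `amp`, then one inverse FFT per channel.
synth_eeg_matrix <- function(n, fs, band_amp_mat) {
  n_ch <- ncol(band_amp_mat)
  bands <- band_definitions()
  freq <- (seq_len(n) - 1) * fs / n
  half <- 2:(ceiling(n / 2))        # positive, non-DC, non-Nyquist bins
  X <- matrix(0 + 0i, n, n_ch)
  for (b in seq_len(nrow(bands))) {
    sel <- half[freq[half] >= bands$low[b] & freq[half] < bands$high[b]]
    M <- length(sel)
    if (M == 0L) next
    phases <- matrix(stats::runif(M * n_ch, 0, 2 * pi), M, n_ch)
    # each cosine gets amplitude amp*sqrt(2/M) so the sum has RMS = amp
    A <- sweep(exp(1i * phases), 2, band_amp_mat[b, ] * sqrt(2 / M) * n / 2,
               "*")
    X[sel, ] <- X[sel, ] + A
  }
  X[n - half + 2, ] <- Conj(X[half, ])
  Re(stats::mvfft(X, inverse = TRUE)) / n
}

#' Generate a synthetic multimodal cohort
#'
#' Draws every subject's fixation set, expression track and EEG recording
#' according to the generative model described in [cohort_spec()]. The
#' result is deterministic given the spec (including its seed).
#'
#' @param spec a [cohort_spec()].
#' @return An object of class `"cohort"`: a list with `subjects` (named
#'   list; each subject has `subject_id`, `label`, `fixations` (n x 2
#'   matrix), `expressions` (character vector of frame labels), `eeg`
#'   ([eeg_recording()])) and `spec`.
#' @examples
#' co <- generate_cohort(cohort_spec(n_asd = 2, n_td = 2, seed = 1,
#'                                   eeg_duration_s = 4))
#' co
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  validate_cohort_spec(spec)
  labels <- rep(c("ASD", "TD"), c(spec$n_asd, spec$n_td))
  ids <- sprintf("%s%02d", ifelse(labels == "ASD", "A", "T"),
                 c(seq_len(spec$n_asd), seq_len(spec$n_td)))
  region_map <- emotiv_region_map()
  theta_channels <- unlist(region_map[spec$theta_regions], use.names = FALSE)
  n_frames <- floor(spec$fps * spec$video_duration_s)
  n_samples <- floor(spec$eeg_fs * spec$eeg_duration_s)
  band_names <- band_definitions()$name
  amp <- spec$band_amp[band_names]

  subjects <- vector("list", length(ids))
  names(subjects) <- ids
  for (i in seq_along(ids)) {
    asd <- labels[i] == "ASD"
    subjects[[i]] <- with_seed(child_seed(spec$seed, i), {
      z <- subject_effect_z(spec$modality_coupling)
      # --- gaze: Gaussian mixture over AOI centers -----------------------
      bias_mean <- if (asd) spec$gaze_social_bias_asd else
        spec$gaze_social_bias_td
      bias_kappa <- if (asd) spec$gaze_bias_kappa_asd else
        spec$gaze_bias_kappa_td
      # high gaze abnormality quantile -> low social bias
      bias <- qbeta_mk(stats::pnorm(-z$gaze), bias_mean, bias_kappa)
      social <- spec$aoi_centers$social
      w <- ifelse(social, bias / sum(social), (1 - bias) / sum(!social))
      comp <- sample.int(nrow(spec$aoi_centers), spec$n_fixations,
                         replace = TRUE, prob = w)
      fix <- cbind(
        x = stats::rnorm(spec$n_fixations, spec$aoi_centers$x[comp],
                         spec$aoi_sd_px),
        y = stats::rnorm(spec$n_fixations, spec$aoi_centers$y[comp],
                         spec$aoi_sd_px))
      fix[, 1] <- pmin(pmax(fix[, 1], 0), spec$screen[1])
      fix[, 2] <- pmin(pmax(fix[, 2], 0), spec$screen[2])

      # --- expression: per-frame independent draws ----------------------
      p_mean <- if (asd) spec$p_target_asd else spec$p_target_td
      p_kappa <- if (asd) spec$p_target_kappa_asd else spec$p_target_kappa_td
      # high expression abnormality quantile -> low target-expression rate
      p <- qbeta_mk(stats::pnorm(-z$expr), p_mean, p_kappa)
      is_target <- stats::runif(n_frames) < p
      expr <- ifelse(is_target, spec$target_label,
                     sample(spec$other_labels, n_frames, replace = TRUE))

      # --- EEG: band-limited components + white noise -------------------
      amp_subject <- exp(stats::rnorm(1, 0, spec$subject_amp_sd))
      gain_sd <- if (asd) spec$theta_gain_sd_asd else spec$theta_gain_sd_td
      gain_mean <- if (asd) spec$theta_gain_asd else 1
      theta_gain <- gain_mean * exp(gain_sd * z$eeg)
      amp_mat <- matrix(amp * amp_subject, length(amp),
                        length(EMOTIV_CHANNELS),
                        dimnames = list(band_names, EMOTIV_CHANNELS))
      amp_mat["theta", theta_channels] <-
        amp_mat["theta", theta_channels] * theta_gain
      sig <- synth_eeg_matrix(n_samples, spec$eeg_fs, amp_mat)
      sig <- sig + stats::rnorm(length(sig), 0, spec$noise_sd)
      eeg <- eeg_recording(t(sig), fs = spec$eeg_fs,
                           channels = EMOTIV_CHANNELS,
                           subject_id = ids[i])
      list(subject_id = ids[i], label = labels[i], fixations = fix,
           expressions = expr, eeg = eeg)
    })
  }
  structure(list(subjects = subjects, spec = spec), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  lab <- cohort_labels(x)
  cat(sprintf("Synthetic multimodal cohort: %d subjects (%d ASD, %d TD)\n",
              length(lab), sum(lab == "ASD"), sum(lab == "TD")))
  s <- x$subjects[[1]]
  cat(sprintf("  per subject: %d fixations, %d frames, EEG %d ch x %d samples at %g Hz\n",
              nrow(s$fixations), length(s$expressions),
              nrow(s$eeg$data), ncol(s$eeg$data), s$eeg$fs))
  invisible(x)
}

#' Convenience accessors for a synthetic cohort
#'
#' @param cohort a [generate_cohort()] result.
#' @return `cohort_labels`: named character vector of diagnosis labels;
#'   `cohort_fixations` / `cohort_expressions`: named lists of per-subject
#'   fixation matrices / frame-label vectors; `cohort_eeg`: named list of
#'   [eeg_recording()] objects.
#' @export
cohort_labels <- function(cohort) {
  vapply(cohort$subjects, `[[`, character(1), "label")
}

#' @rdname cohort_labels
#' @export
cohort_fixations <- function(cohort) {
  lapply(cohort$subjects, `[[`, "fixations")
}

#' @rdname cohort_labels
#' @export
cohort_expressions <- function(cohort) {
  lapply(cohort$subjects, `[[`, "expressions")
}

#' @rdname cohort_labels
#' @export
cohort_eeg <- function(cohort) {
  lapply(cohort$subjects, `[[`, "eeg")
}

#' Reference cohort configurations
#'
#' `null_cohort_spec()` plants no group effect anywhere (equal gaze bias,
#' equal target-expression probability, theta gain 1, symmetric
#' heterogeneity): the two groups' generative distributions are identical,
#' which calibrates false-positive rates of the screening tests.
#'
#' `complementary_cohort_spec()` configures the complementary-strengths
#' scenario used to study fusion gain. ASD presentation is heterogeneous
#' (broad per-subject effect distributions against tight TD ones, so each
#' branch misses the least-affected ASD children while staying specific
#' for TD), the EEG effect is somewhat stronger than the behavioral one,
#' and `modality_coupling = -0.8` makes the children with the weakest EEG
#' signature tend to carry the clearest behavioral signature and vice
#' versa. Each branch then errs mostly by missing ASD subjects — but on
#' largely different subjects — which is the complementary information the
#' decision-fusion layer can exploit.
#'
#' @param seed integer seed.
#' @param n_asd,n_td group sizes.
#' @return A [cohort_spec()].
#' @export
null_cohort_spec <- function(seed = 1L, n_asd = 20L, n_td = 20L) {
  cohort_spec(n_asd = n_asd, n_td = n_td, seed = seed,
              gaze_social_bias_td = 0.6, gaze_social_bias_asd = 0.6,
              p_target_td = 0.45, p_target_asd = 0.45,
              theta_gain_asd = 1)
}

#' @rdname null_cohort_spec
#' @export
complementary_cohort_spec <- function(seed = 1L, n_asd = 25L, n_td = 25L) {
  cohort_spec(n_asd = n_asd, n_td = n_td, seed = seed,
              gaze_social_bias_td = 0.78, gaze_social_bias_asd = 0.57,
              gaze_bias_kappa_td = 80, gaze_bias_kappa_asd = 6,
              p_target_td = 0.58, p_target_asd = 0.46,
              p_target_kappa_td = 80, p_target_kappa_asd = 6,
              theta_gain_asd = 2.05,
              theta_gain_sd_asd = 0.32, theta_gain_sd_td = 0.22,
              subject_amp_sd = 0.12,
              modality_coupling = -0.9)
}
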