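#' EEG recording container
#'
#' A light container for one subject's multichannel EEG: a channels x
#' samples numeric matrix, the sampling rate, and channel names drawn from
#' the 14-electrode Emotiv montage (AF3, F7, F3, FC5, T7, P7, O1, O2, P8,
#' T8, FC6, F4, F8, AF4; international 10-20 placement). The sampling rate
#' must exceed 90 Hz so the gamma band (up to 45 Hz) is below Nyquist.
#'
#' @param data numeric matrix, channels in rows, samples in columns.
#' @param fs sampling rate in Hz.
#' @param channels character vector of channel names, one per row of
#'   `data`; defaults to the row names of `data`.
#' @param subject_id subject identifier.
#' @return An object of class `"eeg_recording"`.
#' @export
eeg_recording <- function(data, fs, channels = rownames(data),
                          subject_id = "subject") {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  check_that(is.numeric(fs) && length(fs) == 1L && fs > 0, "fs",
             "must be a positive sampling rate in Hz")
  check_that(fs > 2 * 45, "fs",
             "must exceed 90 Hz so the 45 Hz band edge is resolvable")
  if (is.null(channels))
    stop("channel names are required (rows of `data`)", call. = FALSE)
  channels <- as.character(channels)
  check_that(length(channels) == nrow(data), "channels",
             "must name every row of `data`")
  check_that(!anyDuplicated(channels), "channels", "must be unique")
  bad <- setdiff(channels, EMOTIV_CHANNELS)
  if (length(bad))
    stop("unknown channel(s) outside the 14-channel montage: ",
         paste(bad, collapse = ", "), call. = FALSE)
  rownames(data) <- channels
  structure(list(data = data, fs = fs, channels = channels,
                 subject_id = subject_id),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("EEG recording '%s': %d channels x %d samples at %g Hz (%.1f s)\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$fs,
              ncol(x$data) / x$fs))
  invisible(x)
}

#' The five analysis frequency bands
#'
#' Half-open intervals `[low, high)` in Hz: theta 4-6, alpha 6-13, low beta
#' 13-20, high beta 20-30, gamma 30-45. Half-open edges ensure a frequency
#' bin on a shared edge (6, 13, 20, 30 Hz) is counted in exactly one band.
#'
#' @return data.frame with columns `name`, `low`, `high`.
#' @export
band_definitions <- function() {
  data.frame(name = c("theta", "alpha", "low_beta", "high_beta", "gamma"),
             low = c(4, 6, 13, 20, 30),
             high = c(6, 13, 20, 30, 45))
}

#' Scalp-region map for the Emotiv montage
#'
#' Groups the 14 channels into six regions by standard 10-20 topography:
#' left/right frontal (LF, RF), left/right temporal (LT, RT), parietal (P)
#' and occipital (O). Regions are disjoint.
#'
#' @return Named list of character vectors of channel names.
#' @export
emotiv_region_map <- function() {
  list(LF = c("AF3", "F3", "F7", "FC5"),
       RF = c("AF4", "F4", "F8", "FC6"),
       LT = "T7",
       RT = "T8",
       P = c("P7", "P8"),
       O = c("O1", "O2"))
}

#' Band-pass filter an EEG recording
#'
#' Zero-phase 4th-order Butterworth band-pass retaining `[low, high]` Hz;
#' the defaults reject drift below 0.2 Hz and noise above 45 Hz. The
#' squared-magnitude Butterworth response — what a forward-backward pass
#' of the filter realizes — is applied in the frequency domain, which
#' introduces no phase distortion or startup transients and filters all
#' channels in two FFTs.
#'
#' @param rec an [eeg_recording()].
#' @param low,high band edges in Hz, `0 < low < high < fs/2`.
#' @return A filtered `"eeg_recording"` of the same shape.
#' @export
bandpass_filter <- function(rec, low = 0.2, high = 45) {
  stopifnot(inherits(rec, "eeg_recording"))
  check_that(is.numeric(low) && low > 0, "low", "must be > 0 Hz")
  check_that(is.numeric(high) && high > low, "high", "must exceed `low`")
  check_that(high < rec$fs / 2, "high",
             sprintf("must be below the Nyquist frequency %g Hz", rec$fs / 2))
  bf <- signal::butter(4, c(low, high) / (rec$fs / 2), type = "pass")
  n <- ncol(rec$data)
  z <- exp(-1i * 2 * pi * (seq_len(n) - 1) / n)
  horner <- function(coef) {
    acc <- rep(0 + 0i, n)
    for (c_k in rev(coef)) acc <- acc * z + c_k
    acc
  }
  H2 <- Mod(horner(bf$b) / horner(bf$a))^2   # |H|^2: zero-phase response
  Y <- stats::mvfft(t(rec$data)) * H2
  out <- rec
  out$data <- t(Re(stats::mvfft(Y, inverse = TRUE)) / n)
  rownames(out$data) <- rec$channels
  out
}

#' Split a recording into epochs and reject high-amplitude artifacts
#'
#' Divides the recording into consecutive non-overlapping epochs of
#' `epoch_s` seconds (a trailing partial epoch is dropped) and rejects any
#' epoch in which some channel's peak absolute amplitude exceeds
#' `amp_thresh` — the amplitude criterion targeting eye-blink, eye-movement
#' and muscle artifacts.
#'
#' @param rec an [eeg_recording()].
#' @param epoch_s epoch length in seconds (default 2).
#' @param amp_thresh rejection threshold in the recording's amplitude units
#'   (default 100, i.e. 100 uV for microvolt data).
#' @return List of retained epochs in original order, each a channels x
#'   samples matrix; attribute `"rejected"` holds the dropped epoch indices.
#' @export
epoch_and_reject <- function(rec, epoch_s = 2, amp_thresh = 100) {
  stopifnot(inherits(rec, "eeg_recording"))
  len <- floor(epoch_s * rec$fs)
  check_that(len >= 2, "epoch_s", "must span at least 2 samples")
  n_ep <- ncol(rec$data) %/% len
  if (n_ep == 0L)
    stop("recording shorter than one epoch", call. = FALSE)
  epochs <- lapply(seq_len(n_ep), function(i)
    rec$data[, ((i - 1L) * len + 1L):(i * len), drop = FALSE])
  peak <- vapply(epochs, function(e) max(abs(e)), numeric(1))
  keep <- peak <= amp_thresh
  if (!any(keep))
    stop(sprintf("all %d epochs exceed the %g amplitude threshold; recording '%s' unusable",
                 n_ep, amp_thresh, rec$subject_id), call. = FALSE)
  out <- epochs[keep]
  attr(out, "rejected") <- which(!keep)
  out
}

# One-sided Hann-windowed periodogram for a set of equal-length series.
# `x` is samples x series; returns list(freq, psd) with psd samples/2+1 x
# series, normalized so that sum(psd) * df approximates the series variance.
periodogram_psd <- function(x, fs) {
  x <- as.matrix(x)
  L <- nrow(x)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(L) / (L + 1)))   # Hann
  xw <- x * w
  X <- stats::mvfft(xw)
  n_keep <- floor(L / 2) + 1L
  psd <- (abs(X[seq_len(n_keep), , drop = FALSE])^2) / (fs * sum(w^2))
  scale <- rep(2, n_keep)
  scale[1] <- 1
  if (L %% 2 == 0) scale[n_keep] <- 1
  psd <- psd * scale
  list(freq = (seq_len(n_keep) - 1) * fs / L, psd = psd)
}

#' Spectral power of one epoch in a frequency band
#'
#' Hann-windowed periodogram power per channel, summed over the frequency
#' bins falling in `[low, high)`. Power is in squared amplitude units.
#'
#' @param epoch channels x samples numeric matrix (one retained epoch).
#' @param fs sampling rate in Hz.
#' @param low,high band edges in Hz, half-open `[low, high)`; `high` must
#'   not exceed the Nyquist frequency.
#' @return Named numeric vector of band power per channel (nonnegative).
#' @export
band_power <- function(epoch, fs, low, high) {
  epoch <- as.matrix(epoch)
  if (ncol(epoch) < 2L) stop("epoch must have at least 2 samples",
                             call. = FALSE)
  check_that(is.numeric(low) && is.numeric(high) && low < high,
             "low", "band edges must satisfy low < high")
  check_that(high <= fs / 2, "high",
             "band extends beyond the Nyquist frequency")
  pg <- periodogram_psd(t(epoch), fs)
  sel <- pg$freq >= low & pg$freq < high
  df <- fs / ncol(epoch)
  p <- colSums(pg$psd[sel, , drop = FALSE]) * df
  stats::setNames(as.numeric(p), rownames(epoch))
}

#' Region-by-band mean power features for one recording
#'
#' The full EEG feature pathway for one subject: band-pass filtering,
#' epoching with amplitude-based artifact rejection, per-epoch Hann
#' periodogram band power, then averaging over retained epochs and over the
#' channels of each scalp region.
#'
#' @param rec an [eeg_recording()].
#' @param bands band table as from [band_definitions()].
#' @param region_map named list of channel sets as from
#'   [emotiv_region_map()]; all channels must be present in `rec`.
#' @param epoch_s epoch length in seconds.
#' @param amp_thresh artifact rejection threshold (amplitude units).
#' @param filter_low,filter_high band-pass edges in Hz applied before
#'   epoching; set `filter_low = NULL` to skip filtering.
#' @return Numeric matrix, regions x bands (rows in `region_map` order,
#'   columns in `bands` order); entries are nonnegative mean powers.
#' @export
region_band_features <- function(rec, bands = band_definitions(),
                                 region_map = emotiv_region_map(),
                                 epoch_s = 2, amp_thresh = 100,
                                 filter_low = 0.2, filter_high = 45) {
  stopifnot(inherits(rec, "eeg_recording"))
  missing_ch <- setdiff(unlist(region_map), rec$channels)
  if (length(missing_ch))
    stop("recording lacks channel(s) required by the region map: ",
         paste(missing_ch, collapse = ", "), call. = FALSE)
  if (!is.null(filter_low))
    rec <- bandpass_filter(rec, filter_low, filter_high)
  epochs <- epoch_and_reject(rec, epoch_s, amp_thresh)
  L <- ncol(epochs[[1]])
  n_ch <- nrow(rec$data)
  # one FFT call across all epochs and channels
  stacked <- do.call(cbind, lapply(epochs, t))      # L x (n_ch * n_epochs)
  pg <- periodogram_psd(stacked, rec$fs)
  df <- rec$fs / L
  out <- matrix(0, length(region_map), nrow(bands),
                dimnames = list(names(region_map), bands$name))
  for (b in seq_len(nrow(bands))) {
    sel <- pg$freq >= bands$low[b] & pg$freq < bands$high[b]
    bp <- colSums(pg$psd[sel, , drop = FALSE]) * df    # per channel x epoch
    bp_mat <- matrix(bp, nrow = n_ch,
                     dimnames = list(rec$channels, NULL))
    ch_mean <- rowMeans(bp_mat)                        # over epochs
    out[, b] <- vapply(region_map, function(chs) mean(ch_mean[chs]),
                       numeric(1))
  }
  out
}

#' Independent-samples t-test screen over region x band power features
#'
#' For each of the region x band features, tests the ASD-vs-TD difference
#' in mean power across subjects. Equality of variances is first assessed
#' with Levene's test (F statistic from a one-way ANOVA on absolute
#' deviations from the group means); when Levene's p < 0.05 a Welch t-test
#' is used, otherwise the pooled-variance Student t-test. A feature is
#' selected when its two-sided p-value falls below `alpha`.
#'
#' @param asd,td lists of region x band matrices (one per subject), as
#'   returned by [region_band_features()]; at least two subjects per group.
#' @param alpha selection threshold on the two-sided p-value (default 0.05).
#' @return data.frame with one row per feature: `region`, `band`,
#'   `feature`, `F` (Levene), `t`, `p`, `mean_diff` (ASD minus TD),
#'   `se`, `welch`, `selected`. Rows are ordered band-major, matching the
#'   band/region report layout.
#' @export
ttest_screen <- function(asd, td, alpha = 0.05) {
  stopifnot(is.list(asd), is.list(td))
  if (length(asd) < 2L || length(td) < 2L)
    stop("need at least two subjects per group", call. = FALSE)
  template <- asd[[1]]
  regions <- rownames(template)
  bands <- colnames(template)
  grab <- function(lst, r, b) vapply(lst, function(m) m[r, b], numeric(1))
  rows <- list()
  for (b in bands) for (r in regions) {
    x <- grab(asd, r, b); y <- grab(td, r, b)
    rows[[paste(r, b, sep = ".")]] <- feature_ttest(x, y, alpha)
  }
  out <- do.call(rbind, rows)
  out$region <- sub("\\..*$", "", rownames(out))
  out$band <- sub("^[^.]*\\.", "", rownames(out))
  out$feature <- rownames(out)
  rownames(out) <- NULL
  out[, c("region", "band", "feature", "F", "t", "p",
          "mean_diff", "se", "welch", "selected")]
}

# Levene-gated two-sample t-test on one feature
feature_ttest <- function(x, y, alpha) {
  if (stats::var(x) == 0 && stats::var(y) == 0 && mean(x) == mean(y))
    return(data.frame(F = 0, t = 0, p = 1, mean_diff = 0, se = 0,
                      welch = FALSE, selected = FALSE))
  g <- factor(rep(c("a", "b"), c(length(x), length(y))))
  z <- abs(c(x - mean(x), y - mean(y)))
  lev <- stats::anova(stats::lm(z ~ g))
  lev_F <- lev$`F value`[1]
  lev_p <- lev$`Pr(>F)`[1]
  if (!is.finite(lev_F)) { lev_F <- 0; lev_p <- 1 }
  welch <- lev_p < 0.05
  tt <- stats::t.test(x, y, var.equal = !welch)
  data.frame(F = lev_F, t = unname(tt$statistic), p = tt$p.value,
             mean_diff = mean(x) - mean(y), se = unname(tt$stderr),
             welch = welch, selected = tt$p.value < alpha)
}

# The fixed 12-feature panel: regions x bands found discriminative in the
# cohort analysis (theta LF/RF/RT/P/O, alpha P/O, low beta LF/RF/P/O,
# gamma LF), in this order.
FIXED12 <- c("LF.theta", "RF.theta", "RT.theta", "P.theta", "O.theta",
             "P.alpha", "O.alpha",
             "LF.low_beta", "RF.low_beta", "P.low_beta", "O.low_beta",
             "LF.gamma")

#' EEG feature matrix for a cohort
#'
#' Flattens each subject's region x band power matrix into a feature row
#' and selects columns by `mode`: `"fixed12"` returns the fixed
#' 12-feature panel (theta in LF, RF, RT, P, O; alpha in P, O; low beta in
#' LF, RF, P, O; gamma in LF — in that order); `"screened"` selects the
#' features passing [ttest_screen()] fitted on the training subjects only
#' (if none pass, the single smallest-p feature is used).
#'
#' @param powers named list of region x band matrices, one per subject.
#' @param mode `"fixed12"` or `"screened"`.
#' @param labels named class labels (`"ASD"`/`"TD"`) for at least the
#'   training subjects; required for `"screened"`.
#' @param train subject names used to fit the screen; defaults to all
#'   labelled subjects.
#' @param alpha screening threshold (default 0.05).
#' @return List with `features` (subjects x selected features matrix),
#'   `selected` (feature names), and `screen` (the [ttest_screen()] table,
#'   `NULL` for `"fixed12"`).
#' @export
eeg_features <- function(powers, mode = c("fixed12", "screened"),
                         labels = NULL, train = NULL, alpha = 0.05) {
  mode <- match.arg(mode)
  stopifnot(is.list(powers), length(powers) >= 1L)
  if (is.null(names(powers))) names(powers) <- paste0("S", seq_along(powers))
  flat <- t(vapply(powers, function(m) {
    v <- as.numeric(m)
    names(v) <- as.vector(outer(rownames(m), colnames(m), paste, sep = "."))
    v
  }, numeric(length(powers[[1]]))))
  screen <- NULL
  if (mode == "fixed12") {
    missing_f <- setdiff(FIXED12, colnames(flat))
    if (length(missing_f))
      stop("power matrices lack required region/band feature(s): ",
           paste(missing_f, collapse = ", "), call. = FALSE)
    selected <- FIXED12
  } else {
    if (is.null(labels))
      stop("`labels` are required for screened mode", call. = FALSE)
    if (is.null(train)) train <- names(labels)
    if (is.numeric(train)) train <- names(powers)[train]
    lab <- labels[train]
    screen <- ttest_screen(powers[train][lab == "ASD"],
                           powers[train][lab == "TD"], alpha = alpha)
    selected <- screen$feature[screen$selected]
    if (length(selected) == 0L)
      selected <- screen$feature[which.min(screen$p)]
  }
  list(features = flat[, selected, drop = FALSE],
       selected = selected, screen = screen)
}
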