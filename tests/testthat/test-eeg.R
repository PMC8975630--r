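fs <- 128

test_that("recording construction validates montage and sampling rate", {
  x <- matrix(rnorm(256), nrow = 2)
  expect_error(eeg_recording(x, fs = 80, channels = c("AF3", "F7")), "fs")
  expect_error(eeg_recording(x, fs = 128, channels = c("AF3", "XX")),
               "montage")
  expect_error(eeg_recording(x, fs = 128, channels = c("AF3", "AF3")),
               "unique")
  rec <- eeg_recording(x, fs = 128, channels = c("AF3", "F7"))
  expect_s3_class(rec, "eeg_recording")
})

test_that("band-pass response attenuates stopband and preserves passband", {
  t <- seq(0, 8 - 1 / fs, by = 1 / fs)
  in50 <- sin(2 * pi * 50 * t)
  out50 <- bandpass_filter(make_rec(in50))$data
  expect_lt(sd(out50) / sd(in50), 0.10)

  in10 <- sin(2 * pi * 10 * t)
  out10 <- bandpass_filter(make_rec(in10))$data
  expect_equal(sd(out10) / sd(in10), 1, tolerance = 0.05)

  # slow drift needs a window long enough to resolve 0.05 from 0.2 Hz
  tl <- seq(0, 40 - 1 / fs, by = 1 / fs)
  drift <- sin(2 * pi * 0.05 * tl)
  outd <- bandpass_filter(make_rec(drift))$data
  expect_lt(sd(outd) / sd(drift), 0.05)

  zero <- bandpass_filter(make_rec(rep(0, 512)))$data
  expect_equal(max(abs(zero)), 0)

  expect_error(bandpass_filter(make_rec(in10), low = 1, high = 70), "high")
})

test_that("epoching counts, rejection, and failure mode are exact", {
  rec <- make_rec(sin(2 * pi * 3 * seq(0, 40 - 1 / fs, by = 1 / fs)))
  eps <- epoch_and_reject(rec, epoch_s = 2, amp_thresh = 100)
  expect_length(eps, 20L)
  expect_equal(attr(eps, "rejected"), integer(0))

  # spike 10x the threshold in epoch 7 only
  x <- rec$data[1, ]
  x[6 * 2 * fs + 5] <- 1000
  eps2 <- epoch_and_reject(make_rec(x), epoch_s = 2, amp_thresh = 100)
  expect_length(eps2, 19L)
  expect_equal(attr(eps2, "rejected"), 7L)

  expect_error(epoch_and_reject(make_rec(rep(500, 512)), 2, 100),
               "unusable")
})

test_that("periodogram band power localizes tones correctly", {
  t <- seq(0, 2 - 1 / fs, by = 1 / fs)
  zero <- matrix(0, 1, length(t), dimnames = list("AF3", NULL))
  for (b in seq_len(nrow(band_definitions()))) {
    bd <- band_definitions()[b, ]
    expect_equal(unname(band_power(zero, fs, bd$low, bd$high)), 0)
  }

  tone5 <- matrix(sin(2 * pi * 5 * t), 1, dimnames = list("AF3", NULL))
  theta <- band_power(tone5, fs, 4, 6)
  total <- band_power(tone5, fs, 0.2, 45)
  expect_gte(theta / total, 0.95)

  two <- matrix(3 * sin(2 * pi * 5 * t) + 2 * sin(2 * pi * 25 * t), 1,
                dimnames = list("AF3", NULL))
  ratio <- band_power(two, fs, 4, 6) / band_power(two, fs, 20, 30)
  expect_equal(unname(ratio), (3 / 2)^2, tolerance = 0.05)

  expect_error(band_power(tone5, fs, 60, 70), "Nyquist")
})

test_that("band powers are nonnegative and bounded by total power", {
  set.seed(31)
  t <- seq(0, 2 - 1 / fs, by = 1 / fs)
  x <- matrix(rnorm(length(t)), 1, dimnames = list("AF3", NULL))
  bands <- band_definitions()
  bp <- vapply(seq_len(nrow(bands)), function(b)
    unname(band_power(x, fs, bands$low[b], bands$high[b])), numeric(1))
  expect_true(all(bp >= 0))
  expect_lte(sum(bp), unname(band_power(x, fs, 0.2, 45)) + 1e-12)
})

test_that("region aggregation is a channel-and-epoch mean", {
  t <- seq(0, 8 - 1 / fs, by = 1 / fs)
  x <- rbind(sin(2 * pi * 5 * t), 0.5 * sin(2 * pi * 5 * t))
  rec <- eeg_recording(x, fs = fs, channels = c("T7", "T8"))
  rm <- list(LT = "T7", RT = "T8")
  m <- region_band_features(rec, region_map = rm, filter_low = NULL)
  # single-channel regions: the region value is that channel's power;
  # halving the amplitude quarters the power
  expect_equal(m["RT", "theta"] / m["LT", "theta"], 0.25,
               tolerance = 1e-6)
  # doubling the signal scales every entry by 4
  rec2 <- eeg_recording(2 * x, fs = fs, channels = c("T7", "T8"))
  m2 <- region_band_features(rec2, region_map = rm, filter_low = NULL)
  expect_equal(m2, 4 * m, tolerance = 1e-10)

  expect_error(region_band_features(rec), "lacks channel")
})

test_that("the t-test screen matches textbook statistics and handles degeneracy", {
  # equal spreads -> Levene F = 0 -> pooled Student t, closed form
  x <- c(1, 2, 3); y <- c(11, 12, 13)
  mk <- function(v) matrix(v, 1, 1, dimnames = list("LF", "theta"))
  sc <- ttest_screen(lapply(x, mk), lapply(y, mk))
  or <- pooled_t_oracle(x, y)
  expect_equal(sc$t, or$t, tolerance = 1e-12)
  expect_equal(sc$p, or$p, tolerance = 1e-12)
  expect_equal(sc$mean_diff, -10)
  expect_false(sc$welch)

  # identical groups -> t = 0, p = 1, not selected
  sc0 <- ttest_screen(lapply(c(1, 2, 3), mk), lapply(c(1, 2, 3), mk))
  expect_equal(sc0$t, 0)
  expect_equal(sc0$p, 1)
  expect_false(sc0$selected)

  # zero variance in both groups, equal means
  scz <- ttest_screen(lapply(c(5, 5), mk), lapply(c(5, 5), mk))
  expect_equal(scz$t, 0)
  expect_equal(scz$p, 1)

  # agreement with independent formulas on random samples, both branches
  set.seed(17)
  for (rep in 1:25) {
    a <- rnorm(sample(5:12, 1), sd = sample(c(1, 4), 1))
    b <- rnorm(sample(5:12, 1))
    sc <- ttest_screen(lapply(a, mk), lapply(b, mk))
    or <- if (sc$welch) welch_t_oracle(a, b) else pooled_t_oracle(a, b)
    expect_equal(sc$t, or$t, tolerance = 1e-8)
    expect_equal(sc$p, or$p, tolerance = 1e-8)
  }
})

test_that("fixed12 panel has the canonical columns in order", {
  set.seed(41)
  co <- generate_cohort(small_spec(1, n_asd = 2, n_td = 2))
  p <- lapply(cohort_eeg(co), region_band_features)
  ef <- eeg_features(p, mode = "fixed12")
  expect_identical(colnames(ef$features),
                   c("LF.theta", "RF.theta", "RT.theta", "P.theta",
                     "O.theta", "P.alpha", "O.alpha", "LF.low_beta",
                     "RF.low_beta", "P.low_beta", "O.low_beta",
                     "LF.gamma"))
  # identical recordings give identical rows
  p2 <- p; p2[[2]] <- p2[[1]]
  ef2 <- eeg_features(p2, mode = "fixed12")
  expect_equal(ef2$features[1, ], ef2$features[2, ])
})

test_that("screened selection uses only training subjects", {
  set.seed(43)
  co <- generate_cohort(cohort_spec(n_asd = 8, n_td = 8, seed = 9,
                                    eeg_duration_s = 8,
                                    theta_gain_asd = 2.5))
  p <- lapply(cohort_eeg(co), region_band_features)
  labels <- cohort_labels(co)
  train <- names(labels)[c(1:6, 9:14)]
  sel1 <- eeg_features(p, "screened", labels = labels, train = train)
  # corrupt the held-out subjects' labels: selection must not move
  labels2 <- labels
  held <- setdiff(names(labels), train)
  labels2[held] <- rev(labels[held])
  sel2 <- eeg_features(p, "screened", labels = labels2, train = train)
  expect_identical(sel1$selected, sel2$selected)
  # the planted theta contrast is what gets picked up
  expect_true(any(grepl("theta", sel1$selected)))
})
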