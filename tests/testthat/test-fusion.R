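make_feats <- function(n, p, shift, ids, seed) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p) + shift
  rownames(x) <- ids
  colnames(x) <- paste0("f", seq_len(p))
  x
}

test_that("confusion matrices are column-normalized percentages", {
  truth <- rep(c("ASD", "TD"), c(40, 40))
  pred <- truth
  pred[1:4] <- "TD"   # 36/40 ASD recovered
  cr <- confusion_report(pred, truth)
  expect_equal(unname(cr$matrix[, "ASD"]), c(90, 10))
  expect_equal(unname(colSums(cr$matrix)), c(100, 100))
  expect_equal(cr$accuracy, 95)
  expect_equal(unname(cr$edges["ASD->TD"]), 10)

  perfect <- confusion_report(truth, truth)
  expect_equal(unname(perfect$matrix), matrix(c(100, 0, 0, 100), 2))
  expect_error(confusion_report(character(0), character(0)), "no predictions")

  g <- confusion_graph(list(eeg = cr, hybrid = perfect))
  expect_equal(nrow(g), 4L)
  expect_equal(g$percent[g$modality == "hybrid"], c(0, 0))
})

test_that("level-1 branches concatenate, train, and flag misalignment", {
  ids <- sprintf("s%02d", 1:20)
  y <- setNames(rep(c("ASD", "TD"), each = 10), ids)
  expr_f <- make_feats(20, 25, rep(c(0, 3), each = 10), ids, 1)
  gaze_f <- make_feats(20, 8, rep(c(0, 3), each = 10), ids, 2)
  for (clf in c("RF", "SVM", "KNN")) {
    d <- level1_behavioral(expr_f, gaze_f, y,
                           fusion_config(base_classifier = clf, seed = 4))
    # perfectly separable features: training-set subdecisions all correct
    expect_equal(as.character(d), unname(y))
  }
  bad <- gaze_f
  rownames(bad)[1] <- "other"
  expect_error(level1_behavioral(expr_f, bad, y), "misaligned|other")

  d1 <- level1_physiological(make_feats(20, 12, rep(c(0, 4), each = 10),
                                        ids, 3), y)
  expect_equal(as.character(d1), unname(y))
})

test_that("decision fusion follows agreement and redundancy exactly", {
  y <- factor(rep(c("ASD", "TD"), each = 10), levels = c("ASD", "TD"))
  # both branches always correct -> fused decisions all correct
  out <- level2_fuse(y, y, y)
  expect_equal(as.character(out$decisions), as.character(y))
  # d2 identical to d1 -> fused accuracy equals the branch accuracy
  d1 <- y
  d1[c(1, 11)] <- rev(d1[c(1, 11)])
  out2 <- level2_fuse(d1, d1, y)
  expect_equal(mean(out2$decisions == y), mean(d1 == y))
})

test_that("fused decisions equal the enumeration oracle on conflicting branches", {
  y <- rep(c("ASD", "TD"), each = 8)
  set.seed(9)
  d1 <- sample(c("ASD", "TD"), 16, replace = TRUE)
  d2 <- sample(c("ASD", "TD"), 16, replace = TRUE)
  out <- level2_fuse(d1, d2, y)
  x <- data.frame(d1 = d1, d2 = d2)
  for (i in seq_along(y)) {
    want <- wnb_oracle_posterior(x, y, x[i, ])
    got <- predict(out$model, x[i, , drop = FALSE], type = "prob")
    expect_equal(as.numeric(got), as.numeric(want), tolerance = 1e-12)
  }
})

test_that("LOOCV yields one held-out prediction per subject, deterministically", {
  co <- generate_cohort(small_spec(21, n_asd = 5, n_td = 5))
  cfg <- fusion_config(base_classifier = "KNN", seed = 2)
  ev <- fusion_loocv(co, cfg, modality = "hybrid")
  expect_equal(nrow(ev$predictions), 10L)
  expect_setequal(ev$predictions$subject, names(co$subjects))
  expect_equal(unname(colSums(ev$confusion$matrix)), c(100, 100))
  ev2 <- fusion_loocv(co, cfg, modality = "hybrid")
  expect_identical(ev, ev2)
  # single-modality path shares the harness
  evg <- fusion_loocv(co, cfg, modality = "expression")
  expect_equal(nrow(evg$predictions), 10L)
})

test_that("screened EEG mode and the RF classifier run inside the harness", {
  co <- generate_cohort(small_spec(26, n_asd = 4, n_td = 4,
                                   theta_gain_asd = 2.5))
  ev <- fusion_loocv(co, fusion_config(base_classifier = "KNN", seed = 1,
                                       eeg_mode = "screened"),
                     modality = "eeg")
  expect_equal(nrow(ev$predictions), 8L)
  ev_rf <- fusion_loocv(co, fusion_config(base_classifier = "RF",
                                          rf_ntree = 50L, seed = 2),
                        modality = "eeg")
  expect_equal(nrow(ev_rf$predictions), 8L)
  expect_identical(ev_rf,
                   fusion_loocv(co, fusion_config(base_classifier = "RF",
                                                  rf_ntree = 50L,
                                                  seed = 2),
                                modality = "eeg"))
})

test_that("a fold whose training set is single-class errors", {
  co <- generate_cohort(small_spec(22, n_asd = 1, n_td = 1))
  expect_error(fusion_loocv(co, fusion_config(base_classifier = "KNN")),
               "single class")
})

test_that("corrupting a held-out label never changes its own prediction", {
  co <- generate_cohort(small_spec(23, n_asd = 5, n_td = 5))
  cfg <- fusion_config(base_classifier = "KNN", seed = 3)
  ev <- fusion_loocv(co, cfg, modality = "hybrid")
  victim <- 3L
  co2 <- co
  co2$subjects[[victim]]$label <-
    ifelse(co2$subjects[[victim]]$label == "ASD", "TD", "ASD")
  ev2 <- fusion_loocv(co2, cfg, modality = "hybrid")
  expect_identical(ev$predictions$predicted[victim],
                   ev2$predictions$predicted[victim])
  expect_identical(ev$predictions$d1[victim], ev2$predictions$d1[victim])
})

test_that("label shuffling drives held-out accuracy to chance", {
  accs <- sapply(1:4, function(s) {
    co <- generate_cohort(null_cohort_spec(seed = 24 + s, n_asd = 6,
                                           n_td = 6))
    labs <- cohort_labels(co)
    set.seed(s)
    shuffled <- sample(labs)
    for (i in seq_along(co$subjects)) co$subjects[[i]]$label <- shuffled[i]
    fusion_loocv(co, fusion_config(base_classifier = "KNN", seed = 5),
                 modality = "eeg")$accuracy
  })
  expect_lte(mean(accs), 70)   # chance is 50%
})

test_that("evaluation reports persist to CSV", {
  co <- generate_cohort(small_spec(25, n_asd = 3, n_td = 3))
  ev <- fusion_loocv(co, fusion_config(base_classifier = "KNN", seed = 1),
                     modality = "gaze")
  stem <- file.path(withr::local_tempdir(), "run")
  write_eval(ev, stem)
  pred <- read.csv(paste0(stem, "_predictions.csv"))
  expect_equal(nrow(pred), 6L)
  cm <- read.csv(paste0(stem, "_confusion.csv"))
  expect_equal(colSums(cm[, c("ASD", "TD")]), c(ASD = 100, TD = 100))
})
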