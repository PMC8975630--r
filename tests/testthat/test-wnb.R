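test_that("weighting coefficients match hand counts on the worked table", {
  # two attributes, so n(m) = 2; d2 is constant and irrelevant to W(d1|.)
  x <- data.frame(d1 = c("ASD", "ASD", "ASD", "TD"),
                  d2 = c("q", "q", "q", "q"))
  y <- c("ASD", "ASD", "TD", "TD")
  fit <- wnb(x, y)
  # n(d1=ASD & ASD) = 2, n(d1=ASD) = 3 -> (2 + 2/3) / 2 = 4/3
  expect_equal(coef(fit)$d1["ASD", "ASD"], 4 / 3)
  # value always co-occurring with one class attains the upper bound
  expect_equal(coef(fit)$d1["TD", "TD"], (2 + 1) / 2)
  # value never observed with a class gets weight exactly 1
  expect_equal(coef(fit)$d1["TD", "ASD"], 1)
})

test_that("posteriors agree with the enumeration oracle on random tables", {
  set.seed(42)
  for (rep in 1:30) {
    n <- sample(4:12, 1)
    n_attr <- sample(2:3, 1)
    x <- as.data.frame(replicate(n_attr,
      sample(c("ASD", "TD"), n, replace = TRUE), simplify = FALSE))
    names(x) <- paste0("d", seq_len(n_attr))
    y <- sample(c("ASD", "TD"), n, replace = TRUE)
    if (length(unique(y)) < 2) y[1:2] <- c("ASD", "TD")
    fit <- wnb(x, y)
    query <- x[sample(n, 1), , drop = FALSE]
    got <- predict(fit, query, type = "prob")
    want <- wnb_oracle_posterior(x, y, query)
    expect_equal(as.numeric(got), as.numeric(want), tolerance = 1e-12)
  }
})

test_that("every weight lies in [1, (n(m)+1)/n(m)]", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(4:15, 1)
    n_attr <- sample(2:4, 1)
    x <- as.data.frame(replicate(n_attr,
      sample(letters[1:3], n, replace = TRUE), simplify = FALSE))
    y <- sample(c("ASD", "TD"), n, replace = TRUE)
    if (length(unique(y)) < 2) y[1:2] <- c("ASD", "TD")
    fit <- wnb(x, y)
    w <- unlist(coef(fit))
    expect_true(all(w >= 1 - 1e-12))
    expect_true(all(w <= (n_attr + 1) / n_attr + 1e-12))
  }
})

test_that("forcing unit weights reproduces standard naive Bayes", {
  # zero-free table so unsmoothed conditionals are well-defined; compared
  # unsmoothed because e1071's `laplace` inflates only the numerator
  combos <- expand.grid(d1 = c("ASD", "TD"), d2 = c("ASD", "TD"),
                        y = c("ASD", "TD"), stringsAsFactors = FALSE)
  reps <- c(3, 1, 2, 2, 1, 2, 2, 4)
  x <- combos[rep(seq_len(8), reps), c("d1", "d2")]
  y <- factor(combos$y[rep(seq_len(8), reps)], levels = c("ASD", "TD"))
  fit <- wnb(x, y, smoothing = 0)
  fit$weights <- lapply(fit$weights, function(m) { m[] <- 1; m })
  ref <- e1071::naiveBayes(x = x, y = y, laplace = 0)
  queries <- unique(x)
  got <- predict(fit, queries, type = "prob")
  want <- predict(ref, queries, type = "raw")
  expect_equal(unname(got[, "ASD"]), unname(want[, "ASD"]),
               tolerance = 1e-10)
})

test_that("posterior is a probability vector and invariant to attribute order", {
  set.seed(3)
  x <- data.frame(d1 = sample(c("ASD", "TD"), 12, replace = TRUE),
                  d2 = sample(c("ASD", "TD"), 12, replace = TRUE))
  y <- c(rep("ASD", 6), rep("TD", 6))
  q <- data.frame(d1 = "ASD", d2 = "TD")
  p12 <- predict(wnb(x, y), q, type = "prob")
  p21 <- predict(wnb(x[, c("d2", "d1")], y), q[, c("d2", "d1")],
                 type = "prob")
  expect_equal(rowSums(p12), 1)
  expect_equal(p12[, c("ASD", "TD")], p21[, c("ASD", "TD")])
})

test_that("duplicating all rows changes neither weights nor conditionals", {
  x <- data.frame(d1 = c("ASD", "ASD", "TD", "TD"),
                  d2 = c("ASD", "TD", "ASD", "TD"))
  y <- c("ASD", "ASD", "TD", "TD")
  f1 <- wnb(x, y, smoothing = 0)
  f2 <- wnb(rbind(x, x), rep(y, 2), smoothing = 0)
  expect_equal(f1$weights, f2$weights)
  expect_equal(f1$conditionals, f2$conditionals)
})

test_that("symmetric tables tie and resolve to ASD by canonical order", {
  x <- data.frame(d1 = c("ASD", "TD"), d2 = c("TD", "ASD"))
  y <- c("ASD", "TD")
  fit <- wnb(x, y)
  q <- data.frame(d1 = "ASD", d2 = "ASD")
  p <- predict(fit, q, type = "prob")
  expect_equal(as.numeric(p), c(0.5, 0.5))
  expect_equal(as.character(predict(fit, q)), "ASD")
})

test_that("degenerate inputs error and unseen values fall back gracefully", {
  expect_error(wnb(data.frame(), character(0)), "empty")
  expect_error(wnb(data.frame(d1 = c("a", "b")), c("ASD", "ASD")),
               "single class")
  fit <- wnb(data.frame(d1 = c("ASD", "ASD", "TD", "TD")),
             c("ASD", "ASD", "TD", "TD"))
  p <- predict(fit, data.frame(d1 = "never_seen"), type = "prob")
  expect_equal(rowSums(p), 1)
  expect_false(anyNA(p))
})

test_that("a fitted model survives a JSON round trip", {
  x <- data.frame(d1 = c("ASD", "ASD", "TD", "TD", "ASD"),
                  d2 = c("TD", "ASD", "ASD", "TD", "ASD"))
  y <- c("ASD", "ASD", "TD", "TD", "TD")
  fit <- wnb(x, y)
  path <- withr::local_tempfile(fileext = ".json")
  write_wnb(fit, path)
  back <- read_wnb(path)
  q <- data.frame(d1 = c("ASD", "TD"), d2 = c("TD", "TD"))
  expect_equal(predict(back, q, type = "prob"),
               predict(fit, q, type = "prob"))
})
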