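#' Attribute-weighted naive Bayes over categorical subdecisions
#'
#' Fits a naive Bayes classifier in which each attribute's conditional
#' probability is multiplied by a data-derived weighting coefficient that
#' reflects how strongly the attribute value co-occurs with the class.
#' For attribute \eqn{d_m}, value \eqn{v} and class \eqn{c_i} the weight is
#' \deqn{W(d_m = v \mid c_i) = \frac{n(m) + n(d_m = v \wedge c_i) / n(d_m = v)}{n(m)},}
#' where \eqn{n(m)} is the number of attributes, \eqn{n(d_m = v \wedge c_i)}
#' the number of training rows with value \eqn{v} and class \eqn{c_i}, and
#' \eqn{n(d_m = v)} the number of training rows with value \eqn{v}. Weights
#' therefore lie in \eqn{[1, (n(m)+1)/n(m)]}: an attribute value never seen
#' with a class contributes weight exactly 1 (no up-weighting), while a value
#' perfectly predictive of the class attains the upper bound. Values unseen
#' in training also receive weight 1.
#'
#' Class priors are the training class frequencies, and conditionals are
#' Laplace-smoothed frequencies with smoothing parameter `smoothing`; the
#' weights are computed from raw (unsmoothed) counts. The posterior score of
#' class \eqn{c_i} for a query \eqn{(d_1, \dots, d_n)} is
#' \deqn{P(c_i)\prod_j P(d_j \mid c_i)\, W(d_j \mid c_i),}
#' normalized over classes (computed in log space).
#'
#' @param x a data.frame (or matrix) of categorical attributes, one row per
#'   training instance; columns are coerced to character. In the fusion
#'   framework these are the per-branch subdecisions.
#' @param y class labels, one per row of `x`; a factor or character vector
#'   with at least two observed classes. If `y` is not a factor its levels
#'   are taken in the order of first appearance with `"ASD"` first when
#'   present.
#' @param smoothing Laplace smoothing parameter \eqn{\lambda \ge 0} applied
#'   to the conditional probability tables (default 1).
#' @param formula a formula of the form `class ~ d1 + d2` (or `class ~ .`).
#' @param data a data.frame holding the formula's variables.
#' @param ... passed between methods.
#'
#' @return An object of class `"wnb"`: a list with elements `priors`
#'   (named numeric), `conditionals` and `weights` (per-attribute
#'   value-by-class matrices), `levels` (class levels), `attributes`
#'   (attribute names), `smoothing`, and `n` (training rows).
#'
#' @examples
#' d <- data.frame(d1 = c("ASD", "ASD", "ASD", "TD"),
#'                 y  = c("ASD", "ASD", "TD", "TD"))
#' fit <- wnb(d["d1"], d$y)
#' coef(fit)$d1          # W(d1 = ASD | ASD) is (2 + 2/3)/2 = 4/3
#' predict(fit, data.frame(d1 = "ASD"), type = "prob")
#' @seealso [predict.wnb()], [level2_fuse()]
#' @export
wnb <- function(x, ...) UseMethod("wnb")

#' @rdname wnb
#' @export
wnb.formula <- function(formula, data, smoothing = 1, ...) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  x <- mf[, -1L, drop = FALSE]
  out <- wnb.default(x, y, smoothing = smoothing)
  out$call <- match.call()
  out
}

#' @rdname wnb
#' @export
wnb.default <- function(x, y, smoothing = 1, ...) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (nrow(x) == 0L || ncol(x) == 0L)
    stop("decision table is empty", call. = FALSE)
  if (length(y) != nrow(x))
    stop("`y` must have one label per row of `x`", call. = FALSE)
  check_that(is.numeric(smoothing) && length(smoothing) == 1L && smoothing >= 0,
             "smoothing", "must be a single nonnegative number")
  if (!is.factor(y)) {
    lev <- unique(as.character(y))
    lev <- c(intersect(CLASSES, lev), setdiff(lev, CLASSES))
    y <- factor(as.character(y), levels = lev)
  }
  y <- droplevels(y)
  classes <- levels(y)
  if (length(classes) < 2L)
    stop("training labels contain a single class; need at least two",
         call. = FALSE)

  n_m <- ncol(x)   # n(m): number of attributes (decisions)
  n_c <- as.numeric(table(y))
  priors <- stats::setNames(n_c / length(y), classes)

  conditionals <- list()
  weights <- list()
  for (m in names(x)) {
    v <- as.character(x[[m]])
    vals <- sort(unique(v))
    counts <- table(factor(v, levels = vals), y)   # values x classes, raw
    # Laplace-smoothed conditionals: columns sum to 1
    cond <- sweep(counts + smoothing, 2,
                  colSums(counts) + smoothing * length(vals), "/")
    # weights from raw counts; W = 1 when n(d_m = v) = 0 cannot
    # arise here (every value was observed), but joint count 0 gives ratio 0
    n_v <- rowSums(counts)
    ratio <- sweep(counts, 1, ifelse(n_v == 0, 1, n_v), "/")
    w <- (n_m + ratio) / n_m
    cond <- as.matrix(unclass(cond))
    w <- as.matrix(unclass(w))
    names(dimnames(cond)) <- names(dimnames(w)) <- NULL
    conditionals[[m]] <- cond
    weights[[m]] <- w
  }

  structure(list(priors = priors,
                 conditionals = conditionals,
                 weights = weights,
                 levels = classes,
                 attributes = names(x),
                 smoothing = smoothing,
                 n = nrow(x),
                 call = match.call()),
            class = "wnb")
}

#' Posterior probabilities and class predictions from a weighted naive Bayes
#'
#' @param object a fitted [wnb()] model.
#' @param newdata a data.frame of attributes matching the training columns;
#'   extra columns are ignored. Attribute values unseen in training fall back
#'   to the smoothed zero-count conditional with weight 1.
#' @param type `"class"` for predicted labels (default) or `"prob"` for the
#'   normalized posterior matrix (rows sum to 1).
#' @param ... ignored.
#'
#' @details Prediction is the posterior argmax. An exact posterior tie is
#'   broken toward the class with the larger prior, and a remaining tie
#'   toward the first class in the model's level order (ASD when present).
#' @return A factor of predicted classes, or an `n x classes` matrix of
#'   posterior probabilities.
#' @export
predict.wnb <- function(object, newdata,
                        type = c("class", "prob"), ...) {
  type <- match.arg(type)
  newdata <- as.data.frame(newdata, stringsAsFactors = FALSE)
  missing_attr <- setdiff(object$attributes, names(newdata))
  if (length(missing_attr))
    stop("newdata lacks attribute(s): ", paste(missing_attr, collapse = ", "),
         call. = FALSE)
  classes <- object$levels
  n <- nrow(newdata)
  logscore <- matrix(rep(log(object$priors), each = n), nrow = n,
                     dimnames = list(NULL, classes))
  for (m in object$attributes) {
    cond <- object$conditionals[[m]]
    w <- object$weights[[m]]
    v <- as.character(newdata[[m]])
    known <- v %in% rownames(cond)
    for (ci in classes) {
      contrib <- numeric(n)
      contrib[known] <- log(cond[v[known], ci]) + log(w[v[known], ci])
      if (any(!known)) {
        # unseen value: smoothed zero-count conditional, weight 1
        lam <- object$smoothing
        if (lam == 0) lam <- 1   # guard: unsmoothed model, unseen value
        n_ci <- object$priors[[ci]] * object$n
        contrib[!known] <- log(lam / (n_ci + lam * nrow(cond)))
      }
      logscore[, ci] <- logscore[, ci] + contrib
    }
  }
  post <- exp(logscore - apply(logscore, 1, max))
  post <- post / rowSums(post)
  if (type == "prob") return(post)
  pick <- function(p) {
    top <- which(p >= max(p) - 1e-12)
    if (length(top) > 1L) {
      pr <- object$priors[top]
      top <- top[pr >= max(pr) - 1e-12]
    }
    top[1L]
  }
  factor(classes[apply(post, 1, pick)], levels = classes)
}

#' @export
print.wnb <- function(x, ...) {
  cat("Attribute-weighted naive Bayes\n")
  cat(sprintf("  %d training rows, %d attribute(s): %s\n", x$n,
              length(x$attributes), paste(x$attributes, collapse = ", ")))
  cat("  priors:", paste(sprintf("%s = %.3f", names(x$priors), x$priors),
                         collapse = ", "), "\n")
  cat(sprintf("  weight bound: [1, %.4f]\n",
              (length(x$attributes) + 1) / length(x$attributes)))
  invisible(x)
}

#' @export
#' @describeIn wnb returns the per-attribute weighting-coefficient matrices.
coef.wnb <- function(object, ...) object$weights

#' Read or write a fitted weighted naive Bayes model as JSON
#'
#' @param object a fitted [wnb()] model.
#' @param path file path.
#' @return `write_wnb` returns `path` invisibly; `read_wnb` a `"wnb"` object.
#' @export
write_wnb <- function(object, path) {
  stopifnot(inherits(object, "wnb"))
  tab <- function(m) list(values = rownames(m),
                          classes = colnames(m),
                          rows = unname(apply(m, 1, as.numeric,
                                              simplify = FALSE)))
  x <- list(priors = as.list(object$priors),
            conditionals = lapply(object$conditionals, tab),
            weights = lapply(object$weights, tab),
            levels = object$levels,
            attributes = object$attributes,
            smoothing = object$smoothing,
            n = object$n)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_wnb
#' @export
read_wnb <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  untab <- function(t) {
    rows <- t$rows
    if (is.list(rows)) rows <- do.call(rbind, lapply(rows, as.numeric))
    m <- as.matrix(rows)
    dimnames(m) <- list(t$values, t$classes)
    m
  }
  structure(list(priors = unlist(x$priors),
                 conditionals = lapply(x$conditionals, untab),
                 weights = lapply(x$weights, untab),
                 levels = x$levels,
                 attributes = x$attributes,
                 smoothing = x$smoothing,
                 n = x$n,
                 call = NULL),
            class = "wnb")
}
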