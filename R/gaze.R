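#' K-means clustering of fixation points into areas of interest
#'
#' Clusters pooled 2-D eye-fixation coordinates into `K` areas of interest
#' (AOIs) with Lloyd's algorithm, minimizing the within-cluster sum of
#' squared distances
#' \deqn{J = \sum_{n=1}^N \sum_{k=1}^K r_{nk} \lVert x_n - \mu_k \rVert^2,}
#' where \eqn{r_{nk}} assigns each fixation point to exactly one cluster and
#' \eqn{\mu_k} is the cluster center. Assignment (nearest center) and update
#' (cluster mean) steps alternate until the centers move less than `tol` or
#' `max_iter` is reached; the best of `n_init` k-means++-seeded restarts by
#' final loss is returned.
#'
#' After Lloyd converges, each restart is polished by first-variation
#' (Hartigan-style) single-point reassignments — accepted only while they
#' strictly lower J — which escapes the assignment-stable local minima
#' Lloyd cannot leave on small point sets; the polished loss is still
#' non-increasing over the run.
#'
#' Deterministic conventions: points equidistant to several centers go to
#' the lowest cluster index; a cluster emptied during iteration is reseeded
#' at the point currently farthest from its assigned center; all randomness
#' derives from `seed`.
#'
#' @param points a numeric matrix or data.frame with two columns (x, y
#'   screen coordinates in pixels); at least `K` distinct rows.
#' @param K number of areas of interest (clusters), \eqn{\ge 1}.
#' @param seed integer seed controlling the restarts.
#' @param n_init number of seeded restarts (default 10).
#' @param max_iter iteration cap per restart (default 100).
#' @param tol convergence threshold on the largest center displacement
#'   (default 1e-8, in the units of `points`).
#'
#' @return An object of class `"aoi_kmeans"`: list with `centers` (K x 2
#'   matrix), `assignments` (cluster index per input point), `loss` (final
#'   J), `loss_trace` (J after each assignment step of the winning restart),
#'   `n_iter`, `converged`, `K`, `seed`.
#' @examples
#' pts <- rbind(matrix(rnorm(40, 100), ncol = 2),
#'              matrix(rnorm(40, 400), ncol = 2))
#' fit <- aoi_kmeans(pts, K = 2, seed = 1)
#' fit$loss
#' @seealso [aoi_frequencies()], [gaze_features()]
#' @export
aoi_kmeans <- function(points, K, seed = 1L, n_init = 10L,
                       max_iter = 100L, tol = 1e-8) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (nrow(points) == 0L) stop("no fixation points supplied", call. = FALSE)
  if (ncol(points) != 2L) stop("`points` must have two columns (x, y)",
                               call. = FALSE)
  if (!all(is.finite(points))) stop("fixation coordinates must be finite",
                                    call. = FALSE)
  check_that(is_count(K), "K", "must be a positive integer")
  check_that(is_count(n_init), "n_init", "must be a positive integer")
  check_that(is_count(max_iter), "max_iter", "must be a positive integer")
  check_that(is.numeric(tol) && tol >= 0, "tol", "must be nonnegative")
  n_distinct <- nrow(unique(points))
  if (K > n_distinct)
    stop(sprintf("K = %d exceeds the number of distinct points (%d)",
                 K, n_distinct), call. = FALSE)

  best <- NULL
  for (r in seq_len(n_init)) {
    run <- with_seed(child_seed(seed, r),
                     lloyd_once(points, K, max_iter, tol))
    if (is.null(best) || run$loss < best$loss) best <- run
  }
  structure(c(best, list(K = K, seed = seed)), class = "aoi_kmeans")
}

# Squared Euclidean distances from every point to every center
sqdist_to_centers <- function(points, centers) {
  outer(rowSums(points^2), rep(1, nrow(centers))) +
    outer(rep(1, nrow(points)), rowSums(centers^2)) -
    2 * points %*% t(centers)
}

# Nearest-center assignment; ties to the lowest cluster index
assign_nearest <- function(points, centers) {
  d2 <- sqdist_to_centers(points, centers)
  max.col(-d2, ties.method = "first")
}

# k-means++ seeding: first center uniform, then proportional to squared
# distance from the nearest chosen center
kmeanspp_centers <- function(points, K) {
  n <- nrow(points)
  centers <- matrix(NA_real_, K, 2)
  centers[1, ] <- points[sample.int(n, 1L), ]
  if (K > 1L) {
    d2 <- rowSums((points - rep(centers[1, ], each = n))^2)
    for (k in 2:K) {
      prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      centers[k, ] <- points[sample.int(n, 1L, prob = prob), ]
      d2 <- pmin(d2, rowSums((points - rep(centers[k, ], each = n))^2))
    }
  }
  centers
}

lloyd_once <- function(points, K, max_iter, tol) {
  centers <- kmeanspp_centers(points, K)
  loss_trace <- numeric(0)
  assign <- rep(1L, nrow(points))
  converged <- FALSE
  iter <- 0L
  pts2 <- rowSums(points^2)
  for (iter in seq_len(max_iter)) {
    d2 <- pts2 - 2 * points %*% t(centers)
    d2 <- sweep(d2, 2, rowSums(centers^2), "+")
    assign <- max.col(-d2, ties.method = "first")
    point_d2 <- d2[cbind(seq_len(nrow(points)), assign)]
    # empty clusters: reseed at the currently worst-fit point
    for (k in which(tabulate(assign, K) == 0L)) {
      far <- which.max(point_d2)
      centers[k, ] <- points[far, ]
      assign[far] <- k
      point_d2[far] <- 0
    }
    loss_trace <- c(loss_trace, sum(point_d2))
    new_centers <- centers
    for (k in seq_len(K)) {
      members <- assign == k
      if (any(members)) new_centers[k, ] <- colMeans(points[members, ,
                                                            drop = FALSE])
    }
    shift <- sqrt(max(rowSums((new_centers - centers)^2)))
    centers <- new_centers
    if (shift <= tol) { converged <- TRUE; break }
  }
  # final loss under the updated centers
  d2 <- sweep(pts2 - 2 * points %*% t(centers), 2, rowSums(centers^2), "+")
  assign <- max.col(-d2, ties.method = "first")
  loss <- sum(d2[cbind(seq_len(nrow(points)), assign)])
  loss_trace <- c(loss_trace, loss)
  ref <- hartigan_polish(points, pts2, assign, K, loss)
  list(centers = ref$centers, assignments = ref$assign, loss = ref$loss,
       loss_trace = c(loss_trace, ref$trace), n_iter = iter,
       converged = converged)
}

# First-variation polish after Lloyd convergence: repeatedly apply the
# single best point reassignment while it strictly lowers J, using the
# exact size-corrected deltas (moving x from cluster a, size n_a, to b,
# size n_b, changes J by n_b/(n_b+1)|x-mu_b|^2 - n_a/(n_a-1)|x-mu_a|^2).
# Escapes assignment-stable local minima that Lloyd cannot leave; J is
# strictly decreasing over accepted moves.
hartigan_polish <- function(points, pts2, assign, K, loss,
                            max_moves = 100L) {
  n <- nrow(points)
  sizes <- tabulate(assign, K)
  sums <- matrix(0, K, ncol(points))
  agg <- rowsum(points, assign)
  sums[as.integer(rownames(agg)), ] <- agg
  trace <- numeric(0)
  centers <- sums / pmax(sizes, 1)
  d2 <- sweep(pts2 - 2 * points %*% t(centers), 2, rowSums(centers^2), "+")
  d2[d2 < 0] <- 0
  col_d2 <- function(k) {
    mu <- sums[k, ] / max(sizes[k], 1)
    pmax(pts2 - 2 * drop(points %*% mu) + sum(mu^2), 0)
  }
  for (mv in seq_len(max_moves)) {
    own <- cbind(seq_len(n), assign)
    gain <- sizes[assign] / pmax(sizes[assign] - 1, 1) * d2[own]
    gain[sizes[assign] == 1L] <- -Inf   # never empty a cluster
    cost <- sweep(d2, 2, sizes / (sizes + 1), "*")
    cost[own] <- Inf
    best_k <- max.col(-cost, ties.method = "first")
    delta <- cost[cbind(seq_len(n), best_k)] - gain
    i <- which.min(delta)
    # stop on negligible relative improvement (large diffuse clouds where
    # single-point moves only shave noise-level amounts off J)
    if (delta[i] >= -1e-6 * max(loss, .Machine$double.eps)) break
    from <- assign[i]; to <- best_k[i]
    sums[from, ] <- sums[from, ] - points[i, ]
    sums[to, ] <- sums[to, ] + points[i, ]
    sizes[from] <- sizes[from] - 1L
    sizes[to] <- sizes[to] + 1L
    assign[i] <- to
    loss <- loss + delta[i]
    trace <- c(trace, loss)
    d2[, from] <- col_d2(from)
    d2[, to] <- col_d2(to)
  }
  centers <- sums / sizes
  d2 <- sweep(pts2 - 2 * points %*% t(centers), 2, rowSums(centers^2), "+")
  loss <- sum(d2[cbind(seq_len(n), assign)])
  list(centers = centers, assign = assign, loss = loss, trace = trace)
}

#' @export
print.aoi_kmeans <- function(x, ...) {
  cat(sprintf("AOI K-means: K = %d, N = %d points, J = %.4g (%s in %d iter)\n",
              x$K, length(x$assignments), x$loss,
              if (x$converged) "converged" else "iteration cap", x$n_iter))
  invisible(x)
}

#' @describeIn aoi_kmeans assigns new fixation points to the fitted AOIs
#'   (nearest center; ties to the lowest index).
#' @param object a fitted `"aoi_kmeans"` model.
#' @param newdata matrix or data.frame of fixation points.
#' @param ... ignored.
#' @export
predict.aoi_kmeans <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  storage.mode(newdata) <- "double"
  if (nrow(newdata) == 0L) stop("no fixation points supplied", call. = FALSE)
  assign_nearest(newdata, object$centers)
}

#' AOI distribution frequencies for one subject
#'
#' Assigns a subject's fixation points to the fitted areas of interest and
#' returns the fraction of the subject's points falling in each AOI: the
#' count of points in region k divided by the subject's total point count.
#' The result is a probability vector over the K AOIs (components sum to 1).
#'
#' @param model a fitted [aoi_kmeans()] AOI model.
#' @param points the subject's fixation points (matrix or data.frame with
#'   columns x, y); at least one point.
#' @return Numeric vector of length `model$K` summing to 1.
#' @examples
#' fit <- aoi_kmeans(cbind(c(0, 0, 10, 10), c(0, 1, 10, 11)), K = 2, seed = 1)
#' aoi_frequencies(fit, cbind(c(0, 10, 10), c(0, 10, 11)))
#' @export
aoi_frequencies <- function(model, points) {
  if (!inherits(model, "aoi_kmeans"))
    stop("`model` must be a fitted aoi_kmeans object", call. = FALSE)
  idx <- predict(model, points)
  tabulate(idx, model$K) / length(idx)
}

#' Per-subject AOI frequency feature matrix
#'
#' Fits the AOI model on pooled *training* fixation points only and returns
#' the AOI distribution-frequency row for every subject in `fixations`
#' (training and held-out alike are projected onto the trained centers), so
#' the function can be used directly inside a cross-validation fold.
#'
#' @param fixations a named list of per-subject fixation point matrices
#'   (columns x, y).
#' @param K number of areas of interest; the study grid is 8, 12, 16, 20.
#' @param seed integer seed for the K-means restarts.
#' @param train subject names (or indices) whose points are pooled for
#'   clustering; defaults to all subjects.
#' @param model optionally, an already fitted [aoi_kmeans()] model to
#'   project onto (then `K`, `seed`, `train` are ignored).
#' @return A list with `features` (subjects x K matrix, rows sum to 1, row
#'   names = subject names) and `model` (the fitted `"aoi_kmeans"`).
#' @export
gaze_features <- function(fixations, K = 8L, seed = 1L, train = NULL,
                          model = NULL) {
  stopifnot(is.list(fixations), length(fixations) >= 1L)
  if (is.null(names(fixations)))
    names(fixations) <- paste0("S", seq_along(fixations))
  if (is.null(model)) {
    if (is.null(train)) train <- names(fixations)
    if (is.numeric(train)) train <- names(fixations)[train]
    pooled <- do.call(rbind, lapply(fixations[train], as.matrix))
    model <- aoi_kmeans(pooled, K = K, seed = seed)
  }
  feat <- t(vapply(fixations, function(p) aoi_frequencies(model, p),
                   numeric(model$K)))
  colnames(feat) <- paste0("aoi", seq_len(model$K))
  list(features = feat, model = model)
}
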