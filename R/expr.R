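#' Count target-expression frames in consecutive windows
#'
#' The stimulus defines a target expression; the behavioral imitation
#' feature is the number of frames on which the child shows that expression
#' within each consecutive block of `window` video frames. Trailing frames
#' that do not fill a complete window are dropped, keeping every count on a
#' common \eqn{[0, \mathrm{window}]} scale.
#'
#' @param labels character (or factor) vector of per-frame expression
#'   labels, one per video frame, in frame order. Any upstream
#'   frame labeler can produce these; see [frame_labeler()].
#' @param target the target expression label to count.
#' @param window frames per window (default 40).
#' @return Integer vector of length `floor(length(labels) / window)`; entry
#'   w counts target frames among frames `[(w-1)*window + 1, w*window]`.
#' @examples
#' count_target_frames(rep(c("happy", "neutral"), 60), "happy", window = 40)
#' @export
count_target_frames <- function(labels, target, window = 40L) {
  labels <- as.character(labels)
  if (length(labels) == 0L) stop("expression track is empty", call. = FALSE)
  check_that(is_count(window), "window", "must be a positive integer")
  check_that(is.character(target) && length(target) == 1L,
             "target", "must be a single label")
  n_win <- length(labels) %/% window
  if (n_win == 0L)
    stop(sprintf("track has %d frames, fewer than one %d-frame window",
                 length(labels), window), call. = FALSE)
  kept <- labels[seq_len(n_win * window)]
  hit <- as.integer(kept == target)
  as.integer(colSums(matrix(hit, nrow = window)))
}

#' Windowed expression-count feature matrix for a cohort
#'
#' Applies [count_target_frames()] to every subject's frame-label track.
#' Tracks of unequal length are truncated to the shortest full-window
#' length (with a warning); a track shorter than one window is an error
#' naming the subject.
#'
#' @param tracks named list of per-frame label vectors, one per subject.
#' @param target the target expression label.
#' @param window frames per window (default 40).
#' @return Integer matrix, one row per subject (row names = subject names),
#'   one column per retained window (`w1`, `w2`, ...).
#' @export
expr_features <- function(tracks, target, window = 40L) {
  stopifnot(is.list(tracks), length(tracks) >= 1L)
  if (is.null(names(tracks))) names(tracks) <- paste0("S", seq_along(tracks))
  len <- vapply(tracks, length, integer(1))
  short <- names(tracks)[len < window]
  if (length(short))
    stop("track(s) shorter than one window: ",
         paste(short, collapse = ", "), call. = FALSE)
  n_win <- min(len) %/% window
  if (any(len %/% window != n_win))
    warning(sprintf("tracks differ in length; truncating all to %d windows",
                    n_win))
  feat <- t(vapply(tracks, function(tr)
    count_target_frames(tr[seq_len(n_win * window)], target, window),
    integer(n_win)))
  colnames(feat) <- paste0("w", seq_len(n_win))
  feat
}

#' Pluggable frame-labeler interface
#'
#' The pipeline's contract starts at per-frame categorical expression
#' labels; how those labels are produced (e.g. a facial-expression
#' recognition model applied to video) is upstream of this package. A frame
#' labeler is any function mapping one subject's raw recording to a
#' character vector of per-frame labels. `frame_labeler()` wraps such a
#' function with its label vocabulary so it can be validated and applied
#' uniformly; `identity_labeler` passes through tracks that are already
#' label vectors (the default for synthetic cohorts).
#'
#' @param fun function(recording) -> character vector of frame labels.
#' @param labels the finite label vocabulary `fun` may emit.
#' @return An object of class `"frame_labeler"`.
#' @examples
#' lab <- frame_labeler(function(x) rep("happy", 10), labels = "happy")
#' apply_labeler(lab, NULL)
#' @export
frame_labeler <- function(fun, labels) {
  stopifnot(is.function(fun), is.character(labels), length(labels) >= 1L)
  structure(list(fun = fun, labels = labels), class = "frame_labeler")
}

#' @rdname frame_labeler
#' @param labeler a `"frame_labeler"`.
#' @param recording the subject's raw recording, passed to the labeler.
#' @export
apply_labeler <- function(labeler, recording) {
  stopifnot(inherits(labeler, "frame_labeler"))
  out <- as.character(labeler$fun(recording))
  bad <- setdiff(unique(out), labeler$labels)
  if (length(bad))
    stop("labeler emitted labels outside its vocabulary: ",
         paste(bad, collapse = ", "), call. = FALSE)
  out
}

#' @rdname frame_labeler
#' @export
identity_labeler <- function(labels) {
  frame_labeler(function(x) as.character(x), labels = labels)
}
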