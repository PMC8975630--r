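# Internal helpers shared across modules.

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Derive a child seed from a base seed and a stream index, staying in
#' 32-bit integer range
#' @noRd
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %%
               .Machine$integer.max)
}

#' Stop with the offending argument named, in the style of base R checks
#' @noRd
check_that <- function(ok, field, msg) {
  if (!isTRUE(ok)) stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
  invisible(TRUE)
}

is_count <- function(x, min = 1L) {
  length(x) == 1L && is.finite(x) && x >= min && x == as.integer(x)
}

is_prob <- function(x) length(x) == 1L && is.finite(x) && x >= 0 && x <= 1

#' Canonical diagnosis classes, ASD first
#' @noRd
CLASSES <- c("ASD", "TD")

#' The 14-channel Emotiv montage in its conventional order
#' @noRd
EMOTIV_CHANNELS <- c("AF3", "F7", "F3", "FC5", "T7", "P7", "O1",
                     "O2", "P8", "T8", "FC6", "F4", "F8", "AF4")
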