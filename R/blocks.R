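#' Time-block average with block-spread error estimate
#'
#' Splits a per-frame observable series into `n_blocks` contiguous blocks of
#' equal frame count (remainder frames at the end are dropped), averages
#' within each block, and reports the grand mean with the standard deviation
#' over block means as the error estimate.
#'
#' @param values Numeric per-frame series, in time order.
#' @param n_blocks Number of contiguous blocks (default 5).
#' @param frame_dt Optional time per frame (ps); if given, `block_length`
#'   (ps) is recorded.
#' @return Object of class `block_average`: `n_blocks`, `block_means`,
#'   `grand_mean`, `sd` (NA when `n_blocks < 2`), `n_frames_used`,
#'   `n_frames_dropped`, `block_length`.
#' @export
block_average <- function(values, n_blocks = 5L, frame_dt = NULL) {
  stopifnot(n_blocks >= 1L)
  n <- length(values)
  per <- n %/% n_blocks
  if (per < 1L) {
    stop("fewer frames (", n, ") than blocks (", n_blocks, ")", call. = FALSE)
  }
  used <- per * n_blocks
  idx <- rep(seq_len(n_blocks), each = per)
  means <- vapply(split(values[seq_len(used)], idx), mean, numeric(1))
  structure(list(
    n_blocks = as.integer(n_blocks),
    block_means = unname(means),
    grand_mean = mean(means),
    sd = if (n_blocks >= 2L) stats::sd(means) else NA_real_,
    n_frames_used = used,
    n_frames_dropped = n - used,
    block_length = if (is.null(frame_dt)) NA_real_ else per * frame_dt
  ), class = "block_average")
}

#' @export
print.block_average <- function(x, ...) {
  cat(sprintf("block average: %.4g +/- %.2g (%d blocks", x$grand_mean,
              x$sd, x$n_blocks))
  if (!is.na(x$block_length)) cat(sprintf(", %g ps each", x$block_length))
  cat(")\n")
  invisible(x)
}

#' @export
format.block_average <- function(x, digits = 3, ...) {
  sprintf("%s +/- %s", signif(x$grand_mean, digits), signif(x$sd, 2))
}
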