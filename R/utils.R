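#' @keywords internal
"_PACKAGE"

#' @importFrom stats approx coef fft median p.adjust
#'   pnorm rlnorm rnorm runif sd wilcox.test filter
#' @importFrom utils head tail write.table read.delim
#' @importFrom graphics abline lines polygon
#' @importFrom methods as
NULL

# classed error helper so callers can condition on failure modes
stop_hfb <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "hfbdeconv_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

#' Derive a per-stage seed from a global seed
#'
#' Keeps all randomness in a multi-stage run reproducible from a single
#' integer while giving each stage an independent stream.
#'
#' @param seed integer global seed (< 2^31).
#' @param stage integer stage index.
#' @return an integer seed below 2^31.
#' @export
derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) + 1000003 * as.numeric(stage)) %% 2147483647L)
}

# moving-average smoother with edge padding, width in samples (odd)
smooth_ma <- function(x, width) {
  if (width <= 1) return(x)
  width <- as.integer(width)
  if (width %% 2L == 0L) width <- width + 1L
  half <- (width - 1L) %/% 2L
  xp <- c(rep(x[1], half), x, rep(x[length(x)], half))
  as.numeric(stats::filter(xp, rep(1 / width, width), sides = 2))[
    (half + 1L):(half + length(x))
  ]
}

# intervals (n x 2 matrix, seconds) -> logical index vector on a sampling grid
intervals_to_index <- function(intervals, n_time, rate) {
  idx <- logical(n_time)
  if (is.null(intervals) || nrow(intervals) == 0) return(idx)
  for (i in seq_len(nrow(intervals))) {
    a <- max(1L, floor(intervals[i, 1] * rate) + 1L)
    b <- min(n_time, ceiling(intervals[i, 2] * rate))
    if (b >= a) idx[a:b] <- TRUE
  }
  idx
}
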