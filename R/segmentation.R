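# Isodata (Ridler-Calvard) automatic thresholding on the 256-bin intensity
# histogram, with stain-dense (dark) pixels as foreground.

#' Intensity histogram of an 8-bit channel
#'
#' @param channel Integer matrix with values in `[0, 255]`.
#' @return Object of class `histogram256`: list with `counts` (256 integers,
#'   `counts[v + 1]` = number of pixels of value `v`) and `total`.
#' @export
intensity_histogram <- function(channel) {
  if (length(channel) == 0L) {
    stop_chromaseg("cannot histogram an empty channel", "chromaseg_argument_error")
  }
  stopifnot(min(channel) >= 0, max(channel) <= 255)
  counts <- tabulate(as.integer(channel) + 1L, nbins = 256L)
  structure(list(counts = counts, total = sum(counts)), class = "histogram256")
}

as_counts256 <- function(hist) {
  counts <- if (inherits(hist, "histogram256")) hist$counts else hist
  stopifnot(is.numeric(counts), length(counts) == 256L, all(counts >= 0))
  counts
}

#' Isodata (Ridler-Calvard) automatic threshold
#'
#' Starting from the global mean intensity, iterates
#' `T <- floor((mu_low(T) + mu_high(T)) / 2)` where `mu_low` is the mean of
#' values `<= T` and `mu_high` the mean of values `> T`, until `T` is a
#' fixed point. Both class means are non-decreasing in `T`, so the iteration
#' is monotone after the first step and terminates; a 256-iteration cap with
#' a warning guards the invariant.
#'
#' Values equal to the threshold belong to the low (foreground) class, both
#' here and in [binarize_dark()].
#'
#' @param hist A `histogram256` or a plain 256-vector of counts.
#' @return Integer threshold in `[0, 255]`.
#' @examples
#' h <- integer(256); h[51] <- 100; h[201] <- 100  # spikes at 50 and 200
#' stopifnot(isodata_threshold(h) == 125)
#' @export
isodata_threshold <- function(hist) {
  counts <- as_counts256(hist)
  if (sum(counts > 0) < 2L) {
    stop_chromaseg(
      "degenerate histogram: a single occupied intensity cannot be segmented",
      "chromaseg_degenerate_histogram")
  }
  counts <- as.numeric(counts)  # avoid integer overflow in cumulative sums
  v <- 0:255
  wsum <- cumsum(v * counts)
  csum <- cumsum(counts)
  tot_w <- wsum[256L]
  tot_n <- csum[256L]
  tt <- as.integer(tot_w %/% tot_n)          # floor of the global mean
  for (k in seq_len(256L)) {
    n_lo <- csum[tt + 1L]
    mu_lo <- wsum[tt + 1L] / n_lo
    mu_hi <- (tot_w - wsum[tt + 1L]) / (tot_n - n_lo)
    tn <- as.integer((mu_lo + mu_hi) %/% 2)
    if (tn == tt) return(tt)
    tt <- tn
  }
  warning("isodata iteration cap reached; returning current threshold")
  tt
}

#' Binarize a channel, dark pixels as foreground
#'
#' Foreground iff `value <= threshold`: chromatin-rich regions are
#' stain-dense and therefore dark in the haematoxylin (or grayscale)
#' channel.
#'
#' @param channel Integer matrix in `[0, 255]`.
#' @param threshold Integer in `[0, 255]`.
#' @return Logical matrix, `TRUE` = foreground.
#' @export
binarize_dark <- function(channel, threshold) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            threshold >= 0, threshold <= 255)
  m <- channel <= threshold
  attr(m, "label") <- NULL
  m
}
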