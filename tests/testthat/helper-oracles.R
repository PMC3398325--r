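# Independent first-principles oracles used to cross-check the vectorised
# implementations. Deliberately written as plain set/loop constructions that
# share no code with the package internals.

# Dilation/erosion with a square structuring element, as explicit offset
# loops. Outside pixels: background for dilation, foreground for erosion.
oracle_dilate <- function(mask, k) {
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(FALSE, h, w)
  for (dy in -k:k) for (dx in -k:k) {
    ys <- max(1, 1 - dy):min(h, h - dy)
    xs <- max(1, 1 - dx):min(w, w - dx)
    out[ys, xs] <- out[ys, xs] | mask[ys + dy, xs + dx]
  }
  out
}

oracle_erode <- function(mask, k) {
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(TRUE, h, w)
  for (dy in -k:k) for (dx in -k:k) {
    ys <- max(1, 1 - dy):min(h, h - dy)
    xs <- max(1, 1 - dx):min(w, w - dx)
    out[ys, xs] <- out[ys, xs] & mask[ys + dy, xs + dx]
  }
  out
}

oracle_close <- function(mask, k, iterations = 1) {
  m <- mask
  for (i in seq_len(iterations)) m <- oracle_dilate(m, k)
  for (i in seq_len(iterations)) m <- oracle_erode(m, k)
  m
}

# Connected-component labeling by breadth-first flood fill.
oracle_label <- function(mask, connectivity = 8) {
  h <- nrow(mask); w <- ncol(mask)
  offs <- if (connectivity == 8) {
    cbind(dy = c(-1, -1, -1, 0, 0, 1, 1, 1), dx = c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(dy = c(-1, 0, 0, 1), dx = c(0, -1, 1, 0))
  }
  lab <- matrix(0L, h, w)
  nextlab <- 0L
  for (y in seq_len(h)) for (x in seq_len(w)) {
    if (!mask[y, x] || lab[y, x] > 0L) next
    nextlab <- nextlab + 1L
    queue <- matrix(c(y, x), ncol = 2)
    lab[y, x] <- nextlab
    while (nrow(queue) > 0) {
      cur <- queue[1, , drop = FALSE]
      queue <- queue[-1, , drop = FALSE]
      for (k in seq_len(nrow(offs))) {
        ny <- cur[1] + offs[k, 1]; nx <- cur[2] + offs[k, 2]
        if (ny >= 1 && ny <= h && nx >= 1 && nx <= w &&
            mask[ny, nx] && lab[ny, nx] == 0L) {
          lab[ny, nx] <- nextlab
          queue <- rbind(queue, c(ny, nx))
        }
      }
    }
  }
  areas <- if (nextlab > 0) tabulate(lab[lab > 0], nbins = nextlab) else integer(0)
  list(label_map = lab, areas = areas, count = nextlab)
}

# Exhaustive isodata fixed-point scan: every T in [0, 254] with both classes
# non-empty and floor((mu_low + mu_high) / 2) == T.
oracle_isodata_fixed_points <- function(counts) {
  counts <- as.numeric(counts)
  v <- 0:255
  fps <- integer(0)
  for (tt in 0:254) {
    lo <- sum(counts[1:(tt + 1)])
    hi <- sum(counts[(tt + 2):256])
    if (lo == 0 || hi == 0) next
    mu_lo <- sum(v[1:(tt + 1)] * counts[1:(tt + 1)]) / lo
    mu_hi <- sum(v[(tt + 2):256] * counts[(tt + 2):256]) / hi
    if (floor((mu_lo + mu_hi) / 2) == tt) fps <- c(fps, tt)
  }
  fps
}

# Random binary mask with foreground probability p.
rand_mask <- function(h, w, p = 0.5) {
  matrix(stats::runif(h * w) < p, h, w)
}

# Random 256-bin histogram; mixes flat Poisson counts with bimodal
# Gaussian-mixture images and sparse spike histograms.
rand_hist <- function() {
  kind <- sample(1:3, 1)
  counts <- if (kind == 1) {
    stats::rpois(256, stats::runif(1, 0.5, 30))
  } else if (kind == 2) {
    x <- c(round(stats::rnorm(3000, sample(30:100, 1), sample(5:25, 1))),
           round(stats::rnorm(sample(500:6000, 1), sample(130:230, 1),
                              sample(5:25, 1))))
    tabulate(pmin(pmax(x, 0), 255) + 1L, nbins = 256L)
  } else {
    counts <- integer(256)
    k <- sample(2:8, 1)
    counts[sample(1:256, k)] <- sample(1:500, k, replace = TRUE)
    counts
  }
  if (sum(counts > 0) < 2) counts[c(10, 200)] <- counts[c(10, 200)] + 1L
  counts
}

# Strip diagnostic attributes (threshold, stage logs) off a mask so it can
# be compared with identical().
mask_of <- function(m) {
  attributes(m) <- list(dim = dim(m))
  m
}

# Half-linear-scale phantom frame used by the end-to-end tests to stay
# inside the runtime budgets (the pipeline is resolution-independent).
test_frame <- list(width = 536, height = 451)
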