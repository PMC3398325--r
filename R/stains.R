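# Stain separation in optical-density (OD) space.
#
# Under the Beer-Lambert law stain contributions are additive in OD, so a
# stained RGB pixel is od = c_h * v_h + c_e * v_e (+ residual), and the
# per-stain concentrations are recovered by inverting the 3x3 matrix whose
# rows are the stain OD direction vectors.
#
# OD convention: od = -log10((i + 1) / 256) for 8-bit intensity i. The +1
# offset keeps the transform total (no log(0) at i = 0); od ranges from
# about 0.0017 (i = 255) to log10(256) ~ 2.408 (i = 0).

# Built-in H&E stain vectors (widely used published values for
# haematoxylin and eosin OD directions; normalized at load).
HE_VECTOR_H <- c(0.644211, 0.716556, 0.266844)
HE_VECTOR_E <- c(0.092789, 0.954111, 0.283111)

#' Convert an 8-bit RGB image to optical density
#'
#' Applies `od = -log10((i + 1) / 256)` per channel. Monotone decreasing in
#' intensity; white (255) maps to ~0.0017, black (0) to `log10(256) ~ 2.408`.
#'
#' @param image `H x W x 3` integer array with values in `[0, 255]`.
#' @return `H x W x 3` numeric array of non-negative optical densities.
#' @export
rgb_to_od <- function(image) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3L] == 3L,
            min(image) >= 0, max(image) <= 255)
  # 8-bit input: evaluate the transform once per grey level
  lut <- -log10((1:256) / 256)
  od <- lut[image + 1L]
  dim(od) <- dim(image)
  od
}

#' Build an H&E stain basis
#'
#' Normalizes the two raw stain OD vectors to unit length, completes them
#' with their normalized cross product (the residual direction, orthogonal
#' to both), and computes the inverse of the mixing matrix. The inverse is
#' verified against the identity to 1e-10.
#'
#' @param v_h_raw,v_e_raw Raw 3-component OD direction vectors (all
#'   components `>= 0`, non-zero, non-parallel).
#' @return An object of class `stain_basis` with elements `v_h`, `v_e`,
#'   `v_residual`, `mixing_matrix` (rows = stain vectors) and
#'   `inverse_matrix`.
#' @examples
#' b <- build_stain_basis(c(1, 0, 0), c(0, 1, 0))
#' stopifnot(all(b$v_residual == c(0, 0, 1)))
#' @export
build_stain_basis <- function(v_h_raw = HE_VECTOR_H, v_e_raw = HE_VECTOR_E) {
  check_vec <- function(v, nm) {
    if (!is.numeric(v) || length(v) != 3L || any(!is.finite(v)) || any(v < 0)) {
      stop_chromaseg(sprintf("%s must be 3 finite non-negative numbers", nm),
                     "chromaseg_basis_error")
    }
    n <- sqrt(sum(v^2))
    if (n < 1e-12) {
      stop_chromaseg(sprintf("%s is (near-)zero: degenerate stain basis", nm),
                     "chromaseg_basis_error")
    }
    v / n
  }
  v_h <- check_vec(v_h_raw, "v_h_raw")
  v_e <- check_vec(v_e_raw, "v_e_raw")
  cr <- c(v_h[2] * v_e[3] - v_h[3] * v_e[2],
          v_h[3] * v_e[1] - v_h[1] * v_e[3],
          v_h[1] * v_e[2] - v_h[2] * v_e[1])
  ncr <- sqrt(sum(cr^2))
  if (ncr < 1e-8) {
    stop_chromaseg("stain vectors are parallel: degenerate stain basis",
                   "chromaseg_basis_error")
  }
  v_r <- cr / ncr
  m <- rbind(h = v_h, e = v_e, residual = v_r)
  colnames(m) <- c("r", "g", "b")
  inv <- solve(m)
  if (max(abs(m %*% inv - diag(3))) > 1e-10) {
    stop_chromaseg("stain basis inversion failed the identity check",
                   "chromaseg_basis_error")
  }
  structure(list(v_h = v_h, v_e = v_e, v_residual = v_r,
                 mixing_matrix = m, inverse_matrix = inv),
            class = "stain_basis")
}

#' Default built-in H&E stain basis
#'
#' @return A `stain_basis` built from the package's built-in H&E vectors.
#' @export
he_basis <- function() build_stain_basis(HE_VECTOR_H, HE_VECTOR_E)

#' Per-pixel stain concentrations from an OD image
#'
#' Solves `od = c %*% mixing_matrix` per pixel and clamps negative
#' concentrations (pixels outside the stain simplex, e.g. marker dye) at 0.
#'
#' @param od `H x W x 3` OD array from [rgb_to_od()].
#' @param basis A `stain_basis`.
#' @return `H x W x 3` array of concentrations (haematoxylin, eosin,
#'   residual).
#' @export
stain_concentrations <- function(od, basis) {
  stopifnot(inherits(basis, "stain_basis"),
            length(dim(od)) == 3L, dim(od)[3L] == 3L)
  d <- dim(od)
  odm <- matrix(od, ncol = 3L)          # pixels x (r,g,b)
  conc <- pmax(odm %*% basis$inverse_matrix, 0)
  array(conc, dim = d)
}

#' Colour-deconvolve an OD image into per-stain 8-bit channels
#'
#' Each per-stain channel reconstructs the transmittance a pixel would have
#' if only that stain were present: `clamp(round(255 * 10^(-c_s)), 0, 255)`.
#' Stain-dense pixels are therefore dark.
#'
#' @param od `H x W x 3` OD array.
#' @param basis A `stain_basis`.
#' @return Named list of three integer `H x W` matrices:
#'   `haematoxylin`, `eosin`, `residual`, each with a `label` attribute.
#' @export
deconvolve <- function(od, basis) {
  conc <- stain_concentrations(od, basis)
  chan <- function(k, label) {
    m <- clamp8(round_half_up(255 * 10^(-conc[, , k])))
    dim(m) <- dim(conc)[1:2]
    storage.mode(m) <- "integer"
    attr(m, "label") <- label
    m
  }
  list(haematoxylin = chan(1L, "haematoxylin"),
       eosin        = chan(2L, "eosin"),
       residual     = chan(3L, "residual"))
}

#' Linear contrast enhancement with quantile saturation
#'
#' Maps the `saturation_fraction / 2` and `1 - saturation_fraction / 2`
#' intensity quantiles linearly to 0 and 255, clamping beyond; with
#' `saturation_fraction = 0` the observed minimum maps to 0 and the maximum
#' to 255. Constant channels are returned unchanged. The stretch is
#' monotone: it never inverts the ordering of two pixel values.
#'
#' @param channel Integer `H x W` matrix with values in `[0, 255]`.
#' @param saturation_fraction Total fraction of pixels allowed to saturate
#'   (half at each end); in `[0, 0.5)`. Default 0.0035 (0.35%), the common
#'   interactive default of desktop image-analysis tools.
#' @return Integer matrix of the same shape, `label` attribute preserved.
#' @export
enhance_contrast <- function(channel, saturation_fraction = 0.0035) {
  stopifnot(is.matrix(channel),
            is.numeric(saturation_fraction), length(saturation_fraction) == 1L,
            saturation_fraction >= 0, saturation_fraction < 0.5)
  # type-1 (order statistic) quantiles, computed from the 256-bin histogram
  n <- length(channel)
  cum <- cumsum(tabulate(as.integer(channel) + 1L, nbins = 256L))
  q <- saturation_fraction / 2
  rank_lo <- max(1L, min(n, floor(q * n) + 1L))
  rank_hi <- max(1L, min(n, ceiling((1 - q) * n)))
  lo <- which(cum >= rank_lo)[1L] - 1L
  hi <- which(cum >= rank_hi)[1L] - 1L
  if (hi <= lo) return(channel)
  lut <- clamp8(round_half_up(255 * ((0:255) - lo) / (hi - lo)))
  out <- as.integer(lut[channel + 1L])
  dim(out) <- dim(channel)
  attr(out, "label") <- attr(channel, "label")
  out
}

#' Convert an RGB image to an 8-bit grayscale channel
#'
#' `gray = round(w . (r, g, b))` per pixel. The default equal weights match
#' the plain unweighted RGB mean; ITU-R BT.601 weights
#' `(0.299, 0.587, 0.114)` can be supplied instead.
#'
#' @param image `H x W x 3` integer array.
#' @param weights Three non-negative weights summing to 1 (within 1e-9).
#' @return Integer `H x W` matrix with `label` attribute `"grayscale"`.
#' @export
rgb_to_gray <- function(image, weights = c(1, 1, 1) / 3) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3L] == 3L)
  if (!is.numeric(weights) || length(weights) != 3L || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-9) {
    stop_chromaseg("weights must be 3 non-negative numbers summing to 1",
                   "chromaseg_argument_error")
  }
  g <- round_half_up(weights[1] * image[, , 1L] +
                     weights[2] * image[, , 2L] +
                     weights[3] * image[, , 3L])
  dim(g) <- dim(image)[1:2]
  storage.mode(g) <- "integer"
  attr(g, "label") <- "grayscale"
  g
}
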