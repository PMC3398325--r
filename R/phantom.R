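# Synthetic H&E phantom images with exactly known ground truth.
#
# Tumour nests are haematoxylin-dominant disks on an eosin-dominant
# background, with optional small basaloid "distractor" disks whose areas
# fall below the particle-size cutoff (they survive thresholding and are
# removed only by the particle filter, isolating that stage's
# contribution). Rendering is the exact Beer-Lambert inverse of the
# package's OD convention, plus additive Gaussian sensor noise in intensity
# space. Everything is a deterministic function of the seed.

#' Phantom specification
#'
#' Defaults describe a plausible H&E photomicrograph at the working
#' magnification: a 1072 x 902 frame, three well-separated tumour nests of
#' 28-45 px radius (areas well above the 750 px particle cutoff),
#' haematoxylin-dominant nests (`c_h = 0.9`) with eosin co-localisation
#' (`c_e = 0.25`) on a lightly counterstained background (`c_h = 0.05`,
#' `c_e = 0.35`), and sensor noise of 4 grey levels.
#'
#' @param width,height Image size in pixels.
#' @param n_nests Number of tumour nests.
#' @param nest_radius_range Min/max nest radius (pixels); the minimum must
#'   give a rasterized area above 750 px (radius >= 16).
#' @param nest_h_concentration,nest_e_concentration Stain concentrations
#'   inside nests (dimensionless Beer-Lambert units).
#' @param background_h_concentration,background_e_concentration Background
#'   concentrations.
#' @param n_distractors Number of sub-threshold basaloid distractor disks.
#' @param distractor_radius_range Min/max distractor radius; the maximum
#'   must keep areas below 750 px (radius <= 15).
#' @param distractor_h_concentration,distractor_e_concentration Distractor
#'   concentrations. Defaults equal the nest concentrations so distractors
#'   survive thresholding and are removed only by the particle filter.
#' @param noise_sd Gaussian noise standard deviation in 8-bit intensity
#'   units.
#' @param clearance Minimum gap (pixels) between placed objects (`>= 1`,
#'   so ground truth never intersects a distractor).
#' @param seed Random seed; the phantom is fully determined by it.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(width = 1072, height = 902,
                         n_nests = 3, nest_radius_range = c(28, 45),
                         nest_h_concentration = 0.9,
                         nest_e_concentration = 0.25,
                         background_h_concentration = 0.05,
                         background_e_concentration = 0.35,
                         n_distractors = 0,
                         distractor_radius_range = c(5, 14),
                         distractor_h_concentration = 0.9,
                         distractor_e_concentration = 0.25,
                         noise_sd = 4, clearance = 15, seed = 1) {
  spec <- list(width = width, height = height, n_nests = n_nests,
               nest_radius_range = nest_radius_range,
               nest_h_concentration = nest_h_concentration,
               nest_e_concentration = nest_e_concentration,
               background_h_concentration = background_h_concentration,
               background_e_concentration = background_e_concentration,
               n_distractors = n_distractors,
               distractor_radius_range = distractor_radius_range,
               distractor_h_concentration = distractor_h_concentration,
               distractor_e_concentration = distractor_e_concentration,
               noise_sd = noise_sd, clearance = clearance, seed = seed)
  stopifnot(width >= 1, height >= 1, n_nests >= 0, n_distractors >= 0,
            noise_sd >= 0, clearance >= 1,
            length(nest_radius_range) == 2L,
            length(distractor_radius_range) == 2L,
            nest_radius_range[1] <= nest_radius_range[2],
            distractor_radius_range[1] <= distractor_radius_range[2],
            nest_h_concentration >= 0, nest_e_concentration >= 0,
            background_h_concentration >= 0, background_e_concentration >= 0,
            distractor_h_concentration >= 0, distractor_e_concentration >= 0)
  if (n_nests > 0 && nest_radius_range[1] < 16) {
    stop_chromaseg(
      "nest radii below 16 px can rasterize under the 750 px particle cutoff",
      "chromaseg_argument_error")
  }
  if (n_distractors > 0 && distractor_radius_range[2] > 15) {
    stop_chromaseg(
      "distractor radii above 15 px can rasterize over the 750 px particle cutoff",
      "chromaseg_argument_error")
  }
  structure(spec, class = "phantom_spec")
}

#' Render stain concentration fields to an 8-bit RGB image
#'
#' Per pixel `od = c_h * v_h + c_e * v_e` and
#' `intensity = clamp(round(256 * 10^(-od) - 1), 0, 255)`, the exact inverse
#' of the package's OD convention, so render -> [rgb_to_od()] ->
#' [stain_concentrations()] round-trips up to 8-bit quantization.
#'
#' @param c_h,c_e Numeric `H x W` matrices of non-negative concentrations.
#' @param basis A `stain_basis`.
#' @return `H x W x 3` integer array.
#' @export
render_stains <- function(c_h, c_e, basis = he_basis()) {
  stopifnot(inherits(basis, "stain_basis"),
            is.matrix(c_h), is.matrix(c_e), min(c_h) >= 0, min(c_e) >= 0)
  if (!identical(dim(c_h), dim(c_e))) {
    stop_chromaseg("concentration field dimensions differ",
                   "chromaseg_shape_error")
  }
  h <- nrow(c_h); w <- ncol(c_h)
  img <- array(0L, dim = c(h, w, 3L))
  for (k in 1:3) {
    od <- c_h * basis$v_h[k] + c_e * basis$v_e[k]
    ch <- clamp8(round_half_up(256 * 10^(-od) - 1))
    storage.mode(ch) <- "integer"
    img[, , k] <- ch
  }
  img
}

# Rasterize a disk: pixels whose centre is within `r` of (cy, cx).
disk_pixels <- function(height, width, cy, cx, r) {
  y0 <- max(1L, floor(cy - r)); y1 <- min(height, ceiling(cy + r))
  x0 <- max(1L, floor(cx - r)); x1 <- min(width, ceiling(cx + r))
  ys <- y0:y1; xs <- x0:x1
  inside <- outer((ys - cy)^2, (xs - cx)^2, `+`) <= r^2
  cbind(row = rep(ys, times = length(xs))[inside],
        col = rep(xs, each = length(ys))[inside])
}

# Rejection-sample non-overlapping disk placements. `others` is a matrix
# with columns cy, cx, r of already-placed objects; new disks keep
# `clearance` pixels of gap from all of them and lie fully inside the frame.
place_disks <- function(n, rmin, rmax, height, width, clearance, others,
                        kind, max_attempts = 2000L) {
  placed <- matrix(numeric(0), ncol = 3,
                   dimnames = list(NULL, c("cy", "cx", "r")))
  for (i in seq_len(n)) {
    ok <- FALSE
    for (att in seq_len(max_attempts)) {
      r <- stats::runif(1, rmin, rmax)
      if (height - 2 * (r + 2) < 0 || width - 2 * (r + 2) < 0) break
      cy <- stats::runif(1, r + 2, height - r - 1)
      cx <- stats::runif(1, r + 2, width - r - 1)
      all_others <- rbind(others, placed)
      if (nrow(all_others) == 0 ||
          all(sqrt((all_others[, 1] - cy)^2 + (all_others[, 2] - cx)^2) >=
              all_others[, 3] + r + clearance)) {
        placed <- rbind(placed, c(cy, cx, r))
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop_chromaseg(sprintf(
        "could not place %s %d of %d without overlap after %d attempts",
        kind, i, n, max_attempts), "chromaseg_placement_error")
    }
  }
  placed
}

#' Generate a synthetic H&E phantom
#'
#' Places nest and distractor disks by rejection sampling (pairwise gaps of
#' at least `spec$clearance` pixels, so truth never intersects a
#' distractor), renders the concentration fields via [render_stains()], and
#' adds clamped per-channel Gaussian noise. Three independent random
#' streams (nests, distractors, noise) are derived from `spec$seed`, so the
#' same seed reproduces identical nests and noise regardless of
#' `n_distractors` -- phantom pairs differing only in distractors are
#' directly comparable.
#'
#' @param spec A [phantom_spec()].
#' @param basis A `stain_basis` used for rendering.
#' @return Object of class `phantom_result`: list with `image`
#'   (`H x W x 3` integer array), `truth` (logical matrix; union of nest
#'   disks only), `placements` (`data.frame`: kind, cy, cx, r) and `spec`.
#' @export
generate_phantom <- function(spec = phantom_spec(), basis = he_basis()) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$height; w <- spec$width

  set.seed(spec$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  subseeds <- sample.int(.Machine$integer.max - 1L, 3L)

  set.seed(subseeds[1])
  nests <- place_disks(spec$n_nests, spec$nest_radius_range[1],
                       spec$nest_radius_range[2], h, w, spec$clearance,
                       matrix(numeric(0), ncol = 3), "nest")
  set.seed(subseeds[2])
  distractors <- place_disks(spec$n_distractors,
                             spec$distractor_radius_range[1],
                             spec$distractor_radius_range[2], h, w,
                             spec$clearance, nests, "distractor")

  c_h <- matrix(spec$background_h_concentration, h, w)
  c_e <- matrix(spec$background_e_concentration, h, w)
  truth <- matrix(FALSE, h, w)
  for (i in seq_len(nrow(nests))) {
    px <- disk_pixels(h, w, nests[i, 1], nests[i, 2], nests[i, 3])
    c_h[px] <- spec$nest_h_concentration
    c_e[px] <- spec$nest_e_concentration
    truth[px] <- TRUE
  }
  for (i in seq_len(nrow(distractors))) {
    px <- disk_pixels(h, w, distractors[i, 1], distractors[i, 2],
                      distractors[i, 3])
    c_h[px] <- spec$distractor_h_concentration
    c_e[px] <- spec$distractor_e_concentration
  }

  img <- render_stains(c_h, c_e, basis)
  if (spec$noise_sd > 0) {
    set.seed(subseeds[3])
    img <- clamp8(round_half_up(img + stats::rnorm(length(img), 0,
                                                   spec$noise_sd)))
    storage.mode(img) <- "integer"
  }

  placements <- data.frame(
    kind = c(rep("nest", nrow(nests)), rep("distractor", nrow(distractors))),
    cy = c(nests[, 1], distractors[, 1]),
    cx = c(nests[, 2], distractors[, 2]),
    r = c(nests[, 3], distractors[, 3]))

  structure(list(image = img, truth = truth, placements = placements,
                 spec = spec),
            class = "phantom_result")
}

# Per-label preset overrides applied to the base spec by generate_suite().
suite_presets <- function(base) {
  list(
    # few large nests
    "nodular-like" = list(n_nests = 3, nest_radius_range = c(35, 60)),
    # small nests plus many distractors crowding close to them (small
    # clearance), the adnexa/basal-layer false-positive scenario
    "superficial-like" = list(n_nests = 6, nest_radius_range = c(18, 26),
                              n_distractors = max(base$n_distractors, 25),
                              distractor_radius_range = c(5, 12),
                              clearance = 2),
    # many small-to-medium nests near the size cutoff
    "infiltrative-like" = list(n_nests = 10, nest_radius_range = c(17, 23))
  )
}

#' Generate a labelled suite of phantoms
#'
#' Cycles through three parameter presets emulating tumour-subtype
#' morphologies at desk scale: `"nodular-like"` (few large nests),
#' `"superficial-like"` (small nests plus many distractors placed close to
#' them) and `"infiltrative-like"` (many nests near the 750 px cutoff).
#' Preset fields override the base spec; everything else (concentrations,
#' noise, frame size) is inherited from `base_spec`. Per-image seeds are
#' derived deterministically from `seed`.
#'
#' @param n_images Number of phantoms (`>= 1`); labels are assigned
#'   round-robin.
#' @param base_spec A [phantom_spec()] supplying inherited parameters.
#' @param seed Suite seed.
#' @param basis A `stain_basis`.
#' @return List of `phantom_result` objects, each with an added `subtype`
#'   element.
#' @export
generate_suite <- function(n_images, base_spec = phantom_spec(), seed = 1,
                           basis = he_basis()) {
  stopifnot(n_images >= 1)
  presets <- suite_presets(base_spec)
  labels <- rep(names(presets), length.out = n_images)
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  image_seeds <- sample.int(.Machine$integer.max - 1L, n_images)
  lapply(seq_len(n_images), function(i) {
    args <- unclass(base_spec)
    over <- presets[[labels[i]]]
    args[names(over)] <- over
    args$seed <- image_seeds[i]
    res <- generate_phantom(do.call(phantom_spec, args), basis)
    res$subtype <- labels[i]
    res
  })
}

#' Write a phantom suite to disk
#'
#' Writes `image_###.png`, `truth_###.png` and a `manifest.csv`
#' (image_id, subtype, paths, seed and key spec parameters).
#'
#' @param suite List of `phantom_result` objects from [generate_suite()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the manifest `data.frame`.
#' @export
write_suite <- function(suite, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(suite), function(i) {
    id <- sprintf("image_%03d", i)
    img_path <- file.path(out_dir, paste0(id, ".png"))
    truth_path <- file.path(out_dir, sprintf("truth_%03d.png", i))
    write_rgb_image(suite[[i]]$image, img_path)
    write_mask(suite[[i]]$truth, truth_path)
    sp <- suite[[i]]$spec
    data.frame(image_id = id, subtype = suite[[i]]$subtype %||% NA_character_,
               image = img_path, truth = truth_path, seed = sp$seed,
               n_nests = sp$n_nests, n_distractors = sp$n_distractors,
               noise_sd = sp$noise_sd)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
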