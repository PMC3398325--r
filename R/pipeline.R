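# End-to-end orchestration of the four-stage extraction algorithm:
# pre-processing (colour deconvolution + contrast enhancement, or grayscale
# conversion), segmentation (isodata), morphological repair, and
# minimum-area particle filtering.

#' Pipeline configuration
#'
#' @param mode `"deconvolution"` (haematoxylin channel of the colour
#'   deconvolution) or `"grayscale"` (plain 8-bit conversion; the
#'   deconvolution step is omitted, all later stages identical).
#' @param vector_h,vector_e Raw stain OD vectors for the basis.
#' @param contrast_saturation Saturation fraction for [enhance_contrast()].
#' @param gray_weights RGB weights for [rgb_to_gray()].
#' @param morphology A [morphology_params()] object.
#' @param min_area Minimum particle area in pixels (default 750).
#' @param connectivity Component connectivity, 8 or 4.
#' @param threshold `"auto"` (isodata) or a fixed integer in `[0, 255]` for
#'   debugging.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("deconvolution", "grayscale"),
                            vector_h = HE_VECTOR_H, vector_e = HE_VECTOR_E,
                            contrast_saturation = 0.0035,
                            gray_weights = c(1, 1, 1) / 3,
                            morphology = morphology_params(),
                            min_area = 750, connectivity = 8,
                            threshold = "auto") {
  mode <- match.arg(mode)
  stopifnot(inherits(morphology, "morphology_params"), min_area >= 0,
            connectivity %in% c(4, 8))
  if (!identical(threshold, "auto")) {
    stopifnot(is.numeric(threshold), length(threshold) == 1L,
              threshold >= 0, threshold <= 255)
  }
  structure(list(mode = mode,
                 basis = build_stain_basis(vector_h, vector_e),
                 contrast_saturation = contrast_saturation,
                 gray_weights = gray_weights,
                 morphology = morphology, min_area = min_area,
                 connectivity = connectivity, threshold = threshold),
            class = "pipeline_config")
}

# Channel extraction: everything upstream of the shared stages.
extract_channel <- function(image, config) {
  if (config$mode == "deconvolution") {
    deconvolve(rgb_to_od(image), config$basis)$haematoxylin
  } else {
    rgb_to_gray(image, config$gray_weights)
  }
}

#' Run the tumour-extraction pipeline on one image
#'
#' Deconvolution mode: `rgb_to_od` -> `deconvolve` (haematoxylin channel
#' retained) -> `enhance_contrast` -> isodata threshold + `binarize_dark` ->
#' `repair_mask` -> `label_components` -> `filter_by_area`. Grayscale mode
#' replaces the first two steps with `rgb_to_gray`; the remaining stages are
#' shared. Deterministic: identical input and config give an identical mask.
#'
#' @param image `H x W x 3` integer array.
#' @param config A [pipeline_config()].
#' @param debug_dir If non-`NULL`, per-stage masks/channels are written
#'   there as numbered PNGs.
#' @param image_id Identifier used in error messages and debug file names.
#' @return Logical prediction mask with attributes `threshold` (the
#'   threshold used) and `stage_log` (named foreground/pixel counts per
#'   stage).
#' @export
run_pipeline <- function(image, config = pipeline_config(), debug_dir = NULL,
                         image_id = "image") {
  stopifnot(inherits(config, "pipeline_config"))
  channel <- extract_channel(image, config)
  enhanced <- enhance_contrast(channel, config$contrast_saturation)

  thr <- if (identical(config$threshold, "auto")) {
    tryCatch(isodata_threshold(intensity_histogram(enhanced)),
             chromaseg_degenerate_histogram = function(e) {
               stop_chromaseg(sprintf("%s: %s", image_id, conditionMessage(e)),
                              "chromaseg_degenerate_histogram")
             })
  } else as.integer(config$threshold)

  raw_mask <- binarize_dark(enhanced, thr)
  repaired <- repair_mask(raw_mask, config$morphology)
  comps <- label_components(repaired, config$connectivity)
  filtered <- filter_by_area(comps, config$min_area)

  if (!is.null(debug_dir)) {
    dir.create(debug_dir, recursive = TRUE, showWarnings = FALSE)
    gray_png <- function(m, nm) png::writePNG(m / 255,
                                              file.path(debug_dir, nm))
    gray_png(channel, sprintf("%s_1_channel.png", image_id))
    gray_png(enhanced, sprintf("%s_2_enhanced.png", image_id))
    write_mask(raw_mask, file.path(debug_dir,
                                   sprintf("%s_3_threshold.png", image_id)))
    write_mask(repaired, file.path(debug_dir,
                                   sprintf("%s_4_repaired.png", image_id)))
    write_mask(filtered, file.path(debug_dir,
                                   sprintf("%s_5_filtered.png", image_id)))
  }

  out <- filtered
  attr(out, "threshold") <- thr
  attr(out, "stage_log") <- c(threshold = thr,
                              fg_threshold = sum(raw_mask),
                              fg_repaired = sum(repaired),
                              n_components = comps$count,
                              fg_filtered = sum(filtered))
  out
}

#' Run the pipeline over a batch of images and evaluate against truth
#'
#' Per-image failures (e.g. a degenerate histogram on a uniform image) are
#' recorded with an `error` flag and the batch continues.
#'
#' @param image_paths,truth_paths Aligned vectors of file paths.
#' @param subtypes Optional vector of group labels (recycled `NA` if
#'   missing).
#' @param config A [pipeline_config()].
#' @param out_dir If non-`NULL`, writes `metrics_<mode>.csv` and
#'   `summary_<mode>.csv` there (file names carry the mode so the
#'   deconvolution-vs-grayscale comparison is reproducible).
#' @return List with `per_image` (data.frame; one row per image, `error`
#'   column) and `summary` (from [aggregate_metrics()], `NULL` if every
#'   image failed).
#' @export
run_batch <- function(image_paths, truth_paths, subtypes = NULL,
                      config = pipeline_config(), out_dir = NULL) {
  stopifnot(length(image_paths) == length(truth_paths))
  n <- length(image_paths)
  if (is.null(subtypes)) subtypes <- rep(NA_character_, n)
  stopifnot(length(subtypes) == n)

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    id <- sub("\\.[^.]*$", "", basename(image_paths[i]))
    rows[[i]] <- tryCatch({
      img <- read_rgb_image(image_paths[i])
      truth <- read_mask(truth_paths[i])
      pred <- run_pipeline(img, config, image_id = id)
      rec <- compute_metrics(confusion_counts(pred, truth), id, subtypes[i])
      rec$threshold <- attr(pred, "threshold")
      rec$error <- NA_character_
      rec
    }, error = function(e) {
      data.frame(image_id = id, subtype = as.character(subtypes[i]),
                 tp = NA_integer_, fp = NA_integer_, fn = NA_integer_,
                 tn = NA_integer_, se = NA_real_, sp = NA_real_,
                 ppv = NA_real_, npv = NA_real_, threshold = NA_integer_,
                 error = conditionMessage(e), stringsAsFactors = FALSE)
    })
  }
  per_image <- do.call(rbind, rows)
  ok <- is.na(per_image$error)
  summary <- if (any(ok)) aggregate_metrics(per_image[ok, , drop = FALSE])
             else NULL

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(per_image,
                     file.path(out_dir, sprintf("metrics_%s.csv", config$mode)),
                     row.names = FALSE)
    if (!is.null(summary)) {
      utils::write.csv(summary,
                       file.path(out_dir, sprintf("summary_%s.csv", config$mode)),
                       row.names = FALSE)
    }
  }
  list(per_image = per_image, summary = summary)
}
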