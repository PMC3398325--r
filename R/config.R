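# Plain-text key=value configuration files, e.g.
#
#   # stain vectors
#   stains.vector_h = 0.644211, 0.716556, 0.266844
#   stains.vector_e = 0.092789, 0.954111, 0.283111
#   stains.contrast_saturation = 0.0035
#   gray.weights = 0.299, 0.587, 0.114
#   morphology.bright_radius = 5
#   morphology.bright_deviation = 50
#   morphology.dark_radius = 5
#   morphology.dark_deviation = 50
#   morphology.close_se_halfwidth = 1
#   morphology.close_iterations = 1
#   pipeline.mode = deconvolution
#   pipeline.min_area = 750
#   pipeline.connectivity = 8

#' Read a pipeline configuration file
#'
#' Parses a `key = value` file (lines starting with `#` are comments,
#' values may be comma-separated numeric vectors) and returns a
#' [pipeline_config()] with the file's settings applied over the defaults.
#' Unknown keys raise an error rather than being silently ignored.
#'
#' @param path Path to the config file.
#' @param ... Further overrides passed to [pipeline_config()] (take
#'   precedence over the file).
#' @return A `pipeline_config`.
#' @export
read_config_file <- function(path, ...) {
  if (!file.exists(path)) {
    stop_chromaseg(sprintf("config file does not exist: '%s'", path),
                   "chromaseg_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) {
    stop_chromaseg(sprintf("malformed config line: '%s'", lines[bad][1]),
                   "chromaseg_config_error")
  }
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, `[`, "", 2L))

  num <- function(v) {
    x <- suppressWarnings(as.numeric(strsplit(v, ",")[[1]]))
    if (any(is.na(x))) {
      stop_chromaseg(sprintf("non-numeric config value: '%s'", v),
                     "chromaseg_config_error")
    }
    x
  }

  args <- list()
  morph <- list()
  for (i in seq_along(keys)) {
    k <- keys[i]; v <- vals[i]
    switch(k,
      "stains.vector_h" = { args$vector_h <- num(v) },
      "stains.vector_e" = { args$vector_e <- num(v) },
      "stains.contrast_saturation" = { args$contrast_saturation <- num(v) },
      "gray.weights" = { args$gray_weights <- num(v) },
      "pipeline.mode" = { args$mode <- v },
      "pipeline.min_area" = { args$min_area <- num(v) },
      "pipeline.connectivity" = { args$connectivity <- num(v) },
      "pipeline.threshold" = {
        args$threshold <- if (identical(v, "auto")) "auto" else num(v)
      },
      "morphology.bright_radius" = { morph$bright_radius <- num(v) },
      "morphology.bright_deviation" = { morph$bright_deviation <- num(v) },
      "morphology.dark_radius" = { morph$dark_radius <- num(v) },
      "morphology.dark_deviation" = { morph$dark_deviation <- num(v) },
      "morphology.close_se_halfwidth" = { morph$close_se_halfwidth <- num(v) },
      "morphology.close_iterations" = { morph$close_iterations <- num(v) },
      stop_chromaseg(sprintf("unknown config key: '%s'", k),
                     "chromaseg_config_error")
    )
  }
  if (length(morph)) args$morphology <- do.call(morphology_params, morph)
  over <- list(...)
  args[names(over)] <- over
  do.call(pipeline_config, args)
}
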