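# TIFF and JSON input/output.
#
# Stacks are written as multi-page TIFF with a JSON sidecar (<path>.json)
# carrying the axes, physical calibration and the intensity scale factor.
# Integer-valued data up to 65535 are stored as 16-bit samples and round-trip
# losslessly; other data are stored as 32-bit float scaled into [0, 1].

#' Write an image stack to a (multi-page) TIFF with a JSON sidecar
#'
#' @param stack an [image_stack].
#' @param path output `.tif` path; the calibration sidecar is written to
#'   `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  data <- stack$data
  mx <- max(data)
  integerish <- all(data == round(data)) && min(data) >= 0 && mx <= 65535
  if (integerish) {
    scale <- 65535
    bits <- 16L
  } else {
    scale <- if (mx > 0) mx else 1
    bits <- 32L
  }
  frames <- lapply(seq_len(n_frames(stack)), function(i)
    get_frame(stack, i) / scale)
  tiff::writeTIFF(frames, path, bits.per.sample = bits,
                  compression = "none", reduce = FALSE)
  meta <- list(axes = stack$axes, pixel_size_um = stack$pixel_size_um,
               z_step_um = stack$z_step_um,
               frame_interval_s = stack$frame_interval_s,
               scale = scale, bits = bits)
  jsonlite::write_json(meta[!vapply(meta, is.null, logical(1))],
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an image stack from TIFF
#'
#' Calibration is taken from the JSON sidecar written by [write_stack] when
#' present; explicit arguments override it. Without a sidecar, the axes (for
#' multi-page files) and the pixel size must be supplied.
#'
#' @param path `.tif` path.
#' @param axes,pixel_size_um,z_step_um,frame_interval_s calibration
#'   overrides; see [image_stack].
#' @return an [image_stack]; integer-typed files are restored losslessly.
#' @export
read_stack <- function(path, axes = NULL, pixel_size_um = NULL,
                       z_step_um = NULL, frame_interval_s = NULL) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- list()
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar))
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  axes <- axes %||% meta$axes
  pixel_size_um <- pixel_size_um %||% meta$pixel_size_um
  z_step_um <- z_step_um %||% meta$z_step_um
  frame_interval_s <- frame_interval_s %||% meta$frame_interval_s
  scale <- meta$scale %||% 1
  if (is.null(pixel_size_um))
    stop("pixel size unknown: no sidecar metadata and no pixel_size_um ",
         "override supplied")
  if (length(pages) == 1L && is.null(axes)) axes <- "YX"
  if (is.null(axes))
    stop("ambiguous axes for a multi-page TIFF: supply axes = 'TYX' or 'ZYX'")
  restore <- function(m) {
    v <- m * scale
    if (isTRUE(meta$bits == 16L)) v <- round(v)
    v
  }
  if (axes == "YX") {
    data <- restore(pages[[1L]])
  } else {
    d <- dim(pages[[1L]])
    data <- array(0, c(length(pages), d[1L], d[2L]))
    for (i in seq_along(pages)) data[i, , ] <- restore(pages[[i]])
  }
  image_stack(data, axes, pixel_size_um, z_step_um = z_step_um,
              frame_interval_s = frame_interval_s)
}

#' Pipeline configuration
#'
#' A single JSON-serializable document holding every stage parameter. All
#' coordinates are 0-based in files and 1-based inside R; frame windows are
#' given inclusive in frames; physical quantities are um and seconds.
#'
#' @param seed integer seed used for every stochastic stage.
#' @param simulate list of generator settings (see [scene_config],
#'   [step_protocol] and [simulate_droplet_kinetics]); set `enabled = TRUE`
#'   to generate the input movie. Without simulation, `input` must point to
#'   a TIFF readable by [read_stack].
#' @param input path to an input movie (ignored when simulating).
#' @param counting list: `low_thr`, `high_thr`, `prominence`,
#'   `gate_factor`, `baseline_frames`.
#' @param windows list: `onset_frame`, `peak` (frames), `washout` (frames).
#' @param classify_boundaries type boundaries in um.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            simulate = list(enabled = TRUE),
                            input = NULL,
                            counting = list(low_thr = 150, high_thr = 450,
                                            prominence = 100,
                                            gate_factor = 1.5,
                                            baseline_frames = 1:10),
                            windows = list(onset_frame = 11L,
                                           peak = 11:44, washout = 50:60),
                            classify_boundaries = c(1.0, 3.6)) {
  structure(list(seed = as.integer(seed), simulate = simulate, input = input,
                 counting = counting, windows = windows,
                 classify_boundaries = classify_boundaries),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as JSON
#' @param config a [pipeline_config].
#' @param path JSON path.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, cfg[intersect(names(cfg),
                                         names(formals(pipeline_config)))])
}
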