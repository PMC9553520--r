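#' Write an OCT volume (and optional label map) to disk
#'
#' Two on-disk layouts are supported. `format = "raw"` stores the intensity
#' array as IEEE little-endian doubles (exact round trip) next to a YAML
#' sidecar holding shape, voxel pitches and label levels. `format = "tiff"`
#' writes one multi-page 32-bit float TIFF per repeat frame (page = depth
#' slice) for viewing in standard image tools; the round trip is then exact
#' only to single precision. The label map, when given, is written as an
#' 8-bit TIFF with label codes scaled by 1/255.
#'
#' @param volume An [oct_volume()].
#' @param path Output directory (created if needed).
#' @param labels Optional [label_map()].
#' @param format `"raw"` (default) or `"tiff"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, labels = NULL, format = c("raw", "tiff")) {
  stopifnot(inherits(volume, "oct_volume"))
  format <- match.arg(format)
  if (!is.null(labels)) {
    stopifnot(inherits(labels, "label_map"))
    if (!identical(dim(labels$labels), dim(volume$intensity)[1:3])) {
      stop("label map shape does not match the volume's spatial shape")
    }
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  dims <- dim(volume$intensity)
  rng <- range(volume$intensity)
  meta <- list(
    shape = as.integer(dims),
    voxel_pitch_um = as.numeric(volume$voxel_pitch),
    format = format,
    # TIFF pages hold (x - min) / (max - min): the container stores [0, 1]
    intensity_range = if (format == "tiff") as.numeric(rng),
    label_levels = if (is.null(labels)) NULL else labels$levels
  )
  yaml::write_yaml(meta, file.path(path, "volume.yaml"))

  if (format == "raw") {
    con <- file(file.path(path, "intensity.raw"), "wb")
    on.exit(close(con), add = TRUE)
    writeBin(as.vector(volume$intensity), con, size = 8, endian = "little")
    if (!is.null(labels)) {
      lcon <- file(file.path(path, "labels.raw"), "wb")
      on.exit(close(lcon), add = TRUE)
      writeBin(as.vector(labels$labels), lcon, size = 4, endian = "little")
    }
  } else {
    span <- if (diff(rng) > 0) diff(rng) else 1
    for (r in seq_len(dims[4])) {
      pages <- lapply(seq_len(dims[1]), function(i) {
        (volume$intensity[i, , , r] - rng[1]) / span
      })
      tiff::writeTIFF(pages, file.path(path, sprintf("repeat_%03d.tiff", r)),
                      bits.per.sample = 32L, reduce = FALSE)
    }
    if (!is.null(labels)) {
      pages <- lapply(seq_len(dims[1]), function(i) labels$labels[i, , ] / 255)
      tiff::writeTIFF(pages, file.path(path, "labels.tiff"),
                      bits.per.sample = 8L)
    }
  }
  invisible(path)
}

#' Read an OCT volume written by [write_volume()]
#'
#' @param path Directory containing `volume.yaml` and the intensity data.
#' @return A list with `volume` ([oct_volume()]) and `labels` ([label_map()]
#'   or `NULL`).
#' @export
read_volume <- function(path) {
  meta_path <- file.path(path, "volume.yaml")
  if (!file.exists(meta_path)) {
    stop("missing sidecar metadata: ", meta_path,
         " (not a volume directory written by write_volume)")
  }
  meta <- yaml::read_yaml(meta_path)
  dims <- as.integer(meta$shape)
  if (identical(meta$format, "raw")) {
    con <- file(file.path(path, "intensity.raw"), "rb")
    on.exit(close(con), add = TRUE)
    vals <- readBin(con, "double", n = prod(dims), size = 8, endian = "little")
    intensity <- array(vals, dim = dims)
    labels <- NULL
    lab_path <- file.path(path, "labels.raw")
    if (file.exists(lab_path)) {
      lcon <- file(lab_path, "rb")
      on.exit(close(lcon), add = TRUE)
      lv <- readBin(lcon, "integer", n = prod(dims[1:3]), size = 4,
                    endian = "little")
      labels <- label_map(array(lv, dim = dims[1:3]))
    }
  } else {
    rng <- as.numeric(meta$intensity_range)
    span <- if (diff(rng) > 0) diff(rng) else 1
    intensity <- array(0, dim = dims)
    for (r in seq_len(dims[4])) {
      pages <- tiff::readTIFF(file.path(path, sprintf("repeat_%03d.tiff", r)),
                              all = TRUE)
      if (!is.list(pages)) pages <- list(pages)
      for (i in seq_len(dims[1])) {
        intensity[i, , , r] <- pages[[i]] * span + rng[1]
      }
    }
    labels <- NULL
    lab_path <- file.path(path, "labels.tiff")
    if (file.exists(lab_path)) {
      pages <- tiff::readTIFF(lab_path, all = TRUE)
      lab <- array(0L, dim = dims[1:3])
      for (i in seq_len(dims[1])) lab[i, , ] <- as.integer(round(pages[[i]] * 255))
      labels <- label_map(lab)
    }
  }
  list(volume = oct_volume(intensity, meta$voxel_pitch_um), labels = labels)
}

#' Read a phantom configuration from a YAML file
#'
#' The file mirrors the arguments of [phantom_config()]; `region_models` is a
#' mapping from region label to the fields of [region_speckle_model()].
#' Fields omitted from the file keep their package defaults. The default
#' configuration shipped at
#' `system.file("extdata", "phantom_default.yaml", package = "octspeckle")`
#' encodes the tube/rod geometry and scan pitches the simulator mirrors.
#'
#' @param path YAML file path.
#' @return A [phantom_config()].
#' @export
read_phantom_config <- function(path) {
  spec <- yaml::read_yaml(path)
  models <- default_region_models()
  for (lab in names(spec$region_models)) {
    fields <- spec$region_models[[lab]]
    models[[lab]] <- do.call(region_speckle_model, c(list(label = lab), fields))
  }
  args <- spec[setdiff(names(spec), "region_models")]
  args$region_models <- models
  do.call(phantom_config, args)
}
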