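# Core containers and file I/O.
#
# Rasters are plain numeric matrices wrapped in light S3 classes so that the
# calibration metadata (bit depth, pixel size, channel role) travels with the
# pixels. Coordinates are (row, col) with the origin at the top-left.

CHANNEL_ROLES <- c("brightfield", "green", "red", "generic")

#' Construct a calibrated 2-D image
#'
#' @param pixels numeric matrix of non-negative, finite intensities.
#' @param bit_depth one of 8, 16 or "float". Describes the native range of
#'   the data; pixel values are never rescaled.
#' @param pixel_size_um physical pixel size in micrometres, or `NA` when the
#'   calibration is unknown (the default; none is assumed).
#' @param channel_role one of `"brightfield"`, `"green"`, `"red"`,
#'   `"generic"`.
#' @return an `Image2D` object (a matrix with class and metadata attributes).
#' @export
image2d <- function(pixels, bit_depth = "float", pixel_size_um = NA_real_,
                    channel_role = "generic") {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("pixels must be a numeric matrix")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("raster must be at least 1x1")
  if (any(!is.finite(pixels)) || any(pixels < 0))
    stop("all pixel values must be finite and non-negative")
  if (!bit_depth %in% list(8, 16, "float", 8L, 16L))
    stop("bit_depth must be 8, 16 or \"float\"")
  channel_role <- match.arg(channel_role, CHANNEL_ROLES)
  if (!is.na(pixel_size_um) && pixel_size_um <= 0)
    stop("pixel_size_um must be positive or NA")
  structure(pixels,
            bit_depth = if (identical(bit_depth, "float")) "float" else as.integer(bit_depth),
            pixel_size_um = as.numeric(pixel_size_um),
            channel_role = channel_role,
            class = c("Image2D", "matrix", "array"))
}

#' @export
print.Image2D <- function(x, ...) {
  cat(sprintf("Image2D %d x %d, bit depth %s, channel %s, pixel size %s um\n",
              nrow(x), ncol(x), attr(x, "bit_depth"), attr(x, "channel_role"),
              ifelse(is.na(attr(x, "pixel_size_um")), "unknown",
                     format(attr(x, "pixel_size_um")))))
  cat(sprintf("  intensity range [%g, %g]\n", min(x), max(x)))
  invisible(x)
}

is_image2d <- function(x) inherits(x, "Image2D")

#' Construct a multi-channel stack
#'
#' All channels must share dimensions. Channels are addressed by role
#' (e.g. `stack$green`), never guessed from file metadata.
#'
#' @param ... named `Image2D` objects; names are channel roles.
#' @return a `ChannelStack` (named list).
#' @export
channel_stack <- function(...) {
  channels <- list(...)
  if (length(channels) == 1L && is.list(channels[[1]]) &&
      !is_image2d(channels[[1]]))
    channels <- channels[[1]]
  if (length(channels) < 1L) stop("at least one channel is required")
  if (is.null(names(channels)) || any(!nzchar(names(channels))))
    stop("channels must be named by role")
  if (!all(names(channels) %in% CHANNEL_ROLES))
    stop("channel names must be roles: ", paste(CHANNEL_ROLES, collapse = ", "))
  dims <- vapply(channels, dim, integer(2))
  if (!all(dims == dims[, 1])) stop("all channels must share dimensions")
  structure(channels, class = "ChannelStack")
}

#' @export
print.ChannelStack <- function(x, ...) {
  cat(sprintf("ChannelStack %d x %d with channels: %s\n",
              nrow(x[[1]]), ncol(x[[1]]), paste(names(x), collapse = ", ")))
  invisible(x)
}

#' Construct a label map
#'
#' @param labels integer matrix; 0 is background, objects are labelled with
#'   the consecutive integers `1..n_objects`.
#' @return a `LabelMap`.
#' @export
label_map <- function(labels) {
  if (!is.matrix(labels)) stop("labels must be a matrix")
  storage.mode(labels) <- "integer"
  u <- sort(unique(as.vector(labels)))
  n <- length(setdiff(u, 0L))
  if (n > 0L && !identical(setdiff(u, 0L), seq_len(n)))
    stop("labels must be exactly {0} union {1..n_objects}")
  structure(labels, n_objects = n, class = c("LabelMap", "matrix", "array"))
}

#' @export
print.LabelMap <- function(x, ...) {
  cat(sprintf("LabelMap %d x %d with %d objects\n",
              nrow(x), ncol(x), attr(x, "n_objects")))
  invisible(x)
}

n_objects <- function(labels) attr(labels, "n_objects")

# Relabel an arbitrary non-negative integer raster to consecutive 1..n.
relabel <- function(m) {
  u <- sort(unique(as.vector(m)))
  u <- u[u != 0]
  out <- matrix(0L, nrow(m), ncol(m))
  if (length(u)) out[] <- match(as.vector(m), u, nomatch = 0L)
  label_map(out)
}

#' Read a grayscale image from TIFF or PNG
#'
#' Pixel values are kept at their native scale: an 8-bit file yields values
#' in 0..255 and a 16-bit file values in 0..65535. The function refuses to
#' silently collapse colour data: an RGB raster must be read with
#' [read_channel_stack()] and an explicit channel mapping.
#'
#' @param path file path (`.tif`, `.tiff` or `.png`).
#' @param channel_role role tag recorded on the image.
#' @param pixel_size_um optional physical calibration (micrometres/pixel).
#' @return an [image2d()] object.
#' @export
read_image <- function(path, channel_role = "generic",
                       pixel_size_um = NA_real_) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    meta <- tiff::readTIFF(path, payload = FALSE)
    bits <- meta$bits.per.sample[1]
    if (bits >= 32L) {
      raw <- tiff::readTIFF(path)          # float samples come back as-is
    } else {
      raw <- tiff::readTIFF(path, as.is = TRUE)
      # multi-sample TIFFs come back 0-1 regardless of as.is; undo the scaling
      if (is.double(raw) && max(raw) <= 1)
        raw <- round(raw * (2^bits - 1))
    }
  } else if (ext == "png") {
    raw <- png::readPNG(path)
    bits <- 8L
    raw <- raw * 255
  } else stop("unsupported raster format: ", ext)
  if (length(dim(raw)) == 3L)
    stop("multi-channel raster: use read_channel_stack() with a channel mapping")
  depth <- if (bits >= 32) "float" else as.integer(bits)
  image2d(matrix(as.numeric(raw), nrow(raw), ncol(raw)), bit_depth = depth,
          pixel_size_um = pixel_size_um, channel_role = channel_role)
}

#' Read an RGB raster as a channel stack
#'
#' @param path TIFF or PNG path holding a 3-plane RGB raster.
#' @param mapping named character vector from colour plane to channel role,
#'   e.g. `c(R = "red", G = "green")`. Unmapped planes are dropped.
#' @inheritParams read_image
#' @return a [channel_stack()].
#' @export
read_channel_stack <- function(path, mapping, pixel_size_um = NA_real_) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (missing(mapping) || is.null(names(mapping)))
    stop("an explicit channel mapping (e.g. c(R = \"red\")) is required")
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    meta <- tiff::readTIFF(path, payload = FALSE)
    bits <- meta$bits.per.sample[1]
    if (bits >= 32L) {
      raw <- tiff::readTIFF(path)          # float samples come back as-is
    } else {
      raw <- tiff::readTIFF(path, as.is = TRUE)
      # multi-sample TIFFs come back 0-1 regardless of as.is; undo the scaling
      if (is.double(raw) && max(raw) <= 1)
        raw <- round(raw * (2^bits - 1))
    }
  } else if (ext == "png") {
    raw <- png::readPNG(path) * 255
    bits <- 8L
  } else stop("unsupported raster format: ", ext)
  if (length(dim(raw)) != 3L) stop("not a multi-plane raster")
  planes <- c(R = 1L, G = 2L, B = 3L)
  depth <- if (bits >= 32) "float" else as.integer(bits)
  chans <- lapply(names(mapping), function(p) {
    image2d(matrix(as.numeric(raw[, , planes[[p]]]), dim(raw)[1], dim(raw)[2]),
            bit_depth = depth, pixel_size_um = pixel_size_um,
            channel_role = mapping[[p]])
  })
  names(chans) <- unname(mapping)
  channel_stack(chans)
}

#' Write an image (or label map) to TIFF or PNG
#'
#' Values are written at the image's native bit depth so that
#' `read_image(write_image(x))` round-trips losslessly. Float images are
#' written as 32-bit float TIFF and must lie in [0, 1] (the function
#' errors rather than silently rescaling out-of-range data). Label maps
#' are written as 16-bit TIFF.
#'
#' @param image an [image2d()] or [label_map()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  ext <- tolower(tools::file_ext(path))
  if (inherits(image, "LabelMap")) {
    m <- unclass(image)
    tiff::writeTIFF(m / 65535, path, bits.per.sample = 16L)
    return(invisible(path))
  }
  depth <- attr(image, "bit_depth")
  m <- unclass(image)
  attributes(m) <- list(dim = dim(m))
  if (ext == "png") {
    png::writePNG(m / 255, path)
  } else if (identical(depth, "float")) {
    if (max(m) > 1)
      stop("float TIFF storage is defined on [0, 1]; rescale explicitly")
    tiff::writeTIFF(m, path, bits.per.sample = 32L)
  } else {
    tiff::writeTIFF(m / (2^as.integer(depth) - 1), path,
                    bits.per.sample = as.integer(depth))
  }
  invisible(path)
}

#' Export records to CSV
#'
#' Writes a header plus one row per record with dot-decimal, locale
#' independent formatting. An empty record list yields a header-only file.
#'
#' @param records data.frame (possibly zero rows) with a non-empty schema.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_table <- function(records, path) {
  records <- as.data.frame(records)
  if (ncol(records) == 0L) stop("records have an empty schema")
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Default run configuration
#'
#' Collects every tunable used by the pipelines, with its default. Values
#' supplied in `...` (or nested lists) override defaults. The effective
#' configuration of every assay run is written to a YAML run log so that a
#' run is reproducible from its log plus its seed.
#'
#' @param ... overrides, e.g. `seed = 7`, `segmentation = list(generous_factor = 0.5)`.
#' @return a nested list with class `RunConfig`.
#' @export
run_config <- function(...) {
  cfg <- list(
    seed = 1L,
    output_dir = ".",
    segmentation = list(
      method = "generous_green",
      generous_factor = 0.6,      # multiplier on the Otsu threshold
      min_object_px = 50L,
      closing_rounds = 2L,
      connectivity = 8L,
      watershed_tolerance = 3
    ),
    mito = list(
      ball_radius_px = 25L,       # background subtraction window half-size
      clahe_tiles = 4L,
      clahe_clip = 2,
      log_sigma_px = 1.0,         # Gaussian scale of the Laplacian filter
      min_mito_px = 7L,           # components below this size are noise/debris
      maxima_tolerance = 0.10     # fraction of object dynamic range
    ),
    rules = activation_rules(),
    motility = list(frame_interval_s = 30)
  )
  modifyList(cfg, list(...), keep.null = TRUE) -> cfg
  class(cfg) <- c("RunConfig", "list")
  cfg
}

#' Read a run configuration from YAML
#'
#' Unknown keys are kept; known keys override [run_config()] defaults.
#'
#' @param path YAML file.
#' @return a `RunConfig`.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- modifyList(run_config(), user, keep.null = TRUE)
  class(cfg) <- c("RunConfig", "list")
  cfg
}

#' Write the effective run configuration to a YAML run log
#'
#' @param config a `RunConfig`.
#' @param path output path (YAML).
#' @return `path`, invisibly.
#' @export
write_run_log <- function(config, path) {
  stopifnot(inherits(config, "RunConfig") || is.list(config))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
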