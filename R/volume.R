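#' Multi-channel 3D volume with physical voxel sizes
#'
#' A `spa_volume` holds a 4D non-negative intensity grid indexed
#' `(channel, z, y, x)` together with its physical voxel spacing in nm.
#' Intensities are stored as doubles regardless of the on-disk type.
#'
#' Pixel/slice coordinates throughout the package are 0-based: an integer
#' index names the center of its voxel and the continuous position in nm is
#' `index * spacing`.
#'
#' @param data 4D numeric array, dimensions `(channel, z, y, x)`.
#' @param voxel_size numeric length-3, `(dz, dy, dx)` in nm; `dy` must equal
#'   `dx` (isotropic lateral sampling).
#' @param channel_labels character vector, one label per channel. Defaults to
#'   `"ch0"`, `"ch1"`, ...
#' @param image_id identifier string carried into per-particle records.
#' @return An object of class `spa_volume` with elements `data`,
#'   `voxel_size`, `channel_labels`, `image_id`.
#' @export
spa_volume <- function(data, voxel_size, channel_labels = NULL,
                       image_id = "volume") {
  if (!is.array(data) || length(dim(data)) != 4L)
    stop("`data` must be a 4D array (channel, z, y, x)")
  if (any(dim(data) < 1L)) stop("all dimensions must be >= 1")
  if (!all(is.finite(data))) stop("all intensities must be finite")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("`voxel_size` must be positive finite (dz, dy, dx) in nm")
  if (abs(voxel_size[2] - voxel_size[3]) > 1e-9 * voxel_size[3])
    stop("non-isotropic lateral pixels: dy must equal dx")
  nc <- dim(data)[1]
  if (is.null(channel_labels))
    channel_labels <- paste0("ch", seq_len(nc) - 1L)
  if (length(channel_labels) != nc)
    stop("length(channel_labels) must equal the number of channels")
  storage.mode(data) <- "double"
  structure(
    list(data = data, voxel_size = voxel_size,
         channel_labels = as.character(channel_labels),
         image_id = as.character(image_id)),
    class = "spa_volume")
}

#' @export
print.spa_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<spa_volume '%s'> %d channel(s) x %d slice(s) x %d x %d\n",
              x$image_id, d[1], d[2], d[3], d[4]))
  cat(sprintf("  voxel size (dz, dy, dx): %g x %g x %g nm\n",
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  cat("  channels:", paste(x$channel_labels, collapse = ", "), "\n")
  invisible(x)
}

#' Numbers of channels / slices and lateral shape
#' @param volume a [spa_volume()]
#' @return integer scalar (or length-2 vector for `lateral_shape`)
#' @export
n_channels <- function(volume) dim(volume$data)[1]

#' @rdname n_channels
#' @export
n_slices <- function(volume) dim(volume$data)[2]

#' @rdname n_channels
#' @export
lateral_shape <- function(volume) dim(volume$data)[3:4]

check_channel <- function(volume, channel) {
  channel <- as.integer(channel)
  if (length(channel) != 1L || is.na(channel) || channel < 0L ||
      channel >= n_channels(volume))
    stop(sprintf("invalid channel %s (volume has %d channels, 0-based)",
                 paste(channel, collapse = ","), n_channels(volume)))
  channel
}

#' Read a multi-page TIFF z-stack as a volume
#'
#' Understands uncompressed single-sample TIFFs (uint8/uint16/float32) with
#' ImageJ-style hyperstack metadata (`channels=`, `slices=`, `spacing=`,
#' `unit=`) in the ImageDescription tag. Page order is assumed
#' channel-fastest (ImageJ XYCZT). Lateral pixel size is taken from the
#' X/YResolution tags (pixels per description unit). Metadata gaps must be
#' filled with `voxel_size_override` or reading fails.
#'
#' @param path TIFF file path.
#' @param voxel_size_override optional `(dz, dy, dx)` nm overriding (or
#'   supplying missing) metadata.
#' @param image_id identifier; defaults to the file name without extension.
#' @return A [spa_volume()] with axes normalized to `(channel, z, y, x)`.
#' @export
read_volume <- function(path, voxel_size_override = NULL, image_id = NULL) {
  tf <- read_tiff_raw(path)
  pages <- tf$pages          # list of y-by-x matrices
  meta <- tf$meta
  n_pages <- length(pages)
  nc <- meta$channels
  nz <- meta$slices
  if (is.null(nc) && is.null(nz)) { nc <- 1L; nz <- n_pages }
  if (is.null(nc)) nc <- n_pages %/% nz
  if (is.null(nz)) nz <- n_pages %/% nc
  if (nc * nz != n_pages)
    stop(sprintf("page count %d inconsistent with channels=%d slices=%d",
                 n_pages, nc, nz))
  vs <- c(meta$dz_nm %||% NA_real_, meta$dxy_nm %||% NA_real_,
          meta$dxy_nm %||% NA_real_)
  if (!is.null(voxel_size_override)) vs <- as.numeric(voxel_size_override)
  if (any(!is.finite(vs)))
    stop("voxel size unknown: no metadata and no override supplied")
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  data <- array(0, dim = c(nc, nz, ny, nx))
  for (p in seq_len(n_pages)) {
    # ImageJ hyperstack page order: channel varies fastest, then slice
    c0 <- (p - 1L) %% nc
    z0 <- (p - 1L) %/% nc
    data[c0 + 1L, z0 + 1L, , ] <- pages[[p]]
  }
  labels <- meta$labels
  if (!is.null(labels) && length(labels) != nc) labels <- NULL
  if (is.null(image_id))
    image_id <- meta$image_id %||% sub("\\.[^.]*$", "", basename(path))
  spa_volume(data, vs, channel_labels = labels, image_id = image_id)
}

#' Write a volume as a multi-page float32 TIFF
#'
#' Pages are written channel-fastest (ImageJ XYCZT order) with an
#' ImageJ-style ImageDescription carrying `channels`, `slices`, axial
#' `spacing` (micron) plus `labels` and `image_id` lines that
#' [read_volume()] recovers. X/YResolution encode the lateral pixel size.
#' A write/read round trip is bit-identical on data and metadata.
#'
#' @param volume a [spa_volume()]
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "spa_volume"))
  d <- dim(volume$data)
  pages <- vector("list", d[1] * d[2])
  for (z0 in seq_len(d[2]) - 1L)
    for (c0 in seq_len(d[1]) - 1L)
      pages[[z0 * d[1] + c0 + 1L]] <-
        matrix(volume$data[c0 + 1L, z0 + 1L, , ], d[3], d[4])
  write_tiff_raw(path, pages,
                 channels = d[1], slices = d[2],
                 dz_nm = volume$voxel_size[1],
                 dxy_nm = volume$voxel_size[3],
                 labels = volume$channel_labels,
                 image_id = volume$image_id)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Manually picked mother/distal seed pairs
#'
#' Reads a seed table CSV with columns `image_id, fit_channel,
#' reference_channel, mother_x, mother_y, distal_x, distal_y`
#' (`reference_channel` may be blank / absent). Coordinates are 0-based
#' lateral pixels; the mother spot is listed first by convention.
#'
#' @param path CSV path (header required).
#' @return A list of `spa_seed_pair` records in file order, each with fields
#'   `image_id`, `fit_channel`, `reference_channel` (or `NULL`),
#'   `mother_seed`, `distal_seed` (each `(x, y)` pixels).
#' @export
read_seeds <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("image_id", "fit_channel", "mother_x", "mother_y",
           "distal_x", "distal_y")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("seed table missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  num_cols <- c("fit_channel", "mother_x", "mother_y", "distal_x", "distal_y")
  for (cl in num_cols)
    if (!is.numeric(df[[cl]]))
      stop("non-numeric values in seed column ", cl)
  key <- do.call(paste, c(df[c("image_id", num_cols)], sep = "|"))
  if (anyDuplicated(key))
    warning("duplicate (image_id, seeds) rows in seed table")
  lapply(seq_len(nrow(df)), function(i) {
    rc <- if ("reference_channel" %in% names(df)) df$reference_channel[i]
          else NA
    rc <- suppressWarnings(as.numeric(rc))
    if (!is.null(rc) && (is.na(rc))) rc <- NULL
    seed_pair(image_id = df$image_id[i],
              fit_channel = as.integer(df$fit_channel[i]),
              reference_channel = if (is.null(rc)) NULL else as.integer(rc),
              mother_seed = c(df$mother_x[i], df$mother_y[i]),
              distal_seed = c(df$distal_x[i], df$distal_y[i]))
  })
}

#' @rdname read_seeds
#' @param image_id,fit_channel,reference_channel,mother_seed,distal_seed
#'   record fields; seeds are `(x, y)` in 0-based pixels.
#' @export
seed_pair <- function(image_id, fit_channel, reference_channel = NULL,
                      mother_seed, distal_seed) {
  mother_seed <- as.numeric(mother_seed); distal_seed <- as.numeric(distal_seed)
  if (length(mother_seed) != 2L || length(distal_seed) != 2L ||
      any(!is.finite(c(mother_seed, distal_seed))))
    stop("seeds must be finite (x, y) pairs")
  if (all(abs(mother_seed - distal_seed) < 1e-12))
    stop("degenerate seed pair: mother and distal seeds coincide")
  if (!is.null(reference_channel) &&
      identical(as.integer(reference_channel), as.integer(fit_channel)))
    stop("fit_channel and reference_channel must differ")
  structure(list(image_id = as.character(image_id),
                 fit_channel = as.integer(fit_channel),
                 reference_channel = if (is.null(reference_channel)) NULL
                                     else as.integer(reference_channel),
                 mother_seed = mother_seed, distal_seed = distal_seed),
            class = "spa_seed_pair")
}

#' @rdname read_seeds
#' @param seeds list of `spa_seed_pair` records to serialize.
#' @export
write_seeds <- function(seeds, path) {
  df <- do.call(rbind, lapply(seeds, function(s) {
    data.frame(image_id = s$image_id, fit_channel = s$fit_channel,
               reference_channel = if (is.null(s$reference_channel)) NA_integer_
                                   else s$reference_channel,
               mother_x = s$mother_seed[1], mother_y = s$mother_seed[2],
               distal_x = s$distal_seed[1], distal_y = s$distal_seed[2])
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
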