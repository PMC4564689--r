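# Minimal baseline-TIFF reader/writer.
#
# No TIFF-capable R package ships with this environment, so the small subset
# needed for SIM z-stacks is implemented here: uncompressed, single sample
# per pixel, uint8/uint16/float32/float64, single or multiple strips,
# little- or big-endian, ImageJ-style hyperstack metadata in the
# ImageDescription tag. This is an I/O shim, not a general TIFF library.

TIFF_TYPE_SIZES <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `5` = 8L,
                     `6` = 1L, `7` = 1L, `8` = 2L, `9` = 4L, `10` = 8L,
                     `11` = 4L, `12` = 8L)

read_tiff_raw <- function(path) {
  if (!file.exists(path)) stop("unreadable file: ", path)
  raw_all <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw_all) < 8L) stop("unreadable TIFF: file too short")
  order_tag <- rawToChar(raw_all[1:2])
  endian <- if (order_tag == "II") "little" else if (order_tag == "MM") "big"
            else stop("unreadable TIFF: bad byte-order mark")
  rd_int <- function(off, size, signed = TRUE) {
    readBin(raw_all[(off + 1):(off + size)], "integer", size = size,
            endian = endian, signed = signed)
  }
  rd_u16 <- function(off) rd_int(off, 2L, signed = FALSE)
  rd_u32 <- function(off) {
    v <- rd_int(off, 4L, signed = TRUE)
    if (v < 0) stop("TIFF offset exceeds 2^31; unsupported")
    v
  }
  if (rd_u16(2L) != 42L) stop("unreadable TIFF: bad magic number")

  pages <- list()
  description <- NULL
  ifd_off <- rd_u32(4L)
  while (ifd_off != 0L) {
    n_entries <- rd_u16(ifd_off)
    tags <- list()
    for (i in seq_len(n_entries)) {
      e <- ifd_off + 2L + (i - 1L) * 12L
      tag <- rd_u16(e); type <- rd_u16(e + 2L); count <- rd_u32(e + 4L)
      tsize <- TIFF_TYPE_SIZES[[as.character(type)]]
      nbytes <- tsize * count
      voff <- if (nbytes <= 4L) e + 8L else rd_u32(e + 8L)
      value <- switch(as.character(type),
        `2` = {  # ASCII
          chars <- raw_all[(voff + 1):(voff + count)]
          rawToChar(chars[chars != as.raw(0)])
        },
        `3` = vapply(seq_len(count) - 1L,
                     function(k) rd_u16(voff + 2L * k), numeric(1)),
        `4` = vapply(seq_len(count) - 1L,
                     function(k) rd_u32(voff + 4L * k), numeric(1)),
        `5` = vapply(seq_len(count) - 1L, function(k)
                     rd_u32(voff + 8L * k) / rd_u32(voff + 8L * k + 4L),
                     numeric(1)),
        NULL)
      tags[[as.character(tag)]] <- value
    }
    g <- function(tag, default = NULL) tags[[as.character(tag)]] %||% default
    width <- g(256); height <- g(257)
    if (is.null(width) || is.null(height)) stop("TIFF page missing dimensions")
    bits <- g(258, 1)[1]
    if (g(259, 1) != 1) stop("compressed TIFF not supported")
    if (g(277, 1) != 1) stop("multi-sample TIFF not supported")
    fmt <- g(339, 1)[1]
    if (is.null(description)) description <- g(270)
    strip_offsets <- g(273); strip_counts <- g(279)
    if (is.null(strip_offsets)) stop("TIFF page missing strip offsets")
    if (is.null(strip_counts))
      strip_counts <- rep(width * height * bits / 8 / length(strip_offsets),
                          length(strip_offsets))
    vals <- numeric(0)
    for (s in seq_along(strip_offsets)) {
      so <- strip_offsets[s]; sc <- strip_counts[s]
      bytes <- raw_all[(so + 1):(so + sc)]
      vals <- c(vals, decode_samples(bytes, bits, fmt, endian))
    }
    if (length(vals) != width * height)
      stop("TIFF strip data inconsistent with page dimensions")
    pages[[length(pages) + 1L]] <-
      matrix(vals, nrow = height, ncol = width, byrow = TRUE)
    # resolution tags from the last page read (identical across pages here)
    xres <- g(282); runit <- g(296, 2)
    attr(pages, "xres") <- xres; attr(pages, "runit") <- runit
    ifd_off <- rd_u32(ifd_off + 2L + n_entries * 12L)
  }
  meta <- parse_imagej_description(description)
  if (is.null(meta$dxy_nm) && !is.null(attr(pages, "xres"))) {
    unit_nm <- switch(as.character(attr(pages, "runit") %||% 2),
                      `2` = 2.54e7, `3` = 1e7, NULL)  # inch / cm
    if (!is.null(meta$unit) && meta$unit %in% c("micron", "um"))
      unit_nm <- 1e3
    if (!is.null(unit_nm) && attr(pages, "xres") > 0)
      meta$dxy_nm <- unit_nm / attr(pages, "xres")
  }
  list(pages = pages, meta = meta)
}

decode_samples <- function(bytes, bits, fmt, endian) {
  n <- length(bytes)
  if (bits == 8 && fmt %in% c(1, 4)) {
    as.numeric(readBin(bytes, "integer", n = n, size = 1L, signed = FALSE))
  } else if (bits == 16 && fmt %in% c(1, 4)) {
    as.numeric(readBin(bytes, "integer", n = n / 2, size = 2L,
                       signed = FALSE, endian = endian))
  } else if (bits == 32 && fmt == 3) {
    readBin(bytes, "double", n = n / 4, size = 4L, endian = endian)
  } else if (bits == 64 && fmt == 3) {
    readBin(bytes, "double", n = n / 8, size = 8L, endian = endian)
  } else if (bits == 32 && fmt %in% c(1, 4)) {
    v <- readBin(bytes, "integer", n = n / 4, size = 4L, endian = endian)
    ifelse(v < 0, v + 2^32, as.numeric(v))
  } else {
    stop(sprintf("unsupported TIFF sample layout: %d bits, format %d",
                 bits, fmt))
  }
}

parse_imagej_description <- function(desc) {
  out <- list()
  if (is.null(desc)) return(out)
  lines <- strsplit(desc, "\n", fixed = TRUE)[[1]]
  kv <- strsplit(lines, "=", fixed = TRUE)
  for (p in kv) {
    if (length(p) < 2L) next
    key <- trimws(p[1]); val <- trimws(paste(p[-1], collapse = "="))
    out[[key]] <- val
  }
  res <- list()
  if (!is.null(out$channels)) res$channels <- as.integer(out$channels)
  if (!is.null(out$slices)) res$slices <- as.integer(out$slices)
  if (!is.null(out$unit)) res$unit <- out$unit
  if (!is.null(out$dz_nm)) res$dz_nm <- as.numeric(out$dz_nm)
  else if (!is.null(out$spacing)) {
    sp <- as.numeric(out$spacing)
    res$dz_nm <- if (!is.null(out$unit) && out$unit %in% c("micron", "um"))
      sp * 1e3 else sp
  }
  if (!is.null(out$dxy_nm)) res$dxy_nm <- as.numeric(out$dxy_nm)
  if (!is.null(out$image_id)) res$image_id <- out$image_id
  if (!is.null(out$labels))
    res$labels <- strsplit(out$labels, ",", fixed = TRUE)[[1]]
  res
}

write_tiff_raw <- function(path, pages, channels, slices, dz_nm, dxy_nm,
                           labels = NULL, image_id = NULL, bits = 64L,
                           write_metadata = TRUE) {
  stopifnot(bits %in% c(32L, 64L))
  n_pages <- length(pages)
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  bpp <- bits / 8L
  desc <- if (!write_metadata) "bare\n" else paste0(
    "ImageJ=1.54f\nimages=", n_pages, "\nchannels=", channels,
    "\nslices=", slices, "\nhyperstack=true\nmode=grayscale\nunit=micron",
    "\nspacing=", sprintf("%.9g", dz_nm / 1e3),
    "\ndz_nm=", sprintf("%.17g", dz_nm),
    "\ndxy_nm=", sprintf("%.17g", dxy_nm),
    if (!is.null(image_id)) paste0("\nimage_id=", image_id) else "",
    if (!is.null(labels)) paste0("\nlabels=", paste(labels, collapse = ","))
    else "",
    "\n")
  desc_raw <- c(charToRaw(desc), as.raw(0))
  if (length(desc_raw) %% 2L == 1L) desc_raw <- c(desc_raw, as.raw(0))

  # layout: header | description | resolution rationals | strips | IFD chain
  desc_off <- 8L
  rat_off <- desc_off + length(desc_raw)
  strip0_off <- rat_off + 16L
  strip_len <- nx * ny * bpp
  strip_off <- strip0_off + (seq_len(n_pages) - 1L) * strip_len
  ifd0_off <- strip0_off + n_pages * strip_len
  n_entries <- c(14L, rep(13L, max(0L, n_pages - 1L)))  # desc on page 1 only
  ifd_len <- 2L + n_entries * 12L + 4L
  ifd_off <- ifd0_off + cumsum(c(0L, ifd_len[-n_pages]))

  # resolution: pixels per micron as a rational
  res_den <- 1e6
  res_num <- round(res_den * 1e3 / dxy_nm)

  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(x) writeBin(as.integer(x), con, size = 2L,
                              endian = "little")
  w32 <- function(x) writeBin(as.integer(x), con, size = 4L,
                              endian = "little")
  writeBin(charToRaw("II"), con); w16(42L); w32(ifd0_off)
  writeBin(desc_raw, con)
  w32(res_num); w32(res_den); w32(res_num); w32(res_den)
  for (p in seq_len(n_pages))
    writeBin(as.numeric(t(pages[[p]])), con, size = bpp, endian = "little")
  entry <- function(tag, type, count, value, offset_value = FALSE) {
    w16(tag); w16(type); w32(count)
    if (offset_value) w32(value)
    else if (type == 3L) { w16(value); w16(0L) }
    else w32(value)
  }
  for (p in seq_len(n_pages)) {
    w16(n_entries[p])
    entry(256L, 4L, 1L, nx)
    entry(257L, 4L, 1L, ny)
    entry(258L, 3L, 1L, bits)
    entry(259L, 3L, 1L, 1L)
    entry(262L, 3L, 1L, 1L)
    if (p == 1L)
      entry(270L, 2L, length(desc_raw), desc_off, offset_value = TRUE)
    entry(273L, 4L, 1L, strip_off[p])
    entry(277L, 3L, 1L, 1L)
    entry(278L, 4L, 1L, ny)
    entry(279L, 4L, 1L, strip_len)
    entry(282L, 5L, 1L, rat_off, offset_value = TRUE)
    entry(283L, 5L, 1L, rat_off + 8L, offset_value = TRUE)
    entry(296L, 3L, 1L, 1L)  # unit carried in the ImageJ description
    entry(339L, 3L, 1L, 3L)
    w32(if (p < n_pages) ifd_off[p + 1L] else 0L)
  }
  invisible(path)
}
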