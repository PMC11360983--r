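# Minimal baseline TIFF codec (little-endian, uncompressed, one grayscale
# image per page). No TIFF reader exists in the installed R stack, and the
# subset needed here -- multi-page single-sample stacks as written by
# microscopy tooling -- is small enough to implement directly. Supported
# sample types: uint8, uint16, float32, float64. Round-trips are lossless
# for integer data stored as uint8/uint16 and for doubles stored as float64.

TIFF_TYPE_SIZES <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `5` = 8L,
                     `6` = 1L, `7` = 1L, `8` = 2L, `9` = 4L, `10` = 8L,
                     `11` = 4L, `12` = 8L)

tiff_dtype_info <- function(dtype) {
  switch(dtype,
    uint8   = list(bits = 8L,  sample_format = 1L, size = 1L),
    uint16  = list(bits = 16L, sample_format = 1L, size = 2L),
    float32 = list(bits = 32L, sample_format = 3L, size = 4L),
    float64 = list(bits = 64L, sample_format = 3L, size = 8L),
    stop("unsupported TIFF dtype '", dtype, "'", call. = FALSE)
  )
}

# pages: list of numeric matrices (rows = y, cols = x), all the same shape
write_tiff_pages <- function(pages, path, dtype = "uint16") {
  info <- tiff_dtype_info(dtype)
  shapes <- unique(lapply(pages, dim))
  if (length(shapes) != 1L) stop("all pages must share one shape", call. = FALSE)
  h <- shapes[[1]][1]; w <- shapes[[1]][2]
  npix <- h * w
  nbytes <- npix * info$size

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  data_start <- 8L
  first_ifd <- data_start + length(pages) * nbytes
  writeBin(as.integer(first_ifd), con, size = 4, endian = "little")

  for (pg in pages) {
    v <- as.vector(t(pg))  # TIFF is row-major
    if (info$sample_format == 1L) {
      iv <- as.integer(round(v))
      maxv <- if (info$bits == 8L) 255L else 65535L
      if (any(iv < 0L | iv > maxv)) {
        stop("values out of range for ", dtype, " TIFF", call. = FALSE)
      }
      writeBin(iv, con, size = info$size, endian = "little")
    } else {
      writeBin(as.double(v), con, size = info$size, endian = "little")
    }
  }

  write_tag <- function(code, type, count, value) {
    writeBin(as.integer(code), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (type == 3L) {  # SHORT, inline left-justified
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }

  ifd_size <- 2L + 10L * 12L + 4L
  for (i in seq_along(pages)) {
    strip_offset <- data_start + (i - 1L) * nbytes
    next_ifd <- if (i < length(pages)) first_ifd + i * ifd_size else 0L
    writeBin(10L, con, size = 2, endian = "little")
    write_tag(256L, 4L, 1L, w)                    # ImageWidth
    write_tag(257L, 4L, 1L, h)                    # ImageLength
    write_tag(258L, 3L, 1L, info$bits)            # BitsPerSample
    write_tag(259L, 3L, 1L, 1L)                   # Compression = none
    write_tag(262L, 3L, 1L, 1L)                   # Photometric = BlackIsZero
    write_tag(273L, 4L, 1L, strip_offset)         # StripOffsets
    write_tag(277L, 3L, 1L, 1L)                   # SamplesPerPixel
    write_tag(278L, 4L, 1L, h)                    # RowsPerStrip
    write_tag(279L, 4L, 1L, nbytes)               # StripByteCounts
    write_tag(339L, 3L, 1L, info$sample_format)   # SampleFormat
    writeBin(as.integer(next_ifd), con, size = 4, endian = "little")
  }
  invisible(path)
}

# returns a list of numeric matrices, one per page
read_tiff_pages <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8L) stop("not a TIFF file (too short): ", path, call. = FALSE)
  byte_order <- rawToChar(raw[1:2])
  if (!byte_order %in% c("II", "MM")) stop("not a TIFF file: ", path, call. = FALSE)
  endian <- if (byte_order == "II") "little" else "big"
  u16 <- function(off) readBin(raw[(off + 1):(off + 2)], "integer", size = 2,
                               signed = FALSE, endian = endian)
  u32 <- function(off) {
    v <- readBin(raw[(off + 1):(off + 4)], "integer", size = 4, endian = endian)
    if (v < 0) v <- v + 2^32
    v
  }
  if (u16(2) != 42L) stop("not a TIFF file (bad magic): ", path, call. = FALSE)

  pages <- list()
  ifd_off <- u32(4)
  while (ifd_off != 0) {
    n_tags <- u16(ifd_off)
    tags <- list()
    for (i in seq_len(n_tags)) {
      toff <- ifd_off + 2 + (i - 1) * 12
      code <- u16(toff); type <- u16(toff + 2); count <- u32(toff + 4)
      tsize <- unname(TIFF_TYPE_SIZES[as.character(type)])
      if (is.na(tsize)) next
      total <- tsize * count
      voff <- if (total <= 4) toff + 8 else u32(toff + 8)
      vals <- if (type == 3L) {
        vapply(seq_len(count) - 1L, function(k) u16(voff + 2 * k), numeric(1))
      } else if (type %in% c(4L, 1L)) {
        vapply(seq_len(count) - 1L,
               function(k) if (type == 4L) u32(voff + 4 * k) else as.numeric(raw[voff + k + 1]),
               numeric(1))
      } else {
        NULL
      }
      if (!is.null(vals)) tags[[as.character(code)]] <- vals
    }
    need <- function(code, default = NULL) {
      v <- tags[[as.character(code)]]
      if (is.null(v)) {
        if (is.null(default)) stop("TIFF page missing required tag ", code, call. = FALSE)
        default
      } else v
    }
    w <- need(256); h <- need(257)
    bits <- need(258, 1L)[1]
    if (need(259, 1L)[1] != 1L) stop("compressed TIFF not supported: ", path, call. = FALSE)
    if (need(277, 1L)[1] != 1L) stop("multi-sample TIFF pages not supported: ", path, call. = FALSE)
    fmt <- need(339, 1L)[1]
    offsets <- need(273); counts <- need(279)
    buf <- raw(sum(counts))
    pos <- 0L
    for (s in seq_along(offsets)) {
      buf[(pos + 1):(pos + counts[s])] <- raw[(offsets[s] + 1):(offsets[s] + counts[s])]
      pos <- pos + counts[s]
    }
    npix <- w * h
    vals <- if (fmt == 3L) {
      readBin(buf, "double", n = npix, size = bits / 8, endian = endian)
    } else if (bits == 8L) {
      readBin(buf, "integer", n = npix, size = 1, signed = FALSE, endian = endian)
    } else if (bits == 16L) {
      readBin(buf, "integer", n = npix, size = 2, signed = FALSE, endian = endian)
    } else if (bits == 32L && fmt == 1L) {
      v <- readBin(buf, "integer", n = npix, size = 4, endian = endian)
      v[v < 0] <- v[v < 0] + 2^32
      v
    } else {
      stop("unsupported TIFF sample layout (bits=", bits, ", format=", fmt, ")", call. = FALSE)
    }
    pages[[length(pages) + 1L]] <- matrix(as.numeric(vals), nrow = h, ncol = w, byrow = TRUE)
    ifd_off <- u32(ifd_off + 2 + n_tags * 12)
  }
  pages
}

sidecar_path <- function(path) paste0(path, ".json")

#' Write an image stack to a multi-page TIFF with a JSON sidecar
#'
#' Pages are written channel-major (all z slices of channel 1, then channel
#' 2, ...). A sidecar JSON (`<path>.json`) records channel names, slice
#' count, page order, spacing, axis roles, the sample type, and any extra
#' provenance supplied — enough for [read_stack()] to reconstruct the stack
#' without arguments.
#'
#' @param stack An [image_stack()].
#' @param path Output TIFF path.
#' @param dtype Sample type: `"uint16"` (default), `"uint8"`, `"float32"`
#'   or `"float64"`. Integer intensities round-trip exactly via the integer
#'   types; arbitrary doubles via `"float64"`.
#' @param provenance Optional named list stored verbatim in the sidecar
#'   (e.g. generator spec and seed).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, dtype = "uint16", provenance = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$voxels)
  pages <- vector("list", d[1] * d[2])
  k <- 1L
  for (ch in seq_len(d[1])) {
    for (z in seq_len(d[2])) {
      pages[[k]] <- matrix(stack$voxels[ch, z, , ], nrow = d[3], ncol = d[4])
      k <- k + 1L
    }
  }
  write_tiff_pages(pages, path, dtype = dtype)
  meta <- list(
    format = "topoquant-stack",
    channel_names = as.list(stack$channel_names),
    n_channels = d[1], n_z = d[2],
    page_order = "channel_major",
    spacing_um = as.list(stack$spacing_um),
    dv_axis = stack$dv_axis,
    dorsal_low = stack$dorsal_low,
    dtype = dtype
  )
  if (!is.null(provenance)) meta$provenance <- provenance
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF into an image stack
#'
#' If a `<path>.json` sidecar written by [write_stack()] exists, channel
#' layout and axis roles are taken from it; otherwise they must be supplied.
#' Intensities are returned as stored, with no rescaling.
#'
#' @param path TIFF path.
#' @param channel_map Optional named integer vector mapping channel names to
#'   1-based channel indices, e.g. `c(clone = 1, reference = 2)`. Overrides
#'   (or, without a sidecar, defines) the channel layout; indices beyond the
#'   available channels are an error.
#' @param axis_config Optional list with entries `spacing_um`, `dv_axis`,
#'   `dorsal_low`, `n_z` and `page_order` (`"channel_major"` or
#'   `"interleaved"`). Without a sidecar, `n_z` (or a `channel_map` whose
#'   length divides the page count) is required.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, channel_map = NULL, axis_config = NULL) {
  if (!file.exists(path)) stop("cannot read stack: no such file: ", path, call. = FALSE)
  pages <- read_tiff_pages(path)
  if (length(pages) == 0L) stop("TIFF contains no pages: ", path, call. = FALSE)
  if (length(unique(lapply(pages, dim))) != 1L) {
    stop("TIFF pages have inconsistent shapes: ", path, call. = FALSE)
  }

  meta <- if (file.exists(sidecar_path(path))) {
    jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  } else NULL
  cfg <- axis_config %||% list()

  n_pages <- length(pages)
  n_z <- cfg$n_z %||% meta$n_z
  n_channels <- meta$n_channels %||%
    (if (!is.null(channel_map)) length(channel_map) else NULL) %||%
    (if (!is.null(n_z)) n_pages / n_z else NULL)
  if (is.null(n_channels)) {
    stop("cannot infer channel layout: provide a sidecar, `channel_map`, ",
         "or `axis_config$n_z`", call. = FALSE)
  }
  if (is.null(n_z)) n_z <- n_pages / n_channels
  if (n_channels * n_z != n_pages) {
    stop(n_pages, " pages inconsistent with ", n_channels, " channel(s) x ",
         n_z, " slice(s)", call. = FALSE)
  }
  page_order <- cfg$page_order %||% meta$page_order %||% "channel_major"

  channel_names <- unlist(meta$channel_names) %||% paste0("channel_", seq_len(n_channels))
  if (!is.null(channel_map)) {
    idx <- as.integer(channel_map)
    if (any(idx < 1L | idx > n_channels)) {
      stop("channel_map refers to channel ", max(idx), " but the file has only ",
           n_channels, " channel(s)", call. = FALSE)
    }
    channel_names[idx] <- names(channel_map)
  }

  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  vox <- array(0, dim = c(n_channels, n_z, h, w))
  for (p in seq_len(n_pages)) {
    if (page_order == "channel_major") {
      ch <- ((p - 1L) %/% n_z) + 1L; z <- ((p - 1L) %% n_z) + 1L
    } else {
      z <- ((p - 1L) %/% n_channels) + 1L; ch <- ((p - 1L) %% n_channels) + 1L
    }
    vox[ch, z, , ] <- pages[[p]]
  }

  spacing <- cfg$spacing_um %||% meta$spacing_um %||% list(z = 0.3, y = 0.15, x = 0.15)
  image_stack(vox,
              spacing_um = c(z = spacing$z %||% spacing[["z"]],
                             y = spacing$y %||% spacing[["y"]],
                             x = spacing$x %||% spacing[["x"]]),
              dv_axis = cfg$dv_axis %||% meta$dv_axis %||% "y",
              dorsal_low = cfg$dorsal_low %||% meta$dorsal_low %||% TRUE,
              channel_names = channel_names)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
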