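# Minimal baseline-TIFF reader/writer for two-channel microscopy stacks.
#
# Dialect: little-endian, uncompressed grayscale, one strip per page, pages
# ordered channel-major (all z of channel 1, then channel 2, ...). Pixel size
# is carried in the X/YResolution rational tags as pixels-per-micrometre with
# ResolutionUnit = 1 (no absolute unit). Sample formats: 16-bit unsigned
# integer, or 32/64-bit IEEE float (SampleFormat = 3).
#
# No TIFF package ships with the analysis environment, so the format is
# implemented here; it round-trips exactly and is readable by standard tools.

#' Construct an image stack
#'
#' The in-memory microscopy container: a 4-D voxel array indexed
#' `[channel, z, y, x]` plus the isotropic in-plane pixel size in µm. A
#' typical acquisition holds 10–12 z-planes and two channels (a centrosome
#' marker such as pericentrin, and acetylated alpha-tubulin marking the
#' axoneme).
#'
#' @param voxels Numeric 4-D array `[channel, z, y, x]`, non-negative.
#' @param pixel_size_um Positive in-plane pixel size, µm/pixel.
#' @param channel_names Character vector, one per channel.
#' @return An `image_stack` object.
#' @export
image_stack <- function(voxels, pixel_size_um,
                        channel_names = paste0("ch", seq_len(dim(voxels)[1]))) {
  assert_that(is.array(voxels) && length(dim(voxels)) == 4L,
    "voxels must be a 4-D array [channel, z, y, x]")
  assert_that(all(dim(voxels) >= 1L), "all stack dimensions must be >= 1")
  pixel_size_um <- assert_number(pixel_size_um, "pixel_size_um", min = 1e-9)
  assert_that(length(channel_names) == dim(voxels)[1],
    "channel_names must match the number of channels")
  structure(
    list(voxels = voxels, pixel_size_um = pixel_size_um,
      channel_names = as.character(channel_names)),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<image_stack> %d channel(s) [%s], %d z-plane(s), %d x %d px @ %.4g um/px\n",
    d[1], paste(x$channel_names, collapse = ", "), d[2], d[4], d[3],
    x$pixel_size_um
  ))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$voxels)

# --- low-level byte helpers --------------------------------------------------

tiff_types <- c(BYTE = 1L, ASCII = 2L, SHORT = 3L, LONG = 4L, RATIONAL = 5L)
tiff_type_size <- c(1L, 1L, 2L, 4L, 8L)

u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

ifd_entry <- function(tag, type, count, value_raw) {
  # value_raw: raw vector; padded to 4 bytes if stored inline
  stopifnot(length(value_raw) <= 4)
  c(u16(tag), u16(type), u32(count),
    c(value_raw, raw(4L - length(value_raw))))
}

#' Write an image stack as a multi-page TIFF
#'
#' Pages are written channel-major (all z-planes of channel 1, then channel
#' 2, ...). Pixel size is stored in the X/YResolution tags as pixels per µm.
#'
#' @param stack An [image_stack()].
#' @param path Output file path.
#' @param bits Sample depth: 32 (float, default), 64 (float, exact
#'   round trip of doubles) or 16 (unsigned integer, values clamped and
#'   rounded to 0..65535).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, bits = 32) {
  assert_that(inherits(stack, "image_stack"), "stack must be an image_stack")
  assert_that(bits %in% c(16, 32, 64), "bits must be 16, 32 or 64")
  d <- dim(stack$voxels)
  nc <- d[1]; nz <- d[2]; h <- d[3]; w <- d[4]
  n_pages <- nc * nz
  bytes_pp <- bits / 8
  strip_bytes <- w * h * bytes_pp
  sample_format <- if (bits == 16) 1L else 3L

  # resolution: pixels per micrometre as a rational
  res_num <- 1000000L
  res_den <- as.integer(round(stack$pixel_size_um * 1e6))

  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(charToRaw("II"), con)
  writeBin(u16(42L), con)
  # first IFD offset: header(8) + first page's strip + the two rationals
  first_ifd <- 8 + strip_bytes + 16
  writeBin(u32(first_ifd), con)

  n_tags <- 13L
  ifd_size <- 2 + n_tags * 12 + 4
  page_block <- strip_bytes + 16 + ifd_size # strip + rationals + IFD

  page_i <- 0L
  for (ch in seq_len(nc)) {
    for (z in seq_len(nz)) {
      page_off <- 8 + page_i * page_block
      strip_off <- page_off
      rat_off <- page_off + strip_bytes
      ifd_off <- rat_off + 16
      next_ifd <- if (page_i == n_pages - 1L) 0 else ifd_off + page_block

      plane <- stack$voxels[ch, z, , ]
      # TIFF is row-major, top row first; R matrices are column-major
      v <- as.vector(t(matrix(plane, nrow = h, ncol = w)))
      if (bits == 16) {
        v <- pmin(pmax(round(v), 0), 65535)
        writeBin(as.integer(v), con, size = 2, endian = "little")
      } else {
        writeBin(as.numeric(v), con, size = bytes_pp, endian = "little")
      }
      writeBin(c(u32(res_num), u32(res_den), u32(res_num), u32(res_den)), con)

      entries <- c(
        ifd_entry(256L, 4L, 1L, u32(w)),
        ifd_entry(257L, 4L, 1L, u32(h)),
        ifd_entry(258L, 3L, 1L, u16(bits)),
        ifd_entry(259L, 3L, 1L, u16(1L)),
        ifd_entry(262L, 3L, 1L, u16(1L)),
        ifd_entry(273L, 4L, 1L, u32(strip_off)),
        ifd_entry(277L, 3L, 1L, u16(1L)),
        ifd_entry(278L, 4L, 1L, u32(h)),
        ifd_entry(279L, 4L, 1L, u32(strip_bytes)),
        ifd_entry(282L, 5L, 1L, u32(rat_off)),
        ifd_entry(283L, 5L, 1L, u32(rat_off + 8)),
        ifd_entry(296L, 3L, 1L, u16(1L)),
        ifd_entry(339L, 3L, 1L, u16(sample_format))
      )
      writeBin(c(u16(n_tags), entries, u32(next_ifd)), con)
      page_i <- page_i + 1L
    }
  }
  invisible(path)
}

read_u16 <- function(raw, off) { # off: 0-based
  sum(as.integer(raw[off + 1:2]) * c(1, 256))
}
read_u32 <- function(raw, off) {
  sum(as.numeric(raw[off + 1:4]) * c(1, 256, 65536, 16777216))
}

#' Read a multi-page TIFF into an image stack
#'
#' Reads the uncompressed grayscale multi-page TIFF dialect written by
#' [write_stack()] (16-bit unsigned or 32/64-bit float pages). The page
#' count must be divisible by `n_channels`; pages are interpreted
#' channel-major. Pixel size is taken from the X-resolution tag
#' (pixels per µm); if the file carries no resolution tag, `pixel_size_um`
#' must be supplied or an error is raised.
#'
#' @param path TIFF file path.
#' @param n_channels Declared channel count (default 1).
#' @param pixel_size_um Optional pixel-size override, µm/pixel. Overrides
#'   file metadata when given.
#' @param channel_names Optional channel names.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, n_channels = 1, pixel_size_um = NULL,
                       channel_names = NULL) {
  n_channels <- assert_number(n_channels, "n_channels", min = 1, integerish = TRUE)
  if (!file.exists(path)) {
    abort(sprintf("TIFF file not found: %s", path), class = "ciliadyn_io_error")
  }
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8 || rawToChar(raw[1:2]) != "II" || read_u16(raw, 2) != 42) {
    abort(sprintf("not a little-endian TIFF file: %s", path),
      class = "ciliadyn_io_error")
  }
  ifd_off <- read_u32(raw, 4)
  planes <- list()
  file_pixel_size <- NULL
  while (ifd_off != 0) {
    if (ifd_off + 2 > length(raw)) {
      abort("corrupt TIFF: IFD offset beyond end of file", class = "ciliadyn_io_error")
    }
    n_tags <- read_u16(raw, ifd_off)
    tags <- list()
    for (i in seq_len(n_tags)) {
      e <- ifd_off + 2 + (i - 1) * 12
      tag <- read_u16(raw, e)
      type <- read_u16(raw, e + 2)
      count <- read_u32(raw, e + 4)
      size <- tiff_type_size[type] * count
      val_off <- if (size <= 4) e + 8 else read_u32(raw, e + 8)
      vals <- switch(as.character(type),
        "3" = vapply(seq_len(count) - 1L, function(k) read_u16(raw, val_off + 2 * k), numeric(1)),
        "4" = vapply(seq_len(count) - 1L, function(k) read_u32(raw, val_off + 4 * k), numeric(1)),
        "5" = vapply(seq_len(count) - 1L, function(k) {
          read_u32(raw, val_off + 8 * k) / read_u32(raw, val_off + 8 * k + 4)
        }, numeric(1)),
        NULL
      )
      tags[[as.character(tag)]] <- vals
    }
    need <- c("256", "257", "258", "273", "279")
    if (!all(need %in% names(tags))) {
      abort("corrupt TIFF page: missing required tags", class = "ciliadyn_io_error")
    }
    w <- tags[["256"]]; h <- tags[["257"]]; bits <- tags[["258"]]
    comp <- tags[["259"]] %||% 1
    if (comp != 1) {
      abort("unsupported TIFF: compressed pages", class = "ciliadyn_io_error")
    }
    fmt <- (tags[["339"]] %||% 1)[1]
    offs <- tags[["273"]]; counts <- tags[["279"]]
    if (!is.null(tags[["282"]]) && tags[["282"]][1] > 0) {
      file_pixel_size <- 1 / tags[["282"]][1] # tag is pixels per micrometre
    }
    bytes <- unlist(lapply(seq_along(offs), function(k) {
      raw[(offs[k] + 1):(offs[k] + counts[k])]
    }))
    v <- if (bits == 16 && fmt == 1) {
      readBin(bytes, "integer", n = w * h, size = 2, signed = FALSE, endian = "little")
    } else if (bits %in% c(32, 64) && fmt == 3) {
      readBin(bytes, "double", n = w * h, size = bits / 8, endian = "little")
    } else {
      abort(sprintf("unsupported TIFF sample type: %d-bit format %d", bits, fmt),
        class = "ciliadyn_io_error")
    }
    planes[[length(planes) + 1L]] <- t(matrix(v, nrow = w, ncol = h))
    ifd_off <- read_u32(raw, ifd_off + 2 + n_tags * 12)
  }
  n_pages <- length(planes)
  if (n_pages == 0L || n_pages %% n_channels != 0L) {
    abort(sprintf("page count (%d) not divisible by declared channel count (%d)",
      n_pages, n_channels), class = "ciliadyn_io_error")
  }
  ps <- pixel_size_um %||% file_pixel_size
  if (is.null(ps)) {
    abort("pixel size unknown: file has no resolution tag and no override given",
      class = "ciliadyn_io_error")
  }
  nz <- n_pages %/% n_channels
  h <- nrow(planes[[1]]); w <- ncol(planes[[1]])
  vox <- array(0, dim = c(n_channels, nz, h, w))
  k <- 1L
  for (ch in seq_len(n_channels)) {
    for (z in seq_len(nz)) {
      vox[ch, z, , ] <- planes[[k]]
      k <- k + 1L
    }
  }
  image_stack(vox, ps,
    channel_names = channel_names %||% paste0("ch", seq_len(n_channels)))
}
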