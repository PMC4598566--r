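# 2-D image primitives used by the cilia detection procedure.
#
# Image matrices are indexed [row = y + 1, col = x + 1]; coordinates are
# 0-based, pixel-centre, x rightward, y downward (storage convention).

gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

# separable Gaussian blur with replicate edge padding
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  k <- gaussian_kernel(sigma)
  r <- (length(k) - 1L) %/% 2L
  h <- nrow(img); w <- ncol(img)
  # horizontal pass
  pad <- img[, c(rep(1L, r), seq_len(w), rep(w, r)), drop = FALSE]
  out <- matrix(0, h, w)
  for (j in seq_along(k)) out <- out + k[j] * pad[, j:(j + w - 1L), drop = FALSE]
  # vertical pass
  pad <- out[c(rep(1L, r), seq_len(h), rep(h, r)), , drop = FALSE]
  out <- matrix(0, h, w)
  for (j in seq_along(k)) out <- out + k[j] * pad[j:(j + h - 1L), , drop = FALSE]
  out
}

#' Maximum-intensity projection along z
#'
#' Collapses one channel of a 3-D acquisition to a 2-D image by taking, for
#' every (y, x), the maximum over z-planes — the first step of the cilia
#' detection procedure.
#'
#' @param stack An [image_stack()].
#' @param channel 1-based channel index.
#' @return A numeric matrix `[y, x]`.
#' @export
project_max <- function(stack, channel) {
  assert_that(inherits(stack, "image_stack"), "stack must be an image_stack")
  d <- dim(stack$voxels)
  channel <- assert_number(channel, "channel", min = 1, max = d[1], integerish = TRUE)
  out <- stack$voxels[channel, 1, , ]
  if (d[2] > 1) {
    for (z in 2:d[2]) out <- pmax(out, stack$voxels[channel, z, , ])
  }
  matrix(out, d[3], d[4])
}

# shifted copy of img padded with `fill` (dy, dx in rows/cols)
shift_img <- function(img, dy, dx, fill = -Inf) {
  h <- nrow(img); w <- ncol(img)
  out <- matrix(fill, h, w)
  ys <- seq_len(h) - dy; xs <- seq_len(w) - dx
  ok_y <- ys >= 1 & ys <= h; ok_x <- xs >= 1 & xs <= w
  out[ok_y, ok_x] <- img[ys[ok_y], xs[ok_x]]
  out
}

#' Detect centrosome spots on a projected image
#'
#' Difference-of-Gaussians band-pass at the spot scale, followed by local
#' 8-neighbourhood maximum detection. A candidate is kept when its projected
#' intensity exceeds the image background median plus `min_peak_snr` robust
#' (MAD-based) standard deviations. Maxima closer than `min_separation_px`
#' are resolved by keeping the brighter spot (ties: smaller (y, x)).
#'
#' @param projected 2-D numeric matrix (max-projected centrosome channel).
#' @param spot_sigma_px Spot scale for the band-pass, pixels.
#' @param min_peak_snr Peak threshold in robust sds above background.
#' @param min_separation_px Minimum allowed distance between spots.
#' @return A tibble of spots: `x`, `y` (0-based px), `peak_intensity`.
#' @export
detect_centrosomes <- function(projected, spot_sigma_px = 2, min_peak_snr = 8,
                               min_separation_px = 5) {
  assert_that(is.matrix(projected) && is.numeric(projected),
    "projected must be a numeric matrix")
  spot_sigma_px <- assert_number(spot_sigma_px, "spot_sigma_px", min = 1e-9)
  min_peak_snr <- assert_number(min_peak_snr, "min_peak_snr", min = 0)
  min_separation_px <- assert_number(min_separation_px, "min_separation_px", min = 0)

  empty <- tibble::tibble(x = numeric(0), y = numeric(0), peak_intensity = numeric(0))
  dog <- gaussian_blur(projected, spot_sigma_px) -
    gaussian_blur(projected, 1.6 * spot_sigma_px)

  is_max <- matrix(TRUE, nrow(projected), ncol(projected))
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    is_max <- is_max & (dog >= shift_img(dog, dy, dx))
  }
  # flat image: every pixel is a plateau "maximum" but none exceeds background
  bg_med <- median(projected)
  bg_sd <- mad(projected)
  thr <- bg_med + min_peak_snr * bg_sd
  cand <- which(is_max & projected > thr & dog > 0, arr.ind = TRUE)
  if (nrow(cand) == 0) return(empty)

  peak <- projected[cand]
  yy <- cand[, 1] - 1; xx <- cand[, 2] - 1
  ord <- order(-peak, yy, xx)
  yy <- yy[ord]; xx <- xx[ord]; peak <- peak[ord]
  keep <- logical(length(peak))
  for (i in seq_along(peak)) {
    if (!any(keep)) {
      keep[i] <- TRUE
      next
    }
    d2 <- (xx[keep] - xx[i])^2 + (yy[keep] - yy[i])^2
    keep[i] <- all(d2 >= min_separation_px^2)
  }
  tibble::tibble(x = xx[keep], y = yy[keep], peak_intensity = peak[keep])
}

#' Crop the peri-centrosomal region from the axoneme channel
#'
#' Cuts a square region of physical side `crop_side_um` (default 11 µm,
#' the published region size) centred on a detected centrosome from the
#' max-projected acetylated-tubulin image. The side in pixels is rounded and
#' forced odd so the centrosome occupies the exact centre pixel;
#' out-of-bounds area is padded with the image background median and the
#' crop flagged as padded.
#'
#' @param tubulin_projected 2-D numeric matrix (axoneme channel projection).
#' @param spot_x,spot_y Centrosome position, 0-based pixels.
#' @param pixel_size_um Pixel size, µm/pixel.
#' @param crop_side_um Physical crop side, µm.
#' @return A list: `crop` (matrix), `origin` (0-based `c(x0, y0)` of the
#'   crop's top-left pixel in image coordinates), `padded` (flag).
#' @export
crop_pericentrosomal <- function(tubulin_projected, spot_x, spot_y,
                                 pixel_size_um, crop_side_um = 11) {
  pixel_size_um <- assert_number(pixel_size_um, "pixel_size_um", min = 1e-9)
  crop_side_um <- assert_number(crop_side_um, "crop_side_um", min = 1e-9)
  side <- round(crop_side_um / pixel_size_um)
  if (side %% 2 == 0) side <- side + 1
  assert_that(side >= 3, sprintf("crop side of %d px is too small (< 3 px)", side))
  half <- (side - 1) / 2
  h <- nrow(tubulin_projected); w <- ncol(tubulin_projected)
  cx <- round(spot_x); cy <- round(spot_y)
  ys <- (cy - half):(cy + half) # 0-based
  xs <- (cx - half):(cx + half)
  padded <- any(ys < 0 | ys >= h | xs < 0 | xs >= w)
  crop <- matrix(median(tubulin_projected), side, side)
  ok_y <- ys >= 0 & ys < h; ok_x <- xs >= 0 & xs < w
  crop[which(ok_y), which(ok_x)] <- tubulin_projected[ys[ok_y] + 1, xs[ok_x] + 1]
  list(crop = crop, origin = c(x0 = xs[1], y0 = ys[1]), padded = padded)
}
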