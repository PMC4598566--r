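# Synthetic two-channel ciliogenesis fields with known ground truth.
#
# The generator emulates the acquisitions the detection procedure was built
# for: sparse diffraction-limited centrosome spots (pericentrin-like channel)
# and curved filamentous axonemes of known arc length attached to a subset of
# centrosomes (acetylated-tubulin-like channel), spread over a 10-plane
# z-stack, with Poisson shot noise on signal plus Gaussian read noise.

#' Parameters for a synthetic ciliogenesis field
#'
#' Defaults describe the package's reference "stated world": a ~192 µm
#' square field (600 px at 0.32 µm/px) holding ~100 cells, 10 z-planes,
#' cilium lengths 2–6 µm with bounded curvature, and moderate
#' signal-to-noise (spot amplitude 200, axoneme amplitude 120, background
#' 20 counts, read noise sd 5, Poisson shot noise on everything).
#'
#' @param field_size_px Integer pair `c(height, width)` in pixels.
#' @param pixel_size_um In-plane pixel size, µm/pixel.
#' @param n_centrosomes Number of centrosomes placed.
#' @param ciliation_fraction Fraction of centrosomes bearing a cilium, in
#'   `[0, 1]`; exactly `round(fraction * n)` are ciliated.
#' @param cilium_length_um_range Min/max true axoneme arc length, µm.
#' @param cilium_curvature Maximum direction change per µm of arc, radians.
#' @param spot_intensity,axoneme_intensity,background_level Signal
#'   amplitudes and background, camera counts.
#' @param noise_sd Gaussian read-noise standard deviation, counts.
#' @param n_z Number of z-planes.
#' @param crowded If `TRUE`, disables the minimum-distance constraint
#'   between centrosomes (stress-testing overlapping crops).
#' @param seed Integer seed; the generator is a pure function of
#'   (parameters, seed).
#' @return A validated parameter list of class `field_params`.
#' @export
field_params <- function(field_size_px = c(600, 600),
                         pixel_size_um = 0.32,
                         n_centrosomes = 100,
                         ciliation_fraction = 0.7,
                         cilium_length_um_range = c(2, 6),
                         cilium_curvature = 0.3,
                         spot_intensity = 200,
                         axoneme_intensity = 120,
                         background_level = 20,
                         noise_sd = 5,
                         n_z = 10,
                         crowded = FALSE,
                         seed = 1L) {
  assert_that(length(field_size_px) == 2 && all(is.finite(field_size_px)) &&
    all(abs(field_size_px - round(field_size_px)) < 1e-8) && all(field_size_px >= 32),
    "field_size_px must be a pair of integers >= 32")
  pixel_size_um <- assert_number(pixel_size_um, "pixel_size_um", min = 1e-9)
  n_centrosomes <- assert_number(n_centrosomes, "n_centrosomes", min = 0, integerish = TRUE)
  ciliation_fraction <- assert_number(ciliation_fraction, "ciliation_fraction", min = 0, max = 1)
  assert_that(length(cilium_length_um_range) == 2 &&
    all(cilium_length_um_range > 0) &&
    cilium_length_um_range[1] <= cilium_length_um_range[2],
    "cilium_length_um_range must be positive with min <= max")
  cilium_curvature <- assert_number(cilium_curvature, "cilium_curvature", min = 0)
  spot_intensity <- assert_number(spot_intensity, "spot_intensity", min = 1e-9)
  axoneme_intensity <- assert_number(axoneme_intensity, "axoneme_intensity", min = 1e-9)
  background_level <- assert_number(background_level, "background_level", min = 0)
  noise_sd <- assert_number(noise_sd, "noise_sd", min = 0)
  n_z <- assert_number(n_z, "n_z", min = 1, integerish = TRUE)
  seed <- assert_number(seed, "seed", integerish = TRUE)
  structure(list(
    field_size_px = as.integer(round(field_size_px)),
    pixel_size_um = pixel_size_um, n_centrosomes = n_centrosomes,
    ciliation_fraction = ciliation_fraction,
    cilium_length_um_range = cilium_length_um_range,
    cilium_curvature = cilium_curvature, spot_intensity = spot_intensity,
    axoneme_intensity = axoneme_intensity, background_level = background_level,
    noise_sd = noise_sd, n_z = n_z, crowded = isTRUE(crowded), seed = seed
  ), class = "field_params")
}

# dart-throwing placement with a minimum pairwise distance and edge margin
place_centrosomes <- function(n, h, w, min_dist, margin, max_attempts = 50000L) {
  xs <- numeric(0); ys <- numeric(0)
  attempts <- 0L
  while (length(xs) < n && attempts < max_attempts) {
    attempts <- attempts + 1L
    x <- runif(1, margin, w - 1 - margin)
    y <- runif(1, margin, h - 1 - margin)
    if (length(xs) == 0 || min_dist <= 0 ||
      all((xs - x)^2 + (ys - y)^2 >= min_dist^2)) {
      xs <- c(xs, x); ys <- c(ys, y)
    }
  }
  assert_that(length(xs) == n, sprintf(
    "could not place %d centrosomes at min distance %.1f px in a %dx%d field",
    n, min_dist, h, w))
  cbind(x = xs, y = ys)
}

# random curved polyline of exact arc length, in pixel units; start at (x, y)
cilium_polyline <- function(x, y, length_um, curvature, pixel_size_um,
                            step_um = 0.2) {
  n_steps <- max(1L, ceiling(length_um / step_um))
  ds <- length_um / n_steps
  theta <- runif(1, 0, 2 * pi)
  dtheta <- runif(n_steps, -1, 1) * curvature * ds
  thetas <- theta + cumsum(c(0, dtheta[-n_steps]))
  dx <- cos(thetas) * ds / pixel_size_um
  dy <- sin(thetas) * ds / pixel_size_um
  cbind(x = x + cumsum(c(0, dx)), y = y + cumsum(c(0, dy)))
}

# splat a polyline onto a matrix as a 1-px-wide path (max assignment)
rasterize_polyline <- function(img, poly, value) {
  for (i in seq_len(nrow(poly) - 1L)) {
    p <- poly[i, ]; q <- poly[i + 1L, ]
    n <- max(2L, ceiling(2 * sqrt(sum((q - p)^2))))
    t <- seq(0, 1, length.out = n)
    xs <- round(p[1] + t * (q[1] - p[1])) + 1L
    ys <- round(p[2] + t * (q[2] - p[2])) + 1L
    ok <- xs >= 1 & xs <= ncol(img) & ys >= 1 & ys <= nrow(img)
    idx <- unique((xs[ok] - 1L) * nrow(img) + ys[ok])
    img[idx] <- pmax(img[idx], value)
  }
  img
}

#' Generate a synthetic two-channel ciliogenesis field
#'
#' Renders centrosome spots (channel 1) and axoneme filaments along each
#' ciliated centrosome's polyline (channel 2) into an `n_z`-plane stack.
#' Signal is distributed across z with a Gaussian focal profile, blurred
#' in-plane by a small Gaussian kernel, then corrupted by Poisson shot noise
#' on signal-plus-background and additive Gaussian read noise (clamped at
#' zero). Exactly `round(ciliation_fraction * n_centrosomes)` centrosomes
#' carry an axoneme whose true arc length is recorded in the ground truth.
#' The same parameters and seed always reproduce the identical field.
#'
#' @param params A [field_params()] object.
#' @return A list of class `cilia_field_sim` with `stack` (an
#'   [image_stack()], channels `centrosome`, `axoneme`) and `truth`, a
#'   tibble with one row per centrosome: `id`, `x`, `y` (0-based px),
#'   `ciliated`, `true_length_um`, plus list-columns `polyline` (n x 2
#'   pixel coordinates) and `axoneme_px` (rendered axoneme pixel indices,
#'   `[row, col]` 1-based).
#' @export
generate_cilia_field <- function(params = field_params()) {
  assert_that(inherits(params, "field_params"), "params must come from field_params()")
  p <- params
  with_seed(p$seed, {
    h <- p$field_size_px[1]; w <- p$field_size_px[2]
    crop_px <- round(11 / p$pixel_size_um)
    if (crop_px %% 2 == 0) crop_px <- crop_px + 1
    min_dist <- if (p$crowded) 0 else crop_px - 1 # 2 x crop half-width
    margin <- min(floor((crop_px - 1) / 2) + 2, floor(min(h, w) / 4))
    n_cil <- round(p$ciliation_fraction * p$n_centrosomes)

    truth <- tibble::tibble(id = integer(0), x = numeric(0), y = numeric(0),
      ciliated = logical(0), true_length_um = numeric(0),
      polyline = list(), axoneme_px = list())
    signal <- array(0, dim = c(2, p$n_z, h, w))
    if (p$n_centrosomes > 0) {
      pos <- place_centrosomes(p$n_centrosomes, h, w, min_dist, margin)
      ciliated <- rep(FALSE, p$n_centrosomes)
      if (n_cil > 0) ciliated[sample.int(p$n_centrosomes, n_cil)] <- TRUE
      lengths <- ifelse(ciliated,
        runif(p$n_centrosomes, p$cilium_length_um_range[1], p$cilium_length_um_range[2]),
        0)
      z0 <- runif(p$n_centrosomes, 1.5, p$n_z - 0.5)

      # per-object sharp renders, accumulated with per-z focal weights
      spot_sigma <- 1.5
      rr <- 4L
      polylines <- vector("list", p$n_centrosomes)
      ax_px <- vector("list", p$n_centrosomes)
      spot_plane <- matrix(0, h, w)
      ax_planes <- lapply(seq_len(p$n_z), function(z) matrix(0, h, w))
      zw_all <- matrix(0, p$n_centrosomes, p$n_z)
      for (i in seq_len(p$n_centrosomes)) {
        zw <- exp(-((seq_len(p$n_z) - z0[i])^2) / 2)
        zw_all[i, ] <- zw / max(zw)
      }
      for (i in seq_len(p$n_centrosomes)) {
        cx <- pos[i, 1]; cy <- pos[i, 2]
        # Gaussian spot footprint
        x_lo <- max(0, round(cx) - rr); x_hi <- min(w - 1, round(cx) + rr)
        y_lo <- max(0, round(cy) - rr); y_hi <- min(h - 1, round(cy) + rr)
        gx <- x_lo:x_hi; gy <- y_lo:y_hi
        g <- p$spot_intensity *
          outer(exp(-((gy - cy)^2) / (2 * spot_sigma^2)),
                exp(-((gx - cx)^2) / (2 * spot_sigma^2)))
        for (z in seq_len(p$n_z)) {
          wz <- zw_all[i, z]
          if (wz < 1e-3) next
          signal[1, z, gy + 1, gx + 1] <- signal[1, z, gy + 1, gx + 1] + wz * g
        }
        if (ciliated[i]) {
          poly <- cilium_polyline(cx, cy, lengths[i], p$cilium_curvature,
            p$pixel_size_um)
          polylines[[i]] <- poly
          line_img <- rasterize_polyline(matrix(0, h, w), poly, p$axoneme_intensity)
          px <- which(line_img > 0, arr.ind = TRUE)
          ax_px[[i]] <- px
          for (z in seq_len(p$n_z)) {
            wz <- zw_all[i, z]
            if (wz < 1e-3) next
            ax_planes[[z]][px] <- pmax(ax_planes[[z]][px], wz * p$axoneme_intensity)
          }
        } else {
          polylines[[i]] <- matrix(numeric(0), 0, 2, dimnames = list(NULL, c("x", "y")))
          ax_px[[i]] <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("row", "col")))
        }
      }
      for (z in seq_len(p$n_z)) {
        signal[2, z, , ] <- gaussian_blur(ax_planes[[z]], 0.7)
      }
      truth <- tibble::tibble(
        id = seq_len(p$n_centrosomes),
        x = pos[, 1], y = pos[, 2],
        ciliated = ciliated, true_length_um = lengths,
        polyline = polylines, axoneme_px = ax_px
      )
    }
    # camera model: Poisson(signal + background) + Gaussian read noise
    vox <- array(0, dim = dim(signal))
    n_vox <- length(signal)
    lambda <- signal + p$background_level
    noisy <- rpois(n_vox, as.vector(lambda))
    if (p$noise_sd > 0) noisy <- noisy + rnorm(n_vox, 0, p$noise_sd)
    vox[] <- pmax(noisy, 0)
    stack <- image_stack(vox, p$pixel_size_um,
      channel_names = c("centrosome", "axoneme"))
    structure(list(stack = stack, truth = truth, params = p),
      class = "cilia_field_sim")
  })
}
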