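# Circular statistics for orientation-vector analysis.
#
# All user-facing angles are degrees in [0, 360), measured counterclockwise
# from the +x axis in a y-up (mathematical) frame. Data stored in image
# convention (y down) must be flipped once, at vector construction
# (see vector_angle(..., frame = "image")).

#' Angle of an orientation vector
#'
#' Computes the direction of the vector from `base` to `tip`, in degrees
#' counterclockwise from the +x axis. This is the angle analysed for basal
#' rootlet orientation vectors (BROVs) and basal body orientation vectors
#' (BBOVs).
#'
#' Coordinates may be supplied in the mathematical frame (y up,
#' `frame = "math"`, the default) or in image-storage convention (y down,
#' `frame = "image"`), in which case the y axis is flipped before the angle
#' is taken. The flip happens here and nowhere else.
#'
#' @param base,tip Numeric length-2 vectors `c(x, y)`, or two-column matrices
#'   of matching size for vectorised use.
#' @param frame `"math"` (y up) or `"image"` (y down).
#' @return Angle(s) in degrees in `[0, 360)`.
#' @examples
#' vector_angle(c(0, 0), c(1, 1)) # 45
#' @export
vector_angle <- function(base, tip, frame = c("math", "image")) {
  frame <- match.arg(frame)
  base <- matrix(as.numeric(base), ncol = 2)
  tip <- matrix(as.numeric(tip), ncol = 2)
  assert_that(nrow(base) == nrow(tip), "base and tip must have matching length")
  dx <- tip[, 1] - base[, 1]
  dy <- tip[, 2] - base[, 2]
  if (frame == "image") dy <- -dy
  degen <- dx == 0 & dy == 0
  assert_that(!any(degen), "degenerate vector: base and tip coincide")
  wrap_deg(rad2deg(atan2(dy, dx)))
}

#' Circular mean and resultant length
#'
#' The circular mean is the direction of the vector sum of unit vectors at
#' the given angles; `r` is the mean resultant length in `[0, 1]`. When the
#' angles balance exactly (`r` numerically zero) the mean direction is
#' undefined and reported as `NA` with `defined = FALSE`.
#'
#' @param angles_deg Numeric vector of angles in degrees; must be non-empty.
#' @return A list with `mean_deg` (in `[0, 360)` or `NA`), `r`, and `defined`.
#' @examples
#' circular_mean(c(350, 10))$mean_deg # 0
#' @export
circular_mean <- function(angles_deg) {
  assert_that(is.numeric(angles_deg) && length(angles_deg) >= 1L &&
    all(is.finite(angles_deg)), "angles must be a non-empty finite numeric vector")
  th <- deg2rad(angles_deg)
  c_bar <- mean(cos(th))
  s_bar <- mean(sin(th))
  r <- sqrt(c_bar^2 + s_bar^2)
  if (r < 1e-12) {
    return(list(mean_deg = NA_real_, r = r, defined = FALSE))
  }
  list(mean_deg = wrap_deg(rad2deg(atan2(s_bar, c_bar))), r = r, defined = TRUE)
}

#' Circular standard deviation
#'
#' The Mardia circular standard deviation, \eqn{\sqrt{-2 \ln R}} where
#' \eqn{R} is the mean resultant length, converted to degrees. This is the
#' per-cell (rotational polarity) and per-field (translational polarity)
#' dispersion statistic: 0 for perfectly aligned vectors, growing without
#' bound as the angles approach uniformity. The angular-deviation
#' \eqn{\sqrt{2(1-R)}} variant is deliberately not used.
#'
#' @param angles_deg Numeric vector of angles in degrees; non-empty.
#' @return CSD in degrees, or `Inf` when `R` is numerically zero
#'   (maximal dispersion), with a warning.
#' @examples
#' circular_sd(c(0, 90)) # 47.71...
#' @export
circular_sd <- function(angles_deg) {
  cm <- circular_mean(angles_deg)
  if (cm$r < 1e-12) {
    warn("mean resultant length is 0; circular SD is infinite")
    return(Inf)
  }
  rad2deg(sqrt(-2 * log(cm$r)))
}

#' Normalize a group of angles to a 90-degree circular mean
#'
#' Re-centres each group of angles so its circular mean sits at 90 degrees:
#' each angle has the group circular mean subtracted and 90 degrees added,
#' modulo 360. This is the normalization applied before pooling angles from
#' different cells (rotational polarity) or fields of view (translational
#' polarity) into one rose plot, so that between-group mean differences do
#' not masquerade as dispersion.
#'
#' @param angles_deg Numeric vector of angles in degrees (one group).
#' @return Normalized angles in `[0, 360)` with circular mean 90.
#' @examples
#' normalize_angles(c(80, 100)) # unchanged: mean already 90
#' @export
normalize_angles <- function(angles_deg) {
  cm <- circular_mean(angles_deg)
  assert_that(cm$defined, "group circular mean undefined (resultant length 0); cannot normalize")
  wrap_deg(angles_deg - cm$mean_deg + 90)
}

#' Bin angles for a rose plot
#'
#' Equal-width bins over `[0, 360)`, left-closed and right-open, the binning
#' behind the package's rose-plot displays.
#'
#' @param angles_deg Numeric vector of angles in degrees (wrapped into
#'   `[0, 360)` first). May be empty.
#' @param n_bins Number of bins, at least 1. Default 24 (15-degree sectors).
#' @return A tibble with `bin_start_deg`, `bin_end_deg`, `count`.
#' @export
angle_histogram <- function(angles_deg, n_bins = 24) {
  n_bins <- assert_number(n_bins, "n_bins", min = 1, integerish = TRUE)
  edges <- seq(0, 360, length.out = n_bins + 1L)
  counts <- integer(n_bins)
  if (length(angles_deg) > 0) {
    a <- wrap_deg(angles_deg)
    idx <- pmin(findInterval(a, edges), n_bins) # a < 360 so only guard rounding
    counts <- tabulate(idx, nbins = n_bins)
  }
  tibble::tibble(
    bin_start_deg = edges[-(n_bins + 1L)],
    bin_end_deg = edges[-1L],
    count = counts
  )
}

# closed-form CSD of a von Mises distribution with concentration kappa:
# R = I1(kappa)/I0(kappa), CSD = sqrt(-2 log R) (degrees). Used by tests and
# documented for users checking calibration.

#' Theoretical circular SD of a von Mises distribution
#'
#' Evaluates \eqn{\sqrt{-2 \ln(I_1(\kappa)/I_0(\kappa))}} in degrees, the
#' population circular standard deviation of a von Mises distribution with
#' concentration `kappa`. Useful for checking empirical CSDs from simulated
#' orientation data.
#'
#' @param kappa Non-negative concentration parameter.
#' @return CSD in degrees (`Inf` for `kappa = 0`).
#' @export
von_mises_csd <- function(kappa) {
  kappa <- assert_number(kappa, "kappa", min = 0)
  if (kappa == 0) {
    return(Inf)
  }
  # expon.scaled avoids overflow at large kappa; the scaling cancels in the ratio
  r <- besselI(kappa, 1, expon.scaled = TRUE) / besselI(kappa, 0, expon.scaled = TRUE)
  rad2deg(sqrt(-2 * log(r)))
}

#' Draw angles from a von Mises distribution
#'
#' Best–Fisher (1979) wrapped-Cauchy rejection sampler. `kappa = 0` reduces
#' to the uniform distribution on the circle. Angles are returned in degrees
#' in `[0, 360)`.
#'
#' @param n Number of draws.
#' @param mu_deg Mean direction in degrees.
#' @param kappa Non-negative concentration.
#' @return Numeric vector of `n` angles in degrees.
#' @export
rvonmises_deg <- function(n, mu_deg, kappa) {
  n <- assert_number(n, "n", min = 0, integerish = TRUE)
  kappa <- assert_number(kappa, "kappa", min = 0)
  mu <- deg2rad(mu_deg)
  if (n == 0L) {
    return(numeric(0))
  }
  if (kappa == 0) {
    return(wrap_deg(runif(n, 0, 360)))
  }
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- runif(1)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      u3 <- runif(1)
      out[i] <- mu + sign(u3 - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  wrap_deg(rad2deg(out))
}
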