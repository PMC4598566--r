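# Segmentation, region growing, skeletonization and geodesic length — steps
# 4-6 of the cilia detection procedure.

# label 8-connected components of a logical matrix; returns integer matrix
# (0 = background). Breadth-first flood fill, adequate for crop-sized masks.
label_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  labels <- matrix(0L, h, w)
  nb_dy <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  nb_dx <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  current <- 0L
  todo <- which(mask)
  for (s in todo) {
    if (labels[s] != 0L) next
    current <- current + 1L
    frontier <- s
    labels[s] <- current
    while (length(frontier) > 0) {
      ys <- ((frontier - 1L) %% h) + 1L
      xs <- ((frontier - 1L) %/% h) + 1L
      ny <- rep(ys, each = 8L) + nb_dy
      nx <- rep(xs, each = 8L) + nb_dx
      ok <- ny >= 1L & ny <= h & nx >= 1L & nx <= w
      idx <- (nx[ok] - 1L) * h + ny[ok]
      idx <- unique(idx[mask[idx] & labels[idx] == 0L])
      labels[idx] <- current
      frontier <- idx
    }
  }
  labels
}

# binary dilation with a (2r+1) square structuring element
dilate_mask <- function(mask, r = 1L) {
  out <- mask
  for (dy in -r:r) for (dx in -r:r) {
    if (dy == 0 && dx == 0) next
    out <- out | shift_img(mask, dy, dx, fill = FALSE)
  }
  out
}

#' Segment the bright proximal axoneme cluster in a crop
#'
#' Thresholds the peri-centrosomal crop at its `seed_quantile` intensity
#' quantile (strictly above, so a constant crop yields nothing) and keeps
#' the 8-connected component nearest the crop centre with area at least
#' `min_seed_px`. This bright cluster marks the proximal part of the ciliary
#' axoneme and seeds the region growing of [grow_axoneme()].
#'
#' @param crop Numeric matrix (odd-sided peri-centrosomal crop).
#' @param seed_quantile Intensity quantile in (0, 1) for the threshold.
#' @param min_seed_px Minimum component area, pixels.
#' @return Logical matrix of the seed (all `FALSE` when nothing qualifies).
#' @export
segment_proximal_cluster <- function(crop, seed_quantile = 0.99, min_seed_px = 3) {
  assert_that(is.matrix(crop) && is.numeric(crop), "crop must be a numeric matrix")
  seed_quantile <- assert_number(seed_quantile, "seed_quantile", min = 1e-9, max = 1 - 1e-9)
  min_seed_px <- assert_number(min_seed_px, "min_seed_px", min = 1, integerish = TRUE)
  thr <- stats::quantile(crop, seed_quantile, names = FALSE)
  mask <- crop > thr
  if (!any(mask)) return(mask)
  labels <- label_components(mask)
  areas <- tabulate(labels[labels > 0])
  ok <- which(areas >= min_seed_px)
  if (length(ok) == 0) return(matrix(FALSE, nrow(crop), ncol(crop)))
  # nearest component: minimal pixel distance to the crop centre
  cy <- (nrow(crop) + 1) / 2; cx <- (ncol(crop) + 1) / 2
  best <- ok[which.min(vapply(ok, function(l) {
    px <- which(labels == l, arr.ind = TRUE)
    min((px[, 1] - cy)^2 + (px[, 2] - cx)^2)
  }, numeric(1)))]
  labels == best
}

#' Grow the full axoneme mask from a seed by contrast-based region growing
#'
#' Iteratively admits 8-connected border pixels whose intensity is at least
#' `contrast_stop_ratio` times the local background, where the background is
#' the median of crop pixels outside the current mask dilated by 2 px.
#' Growing stops when no border pixel passes or after `max_iterations`.
#' The result is always a superset of the seed; an empty seed returns an
#' empty mask with a warning.
#'
#' @param crop Numeric matrix.
#' @param seed Logical matrix (from [segment_proximal_cluster()]).
#' @param contrast_stop_ratio Required intensity-to-background ratio (> 1).
#' @param max_iterations Iteration cap.
#' @return Logical axoneme mask.
#' @export
grow_axoneme <- function(crop, seed, contrast_stop_ratio = 1.5, max_iterations = 50) {
  contrast_stop_ratio <- assert_number(contrast_stop_ratio, "contrast_stop_ratio", min = 1 + 1e-9)
  max_iterations <- assert_number(max_iterations, "max_iterations", min = 0, integerish = TRUE)
  assert_that(is.matrix(seed) && all(dim(seed) == dim(crop)),
    "seed must be a logical matrix matching the crop")
  if (!any(seed)) {
    warn("empty seed: returning empty axoneme mask")
    return(seed)
  }
  mask <- seed
  iter <- 0L
  while (iter < max_iterations) {
    outside <- !dilate_mask(mask, 2L)
    if (!any(outside)) break
    bg <- max(median(crop[outside]), 1e-6)
    border <- dilate_mask(mask, 1L) & !mask
    admit <- border & (crop >= bg * contrast_stop_ratio)
    if (!any(admit)) break
    mask <- mask | admit
    iter <- iter + 1L
  }
  mask
}

# Thinning to a 1-px-wide, 8-connected skeleton: the Lam-Lee-Suen G123
# two-subcycle parallel algorithm (crossing-number condition G1, neighbour
# count G2, alternating directional conditions G3/G3'). Unlike naive
# parallel Zhang-Suen, it does not annihilate 2-px-wide diagonal bands or
# 2x2 staircases, which is exactly the geometry of thresholded thin
# filaments; line endpoints are preserved.
skeletonize <- function(mask) {
  m <- mask
  repeat {
    changed <- FALSE
    for (subcycle in 1:2) {
      # neighbours x1..x8 counterclockwise from east
      g <- function(dy, dx) shift_img(m, -dy, -dx, FALSE)
      x1 <- g(0L, 1L); x2 <- g(-1L, 1L); x3 <- g(-1L, 0L); x4 <- g(-1L, -1L)
      x5 <- g(0L, -1L); x6 <- g(1L, -1L); x7 <- g(1L, 0L); x8 <- g(1L, 1L)
      xh <- (!x1 & (x2 | x3)) + (!x3 & (x4 | x5)) +
        (!x5 & (x6 | x7)) + (!x7 & (x8 | x1))
      n1 <- (x1 | x2) + (x3 | x4) + (x5 | x6) + (x7 | x8)
      n2 <- (x2 | x3) + (x4 | x5) + (x6 | x7) + (x8 | x1)
      nmin <- pmin(n1, n2)
      g3 <- if (subcycle == 1) {
        !((x2 | x3 | !x8) & x1)
      } else {
        !((x6 | x7 | !x4) & x5)
      }
      cond <- m & xh == 1 & nmin >= 2 & nmin <= 3 & g3
      if (any(cond)) {
        m[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

#' Measure axoneme length from a segmented mask
#'
#' Thins the axoneme mask to a 1-px skeleton and reports the longest
#' geodesic path through it: the maximum over pixel pairs of the shortest
#' path, with step cost 1 for axial and sqrt(2) for diagonal moves, scaled
#' by the pixel size. An empty mask has length 0; a single-pixel skeleton
#' likewise (no steps to take).
#'
#' @param mask Logical axoneme mask.
#' @param pixel_size_um Pixel size, µm/pixel.
#' @return Length in µm.
#' @export
measure_axoneme_length <- function(mask, pixel_size_um) {
  pixel_size_um <- assert_number(pixel_size_um, "pixel_size_um", min = 1e-9)
  if (!any(mask)) return(0)
  skel <- skeletonize(mask)
  px <- which(skel, arr.ind = TRUE)
  n <- nrow(px)
  if (n < 2) return(0)
  # edges between 8-neighbouring skeleton pixels
  key <- (px[, 2] - 1L) * nrow(mask) + px[, 1] # linear index
  idx_of <- setNames(seq_len(n), key)
  from <- integer(0); to <- integer(0); wgt <- numeric(0)
  offs <- rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1)) # half the moves: no duplicates
  for (k in seq_len(4)) {
    ny <- px[, 1] + offs[k, 1]; nx <- px[, 2] + offs[k, 2]
    ok <- ny >= 1 & ny <= nrow(mask) & nx >= 1 & nx <= ncol(mask)
    nk <- (nx - 1L) * nrow(mask) + ny
    hit <- ok & !is.na(idx_of[as.character(nk)])
    if (any(hit)) {
      from <- c(from, which(hit))
      to <- c(to, unname(idx_of[as.character(nk[hit])]))
      wgt <- c(wgt, rep(if (all(offs[k, ] != 0)) sqrt(2) else 1, sum(hit)))
    }
  }
  if (length(from) == 0) return(0)
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, weight = wgt),
    directed = FALSE, vertices = data.frame(name = seq_len(n))
  )
  d <- igraph::distances(g)
  max(d[is.finite(d)]) * pixel_size_um
}
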