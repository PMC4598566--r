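# Rotational (per-cell rootlet alignment) and translational (per-field
# basal-body displacement) polarity analysis.

# even-odd ray-casting point-in-polygon, vectorised over points
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# uniform-area (shoelace) centroid of a simple polygon
polygon_centroid <- function(vx, vy) {
  n <- length(vx)
  j <- c(2:n, 1)
  cross <- vx * vy[j] - vx[j] * vy
  area2 <- sum(cross)
  if (abs(area2) < 1e-12) {
    return(c(x = mean(vx), y = mean(vy))) # degenerate: fall back to vertex mean
  }
  c(x = sum((vx + vx[j]) * cross) / (3 * area2),
    y = sum((vy + vy[j]) * cross) / (3 * area2))
}

# mean filter with a square window, averaging over in-bounds pixels only
box_mean <- function(img, window_px) {
  r <- (window_px - 1) %/% 2
  h <- nrow(img); w <- ncol(img)
  # integral images with a zero top/left border
  int <- matrix(0, h + 1, w + 1)
  int[-1, -1] <- apply(apply(img, 2, cumsum), 1, cumsum) |> t()
  cnt <- matrix(0, h + 1, w + 1)
  cnt[-1, -1] <- apply(apply(matrix(1, h, w), 2, cumsum), 1, cumsum) |> t()
  y1 <- pmax(seq_len(h) - r, 1); y2 <- pmin(seq_len(h) + r, h)
  x1 <- pmax(seq_len(w) - r, 1); x2 <- pmin(seq_len(w) + r, w)
  s <- int[y2 + 1, x2 + 1] - int[y1, x2 + 1] - int[y2 + 1, x1] + int[y1, x1]
  m <- cnt[y2 + 1, x2 + 1] - cnt[y1, x2 + 1] - cnt[y2 + 1, x1] + cnt[y1, x1]
  s / m
}

#' Segment the basal-body patch inside a cell outline
#'
#' Adaptive local-mean thresholding of the gamma-tubulin channel: a pixel is
#' kept when its intensity exceeds the mean of a square `window_px`
#' neighbourhood by more than `offset`. The result is masked to the
#' interior of the traced cell outline and the largest 8-connected
#' component is retained as the basal-body patch.
#'
#' @param gamma_tubulin 2-D numeric matrix.
#' @param roi Two-column matrix or data frame of polygon vertices
#'   (`x`, `y`, 0-based pixel-centre coordinates).
#' @param window_px Adaptive window side, pixels (odd; default 51).
#' @param offset Intensity offset over the local mean (default 0).
#' @return Logical matrix; all-`FALSE` (with attribute `empty = TRUE`) when
#'   no pixel passes.
#' @export
segment_basal_bodies <- function(gamma_tubulin, roi, window_px = 51, offset = 0) {
  assert_that(is.matrix(gamma_tubulin) && is.numeric(gamma_tubulin),
    "gamma_tubulin must be a numeric matrix")
  window_px <- assert_number(window_px, "window_px", min = 3, integerish = TRUE)
  roi <- as.matrix(as.data.frame(roi)[, 1:2])
  assert_that(nrow(roi) >= 3, "ROI polygon needs at least 3 vertices")
  h <- nrow(gamma_tubulin); w <- ncol(gamma_tubulin)

  idx <- which(matrix(TRUE, h, w), arr.ind = TRUE)
  px <- idx[, 2] - 1; py <- idx[, 1] - 1 # 0-based pixel centres
  roi_mask <- matrix(point_in_polygon(px, py, roi[, 1], roi[, 2]), h, w)
  assert_that(any(roi_mask), "ROI polygon lies fully outside the image")

  local_mean <- box_mean(gamma_tubulin, window_px)
  mask <- (gamma_tubulin > local_mean + offset) & roi_mask
  if (!any(mask)) {
    out <- matrix(FALSE, h, w)
    attr(out, "empty") <- TRUE
    return(out)
  }
  labels <- label_components(mask)
  areas <- tabulate(labels[labels > 0])
  out <- labels == which.max(areas)
  attr(out, "empty") <- FALSE
  out
}

#' Basal-body orientation vector angle
#'
#' The BBOV points from the uniform-area centroid of the traced cell
#' outline to the (intensity-unweighted) pixel centroid of the segmented
#' basal-body patch; its angle is returned in the y-up mathematical frame
#' (image-storage y-down coordinates are flipped here).
#'
#' @param roi Two-column vertex matrix (`x`, `y`, image coordinates).
#' @param bb_mask Logical basal-body patch from [segment_basal_bodies()].
#' @return Angle in degrees in `[0, 360)`, or `NA` with a warning when the
#'   two centroids coincide (degenerate, excluded from analysis).
#' @export
bbov <- function(roi, bb_mask) {
  roi <- as.matrix(as.data.frame(roi)[, 1:2])
  assert_that(any(bb_mask), "empty basal-body patch")
  cc <- polygon_centroid(roi[, 1], roi[, 2])
  px <- which(bb_mask, arr.ind = TRUE)
  bb <- c(x = mean(px[, 2] - 1), y = mean(px[, 1] - 1))
  if (sqrt(sum((bb - cc)^2)) < 1e-9) {
    warn("BB patch centroid coincides with cell centroid; BBOV undefined")
    return(NA_real_)
  }
  vector_angle(cc, bb, frame = "image")
}

# shared machinery: per-group CSD + condition roll-up + Mann-Whitney
polarity_core <- function(angles_tbl, group_col, kind, n_bins) {
  groups <- angles_tbl |>
    dplyr::group_by(.data$condition, group_id = .data[[group_col]]) |>
    dplyr::summarise(n_vectors = dplyr::n(),
      csd_deg = circular_sd(.data$angle_deg), .groups = "drop")
  small <- groups$n_vectors < 2
  if (any(small)) {
    warn(sprintf("%d group(s) with a single vector excluded from CSD analysis",
      sum(small)))
    groups <- groups[!small, ]
  }
  conditions <- groups |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(
      mean_csd_deg = mean(.data$csd_deg),
      sd_csd_deg = if (dplyr::n() >= 2) stats::sd(.data$csd_deg) else NA_real_,
      n_groups = dplyr::n(), .groups = "drop"
    )
  # pooled rose-plot angles: normalize within group, then pool per condition
  angles <- angles_tbl |>
    dplyr::semi_join(groups, by = c("condition", stats::setNames("group_id", group_col))) |>
    dplyr::group_by(.data$condition, .data[[group_col]]) |>
    dplyr::mutate(normalized_deg = normalize_angles(.data$angle_deg)) |>
    dplyr::ungroup()
  histograms <- angles |>
    dplyr::group_by(.data$condition) |>
    dplyr::reframe(angle_histogram(.data$normalized_deg, n_bins))
  conds <- unique(groups$condition)
  test <- NULL
  if (length(conds) == 2) {
    mw <- mann_whitney(groups$csd_deg[groups$condition == conds[1]],
      groups$csd_deg[groups$condition == conds[2]])
    test <- tibble::tibble(condition_a = conds[1], condition_b = conds[2],
      U = mw$U, p_value = mw$p_value, method = mw$method)
  }
  structure(list(groups = groups, conditions = conditions, angles = angles,
    histograms = histograms, test = test, kind = kind),
    class = "polarity_summary")
}

#' Rotational polarity summary
#'
#' Quantifies how well basal rootlet orientation vectors align *within*
#' cells: each traced vector's angle is computed, the circular standard
#' deviation (CSD) is taken per cell, and each condition is characterised
#' by the mean ± s.d. of CSDs across its cells. Angles are normalized per
#' cell to a 90° circular mean and pooled per condition for rose-plot
#' display. With exactly two conditions, per-cell CSDs are compared with a
#' two-sided Mann–Whitney test. Cells with a single vector are excluded
#' with a warning.
#'
#' @param vectors Tibble with `condition`, `cell_id`, `base_x`, `base_y`,
#'   `tip_x`, `tip_y` (see [read_vectors()] / [generate_polarity_cells()]).
#' @param frame Coordinate convention of the traced points: `"math"`
#'   (y up, default) or `"image"` (y down).
#' @param n_bins Rose-plot bins (default 24).
#' @return A `polarity_summary` object: tibbles `groups` (per-cell CSD),
#'   `conditions` (mean ± sd CSD), `angles` (pooled normalized angles),
#'   `histograms`, and `test` (Mann–Whitney, when two conditions).
#' @export
rotational_polarity_summary <- function(vectors, frame = c("math", "image"),
                                        n_bins = 24) {
  frame <- match.arg(frame)
  assert_cols(vectors, c("cell_id", "base_x", "base_y", "tip_x", "tip_y"),
    "vectors")
  if (!"condition" %in% names(vectors)) vectors$condition <- "all"
  angles_tbl <- vectors |>
    dplyr::mutate(angle_deg = vector_angle(
      cbind(.data$base_x, .data$base_y), cbind(.data$tip_x, .data$tip_y),
      frame = frame
    )) |>
    dplyr::select("condition", "cell_id", "angle_deg")
  polarity_core(angles_tbl, "cell_id", "rotational", n_bins)
}

#' Translational polarity summary
#'
#' Quantifies tissue-level coordination of basal-body patch displacement:
#' BBOV angles are grouped per field of view, the CSD is taken across all
#' BBOVs within each field, and each condition is characterised by the
#' mean ± s.d. of field CSDs. Normalization to a 90° circular mean is
#' applied per field before pooling; two conditions are compared by
#' Mann–Whitney on field CSDs. Fields with fewer than two valid BBOVs are
#' excluded with a warning.
#'
#' @param bbov_angles Tibble with `condition`, `field_id`, `angle_deg`
#'   (degrees; e.g. assembled from [bbov()] over segmented cells).
#' @param n_bins Rose-plot bins.
#' @return A `polarity_summary` object (see
#'   [rotational_polarity_summary()]), grouped by field instead of cell.
#' @export
translational_polarity_summary <- function(bbov_angles, n_bins = 24) {
  assert_cols(bbov_angles, c("field_id", "angle_deg"), "bbov_angles")
  if (!"condition" %in% names(bbov_angles)) bbov_angles$condition <- "all"
  angles_tbl <- bbov_angles |>
    dplyr::filter(is.finite(.data$angle_deg)) |>
    dplyr::select("condition", "field_id", "angle_deg")
  polarity_core(angles_tbl, "field_id", "translational", n_bins)
}

#' @export
print.polarity_summary <- function(x, ...) {
  cat(sprintf("<polarity_summary> (%s polarity)\n", x$kind))
  print(x$conditions)
  if (!is.null(x$test)) {
    cat(sprintf("Mann-Whitney (%s): U = %g, p = %.4g\n",
      x$test$method, x$test$U, x$test$p_value))
  }
  invisible(x)
}
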