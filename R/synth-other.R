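# Synthetic generators for orientation vectors, bead tracks and LUMIER tables.

#' Generate per-cell orientation vectors with von Mises dispersion
#'
#' Emulates manually traced base-to-tip vectors (e.g. basal rootlet to basal
#' body lines) grouped by cell. Each cell receives a mean direction (a
#' global direction plus Gaussian between-cell spread); each vector's angle
#' is drawn from a von Mises distribution around its cell mean with
#' concentration `kappa` (`kappa = 0` gives uniform angles). Base points sit
#' on a jittered grid; tips are base plus the unit vector at the drawn
#' angle, in the y-up mathematical frame.
#'
#' @param n_cells,vectors_per_cell Positive integers.
#' @param kappa Non-negative von Mises concentration.
#' @param cell_mean_spread_deg SD of cell means about the global direction,
#'   degrees.
#' @param seed Integer seed.
#' @return A tibble: `cell_id`, `base_x`, `base_y`, `tip_x`, `tip_y`,
#'   `true_angle_deg`, `true_cell_mean_deg`.
#' @export
generate_polarity_cells <- function(n_cells, vectors_per_cell, kappa,
                                    cell_mean_spread_deg = 20, seed = 1L) {
  n_cells <- assert_number(n_cells, "n_cells", min = 1, integerish = TRUE)
  vectors_per_cell <- assert_number(vectors_per_cell, "vectors_per_cell",
    min = 1, integerish = TRUE)
  kappa <- assert_number(kappa, "kappa", min = 0)
  cell_mean_spread_deg <- assert_number(cell_mean_spread_deg,
    "cell_mean_spread_deg", min = 0)
  seed <- assert_number(seed, "seed", integerish = TRUE)
  with_seed(seed, {
    global <- runif(1, 0, 360)
    grid_n <- ceiling(sqrt(n_cells))
    cell_px <- 12 # grid pitch in px
    purrr::map_dfr(seq_len(n_cells), function(i) {
      mu <- wrap_deg(global + rnorm(1, 0, cell_mean_spread_deg))
      gx <- ((i - 1) %% grid_n) * cell_px
      gy <- ((i - 1) %/% grid_n) * cell_px
      ang <- rvonmises_deg(vectors_per_cell, mu, kappa)
      bx <- gx + runif(vectors_per_cell, 2, cell_px - 2)
      by <- gy + runif(vectors_per_cell, 2, cell_px - 2)
      tibble::tibble(
        cell_id = sprintf("cell%03d", i),
        base_x = bx, base_y = by,
        tip_x = bx + cos(deg2rad(ang)),
        tip_y = by + sin(deg2rad(ang)),
        true_angle_deg = ang, true_cell_mean_deg = mu
      )
    })
  })
}

#' Generate directed-plus-diffusive bead tracks
#'
#' Emulates microsphere trajectories in cilia-driven flow: each track drifts
#' at `speed_um_s` along a fixed random heading, with isotropic Gaussian
#' positional jitter of sd `diffusion_sd_um` added independently per frame.
#' `diffusion_sd_um = 0` gives perfectly straight tracks.
#'
#' @param n_tracks Number of tracks.
#' @param speed_um_s Drift speed, µm/s.
#' @param diffusion_sd_um Per-frame isotropic jitter sd, µm.
#' @param n_frames Frames per track (>= 2).
#' @param frame_interval_s Frame interval, seconds (default 1/37 s, the
#'   acquisition rate of the emulated movies).
#' @param seed Integer seed.
#' @return A tibble `track_id`, `frame`, `x`, `y` (µm) with attribute
#'   `frame_interval_s`.
#' @export
generate_bead_tracks <- function(n_tracks, speed_um_s, diffusion_sd_um,
                                 n_frames, frame_interval_s = 1 / 37, seed = 1L) {
  n_tracks <- assert_number(n_tracks, "n_tracks", min = 1, integerish = TRUE)
  speed_um_s <- assert_number(speed_um_s, "speed_um_s", min = 0)
  diffusion_sd_um <- assert_number(diffusion_sd_um, "diffusion_sd_um", min = 0)
  n_frames <- assert_number(n_frames, "n_frames", min = 2, integerish = TRUE)
  frame_interval_s <- assert_number(frame_interval_s, "frame_interval_s", min = 1e-12)
  seed <- assert_number(seed, "seed", integerish = TRUE)
  with_seed(seed, {
    out <- purrr::map_dfr(seq_len(n_tracks), function(i) {
      heading <- runif(1, 0, 2 * pi)
      step <- speed_um_s * frame_interval_s
      x0 <- runif(1, 0, 100); y0 <- runif(1, 0, 100)
      t <- 0:(n_frames - 1)
      x <- x0 + t * step * cos(heading)
      y <- y0 + t * step * sin(heading)
      if (diffusion_sd_um > 0) {
        x <- x + rnorm(n_frames, 0, diffusion_sd_um)
        y <- y + rnorm(n_frames, 0, diffusion_sd_um)
      }
      tibble::tibble(track_id = sprintf("track%04d", i), frame = t, x = x, y = y)
    })
    attr(out, "frame_interval_s") <- frame_interval_s
    out
  })
}

#' Generate a synthetic LUMIER screen table
#'
#' Builds a duplicate-screen luminescence-intensity-ratio (LIR) table with a
#' known hit structure: exactly `n_true_hits` preys receive both replicate
#' LIRs inside `hit_lir_range` (which must lie entirely at or above the hit
#' threshold of 3), all others inside `null_lir_range` (entirely below 3).
#'
#' @param n_preys Number of preys (rows).
#' @param n_true_hits Number of true interactors (<= `n_preys`).
#' @param hit_lir_range,null_lir_range LIR ranges for hits / non-hits.
#' @param seed Integer seed.
#' @return A tibble `prey`, `lir_rep1`, `lir_rep2`, `true_hit`.
#' @export
generate_lumier_table <- function(n_preys, n_true_hits,
                                  hit_lir_range = c(3, 12),
                                  null_lir_range = c(0, 2.9),
                                  seed = 1L) {
  n_preys <- assert_number(n_preys, "n_preys", min = 1, integerish = TRUE)
  n_true_hits <- assert_number(n_true_hits, "n_true_hits", min = 0,
    max = n_preys, integerish = TRUE)
  assert_that(length(hit_lir_range) == 2 && all(hit_lir_range >= 3),
    "hit_lir_range must lie entirely at or above the hit threshold of 3")
  assert_that(length(null_lir_range) == 2 && all(null_lir_range >= 0) &&
    all(null_lir_range < 3),
    "null_lir_range must lie entirely below the hit threshold of 3")
  seed <- assert_number(seed, "seed", integerish = TRUE)
  with_seed(seed, {
    hit <- rep(FALSE, n_preys)
    if (n_true_hits > 0) hit[sample.int(n_preys, n_true_hits)] <- TRUE
    draw <- function(is_hit, n) {
      rng <- if (is_hit) hit_lir_range else null_lir_range
      runif(n, rng[1], rng[2])
    }
    tibble::tibble(
      prey = sprintf("prey%03d", seq_len(n_preys)),
      lir_rep1 = ifelse(hit, draw(TRUE, n_preys), draw(FALSE, n_preys)),
      lir_rep2 = ifelse(hit, draw(TRUE, n_preys), draw(FALSE, n_preys)),
      true_hit = hit
    )
  })
}
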