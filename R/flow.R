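# Bead-trajectory linking and flow velocity / tortuosity statistics.

#' Link per-frame bead detections into tracks
#'
#' Greedy mutual-nearest-neighbour linking between consecutive frames:
#' a detection in frame t+1 joins the track whose last position is its
#' nearest neighbour, provided the track's position also has that detection
#' as its nearest candidate and the displacement is at most `max_disp_um`.
#' Remaining detections start new tracks; a track that finds no match ends.
#' Ambiguities resolve by smaller distance, then lexicographic position.
#'
#' @param detections Tibble with `frame` (integer) and `x`, `y` (µm).
#' @param max_disp_um Maximum frame-to-frame displacement, µm.
#' @param frame_interval_s Frame interval, seconds (stored as an attribute).
#' @return A tibble `track_id`, `frame`, `x`, `y` ordered by track and
#'   frame, with attribute `frame_interval_s`.
#' @export
link_tracks <- function(detections, max_disp_um, frame_interval_s = 1 / 37) {
  assert_cols(detections, c("frame", "x", "y"), "detections")
  max_disp_um <- assert_number(max_disp_um, "max_disp_um", min = 1e-12)
  frame_interval_s <- assert_number(frame_interval_s, "frame_interval_s", min = 1e-12)
  frames <- sort(unique(detections$frame))
  assert_that(length(frames) >= 2, "need detections in at least 2 frames")

  next_id <- 0L
  new_track <- function() {
    next_id <<- next_id + 1L
    sprintf("track%04d", next_id)
  }
  # active tracks: last position and frame
  first <- detections[detections$frame == frames[1], ]
  first <- first[order(first$x, first$y), ]
  active <- tibble::tibble(
    track_id = vapply(seq_len(nrow(first)), function(i) new_track(), character(1)),
    frame = first$frame, x = first$x, y = first$y
  )
  out <- active
  for (fi in seq_along(frames)[-1]) {
    f <- frames[fi]
    dets <- detections[detections$frame == f, c("frame", "x", "y")]
    dets <- dets[order(dets$x, dets$y), ]
    links <- character(nrow(dets))
    # only tracks seen in the immediately preceding frame remain linkable:
    # a detection vanishing mid-movie ends its track
    linkable <- active[active$frame == f - 1, ]
    if (nrow(linkable) > 0 && nrow(dets) > 0) {
      d <- outer(linkable$x, dets$x, "-")^2 + outer(linkable$y, dets$y, "-")^2
      d[d > max_disp_um^2] <- Inf
      # repeated mutual-nearest-neighbour matching
      repeat {
        if (all(!is.finite(d))) break
        best <- which(d == min(d), arr.ind = TRUE)
        best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
        i <- best[1]; j <- best[2]
        links[j] <- active$track_id[i]
        d[i, ] <- Inf
        d[, j] <- Inf
      }
    }
    unmatched <- links == ""
    links[unmatched] <- vapply(seq_len(sum(unmatched)), function(i) new_track(),
      character(1))
    step <- tibble::tibble(track_id = links, frame = dets$frame,
      x = dets$x, y = dets$y)
    out <- dplyr::bind_rows(out, step)
    active <- step # only tracks updated this frame stay linkable
  }
  out <- dplyr::arrange(out, .data$track_id, .data$frame)
  attr(out, "frame_interval_s") <- frame_interval_s
  out
}

#' Bead velocity of one track
#'
#' Total path length (sum of successive point-to-point distances) divided by
#' elapsed time (frame span times the frame interval). Defined for tracks
#' with at least two points; shorter tracks yield `NA` with a warning.
#'
#' @param track Tibble with `frame`, `x`, `y` for a single track (µm).
#' @param frame_interval_s Frame interval, seconds.
#' @return Velocity in µm/s.
#' @export
track_velocity <- function(track, frame_interval_s = 1 / 37) {
  frame_interval_s <- assert_number(frame_interval_s, "frame_interval_s", min = 1e-12)
  if (nrow(track) < 2) {
    warn("single-point track: velocity undefined")
    return(NA_real_)
  }
  track <- track[order(track$frame), ]
  path <- sum(sqrt(diff(track$x)^2 + diff(track$y)^2))
  elapsed <- (max(track$frame) - min(track$frame)) * frame_interval_s
  path / elapsed
}

#' Tortuosity of one track
#'
#' The ratio of total path length to the straight-line distance between the
#' first and last point: 1 for a perfectly straight trajectory, larger as
#' directionality is lost. Tracks whose net displacement falls below
#' `min_net_disp_um` are non-motile and excluded (`NA` with attribute).
#'
#' @param track Tibble with `frame`, `x`, `y` for a single track (µm).
#' @param min_net_disp_um Net-displacement floor, µm (default 0.1).
#' @return Tortuosity (>= 1), or `NA` for non-motile tracks.
#' @export
track_tortuosity <- function(track, min_net_disp_um = 0.1) {
  min_net_disp_um <- assert_number(min_net_disp_um, "min_net_disp_um", min = 0)
  if (nrow(track) < 2) {
    warn("single-point track: tortuosity undefined")
    return(NA_real_)
  }
  track <- track[order(track$frame), ]
  path <- sum(sqrt(diff(track$x)^2 + diff(track$y)^2))
  chord <- sqrt((track$x[nrow(track)] - track$x[1])^2 +
    (track$y[nrow(track)] - track$y[1])^2)
  if (chord <= min_net_disp_um) {
    out <- NA_real_
    attr(out, "non_motile") <- TRUE
    return(out)
  }
  path / chord
}

#' Flow summary across conditions
#'
#' Computes per-track velocity and tortuosity, rolls them up to
#' per-condition means ± s.e.m., expresses each condition relative to a
#' named control (condition mean over control mean), and tests each
#' condition against the control with a two-sided Welch t-test. Non-motile
#' tracks are excluded from tortuosity (flagged), single-point tracks from
#' everything.
#'
#' @param tracks Tibble with `condition`, `track_id`, `frame`, `x`, `y`.
#' @param control Name of the control condition.
#' @param frame_interval_s Frame interval, seconds.
#' @param min_net_disp_um Net-displacement floor for tortuosity, µm.
#' @return A list of class `flow_summary`: `tracks` (per-track statistics),
#'   `conditions` (means, s.e.m., `relative_velocity`,
#'   `relative_tortuosity`), `tests` (Welch t vs control for both
#'   readouts).
#' @export
flow_summary <- function(tracks, control, frame_interval_s = 1 / 37,
                         min_net_disp_um = 0.1) {
  assert_cols(tracks, c("track_id", "frame", "x", "y"), "tracks")
  if (!"condition" %in% names(tracks)) tracks$condition <- "all"
  assert_that(control %in% tracks$condition,
    sprintf("control condition '%s' not present", control))

  per_track <- tracks |>
    dplyr::group_by(.data$condition, .data$track_id) |>
    dplyr::group_modify(function(tr, key) {
      if (nrow(tr) < 2) {
        return(tibble::tibble(n_points = nrow(tr), velocity_um_s = NA_real_,
          tortuosity = NA_real_, non_motile = NA))
      }
      tort <- suppressWarnings(track_tortuosity(tr, min_net_disp_um))
      tibble::tibble(
        n_points = nrow(tr),
        velocity_um_s = track_velocity(tr, frame_interval_s),
        tortuosity = as.numeric(tort),
        non_motile = isTRUE(attr(tort, "non_motile"))
      )
    }) |>
    dplyr::ungroup()
  if (any(per_track$n_points < 2)) {
    warn(sprintf("%d single-point track(s) excluded", sum(per_track$n_points < 2)))
  }

  conditions <- per_track |>
    dplyr::filter(.data$n_points >= 2) |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(
      n_tracks = dplyr::n(),
      mean_velocity_um_s = mean(.data$velocity_um_s),
      sem_velocity = suppressWarnings(sem(.data$velocity_um_s)),
      mean_tortuosity = mean(.data$tortuosity, na.rm = TRUE),
      sem_tortuosity = suppressWarnings(sem(.data$tortuosity[is.finite(.data$tortuosity)])),
      n_non_motile = sum(.data$non_motile, na.rm = TRUE),
      .groups = "drop"
    )
  ctl <- conditions[conditions$condition == control, ]
  conditions$relative_velocity <- conditions$mean_velocity_um_s / ctl$mean_velocity_um_s
  conditions$relative_tortuosity <- conditions$mean_tortuosity / ctl$mean_tortuosity

  other <- setdiff(conditions$condition, control)
  tests <- purrr::map_dfr(other, function(cond) {
    va <- per_track$velocity_um_s[per_track$condition == cond]
    vb <- per_track$velocity_um_s[per_track$condition == control]
    ta <- per_track$tortuosity[per_track$condition == cond]
    tb <- per_track$tortuosity[per_track$condition == control]
    wv <- welch_t_test(va, vb)
    wt <- welch_t_test(ta[is.finite(ta)], tb[is.finite(tb)])
    tibble::tibble(
      condition = cond,
      metric = c("velocity_um_s", "tortuosity"),
      t = c(wv$t, wt$t), p_value = c(wv$p_value, wt$p_value)
    )
  })
  structure(list(tracks = per_track, conditions = conditions, tests = tests,
    control = control, frame_interval_s = frame_interval_s),
    class = "flow_summary")
}

#' @export
print.flow_summary <- function(x, ...) {
  cat(sprintf("<flow_summary> control = %s\n", x$control))
  print(x$conditions)
  invisible(x)
}
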