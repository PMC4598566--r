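# The multi-step cilia detection / length measurement engine and the
# disassembly time-course aggregation.

#' Detect and measure cilia in a two-channel field
#'
#' Runs the full detection procedure on one acquisition: (1) max-project the
#' centrosome channel along z, (2) detect centrosome spots, (3) crop an
#' 11 µm peri-centrosomal region from the max-projected axoneme channel for
#' each spot, (4) segment the bright proximal axoneme cluster, (5) grow the
#' complete axoneme mask by contrast-limited region growing, (6) skeletonize
#' and measure axoneme length. A centrosome is called ciliated when its
#' measured length reaches `min_cilium_length_um` (default 1 µm).
#'
#' @param stack A two-channel [image_stack()].
#' @param config Parameter list, see [default_config()]; the stack's own
#'   pixel size is used.
#' @param centrosome_channel,axoneme_channel Channel indices.
#' @param condition,timepoint_h,field_id Labels carried into the summary.
#' @param keep_masks Keep per-cilium axoneme masks as a list-column
#'   (default `TRUE`; set `FALSE` to save memory on large batches).
#' @return A list of class `cilia_field` with `records` (tibble: one row
#'   per centrosome with `field_id`, `centrosome_x`, `centrosome_y`,
#'   `peak_intensity`, `ciliated`, `length_um`, and, if kept, list-columns
#'   `axoneme_mask` and `crop_origin`) and `summary` (tibble: `condition`,
#'   `timepoint_h`, `field_id`, `n_cells`, `percent_ciliated`,
#'   `mean_length_um`, `sd_length_um`, `valid`). Length statistics cover
#'   ciliated cells only.
#' @export
quantify_field <- function(stack, config = default_config(),
                           centrosome_channel = 1, axoneme_channel = 2,
                           condition = NA_character_, timepoint_h = NA_real_,
                           field_id = "field1", keep_masks = TRUE) {
  assert_that(inherits(stack, "image_stack"), "stack must be an image_stack")
  assert_that(dim(stack$voxels)[1] >= 2, "stack must have at least 2 channels")
  cfg <- utils::modifyList(default_config(), config)
  ps <- stack$pixel_size_um

  proj_cent <- project_max(stack, centrosome_channel)
  proj_ax <- project_max(stack, axoneme_channel)
  spots <- detect_centrosomes(proj_cent,
    spot_sigma_px = cfg$spot_sigma_px,
    min_peak_snr = cfg$min_peak_snr,
    min_separation_px = cfg$min_separation_px)

  n <- nrow(spots)
  records <- tibble::tibble(
    field_id = character(0), centrosome_x = numeric(0), centrosome_y = numeric(0),
    peak_intensity = numeric(0), ciliated = logical(0), length_um = numeric(0)
  )
  masks <- vector("list", n)
  origins <- vector("list", n)
  if (n > 0) {
    lengths <- numeric(n)
    for (i in seq_len(n)) {
      cr <- crop_pericentrosomal(proj_ax, spots$x[i], spots$y[i], ps,
        crop_side_um = cfg$crop_side_um)
      seed <- segment_proximal_cluster(cr$crop,
        seed_quantile = cfg$seed_quantile, min_seed_px = cfg$min_seed_px)
      if (any(seed)) {
        mask <- grow_axoneme(cr$crop, seed,
          contrast_stop_ratio = cfg$contrast_stop_ratio,
          max_iterations = cfg$max_grow_iterations)
        lengths[i] <- measure_axoneme_length(mask, ps)
      } else {
        mask <- seed
      }
      ciliated_i <- lengths[i] >= cfg$min_cilium_length_um
      if (!ciliated_i) { # non-ciliated: empty mask and zero length by contract
        mask <- matrix(FALSE, nrow(cr$crop), ncol(cr$crop))
        lengths[i] <- 0
      }
      masks[[i]] <- mask
      origins[[i]] <- cr$origin
    }
    records <- tibble::tibble(
      field_id = field_id,
      centrosome_x = spots$x, centrosome_y = spots$y,
      peak_intensity = spots$peak_intensity,
      ciliated = lengths >= cfg$min_cilium_length_um,
      length_um = lengths
    )
    if (keep_masks) {
      records$axoneme_mask <- masks
      records$crop_origin <- origins
    }
  }

  cil <- records$length_um[records$ciliated]
  summary <- tibble::tibble(
    condition = condition, timepoint_h = timepoint_h, field_id = field_id,
    n_cells = n,
    percent_ciliated = if (n > 0) 100 * sum(records$ciliated) / n else NA_real_,
    mean_length_um = if (length(cil) > 0) mean(cil) else NA_real_,
    sd_length_um = if (length(cil) > 1) stats::sd(cil) else NA_real_,
    valid = n >= 1
  )
  if (n == 0) warn(sprintf("field '%s': no centrosomes detected; summary flagged invalid", field_id))
  structure(list(records = records, summary = summary), class = "cilia_field")
}

#' @export
print.cilia_field <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<cilia_field> %s: %d cells, %.1f%% ciliated, mean length %.2f um\n",
    s$field_id, s$n_cells, s$percent_ciliated %||% NA,
    s$mean_length_um %||% NA))
  invisible(x)
}

#' Summarise a cilia disassembly time course
#'
#' Aggregates per-field summaries (one row per replicate field) into mean
#' and s.e.m. of `percent_ciliated` per condition and timepoint, and tests
#' each condition against a named control at each timepoint with a
#' two-sided Welch (unequal-variance) t-test. With a single replicate the
#' s.e.m. is reported missing and the test skipped with a warning.
#'
#' @param field_summaries Tibble with columns `condition`, `timepoint_h`,
#'   `percent_ciliated` (one row per replicate field; e.g. row-bound
#'   `summary` components of [quantify_field()]).
#' @param control Name of the control condition (must be present).
#' @return A list of class `cilia_timecourse`: `points` (tibble of
#'   `condition`, `timepoint_h`, `mean_percent_ciliated`, `sem`,
#'   `n_replicates`) and `tests` (tibble of `condition`, `timepoint_h`,
#'   `t`, `df`, `p_value` vs control).
#' @export
summarize_timecourse <- function(field_summaries, control) {
  assert_cols(field_summaries, c("condition", "timepoint_h", "percent_ciliated"),
    "field_summaries")
  assert_that(control %in% field_summaries$condition,
    sprintf("unknown control condition '%s'", control))
  df <- dplyr::filter(field_summaries, is.finite(.data$percent_ciliated))

  points <- df |>
    dplyr::group_by(.data$condition, .data$timepoint_h) |>
    dplyr::summarise(
      mean_percent_ciliated = mean(.data$percent_ciliated),
      sem = if (dplyr::n() >= 2) {
        stats::sd(.data$percent_ciliated) / sqrt(dplyr::n())
      } else {
        NA_real_
      },
      n_replicates = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::arrange(.data$condition, .data$timepoint_h)
  if (any(points$n_replicates < 2)) {
    warn("groups with a single replicate: s.e.m. reported missing")
  }

  other <- setdiff(unique(df$condition), control)
  tests <- purrr::map_dfr(other, function(cond) {
    purrr::map_dfr(sort(unique(df$timepoint_h[df$condition == cond])), function(tp) {
      a <- df$percent_ciliated[df$condition == cond & df$timepoint_h == tp]
      b <- df$percent_ciliated[df$condition == control & df$timepoint_h == tp]
      if (length(a) < 2 || length(b) < 2) {
        warn(sprintf("t-test skipped for %s at %g h: fewer than 2 replicates", cond, tp))
        return(tibble::tibble(condition = cond, timepoint_h = tp,
          t = NA_real_, df = NA_real_, p_value = NA_real_))
      }
      wt <- welch_t_test(a, b)
      tibble::tibble(condition = cond, timepoint_h = tp,
        t = wt$t, df = wt$df, p_value = wt$p_value)
    })
  })
  structure(list(points = points, tests = tests, control = control),
    class = "cilia_timecourse")
}

#' @export
print.cilia_timecourse <- function(x, ...) {
  cat(sprintf("<cilia_timecourse> control = %s\n", x$control))
  print(x$points)
  if (nrow(x$tests) > 0) {
    cat("Welch t-tests vs control:\n")
    print(x$tests)
  }
  invisible(x)
}
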