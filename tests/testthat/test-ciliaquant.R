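# The multi-step detection procedure, step by step and end to end.

test_that("project_max matches the brute-force z loop", {
  vox <- withr::with_seed(1, array(runif(2 * 3 * 4 * 4, 0, 10), dim = c(2, 3, 4, 4)))
  s <- image_stack(vox, 0.5)
  for (ch in 1:2) {
    expect_equal(project_max(s, ch), bf_project_max(vox, ch))
  }
  # single z-plane: identity
  s1 <- image_stack(vox[, 1, , , drop = FALSE], 0.5)
  expect_equal(project_max(s1, 2), matrix(vox[2, 1, , ], 4, 4))
  # all-zero stack
  s0 <- image_stack(array(0, dim = c(1, 3, 5, 5)), 0.5)
  expect_true(all(project_max(s0, 1) == 0))
  expect_error(project_max(s, 3), class = "ciliadyn_parameter_error")
})

test_that("centrosome detection finds isolated spots and nothing on flat images", {
  expect_equal(nrow(detect_centrosomes(matrix(7, 60, 60))), 0)

  # one noiseless Gaussian spot: the detector must land on the intensity argmax
  img <- matrix(10, 64, 64)
  for (y in 0:63) for (x in 0:63) {
    img[y + 1, x + 1] <- img[y + 1, x + 1] +
      200 * exp(-((x - 30)^2 + (y - 22)^2) / (2 * 1.5^2))
  }
  spots <- detect_centrosomes(img)
  expect_equal(nrow(spots), 1)
  amax <- which(img == max(img), arr.ind = TRUE)
  expect_lt(sqrt((spots$x - (amax[2] - 1))^2 + (spots$y - (amax[1] - 1))^2), 1.01)

  # two spots 20 px apart with min_separation 5 are both kept
  img2 <- matrix(10, 64, 64)
  for (y in 0:63) for (x in 0:63) {
    img2[y + 1, x + 1] <- img2[y + 1, x + 1] +
      200 * exp(-((x - 20)^2 + (y - 30)^2) / (2 * 1.5^2)) +
      150 * exp(-((x - 40)^2 + (y - 30)^2) / (2 * 1.5^2))
  }
  spots2 <- detect_centrosomes(img2, min_separation_px = 5)
  expect_equal(nrow(spots2), 2)
})

test_that("peri-centrosomal crops have the stated geometry", {
  img <- withr::with_seed(2, matrix(runif(100 * 100), 100, 100))
  # 11 um at 0.5 um/px -> 22 px, forced odd -> 23
  cr <- crop_pericentrosomal(img, 50, 40, pixel_size_um = 0.5)
  expect_equal(dim(cr$crop), c(23, 23))
  expect_false(cr$padded)
  # the centrosome is the exact centre pixel
  expect_equal(cr$crop[12, 12], img[41, 51])
  # corner spot: padded with the background median and flagged
  cr2 <- crop_pericentrosomal(img, 0, 0, pixel_size_um = 0.5)
  expect_true(cr2$padded)
  expect_equal(cr2$crop[1, 1], median(img))
  expect_error(crop_pericentrosomal(img, 50, 50, pixel_size_um = 10),
    class = "ciliadyn_parameter_error")
})

test_that("seed segmentation matches a threshold + flood-fill oracle", {
  crop <- matrix(5, 21, 21)
  crop[9:13, 9:13] <- 100 # bright blob at the centre
  seed <- segment_proximal_cluster(crop, seed_quantile = 0.9, min_seed_px = 3)
  thr <- quantile(crop, 0.9, names = FALSE)
  oracle <- bf_flood_component(crop, thr, c(11, 11))
  expect_identical(seed, oracle)

  # constant crop: nothing qualifies
  expect_false(any(segment_proximal_cluster(matrix(4, 15, 15))))

  # centre blob wins over a corner blob
  crop2 <- matrix(0, 21, 21)
  crop2[10:12, 10:12] <- 50
  crop2[1:4, 1:4] <- 80
  seed2 <- segment_proximal_cluster(crop2, seed_quantile = 0.5, min_seed_px = 3)
  expect_true(seed2[11, 11])
  expect_false(seed2[2, 2])
})

test_that("region growing recovers a noiseless filament and respects its contract", {
  # synthetic filament on a flat background
  crop <- matrix(10, 35, 35)
  filament <- matrix(FALSE, 35, 35)
  for (t in seq(0, 1, length.out = 80)) {
    y <- round(18 + 14 * t); x <- round(18 + 10 * t - 14 * t^2)
    filament[y, x] <- TRUE
  }
  crop[filament] <- 100
  seed <- matrix(FALSE, 35, 35)
  seed[18:19, 18] <- TRUE
  mask <- grow_axoneme(crop, seed, contrast_stop_ratio = 1.5)
  iou <- sum(mask & filament) / sum(mask | filament)
  expect_gte(iou, 0.8)

  # flat constant crop: no growth beyond the seed
  flat <- matrix(3, 15, 15)
  s <- matrix(FALSE, 15, 15); s[7:8, 7] <- TRUE
  expect_identical(grow_axoneme(flat, s), s)
  # max_iterations = 0: the seed comes straight back
  expect_identical(grow_axoneme(crop, seed, max_iterations = 0), seed)
  # empty seed: empty mask with a warning
  expect_warning(out <- grow_axoneme(crop, matrix(FALSE, 35, 35)))
  expect_false(any(out))
})

test_that("axoneme length equals the exhaustive longest-path search", {
  # stated arithmetic: 11-px horizontal run at 0.5 um/px -> 5 um
  m <- matrix(FALSE, 9, 15); m[5, 3:13] <- TRUE
  expect_equal(measure_axoneme_length(m, 0.5), 5)
  expect_equal(measure_axoneme_length(matrix(FALSE, 5, 5), 0.5), 0)

  # L-shaped path and random small skeletons vs Floyd-Warshall
  l <- matrix(FALSE, 14, 14); l[3, 2:11] <- TRUE; l[3:12, 11] <- TRUE
  expect_equal(measure_axoneme_length(l, 1),
    bf_longest_geodesic(ciliadyn:::skeletonize(l)))

  withr::with_seed(42, {
    for (rep in 1:6) {
      m <- matrix(FALSE, 10, 10)
      y <- sample(2:9, 1); x <- 2
      m[y, x] <- TRUE
      for (s in 1:14) { # random thin walk, <= 25 px
        y <- min(max(y + sample(-1:1, 1), 1), 10)
        x <- min(max(x + sample(0:1, 1), 1), 10)
        m[y, x] <- TRUE
      }
      skel <- ciliadyn:::skeletonize(m)
      expect_lte(sum(skel), 25)
      expect_equal(measure_axoneme_length(m, 1), bf_longest_geodesic(skel))
    }
  })
})

test_that("quantify_field recovers ground truth on synthetic fields", {
  # forced-zero ciliation
  sim0 <- generate_cilia_field(field_params(
    field_size_px = c(320, 320), n_centrosomes = 25, ciliation_fraction = 0,
    seed = 31))
  r0 <- quantify_field(sim0$stack, keep_masks = FALSE)
  expect_equal(r0$summary$percent_ciliated, 0)

  # moderate-SNR field: fraction within +-5 points, lengths within 0.5 um
  sim <- generate_cilia_field(field_params(
    n_centrosomes = 100, ciliation_fraction = 0.6, seed = 32))
  r <- quantify_field(sim$stack, keep_masks = FALSE)
  expect_lt(abs(r$summary$percent_ciliated - 60), 5)

  sim1 <- generate_cilia_field(field_params(
    n_centrosomes = 60, ciliation_fraction = 1,
    cilium_length_um_range = c(4, 6), seed = 33))
  r1 <- quantify_field(sim1$stack, keep_masks = FALSE)
  truth_mean <- mean(sim1$truth$true_length_um[sim1$truth$ciliated])
  expect_lt(abs(r1$summary$mean_length_um - truth_mean), 0.5)
  # ciliated <-> length >= threshold, non-ciliated rows have zero length
  expect_true(all(r1$records$ciliated == (r1$records$length_um >= 1)))
  expect_equal(r1$summary$percent_ciliated,
    100 * sum(r1$records$ciliated) / r1$summary$n_cells)
})

test_that("percent_ciliated is invariant to affine intensity rescaling", {
  sim <- generate_cilia_field(field_params(n_centrosomes = 40, seed = 35))
  base <- quantify_field(sim$stack, keep_masks = FALSE)$summary$percent_ciliated
  rescaled <- sim$stack
  rescaled$voxels <- 3 * rescaled$voxels + 50
  expect_equal(
    quantify_field(rescaled, keep_masks = FALSE)$summary$percent_ciliated,
    base)
})

test_that("time-course aggregation reports means, s.e.m. and Welch tests", {
  df <- tibble::tibble(
    condition = rep(c("siCTL", "siPTEN"), each = 3),
    timepoint_h = 2,
    percent_ciliated = c(10, 12, 11, 20, 22, 21)
  )
  tc <- summarize_timecourse(df, control = "siCTL")
  oracle <- bf_welch(c(20, 22, 21), c(10, 12, 11))
  expect_equal(tc$tests$t, oracle$t, tolerance = 1e-12)
  expect_equal(tc$tests$p_value, oracle$p, tolerance = 1e-12)
  expect_equal(tc$points$sem[tc$points$condition == "siCTL"],
    sd(c(10, 12, 11)) / sqrt(3))

  # identical replicate sets: t = 0, p = 1
  df2 <- df; df2$percent_ciliated <- rep(c(10, 12, 11), 2)
  tc2 <- summarize_timecourse(df2, control = "siCTL")
  expect_equal(tc2$tests$t, 0)
  expect_equal(tc2$tests$p_value, 1)

  # single replicate: s.e.m. missing, test skipped with warning
  df3 <- df[c(1, 4), ]
  w <- capture_warnings(tc3 <- summarize_timecourse(df3, control = "siCTL"))
  expect_true(any(grepl("single replicate", w)))
  expect_true(any(grepl("skipped", w)))
  expect_true(all(is.na(tc3$points$sem)))
  expect_true(all(is.na(tc3$tests$p_value)))

  expect_error(summarize_timecourse(df, control = "nope"),
    class = "ciliadyn_parameter_error")
})

test_that("lowering true ciliation never raises detected ciliation (paired seeds)", {
  res <- sapply(c(0.3, 0.6, 0.9), function(f) {
    mean(sapply(41:42, function(s) {
      sim <- generate_cilia_field(field_params(
        field_size_px = c(400, 400), n_centrosomes = 45, ciliation_fraction = f,
        seed = s))
      quantify_field(sim$stack, keep_masks = FALSE)$summary$percent_ciliated
    }))
  })
  expect_true(all(diff(res) > 0))
})
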