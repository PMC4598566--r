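# Synthetic-data generators: determinism, ground-truth invariants, edge cases.

test_that("cilia field generator honours the ciliation fraction exactly", {
  sim0 <- generate_cilia_field(field_params(
    field_size_px = c(256, 256), n_centrosomes = 20, ciliation_fraction = 0,
    seed = 5))
  expect_equal(sum(sim0$truth$ciliated), 0)
  # channel 2 holds only background: no axoneme pixels and mean near background
  expect_true(all(vapply(sim0$truth$axoneme_px, nrow, integer(1)) == 0))
  expect_lt(abs(mean(sim0$stack$voxels[2, , , ]) - 20), 1.5)

  sim1 <- generate_cilia_field(field_params(
    field_size_px = c(480, 480), n_centrosomes = 50, ciliation_fraction = 1,
    seed = 6))
  expect_equal(sum(sim1$truth$ciliated), 50)
  expect_true(all(sim1$truth$true_length_um[sim1$truth$ciliated] >= 2 - 1e-9))
  expect_true(all(sim1$truth$true_length_um[sim1$truth$ciliated] <= 6 + 1e-9))

  # round(fraction * n) for a grid of settings
  for (fr in c(0.25, 0.5, 0.33, 0.9)) {
    for (n in c(4, 7, 11)) {
      sim <- generate_cilia_field(field_params(
        field_size_px = c(256, 256), n_centrosomes = n, ciliation_fraction = fr,
        seed = 2))
      expect_equal(sum(sim$truth$ciliated), round(fr * n))
    }
  }
})

test_that("generators are pure functions of parameters and seed", {
  a <- generate_cilia_field(tiny_field_params(seed = 3))
  b <- generate_cilia_field(tiny_field_params(seed = 3))
  expect_identical(a$stack$voxels, b$stack$voxels)
  expect_identical(a$truth$true_length_um, b$truth$true_length_um)
  c <- generate_cilia_field(tiny_field_params(seed = 4))
  expect_false(identical(a$stack$voxels, c$stack$voxels))

  v1 <- generate_polarity_cells(5, 8, kappa = 4, seed = 9)
  v2 <- generate_polarity_cells(5, 8, kappa = 4, seed = 9)
  expect_identical(v1, v2)

  t1 <- generate_bead_tracks(5, 10, 0.1, 20, seed = 9)
  t2 <- generate_bead_tracks(5, 10, 0.1, 20, seed = 9)
  expect_identical(t1, t2)

  l1 <- generate_lumier_table(30, 4, seed = 9)
  l2 <- generate_lumier_table(30, 4, seed = 9)
  expect_identical(l1, l2)
})

test_that("ground-truth polylines have the stated arc length", {
  sim <- generate_cilia_field(field_params(
    field_size_px = c(480, 480), n_centrosomes = 25, ciliation_fraction = 1,
    seed = 12))
  for (i in which(sim$truth$ciliated)) {
    poly <- sim$truth$polyline[[i]]
    arc <- sum(sqrt(diff(poly[, 1])^2 + diff(poly[, 2])^2)) * 0.32
    expect_equal(arc, sim$truth$true_length_um[i], tolerance = 1e-6)
  }
})

test_that("rendered axoneme intensity grows with true length", {
  sums <- vapply(c(2, 3, 4, 5, 6), function(L) {
    sim <- generate_cilia_field(field_params(
      field_size_px = c(128, 128), n_centrosomes = 1, ciliation_fraction = 1,
      cilium_length_um_range = c(L, L), background_level = 0, noise_sd = 0,
      seed = 21))
    sum(sim$stack$voxels[2, , , ])
  }, numeric(1))
  expect_true(all(diff(sums) >= 0))
})

test_that("field generator rejects invalid parameters", {
  expect_error(field_params(field_size_px = c(100.5, 100)), class = "ciliadyn_parameter_error")
  expect_error(field_params(noise_sd = -1), class = "ciliadyn_parameter_error")
  expect_error(field_params(ciliation_fraction = 1.2), class = "ciliadyn_parameter_error")
  expect_error(field_params(cilium_length_um_range = c(5, 2)), class = "ciliadyn_parameter_error")
})

test_that("polarity-cell generator reproduces the requested concentration", {
  # near-degenerate concentration: every vector hugs its cell mean
  v <- generate_polarity_cells(4, 10, kappa = 1e6, seed = 2)
  dev <- abs((v$true_angle_deg - v$true_cell_mean_deg + 180) %% 360 - 180)
  expect_true(all(dev < 0.5))

  # kappa = 0 is uniform: CSD compatible with a direct uniform-sampling oracle
  v0 <- generate_polarity_cells(1, 10000, kappa = 0, seed = 3)
  csd_gen <- circular_sd(v0$true_angle_deg)
  csd_mc <- withr::with_seed(99, replicate(50, circular_sd(runif(10000, 0, 360))))
  expect_gt(csd_gen, mean(csd_mc) - 5 * sd(csd_mc) - 5)
  expect_lt(csd_gen, mean(csd_mc) + 5 * sd(csd_mc) + 5)

  expect_error(generate_polarity_cells(2, 3, kappa = -1), class = "ciliadyn_parameter_error")
})

test_that("bead-track generator produces the stated kinematics", {
  # zero diffusion: perfectly collinear points
  tr <- generate_bead_tracks(5, 3, 0, 30, frame_interval_s = 1 / 37, seed = 4)
  for (id in unique(tr$track_id)) {
    t1 <- tr[tr$track_id == id, ]
    dx <- diff(t1$x); dy <- diff(t1$y)
    cross <- dx[-1] * dy[-length(dy)] - dy[-1] * dx[-length(dx)]
    expect_true(all(abs(cross) < 1e-9))
    # per-step displacement = speed x interval
    expect_equal(sqrt(dx^2 + dy^2), rep(3 / 37, length(dx)), tolerance = 1e-9)
  }
  # zero speed and diffusion: all points coincide
  tr0 <- generate_bead_tracks(3, 0, 0, 10, seed = 5)
  expect_equal(max(tapply(tr0$x, tr0$track_id, function(x) diff(range(x)))), 0)
  expect_error(generate_bead_tracks(3, 1, 0, 1), class = "ciliadyn_parameter_error")
})

test_that("LUMIER generator plants exactly the requested hits", {
  tb <- generate_lumier_table(80, 5, seed = 6)
  both_high <- tb$lir_rep1 >= 3 & tb$lir_rep2 >= 3
  expect_equal(sum(both_high), 5)
  expect_identical(both_high, tb$true_hit)
  # downstream filter recovers exactly the planted preys
  expect_setequal(filter_lumier_hits(tb), tb$prey[tb$true_hit])

  tb0 <- generate_lumier_table(20, 0, seed = 7)
  expect_length(filter_lumier_hits(tb0), 0)

  expect_error(generate_lumier_table(10, 2, hit_lir_range = c(2, 5)),
    class = "ciliadyn_parameter_error")
  expect_error(generate_lumier_table(10, 2, null_lir_range = c(1, 3.5)),
    class = "ciliadyn_parameter_error")
})
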