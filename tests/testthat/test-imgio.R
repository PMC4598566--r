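# File formats: TIFF stacks, CSV tables, ground-truth JSON, configuration.

test_that("TIFF stacks round-trip exactly", {
  vox <- array(runif(2 * 3 * 10 * 12, 0, 500), dim = c(2, 3, 10, 12))
  s <- image_stack(vox, 0.32, channel_names = c("centrosome", "axoneme"))
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack(s, path, bits = 64)
  s2 <- read_stack(path, n_channels = 2)
  expect_identical(s2$voxels, s$voxels)
  expect_equal(s2$pixel_size_um, 0.32, tolerance = 1e-6)

  # 16-bit round trip quantizes to integers
  write_stack(s, path, bits = 16)
  s3 <- read_stack(path, n_channels = 2)
  expect_equal(s3$voxels, round(vox), tolerance = 0)

  # single-page file declared 1 channel -> shape (1, 1, H, W)
  s1 <- image_stack(array(1:20, dim = c(1, 1, 4, 5)), 0.5)
  write_stack(s1, path)
  r1 <- read_stack(path)
  expect_equal(dim(r1$voxels), c(1, 1, 4, 5))
})

test_that("stack reader reports I/O problems distinctly", {
  expect_error(read_stack(file.path(tempdir(), "absent.tif")),
    class = "ciliadyn_io_error")

  # page count not divisible by the declared channel count
  s <- image_stack(array(0, dim = c(1, 3, 4, 4)), 0.5)
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack(s, path)
  expect_error(read_stack(path, n_channels = 2), class = "ciliadyn_io_error")

  # a TIFF without resolution tags and no override: pixel size unknown.
  # Craft a minimal single-page file by hand (4x1, 16-bit).
  p2 <- withr::local_tempfile(fileext = ".tif")
  con <- file(p2, "wb")
  writeBin(charToRaw("II"), con)
  writeBin(ciliadyn:::u16(42L), con)
  writeBin(ciliadyn:::u32(16L), con) # IFD after 8-byte strip
  writeBin(as.integer(c(1, 2, 3, 4)), con, size = 2, endian = "little")
  entries <- c(
    ciliadyn:::ifd_entry(256L, 4L, 1L, ciliadyn:::u32(4L)),
    ciliadyn:::ifd_entry(257L, 4L, 1L, ciliadyn:::u32(1L)),
    ciliadyn:::ifd_entry(258L, 3L, 1L, ciliadyn:::u16(16L)),
    ciliadyn:::ifd_entry(259L, 3L, 1L, ciliadyn:::u16(1L)),
    ciliadyn:::ifd_entry(273L, 4L, 1L, ciliadyn:::u32(8L)),
    ciliadyn:::ifd_entry(279L, 4L, 1L, ciliadyn:::u32(8L))
  )
  writeBin(c(ciliadyn:::u16(6L), entries, ciliadyn:::u32(0L)), con)
  close(con)
  expect_error(read_stack(p2), regexp = "pixel size unknown",
    class = "ciliadyn_io_error")
  # with an override it reads fine
  r <- read_stack(p2, pixel_size_um = 0.25)
  expect_equal(as.vector(r$voxels), c(1, 2, 3, 4))
})

test_that("table readers round-trip and validate their schemas", {
  path <- withr::local_tempfile(fileext = ".csv")

  v <- generate_polarity_cells(3, 4, kappa = 5, seed = 1)
  readr::write_csv(v[, c("cell_id", "base_x", "base_y", "tip_x", "tip_y")], path)
  v2 <- read_vectors(path)
  expect_equal(v2$base_x, v$base_x, tolerance = 1e-12)
  expect_equal(v2$tip_y, v$tip_y, tolerance = 1e-12)

  # empty-but-headered file is an empty collection, not an error
  readr::write_csv(v[0, c("cell_id", "base_x", "base_y", "tip_x", "tip_y")], path)
  expect_equal(nrow(read_vectors(path)), 0)

  # missing required column is named in the error
  readr::write_csv(v[, c("cell_id", "base_x", "base_y", "tip_x")], path)
  expect_error(read_vectors(path), regexp = "tip_y", class = "ciliadyn_parse_error")

  # a non-numeric coordinate is reported with its line
  bad <- v[, c("cell_id", "base_x", "base_y", "tip_x", "tip_y")]
  bad$tip_x <- as.character(bad$tip_x)
  bad$tip_x[2] <- "oops"
  readr::write_csv(bad, path)
  expect_error(read_vectors(path), regexp = "line 3", class = "ciliadyn_parse_error")

  tr <- generate_bead_tracks(3, 2, 0.05, 10, seed = 2)
  readr::write_csv(tr, path)
  expect_equal(read_tracks(path)$x, tr$x, tolerance = 1e-12)

  lt <- generate_lumier_table(10, 2, seed = 3)
  readr::write_csv(lt[, 1:3], path)
  expect_equal(read_lumier(path)$lir_rep2, lt$lir_rep2, tolerance = 1e-12)

  roi <- tibble::tibble(cell_id = "c1", vertex = 1:4,
    x = c(0, 10, 10, 0), y = c(0, 0, 10, 10))
  readr::write_csv(roi, path)
  expect_equal(read_rois(path)$x, roi$x)
  readr::write_csv(roi[1:2, ], path)
  expect_error(read_rois(path), class = "ciliadyn_parse_error")
})

test_that("write_results is deterministic and unicode-safe", {
  df <- tibble::tibble(
    condition = c("siPTEN", "contrôle-β"),
    value = c(1 / 3, 2.123456789)
  )
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_results(df, p1)
  write_results(df[2:1, ], p2) # different input order, same sorted output
  expect_identical(readBin(p1, "raw", file.size(p1)),
    readBin(p2, "raw", file.size(p2)))
  back <- readr::read_csv(p1, show_col_types = FALSE)
  expect_setequal(back$condition, df$condition)
  # 6 significant digits
  expect_true("0.333333" %in% format(back$value))

  p3 <- withr::local_tempfile(fileext = ".csv")
  write_results(df[0, ], p3)
  expect_equal(readLines(p3), "condition,value")
})

test_that("ground truth survives a JSON round trip", {
  sim <- generate_cilia_field(tiny_field_params(seed = 2))
  path <- withr::local_tempfile(fileext = ".json")
  cols <- c("id", "x", "y", "ciliated", "true_length_um")
  write_ground_truth(sim$truth[, cols], path)
  back <- read_ground_truth(path)
  expect_equal(back$true_length_um, sim$truth$true_length_um, tolerance = 1e-12)
  expect_equal(back$ciliated, sim$truth$ciliated)
})

test_that("configuration files are parsed and validated", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("# tuned for high background", "min_peak_snr: 6",
    "contrast_stop_ratio: 1.8"), path)
  cfg <- read_config(path)
  expect_equal(cfg$min_peak_snr, 6)
  expect_equal(cfg$contrast_stop_ratio, 1.8)
  expect_equal(cfg$seed_quantile, default_config()$seed_quantile)

  writeLines("not_a_key: 1", path)
  expect_error(read_config(path), regexp = "not_a_key", class = "ciliadyn_parse_error")
  writeLines("min_peak_snr: high", path)
  expect_error(read_config(path), class = "ciliadyn_parse_error")
  # pixel size is deliberately never defaulted
  expect_true(is.na(default_config()$pixel_size_um))
})
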