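test_that("build_grid produces uniform channel grids and rejects bad ranges", {
  g <- build_grid(350, 2500, 1)
  expect_length(g$channels, 2151)
  expect_equal(g$channels[1], 350)
  expect_equal(g$channels[2151], 2500)
  expect_equal(unique(diff(g$channels)), 1)

  expect_length(build_grid(350, 350, 1)$channels, 1)
  expect_equal(build_grid(400, 402, 1)$channels, c(400, 401, 402))
  expect_error(build_grid(350, 2500, 3), "not divisible")
  expect_error(build_grid(500, 400, 1), "start_nm")
  expect_error(build_grid(350, 2500, 0), "step_nm")
})

test_that("region classification follows the closed printed intervals", {
  expect_equal(classify_regions(550)$regions[[1]], "VIS")
  expect_equal(classify_regions(550)$primary, "VIS")
  expect_setequal(classify_regions(690)$regions[[1]], c("VIS", "RDE"))
  expect_equal(classify_regions(690)$primary, "RDE")
  expect_equal(classify_regions(2000)$regions[[1]], "MIR")
  expect_equal(classify_regions(2000)$primary, "MIR")
  expect_error(classify_regions(300), "350-2500")
  expect_error(classify_regions(2501), "350-2500")
})

test_that("region membership is exhaustively consistent on every channel", {
  # independent reconstruction from the interval bounds
  intervals <- list(VIS = c(350, 700), RDE = c(680, 750),
                    NIR = c(700, 1300), MIR = c(1300, 2500))
  wl <- 350:2500
  got <- classify_regions(wl)
  for (nm in names(intervals)) {
    expected_in <- wl >= intervals[[nm]][1] & wl <= intervals[[nm]][2]
    member <- vapply(got$regions, function(rs) nm %in% rs, logical(1))
    expect_equal(member, expected_in, info = nm)
  }
  # precedence: red edge beats everything, VIS beats NIR, NIR beats MIR
  expect_true(all(got$primary[wl >= 680 & wl <= 750] == "RDE"))
  expect_true(all(got$primary[wl < 680] == "VIS"))
  expect_true(all(got$primary[wl > 750 & wl <= 1300] == "NIR"))
  expect_true(all(got$primary[wl > 1300] == "MIR"))
})

test_that("two-column spectrum files parse, dedupe and resample", {
  g <- build_grid(400, 401, 1)
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("Wavelength Reflectance", "400 0.1", "401 0.2"), f)
  s <- read_spectrum_text(f, g)
  expect_equal(s$reflectance, c(0.1, 0.2))

  f2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("400,0.1", "500,0.2", "500,0.4", "600,0.3"), f2)
  expect_warning(s2 <- read_spectrum_text(f2, build_grid(400, 600, 100)),
                 "duplicate")
  expect_equal(s2$reflectance[s2$grid$channels == 500], 0.3)

  f3 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("400 0.1", "garbage row", "402 0.2"), f3)
  expect_error(read_spectrum_text(f3, g), "non-numeric")

  f4 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("400 0.1", "401 1.5"), f4)
  expect_error(read_spectrum_text(f4, g), "outside")
})

test_that("library CSV write/read round-trips values and metadata", {
  lib <- tiny_library()
  f <- withr::local_tempfile(fileext = ".csv")
  write_library_csv(lib, f)
  back <- read_library_csv(f, lib$grid)
  expect_equal(back$reflectance, lib$reflectance)
  expect_equal(back$metadata, lib$metadata)
})

test_that("resampling interpolates linearly and refuses extrapolation", {
  tgt <- build_grid(401, 401, 1)
  src <- list(wavelength = c(400, 402), reflectance = c(0, 1))
  expect_equal(resample_to_grid(src, tgt)$reflectance, 0.5)

  g <- build_grid(400, 410, 1)
  s <- new_spectrum(seq(0.1, 0.6, length.out = 11), g, "a")
  expect_equal(resample_to_grid(s, g)$reflectance, s$reflectance)

  const <- list(wavelength = c(400, 410), reflectance = c(0.2, 0.2))
  expect_true(all(resample_to_grid(const, g)$reflectance == 0.2))

  expect_error(resample_to_grid(src, build_grid(398, 402, 1)), "extrapolate")
})

test_that("reflectance validation clips small excursions and rejects large", {
  g <- build_grid(400, 402, 1)
  expect_warning(s <- new_spectrum(c(-0.02, 0.5, 1.03), g), "clipping")
  expect_equal(s$reflectance, c(0, 0.5, 1))
  expect_error(new_spectrum(c(-0.2, 0.5, 0.5), g), "outside")
})

test_that("pot aggregation averages leaves and is idempotent", {
  lib <- tiny_library()
  pots <- aggregate(lib, level = "pot")
  expect_equal(n_spectra(pots), 2)
  expect_equal(unname(pots$reflectance["p1", ]), rep(0.3, 5))
  # single-leaf pot passes through unchanged
  expect_equal(unname(pots$reflectance["p2", ]),
               unname(lib$reflectance["p2_l1", ]))
  again <- aggregate(pots, level = "pot")
  expect_equal(again$reflectance, pots$reflectance)
})

test_that("library constructor enforces unique ids and complete metadata", {
  lib <- tiny_library()
  meta_dup <- lib$metadata
  meta_dup$sample_id <- rep("x", 3)
  expect_error(spectral_library(lib$reflectance, meta_dup, lib$grid),
               "unique")
  expect_error(spectral_library(lib$reflectance, lib$metadata[, -2],
                                lib$grid), "lacks column")
})
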