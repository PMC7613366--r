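test_that("default dosing design has the experiment's bookkeeping", {
  d <- default_design()
  expect_equal(nrow(d$pots), 84)
  expect_equal(nrow(d$pots) * d$leaves_per_pot, 420)
  expect_equal(sum(d$pots$level == "C"), 4)
  expect_false(anyDuplicated(d$pots$pot_id) > 0)

  d1 <- default_design(replicates_per_cell = 1)
  expect_equal(nrow(d1$pots), 21)  # 1 shared control + 5 metals x 4 levels

  d2 <- default_design(control_shared = FALSE)
  expect_equal(nrow(d2$pots), 5 * 4 + 5 * 4 * 4)
})

test_that("noiseless concentrations follow the dose-response exactly", {
  d <- default_design()
  nz <- noise_model(conc_cv = 0, seed = 1)
  resp <- stress_response()
  conc <- generate_concentrations(d, resp, nz)
  # control pots sit exactly at the baseline for every metal
  ctrl <- conc[conc$pot_id == "C-r1", ]
  expect_equal(ctrl$concentration_mgkg[ctrl$metal == "Cu"],
               unname(resp$conc_baseline_mgkg["Cu"]))
  # strictly increasing across L1..L4 for each metal (own-metal rows)
  for (m in d$metals) {
    lv <- sapply(1:4, function(l) {
      conc$concentration_mgkg[conc$pot_id == sprintf("%s-L%d-r1", m, l) &
                                conc$metal == m]
    })
    expect_true(all(diff(lv) > 0), info = m)
  }
})

test_that("values below the detection limit are reported at the limit", {
  d <- default_design(metals = "Cd")
  resp <- stress_response(conc_baseline_mgkg = c(Cd = 0),
                          conc_slope_mgkg = c(Cd = 90))
  conc <- generate_concentrations(d, resp, noise_model(conc_cv = 0, seed = 1))
  ctrl <- conc[conc$pot_id == "C-r1", ]
  expect_equal(ctrl$concentration_mgkg, 0.009)
  expect_true(ctrl$censored)
  stressed <- conc[conc$pot_id == "Cd-L4-r1", ]
  expect_false(stressed$censored)
})

test_that("zero effect and zero noise reproduce the baseline spectrum", {
  d <- default_design(metals = "Cd", replicates_per_cell = 1,
                      leaves_per_pot = 2)
  resp <- stress_response(band_amp = 0, band_cv = 0,
                          region_lift = c(VIS = 0, RDE = 0, NIR = 0, MIR = 0))
  nz <- noise_model(smooth_sd = 0, uv_sd = 0, conc_cv = 0, seed = 1)
  ds <- generate_dataset(d, resp, nz)
  base <- baseline_spectrum(canonical_grid())
  for (i in seq_len(n_spectra(ds$library))) {
    expect_equal(unname(ds$library$reflectance[i, ]), base)
  }
})

test_that("stress lifts mean VIS reflectance above the control", {
  d <- default_design(metals = "Cd", replicates_per_cell = 1,
                      leaves_per_pot = 1)
  nz <- noise_model(smooth_sd = 0, uv_sd = 0, conc_cv = 0, seed = 1)
  ds <- generate_dataset(d, stress_response(), nz)
  vis <- ds$library$grid$channels <= 700
  ctrl_vis <- mean(ds$library$reflectance["C-r1_leaf1", vis])
  for (lev in 1:4) {
    id <- sprintf("Cd-L%d-r1_leaf1", lev)
    expect_gt(mean(ds$library$reflectance[id, vis]), ctrl_vis)
  }
})

test_that("the same seed reproduces the dataset bit for bit", {
  a <- quick_dataset(seed = 42)
  b <- quick_dataset(seed = 42)
  expect_identical(a$library$reflectance, b$library$reflectance)
  expect_identical(a$concentrations, b$concentrations)
  c <- quick_dataset(seed = 43)
  expect_false(identical(a$library$reflectance, c$library$reflectance))
})

test_that("stressed group-mean spectrum dominates the healthy mean", {
  ds <- generate_dataset(default_design(), stress_response(),
                         noise_model(seed = 5))
  ms <- mean_spectra_by_group(ds$library, "status")
  stressed <- ms$mean_reflectance[ms$group == "stressed"]
  healthy <- ms$mean_reflectance[ms$group == "healthy"]
  expect_true(all(stressed >= healthy))
})

test_that("the 350-400 nm range is noisier than 500-700 nm", {
  d <- default_design(metals = "Cd", replicates_per_cell = 1,
                      leaves_per_pot = 30)
  nz <- noise_model(smooth_sd = 0.005, uv_sd = 0.02, seed = 8)
  ds <- generate_dataset(d, stress_response(), nz)
  wl <- ds$library$grid$channels
  ctrl <- ds$library$reflectance[ds$library$metadata$level == "C", ]
  v <- apply(ctrl, 2, var)
  expect_gt(mean(v[wl >= 350 & wl <= 400]), mean(v[wl >= 500 & wl <= 700]))
})

test_that("generator rejects invalid response and noise parameters", {
  expect_error(stress_response(conc_slope_mgkg = c(Cd = -1)), "slopes")
  expect_error(noise_model(conc_cv = -0.1), "conc_cv")
})
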