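# Shared fixtures for the test suite. Everything is generated in code; no
# binary data is stored.

# A spectrum with iid uniform reflectance on the canonical grid.
random_spectrum <- function(seed = 1, lo = 0.05, hi = 0.95) {
  g <- canonical_grid()
  set.seed(seed)
  new_spectrum(runif(length(g$channels), lo, hi), g,
               paste0("rand", seed))
}

flat_spectrum <- function(value = 0.5) {
  g <- canonical_grid()
  new_spectrum(rep(value, length(g$channels)), g, "flat")
}

# Reflectance lookup helpers used by the hand-coded index oracles: direct
# positional indexing on the canonical grid, independent of the registry's
# accessor machinery.
R_at <- function(s, wl) s$reflectance[wl - 350 + 1]
W_at <- function(s, lo, hi) mean(s$reflectance[(lo - 350 + 1):(hi - 350 + 1)])

# Independently hand-coded index formulas (kept deliberately separate from
# the registry implementations; each is typed out from the published
# band-arithmetic recipe).
index_oracles <- list(
  CAI = function(s) 0.5 * (R_at(s, 2000) + R_at(s, 2200)) - R_at(s, 2100),
  MSI = function(s) R_at(s, 1600) / R_at(s, 820),
  NDWI = function(s) (R_at(s, 860) - R_at(s, 1240)) / (R_at(s, 860) + R_at(s, 1240)),
  DWSI = function(s) (R_at(s, 802) + R_at(s, 547)) / (R_at(s, 1657) + R_at(s, 682)),
  RATIO975 = function(s) 2 * W_at(s, 960, 990) / (W_at(s, 920, 940) + W_at(s, 1090, 1110)),
  RATIO975_2 = function(s) 2 * W_at(s, 1180, 1220) / (W_at(s, 1090, 1110) + W_at(s, 1265, 1285)),
  LCI = function(s) (R_at(s, 850) - R_at(s, 710)) / (R_at(s, 850) + R_at(s, 680)),
  DattA = function(s) (R_at(s, 780) - R_at(s, 710)) / (R_at(s, 780) - R_at(s, 680)),
  mNDVI705 = function(s) (R_at(s, 750) + R_at(s, 705)) / (R_at(s, 750) + R_at(s, 705) - 2 * R_at(s, 445)),
  SGB = function(s) (R_at(s, 750) - R_at(s, 445)) / (R_at(s, 705) - R_at(s, 445)),
  SIPI = function(s) (R_at(s, 445) - R_at(s, 800)) / (R_at(s, 680) - R_at(s, 800)),
  SR = function(s) R_at(s, 774) / R_at(s, 677),
  R550 = function(s) R_at(s, 550),
  R680 = function(s) R_at(s, 680),
  WI = function(s) R_at(s, 900) / R_at(s, 970),
  GM1 = function(s) R_at(s, 750) / R_at(s, 550),
  GM2 = function(s) R_at(s, 750) / R_at(s, 700),
  Lic1 = function(s) (R_at(s, 800) - R_at(s, 680)) / (R_at(s, 800) + R_at(s, 680)),
  Lic2 = function(s) R_at(s, 440) / R_at(s, 690),
  Lic3 = function(s) R_at(s, 440) / R_at(s, 740),
  SRPI = function(s) R_at(s, 430) / R_at(s, 680),
  NPQI = function(s) (R_at(s, 415) - R_at(s, 435)) / (R_at(s, 415) + R_at(s, 435)),
  NPCI = function(s) (R_at(s, 680) - R_at(s, 430)) / (R_at(s, 680) + R_at(s, 430)),
  GI = function(s) R_at(s, 554) / R_at(s, 677),
  WI1180 = function(s) R_at(s, 900) / R_at(s, 1180),
  NDVI = function(s) (R_at(s, 831) - R_at(s, 667)) / (R_at(s, 831) + R_at(s, 667)),
  CI = function(s) R_at(s, 760) / R_at(s, 695),
  VOG = function(s) R_at(s, 740) / R_at(s, 720),
  CRI = function(s) R_at(s, 800) * (1 / R_at(s, 520) - 1 / R_at(s, 550)),
  PRI1 = function(s) (R_at(s, 531) - R_at(s, 570)) / (R_at(s, 531) + R_at(s, 570)),
  PRI2 = function(s) 1.5 * (R_at(s, 830) - R_at(s, 660)) / (R_at(s, 830) - R_at(s, 660) + 0.5),
  PRI3 = function(s) (R_at(s, 539) - R_at(s, 570)) / (R_at(s, 539) + R_at(s, 570))
)

# Small leaf-level library on a short grid, built by hand.
tiny_library <- function() {
  g <- build_grid(400, 404, 1)
  refl <- rbind(
    c(0.2, 0.2, 0.2, 0.2, 0.2),
    c(0.4, 0.4, 0.4, 0.4, 0.4),
    c(0.1, 0.2, 0.3, 0.4, 0.5)
  )
  meta <- tibble::tibble(
    sample_id = c("p1_l1", "p1_l2", "p2_l1"),
    pot_id = c("p1", "p1", "p2"),
    metal = c("Cu", "Cu", "none"),
    level = c("L1", "L1", "C"),
    replicate = c(1L, 1L, 1L),
    leaf = c(1L, 2L, 1L)
  )
  spectral_library(refl, meta, g)
}

# Fast low-noise synthetic settings used by several pipeline tests.
quick_dataset <- function(seed = 1, metals = "Cd", reps = 4, leaves = 2) {
  generate_dataset(
    default_design(metals = metals, replicates_per_cell = reps,
                   leaves_per_pot = leaves),
    stress_response(),
    noise_model(seed = seed)
  )
}
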