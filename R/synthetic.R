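#' Default pot-dosing design of the stress experiment
#'
#' The emulated experiment doses grapevine seedling pots with one of five
#' heavy metals at 1-4 times the maximum allowed level (MAL) of the metal in
#' irrigation water, alongside undosed control pots. With the defaults --
#' five metals, four stressed levels, four replicate pots per metal x level
#' cell, and a single control group of four pots shared across metals -- the
#' design has 4 + 5 x 4 x 4 = 84 pots, and with five sampled leaves per pot,
#' 420 leaf spectra.
#'
#' @param metals Character vector of metal labels.
#' @param levels Integer dose multipliers for the stressed levels (units of
#'   MAL); level 0 (control) is implicit.
#' @param replicates_per_cell Replicate pots per metal x level cell.
#' @param control_shared If `TRUE` (default) one control group of
#'   `replicates_per_cell` pots is shared by all metals; if `FALSE` each metal
#'   gets its own control pots.
#' @param leaves_per_pot Leaves sampled per pot for spectroscopy.
#' @param mal_ugL Named vector of per-metal MALs in irrigation water (ug/L).
#'   The default carries the irrigation-water standard values for Cu, Zn, Pb
#'   and Cd; no standard value is available for Cr, so its entry is `NA` and
#'   must be supplied if a Cr water concentration is ever needed. The MALs
#'   are design metadata only: leaf concentrations are driven by the dose
#'   multiplier, not by the water concentration.
#'
#' @return An object of class `design_spec` with a `pots` tibble
#'   (`pot_id`, `metal`, `level`, `dose`, `replicate`).
#' @examples
#' d <- default_design()
#' nrow(d$pots)            # 84
#' nrow(d$pots) * d$leaves_per_pot  # 420
#' @export
default_design <- function(metals = c("Cu", "Zn", "Pb", "Cr", "Cd"),
                           levels = 1:4,
                           replicates_per_cell = 4,
                           control_shared = TRUE,
                           leaves_per_pot = 5,
                           mal_ugL = c(Cu = 200, Zn = 2000, Pb = 100,
                                       Cr = NA_real_, Cd = 10)) {
  stopifnot(length(metals) >= 1, all(levels > 0), replicates_per_cell >= 1,
            leaves_per_pot >= 1)
  reps <- seq_len(replicates_per_cell)
  stressed <- expand.grid(replicate = reps, dose = levels, metal = metals,
                          stringsAsFactors = FALSE)
  stressed$level <- paste0("L", stressed$dose)
  stressed$pot_id <- sprintf("%s-%s-r%d", stressed$metal, stressed$level,
                             stressed$replicate)
  if (control_shared) {
    controls <- data.frame(replicate = reps, dose = 0, metal = "none",
                           level = "C", pot_id = sprintf("C-r%d", reps))
  } else {
    controls <- expand.grid(replicate = reps, metal = metals,
                            stringsAsFactors = FALSE)
    controls$dose <- 0
    controls$level <- "C"
    controls$pot_id <- sprintf("%s-C-r%d", controls$metal, controls$replicate)
  }
  cols <- c("pot_id", "metal", "level", "dose", "replicate")
  pots <- tibble::as_tibble(rbind(controls[cols], stressed[cols]))
  structure(list(metals = metals, levels = levels,
                 replicates_per_cell = replicates_per_cell,
                 control_shared = control_shared,
                 leaves_per_pot = leaves_per_pot,
                 mal_ugL = mal_ugL, pots = pots),
            class = "design_spec")
}

#' @export
print.design_spec <- function(x, ...) {
  cat(sprintf("<design_spec> %d pots (%d metals x %d levels x %d reps%s), %d leaves/pot -> %d spectra\n",
              nrow(x$pots), length(x$metals), length(x$levels),
              x$replicates_per_cell,
              if (x$control_shared) " + shared control" else " + per-metal controls",
              x$leaves_per_pot, nrow(x$pots) * x$leaves_per_pot))
  invisible(x)
}

#' Parametric healthy-leaf reflectance baseline
#'
#' A qualitative green-leaf reflectance shape: low visible reflectance with a
#' green peak near 550 nm, a logistic red-edge rise between roughly 680 and
#' 750 nm to a near-infrared plateau, Gaussian water-absorption dips near
#' 1200, 1450 and 1940 nm, and a declining mid-infrared tail.
#'
#' @param grid A [`wavelength_grid`][build_grid].
#' @return Numeric reflectance vector on `grid` (values in \[0, 1\]).
#' @export
baseline_spectrum <- function(grid = canonical_grid()) {
  wl <- grid$channels
  r <- 0.04 +
    0.05 * exp(-(wl - 550)^2 / (2 * 35^2)) +              # green peak
    0.43 / (1 + exp(-(wl - 715) / 14)) +                  # red edge -> NIR
    -0.16 / (1 + exp(-(wl - 1350) / 120)) +               # MIR decline
    -0.04 * exp(-(wl - 1200)^2 / (2 * 30^2)) +            # weak water band
    -0.13 * exp(-(wl - 1450)^2 / (2 * 35^2)) +            # 1450 water band
    -0.18 * exp(-(wl - 1940)^2 / (2 * 50^2)) +            # 1940 water band
    -0.05 * exp(-(wl - 2500)^2 / (2 * 150^2))
  pmin(pmax(r, 0), 1)
}

# Wavelengths (nm) at which each metal's stress signal is planted; these are
# the bands the study design treats as metal-sensitive.
.SENSITIVE_BANDS <- list(
  Cu = c(2431, 809, 489, 616),
  Zn = c(2032, 883, 665, 564, 688, 437),
  Pb = c(1865, 728, 692, 683, 356),
  Cr = c(863, 2044, 415, 652, 713, 1036),
  Cd = c(1373, 631, 744, 438)
)

#' Stress-response model for spectra and leaf concentrations
#'
#' Describes how heavy-metal dose reshapes the leaf spectrum and raises leaf
#' concentrations. Per unit dose (one MAL), the reflectance of a stressed pot
#' is lifted broadband (region-specific amounts, reproducing the observation
#' that stressed leaves reflect more than healthy ones across the whole
#' range) and additionally bumped by Gaussian peaks centred at the metal's
#' sensitive bands. Pot-to-pot variability has two layers: a common
#' lognormal *uptake* factor (spread `uptake_cv`) scaling all of a pot's
#' band responses together -- pots that take up more metal respond more --
#' and an independent lognormal per-band jitter (spread `band_cv`) letting
#' the individual response mechanisms vary in relative strength. Leaf
#' concentration of the dosed metal follows a linear dose-response in the
#' dose multiplier.
#'
#' @param sensitive_bands Named list of band centres (nm) per metal.
#' @param band_amp Reflectance bump per unit dose at a band centre.
#' @param band_sd Gaussian width (nm) of each band bump.
#' @param region_lift Named vector: broadband reflectance lift per unit dose
#'   applied by primary spectral region.
#' @param uptake_cv Lognormal sigma of the per-pot common uptake factor
#'   (0 = all pots take up their nominal dose).
#' @param band_cv Lognormal sigma of the per-pot, per-band response jitter
#'   (0 = every band responds in fixed proportion to uptake).
#' @param conc_baseline_mgkg Named vector of control-leaf concentrations
#'   (mg/kg dry weight) per metal.
#' @param conc_slope_mgkg Named vector: concentration increase (mg/kg) per
#'   unit dose multiplier.
#' @param uptake_coupling If `TRUE` (default), a pot's measured concentration
#'   of its own dosing metal scales with the pot's realized uptake factor:
#'   pots that physiologically express the stress more strongly also
#'   accumulate more metal, so the spectral response carries information
#'   about the realized concentration beyond the nominal dose ladder. Only
#'   [generate_dataset()] (which draws the uptake factors) applies this;
#'   [generate_concentrations()] used standalone follows the nominal
#'   dose-response exactly.
#'
#' @return An object of class `stress_response`.
#' @export
stress_response <- function(sensitive_bands = .SENSITIVE_BANDS,
                            band_amp = 0.012,
                            band_sd = 10,
                            region_lift = c(VIS = 0.008, RDE = 0.008,
                                            NIR = 0.004, MIR = 0.006),
                            uptake_cv = 0.25,
                            band_cv = 0.3,
                            conc_baseline_mgkg = c(Cu = 8, Zn = 25, Pb = 4,
                                                   Cr = 1.5, Cd = 0.005),
                            conc_slope_mgkg = c(Cu = 25, Zn = 55, Pb = 25,
                                                Cr = 7, Cd = 90),
                            uptake_coupling = TRUE) {
  stopifnot(band_amp >= 0, band_sd > 0, all(region_lift >= 0),
            uptake_cv >= 0, band_cv >= 0)
  if (any(conc_slope_mgkg < 0)) stop("concentration slopes must be >= 0",
                                     call. = FALSE)
  if (any(conc_baseline_mgkg < 0)) stop("baseline concentrations must be >= 0",
                                        call. = FALSE)
  structure(list(sensitive_bands = sensitive_bands, band_amp = band_amp,
                 band_sd = band_sd, region_lift = region_lift,
                 uptake_cv = uptake_cv, band_cv = band_cv,
                 conc_baseline_mgkg = conc_baseline_mgkg,
                 conc_slope_mgkg = conc_slope_mgkg,
                 uptake_coupling = isTRUE(uptake_coupling)),
            class = "stress_response")
}

#' Measurement-noise model
#'
#' @param smooth_sd Standard deviation of smooth, spectrally correlated
#'   leaf-to-leaf reflectance noise (Gaussian-kernel-smoothed white noise).
#' @param smooth_bw_nm Smoothing bandwidth (nm) of the correlated noise.
#' @param uv_sd Extra white-noise standard deviation applied at 350-400 nm,
#'   where field spectra are noisiest.
#' @param conc_cv Coefficient of variation of the multiplicative lognormal
#'   assay noise on measured concentrations; the default reflects the
#'   sub-10-percent relative standard deviation typical of graphite-furnace
#'   AAS with acid digestion.
#' @param detection_limits_mgkg Named vector of instrument detection limits
#'   (mg/kg dry weight); measured values below the limit are reported *at*
#'   the limit and flagged as left-censored.
#' @param seed Integer RNG seed; the same seed reproduces the dataset
#'   bit-for-bit.
#'
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(smooth_sd = 0.01,
                        smooth_bw_nm = 50,
                        uv_sd = 0.02,
                        conc_cv = 0.09,
                        detection_limits_mgkg = c(Zn = 0.008, Cu = 0.025,
                                                  Pb = 0.01, Cr = 0.04,
                                                  Cd = 0.009),
                        seed = 1L) {
  stopifnot(smooth_sd >= 0, smooth_bw_nm > 0, uv_sd >= 0)
  if (conc_cv < 0) stop("`conc_cv` must be >= 0", call. = FALSE)
  structure(list(smooth_sd = smooth_sd, smooth_bw_nm = smooth_bw_nm,
                 uv_sd = uv_sd, conc_cv = conc_cv,
                 detection_limits_mgkg = detection_limits_mgkg,
                 seed = as.integer(seed)),
            class = "noise_model")
}

# Evaluate code with a temporary RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Smooth correlated noise: white noise convolved with a Gaussian kernel,
# rescaled to unit sd, so amplitude and correlation length are decoupled.
.smooth_noise <- function(n_channels, bw_channels) {
  half <- max(1L, ceiling(3 * bw_channels))
  w <- stats::dnorm(seq(-half, half), sd = bw_channels)
  e <- stats::rnorm(n_channels + 2 * half)
  z <- stats::filter(e, w / sum(w), sides = 2)
  z <- as.numeric(z[(half + 1):(half + n_channels)])
  z / stats::sd(z)
}

# Per-unit-dose reflectance effect profile for one pot: broadband regional
# lift plus Gaussian bumps at the metal's sensitive bands, each bump scaled
# by the pot's sensitivity factor.
.effect_profile <- function(wl, bands, sens, response, lift_by_channel) {
  eff <- lift_by_channel
  for (i in seq_along(bands)) {
    eff <- eff + response$band_amp * sens[i] *
      exp(-(wl - bands[i])^2 / (2 * response$band_sd^2))
  }
  eff
}

#' Generate measured leaf concentrations for a design
#'
#' Every pot is assayed for every metal in the design. The expected
#' concentration of a metal in a pot is `baseline + slope x dose`, where the
#' dose multiplier is nonzero only for the pot's own dosing metal. Measured
#' values carry mean-preserving multiplicative lognormal noise with
#' coefficient of variation `noise$conc_cv`, and values below the metal's
#' detection limit are reported at the limit with the `censored` flag set.
#'
#' @param design A [`design_spec`][default_design].
#' @param response A [`stress_response`].
#' @param noise A [`noise_model`] (its `seed` makes the draw deterministic).
#'
#' @return A tibble with columns `pot_id`, `metal`, `concentration_mgkg`,
#'   `censored`, one row per pot x metal.
#' @export
generate_concentrations <- function(design, response = stress_response(),
                                    noise = noise_model()) {
  stopifnot(inherits(design, "design_spec"), inherits(response, "stress_response"),
            inherits(noise, "noise_model"))
  .conc_table(design, response, noise,
              uptake = rep(1, nrow(design$pots)))
}

# Concentration table with per-pot uptake multipliers on the dose term
# (uptake = 1 reproduces the nominal dose-response).
.conc_table <- function(design, response, noise, uptake) {
  pots <- design$pots
  grid_df <- expand.grid(pot_id = pots$pot_id, metal = design$metals,
                         stringsAsFactors = FALSE)
  pot_row <- match(grid_df$pot_id, pots$pot_id)
  grid_df$dose <- ifelse(pots$metal[pot_row] == grid_df$metal,
                         pots$dose[pot_row] * uptake[pot_row], 0)
  mu <- response$conc_baseline_mgkg[grid_df$metal] +
    response$conc_slope_mgkg[grid_df$metal] * grid_df$dose
  sdlog <- sqrt(log(1 + noise$conc_cv^2))
  vals <- .with_seed(noise$seed, {
    mu * exp(stats::rnorm(length(mu), 0, sdlog) - sdlog^2 / 2)
  })
  lim <- noise$detection_limits_mgkg[grid_df$metal]
  censored <- !is.na(lim) & vals < lim
  vals[censored] <- lim[censored]
  tibble::tibble(pot_id = grid_df$pot_id, metal = grid_df$metal,
                 concentration_mgkg = as.numeric(vals),
                 censored = as.logical(censored))
}

#' Generate a full synthetic stress-experiment dataset
#'
#' Produces a leaf-level spectral library plus the matching concentration
#' table for a dosing design. Each pot receives a deterministic stressed
#' spectrum (healthy baseline plus its dose-scaled effect profile); each leaf
#' spectrum is the pot spectrum plus smooth correlated noise and extra
#' white noise in the 350-400 nm range, clipped to \[0, 1\]. The same
#' `noise$seed` reproduces the dataset exactly.
#'
#' @inheritParams generate_concentrations
#' @param grid Wavelength grid for the spectra (default canonical
#'   350-2500 nm at 1 nm).
#'
#' @return A list with elements `library` (a
#'   [`spectral_library`][spectral_library] of
#'   `nrow(design$pots) * design$leaves_per_pot` spectra) and
#'   `concentrations` (tibble as from [generate_concentrations()]).
#' @examples
#' ds <- generate_dataset(default_design(), noise = noise_model(seed = 7))
#' ds$library
#' @export
generate_dataset <- function(design = default_design(),
                             response = stress_response(),
                             noise = noise_model(),
                             grid = canonical_grid()) {
  stopifnot(inherits(design, "design_spec"), inherits(response, "stress_response"),
            inherits(noise, "noise_model"), inherits(grid, "wavelength_grid"))
  wl <- grid$channels
  base <- baseline_spectrum(grid)
  lift <- unname(response$region_lift[primary_region(wl)])
  pots <- design$pots
  n_leaf <- design$leaves_per_pot
  bw_ch <- noise$smooth_bw_nm / grid$step_nm

  spectra_seed <- (noise$seed + 1000003L) %% .Machine$integer.max
  uptake <- rep(1, nrow(pots))
  refl <- .with_seed(spectra_seed, {
    rows <- vector("list", nrow(pots) * n_leaf)
    k <- 0L
    for (i in seq_len(nrow(pots))) {
      bands <- response$sensitive_bands[[pots$metal[i]]]
      if (is.null(bands)) bands <- numeric(0)
      u <- exp(stats::rnorm(1, 0, response$uptake_cv))
      sens <- u * exp(stats::rnorm(length(bands), 0, response$band_cv))
      if (response$uptake_coupling && length(bands)) uptake[i] <- u
      # the broadband lift tracks the applied dose; the metal-specific band
      # responses track the pot's realized uptake, which is what makes the
      # sensitive bands the most concentration-informative channels
      pot_spec <- base + pots$dose[i] *
        .effect_profile(wl, bands, sens, response, lift)
      for (j in seq_len(n_leaf)) {
        leaf <- pot_spec
        if (noise$smooth_sd > 0)
          leaf <- leaf + noise$smooth_sd * .smooth_noise(length(wl), bw_ch)
        if (noise$uv_sd > 0) {
          uv <- wl <= 400
          leaf[uv] <- leaf[uv] + stats::rnorm(sum(uv), 0, noise$uv_sd)
        }
        k <- k + 1L
        rows[[k]] <- pmin(pmax(leaf, 0), 1)
      }
    }
    do.call(rbind, rows)
  })

  meta <- tibble::tibble(
    sample_id = paste0(rep(pots$pot_id, each = n_leaf), "_leaf",
                       rep(seq_len(n_leaf), nrow(pots))),
    pot_id = rep(pots$pot_id, each = n_leaf),
    metal = rep(pots$metal, each = n_leaf),
    level = rep(pots$level, each = n_leaf),
    replicate = rep(pots$replicate, each = n_leaf),
    leaf = rep(seq_len(n_leaf), nrow(pots))
  )
  list(library = spectral_library(refl, meta, grid),
       concentrations = .conc_table(design, response, noise, uptake))
}
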