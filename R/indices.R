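# Registry of the 32 vegetation spectral indices used by the pipeline.
# Each definition evaluates a band-arithmetic recipe through two accessors:
#   r(wl)       reflectance at a single wavelength (nm)
#   w(lo, hi)   arithmetic mean reflectance over the inclusive window (nm)
# Window notation such as R960-990 is read as the mean over the 1 nm grid.

.index_defs <- function(mndvi705 = c("printed", "literature")) {
  mndvi705 <- match.arg(mndvi705)
  defs <- list(
    list(name = "CAI", label = "Cellulose Absorption Index",
         expression = "0.5*(R2000 + R2200) - R2100",
         bands = c(2000, 2200, 2100),
         fun = function(r, w) 0.5 * (r(2000) + r(2200)) - r(2100)),
    list(name = "MSI", label = "Moisture Stress Index",
         expression = "R1600/R820", bands = c(1600, 820),
         fun = function(r, w) r(1600) / r(820)),
    list(name = "NDWI", label = "Normalized Difference Water Index",
         expression = "(R860 - R1240)/(R860 + R1240)", bands = c(860, 1240),
         fun = function(r, w) (r(860) - r(1240)) / (r(860) + r(1240))),
    list(name = "DWSI", label = "Disease Water Stress Index",
         expression = "(R802 + R547)/(R1657 + R682)",
         bands = c(802, 547, 1657, 682),
         fun = function(r, w) (r(802) + r(547)) / (r(1657) + r(682))),
    list(name = "RATIO975", label = "Band ratio at 975 nm",
         expression = "2*mean(R960:990)/(mean(R920:940) + mean(R1090:1110))",
         windows = list(c(960, 990), c(920, 940), c(1090, 1110)),
         fun = function(r, w) 2 * w(960, 990) / (w(920, 940) + w(1090, 1110))),
    list(name = "RATIO975_2", label = "Band ratio at 1200 nm",
         expression = "2*mean(R1180:1220)/(mean(R1090:1110) + mean(R1265:1285))",
         windows = list(c(1180, 1220), c(1090, 1110), c(1265, 1285)),
         fun = function(r, w) 2 * w(1180, 1220) / (w(1090, 1110) + w(1265, 1285))),
    list(name = "LCI", label = "Leaf Chlorophyll Index",
         expression = "(R850 - R710)/(R850 + R680)", bands = c(850, 710, 680),
         fun = function(r, w) (r(850) - r(710)) / (r(850) + r(680))),
    list(name = "DattA", label = "Datt index",
         expression = "(R780 - R710)/(R780 - R680)", bands = c(780, 710, 680),
         fun = function(r, w) (r(780) - r(710)) / (r(780) - r(680))),
    list(name = "mNDVI705",
         label = "Modified Red Edge Normalized Difference Vegetation Index",
         expression = if (mndvi705 == "printed")
           "(R750 + R705)/(R750 + R705 - 2*R445)"
         else "(R750 - R705)/(R750 + R705 - 2*R445)",
         bands = c(750, 705, 445),
         fun = if (mndvi705 == "printed") {
           function(r, w) (r(750) + r(705)) / (r(750) + r(705) - 2 * r(445))
         } else {
           function(r, w) (r(750) - r(705)) / (r(750) + r(705) - 2 * r(445))
         }),
    list(name = "SGB", label = "Chlorophyll Index SGB",
         expression = "(R750 - R445)/(R705 - R445)", bands = c(750, 705, 445),
         fun = function(r, w) (r(750) - r(445)) / (r(705) - r(445))),
    list(name = "SIPI", label = "Structure Intensive Pigment Index",
         expression = "(R445 - R800)/(R680 - R800)", bands = c(445, 800, 680),
         fun = function(r, w) (r(445) - r(800)) / (r(680) - r(800))),
    list(name = "SR", label = "Simple Ratio",
         expression = "R774/R677", bands = c(774, 677),
         fun = function(r, w) r(774) / r(677)),
    list(name = "R550", label = "Reflectance at 550 nm",
         expression = "R550", bands = 550, fun = function(r, w) r(550)),
    list(name = "R680", label = "Reflectance at 680 nm",
         expression = "R680", bands = 680, fun = function(r, w) r(680)),
    list(name = "WI", label = "Water Index",
         expression = "R900/R970", bands = c(900, 970),
         fun = function(r, w) r(900) / r(970)),
    list(name = "GM1", label = "Gitelson and Merzlyak chlorophyll 1",
         expression = "R750/R550", bands = c(750, 550),
         fun = function(r, w) r(750) / r(550)),
    list(name = "GM2", label = "Gitelson and Merzlyak chlorophyll 2",
         expression = "R750/R700", bands = c(750, 700),
         fun = function(r, w) r(750) / r(700)),
    list(name = "Lic1", label = "Lichtenthaler Index 1",
         expression = "(R800 - R680)/(R800 + R680)", bands = c(800, 680),
         fun = function(r, w) (r(800) - r(680)) / (r(800) + r(680))),
    list(name = "Lic2", label = "Lichtenthaler Index 2",
         expression = "R440/R690", bands = c(440, 690),
         fun = function(r, w) r(440) / r(690)),
    list(name = "Lic3", label = "Lichtenthaler Index 3",
         expression = "R440/R740", bands = c(440, 740),
         fun = function(r, w) r(440) / r(740)),
    list(name = "SRPI", label = "Simple Ratio Pigment Index",
         expression = "R430/R680", bands = c(430, 680),
         fun = function(r, w) r(430) / r(680)),
    list(name = "NPQI", label = "Normalized Phaeophytinization Index",
         expression = "(R415 - R435)/(R415 + R435)", bands = c(415, 435),
         fun = function(r, w) (r(415) - r(435)) / (r(415) + r(435))),
    list(name = "NPCI", label = "Normalized Pigment Chlorophyll Ratio Index",
         expression = "(R680 - R430)/(R680 + R430)", bands = c(680, 430),
         fun = function(r, w) (r(680) - r(430)) / (r(680) + r(430))),
    list(name = "GI", label = "Greenness Index",
         expression = "R554/R677", bands = c(554, 677),
         fun = function(r, w) r(554) / r(677)),
    list(name = "WI1180", label = "Water Index at 1180 nm",
         expression = "R900/R1180", bands = c(900, 1180),
         fun = function(r, w) r(900) / r(1180)),
    list(name = "NDVI", label = "Normalized Difference Vegetation Index",
         expression = "(R831 - R667)/(R831 + R667)", bands = c(831, 667),
         fun = function(r, w) (r(831) - r(667)) / (r(831) + r(667))),
    list(name = "CI", label = "Carter Index",
         expression = "R760/R695", bands = c(760, 695),
         fun = function(r, w) r(760) / r(695)),
    list(name = "VOG", label = "Vogelmann Index",
         expression = "R740/R720", bands = c(740, 720),
         fun = function(r, w) r(740) / r(720)),
    list(name = "CRI", label = "Carotenoid Reflectance Index",
         expression = "R800*(1/R520 - 1/R550)", bands = c(800, 520, 550),
         fun = function(r, w) r(800) * (1 / r(520) - 1 / r(550))),
    list(name = "PRI1", label = "Photochemical Reflectance Index 1",
         expression = "(R531 - R570)/(R531 + R570)", bands = c(531, 570),
         fun = function(r, w) (r(531) - r(570)) / (r(531) + r(570))),
    list(name = "PRI2", label = "Photochemical Reflectance Index 2",
         expression = "1.5*(R830 - R660)/(R830 - R660 + 0.5)",
         bands = c(830, 660),
         fun = function(r, w) 1.5 * (r(830) - r(660)) / (r(830) - r(660) + 0.5)),
    list(name = "PRI3", label = "Photochemical Reflectance Index 3",
         expression = "(R539 - R570)/(R539 + R570)", bands = c(539, 570),
         fun = function(r, w) (r(539) - r(570)) / (r(539) + r(570)))
  )
  names(defs) <- vapply(defs, `[[`, character(1), "name")
  defs
}

#' Registry of the 32 spectral indices
#'
#' Returns the executable definitions of the 32 vegetation indices computed
#' by the pipeline: name, long label, band-arithmetic expression, the
#' single-band wavelengths and band windows it requires, and an evaluator.
#' Two entries are plain single-band reflectances (R550, R680) and two are
#' window-mean band ratios (RATIO975, RATIO975_2) whose window terms are
#' arithmetic means over the inclusive window on the 1 nm grid.
#'
#' @param mndvi705 Which algebraic form of mNDVI705 to register:
#'   `"printed"` (default), `(R750 + R705)/(R750 + R705 - 2 R445)`, or the
#'   `"literature"` red-edge NDVI form `(R750 - R705)/(R750 + R705 - 2 R445)`.
#'
#' @return Named list of 32 index definitions.
#' @examples
#' length(index_registry())       # 32
#' index_registry()[["NDVI"]]$expression
#' @export
index_registry <- function(mndvi705 = c("printed", "literature")) {
  .index_defs(match.arg(mndvi705))
}

# Band accessors for one spectrum on its grid.
.band_accessors <- function(reflectance, channels) {
  r <- function(wl) {
    i <- match(wl, channels)
    if (is.na(i)) stop("wavelength ", wl, " nm not on the spectrum grid",
                       call. = FALSE)
    reflectance[i]
  }
  w <- function(lo, hi) {
    sel <- channels >= lo & channels <= hi
    if (!any(sel)) stop("window ", lo, "-", hi, " nm not on the spectrum grid",
                        call. = FALSE)
    mean(reflectance[sel])
  }
  list(r = r, w = w)
}

#' Compute one spectral index for a spectrum
#'
#' Evaluates the registered band-arithmetic recipe exactly. A zero
#' denominator yields a non-finite value (`Inf`/`NaN`) rather than an error;
#' non-finite results are the caller's signal that the formula degenerated on
#' this spectrum.
#'
#' @param spectrum A [`spectrum`][new_spectrum] on the canonical grid (any
#'   grid containing the index's bands works).
#' @param name Index short code, e.g. `"NDVI"`, `"SIPI"`.
#' @param registry Index registry (default [index_registry()]).
#'
#' @return A single numeric value (possibly non-finite).
#' @examples
#' s <- new_spectrum(rep(0.5, 2151), canonical_grid(), "flat")
#' compute_index(s, "NDVI")  # 0
#' compute_index(s, "MSI")   # 1
#' @export
compute_index <- function(spectrum, name, registry = index_registry()) {
  stopifnot(inherits(spectrum, "spectrum"))
  def <- registry[[name]]
  if (is.null(def)) stop("unknown index '", name, "'", call. = FALSE)
  acc <- .band_accessors(spectrum$reflectance, spectrum$grid$channels)
  as.numeric(def$fun(acc$r, acc$w))
}

#' Compute the full feature table of a library
#'
#' One row per spectrum, one column per registered index (32 by default),
#' preceded by `sample_id`. Non-finite index values are kept in place and
#' additionally listed in the `flagged` attribute (a tibble of
#' `sample_id`/`index` pairs); they are never silently dropped.
#'
#' @param lib A [`spectral_library`][spectral_library]. For the dosing
#'   experiment this is normally the pot-level library
#'   (see [aggregate.spectral_library()]).
#' @param registry Index registry (default [index_registry()]).
#'
#' @return A tibble `sample_id` + 32 index columns with attribute `flagged`.
#' @export
compute_feature_table <- function(lib, registry = index_registry()) {
  stopifnot(inherits(lib, "spectral_library"))
  if (nrow(lib$reflectance) == 0) stop("library is empty", call. = FALSE)
  channels <- lib$grid$channels
  vals <- vapply(seq_len(nrow(lib$reflectance)), function(i) {
    acc <- .band_accessors(lib$reflectance[i, ], channels)
    vapply(registry, function(def) as.numeric(def$fun(acc$r, acc$w)),
           numeric(1))
  }, numeric(length(registry)))
  tab <- tibble::as_tibble(t(vals))
  names(tab) <- names(registry)
  out <- tibble::tibble(sample_id = lib$metadata$sample_id)
  out <- cbind(out, tab)
  out <- tibble::as_tibble(out)
  nf <- which(!is.finite(as.matrix(tab)), arr.ind = TRUE)
  flagged <- tibble::tibble(
    sample_id = out$sample_id[nf[, "row"]],
    index = names(registry)[nf[, "col"]]
  )
  attr(out, "flagged") <- flagged
  out
}
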