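#' Build a uniform wavelength grid
#'
#' A wavelength grid is the ordered set of channel centres (in nm) on which
#' all spectra in a library live. The canonical grid used throughout the
#' package is 350--2500 nm at 1 nm spacing, i.e. 2151 channels, matching a
#' full-range field spectroradiometer export.
#'
#' @param start_nm First channel centre (nm).
#' @param stop_nm Last channel centre (nm). Must satisfy `start_nm <= stop_nm`
#'   and `(stop_nm - start_nm)` must be an integer multiple of `step_nm`.
#' @param step_nm Channel spacing (nm), strictly positive.
#'
#' @return An object of class `wavelength_grid`: a list with fields
#'   `start_nm`, `stop_nm`, `step_nm` and `channels` (numeric vector of
#'   channel centres, strictly increasing, uniformly spaced).
#' @examples
#' g <- build_grid(350, 2500, 1)
#' length(g$channels) # 2151
#' @export
build_grid <- function(start_nm = 350, stop_nm = 2500, step_nm = 1) {
  stopifnot(is.numeric(start_nm), is.numeric(stop_nm), is.numeric(step_nm))
  if (step_nm <= 0) stop("`step_nm` must be > 0", call. = FALSE)
  if (start_nm > stop_nm) stop("`start_nm` must be <= `stop_nm`", call. = FALSE)
  n_steps <- (stop_nm - start_nm) / step_nm
  if (abs(n_steps - round(n_steps)) > 1e-8) {
    stop("wavelength range (", start_nm, "-", stop_nm,
         " nm) is not divisible by step ", step_nm, " nm", call. = FALSE)
  }
  channels <- start_nm + step_nm * seq(0, round(n_steps))
  structure(
    list(start_nm = start_nm, stop_nm = stop_nm, step_nm = step_nm,
         channels = channels),
    class = "wavelength_grid"
  )
}

#' Canonical 350-2500 nm, 1 nm grid
#'
#' @return A `wavelength_grid` with 2151 channels.
#' @export
canonical_grid <- function() build_grid(350, 2500, 1)

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf("<wavelength_grid> %g-%g nm, step %g nm (%d channels)\n",
              x$start_nm, x$stop_nm, x$step_nm, length(x$channels)))
  invisible(x)
}

# Closed spectral-region intervals (nm). RDE deliberately overlaps VIS and
# NIR, and NIR overlaps MIR at 1300, as conventionally tabulated.
.REGIONS <- list(
  VIS = c(350, 700),
  RDE = c(680, 750),
  NIR = c(700, 1300),
  MIR = c(1300, 2500)
)

# Precedence used to assign a unique "primary" region to wavelengths that
# fall inside overlapping intervals.
.REGION_PRECEDENCE <- c("RDE", "VIS", "NIR", "MIR")

#' Classify a wavelength into spectral regions
#'
#' The 350--2500 nm spectrum is divided into four conventional regions:
#' visible (VIS, 350--700 nm), red edge (RDE, 680--750 nm), near-infrared
#' (NIR, 700--1300 nm) and mid-infrared (MIR, 1300--2500 nm). The intervals
#' are closed at both ends, so boundary wavelengths belong to every region
#' containing them; a single *primary* region is assigned by the precedence
#' RDE > VIS > NIR > MIR (the red edge, being the physiologically most
#' specific region, wins any overlap).
#'
#' @param wavelength_nm Numeric vector of wavelengths, each within 350--2500.
#'
#' @return A tibble with columns `wavelength_nm`, `regions` (list-column of
#'   character vectors) and `primary` (character).
#' @examples
#' classify_regions(c(550, 690, 2000))
#' @export
classify_regions <- function(wavelength_nm) {
  stopifnot(is.numeric(wavelength_nm))
  if (any(wavelength_nm < 350 | wavelength_nm > 2500)) {
    stop("wavelengths must lie within 350-2500 nm", call. = FALSE)
  }
  regions <- lapply(wavelength_nm, function(w) {
    names(.REGIONS)[vapply(.REGIONS, function(r) w >= r[1] && w <= r[2],
                           logical(1))]
  })
  primary <- vapply(regions, function(rs) {
    .REGION_PRECEDENCE[min(match(rs, .REGION_PRECEDENCE))]
  }, character(1))
  tibble::tibble(wavelength_nm = wavelength_nm, regions = regions,
                 primary = primary)
}

#' Primary spectral region of a wavelength
#'
#' Convenience wrapper around [classify_regions()] returning only the primary
#' region label.
#'
#' @inheritParams classify_regions
#' @return Character vector of region names (`"VIS"`, `"RDE"`, `"NIR"`,
#'   `"MIR"`).
#' @export
primary_region <- function(wavelength_nm) {
  classify_regions(wavelength_nm)$primary
}
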