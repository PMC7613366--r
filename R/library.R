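#' Construct a single reflectance spectrum
#'
#' @param reflectance Numeric vector of reflectance fractions, one per grid
#'   channel, each in \[0, 1\].
#' @param grid A [`wavelength_grid`][build_grid].
#' @param sample_id Sample identifier.
#'
#' @return An object of class `spectrum`.
#' @export
new_spectrum <- function(reflectance, grid, sample_id = "sample") {
  stopifnot(inherits(grid, "wavelength_grid"))
  reflectance <- .validate_reflectance(as.numeric(reflectance), sample_id)
  if (length(reflectance) != length(grid$channels)) {
    stop("spectrum has ", length(reflectance), " values but grid has ",
         length(grid$channels), " channels", call. = FALSE)
  }
  if (anyNA(reflectance)) stop("reflectance contains missing values", call. = FALSE)
  structure(list(grid = grid, reflectance = reflectance,
                 sample_id = as.character(sample_id)),
            class = "spectrum")
}

# Clips small instrument-noise excursions outside [0,1] (up to 0.05) with a
# warning; larger excursions indicate a calibration problem and are an error.
.validate_reflectance <- function(x, id = "sample") {
  bad <- x < -0.05 | x > 1.05
  if (any(bad, na.rm = TRUE)) {
    stop("reflectance for '", id, "' outside [-0.05, 1.05] at ",
         sum(bad, na.rm = TRUE), " channel(s)", call. = FALSE)
  }
  out_of_unit <- x < 0 | x > 1
  if (any(out_of_unit, na.rm = TRUE)) {
    warning("clipping ", sum(out_of_unit, na.rm = TRUE),
            " reflectance value(s) of '", id, "' into [0, 1]", call. = FALSE)
    x <- pmin(pmax(x, 0), 1)
  }
  x
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> '%s' on %g-%g nm (%d channels)\n", x$sample_id,
              x$grid$start_nm, x$grid$stop_nm, length(x$reflectance)))
  invisible(x)
}

.METADATA_COLS <- c("sample_id", "pot_id", "metal", "level", "replicate", "leaf")

#' Construct a spectral library
#'
#' A spectral library couples a reflectance matrix (samples x channels, all on
#' one wavelength grid) with per-sample experiment metadata: the pot the leaf
#' came from, which metal the pot was dosed with (`"none"` for controls), the
#' treatment level (`"C"`, `"L1"`..`"L4"`), the replicate pot index and the
#' leaf index within the pot.
#'
#' @param reflectance Numeric matrix, one row per sample, one column per grid
#'   channel; values in \[0, 1\].
#' @param metadata Data frame with columns `sample_id`, `pot_id`, `metal`,
#'   `level`, `replicate`, `leaf`; one row per spectrum, `sample_id` unique.
#' @param grid A [`wavelength_grid`][build_grid] shared by all spectra.
#'
#' @return An object of class `spectral_library` with fields `grid`,
#'   `reflectance` (rownames = sample ids) and `metadata` (tibble).
#' @export
spectral_library <- function(reflectance, metadata, grid) {
  stopifnot(inherits(grid, "wavelength_grid"))
  reflectance <- as.matrix(reflectance)
  metadata <- tibble::as_tibble(metadata)
  missing_cols <- setdiff(.METADATA_COLS, names(metadata))
  if (length(missing_cols)) {
    stop("metadata lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(reflectance) != nrow(metadata)) {
    stop("reflectance has ", nrow(reflectance), " rows but metadata has ",
         nrow(metadata), call. = FALSE)
  }
  if (ncol(reflectance) != length(grid$channels)) {
    stop("reflectance has ", ncol(reflectance), " columns but grid has ",
         length(grid$channels), " channels", call. = FALSE)
  }
  if (anyDuplicated(metadata$sample_id)) {
    stop("sample_ids must be unique", call. = FALSE)
  }
  if (anyNA(reflectance)) stop("reflectance contains missing values", call. = FALSE)
  rownames(reflectance) <- metadata$sample_id
  colnames(reflectance) <- paste0("R", grid$channels)
  structure(list(grid = grid, reflectance = reflectance, metadata = metadata),
            class = "spectral_library")
}

#' @export
print.spectral_library <- function(x, ...) {
  cat(sprintf("<spectral_library> %d spectra x %d channels (%g-%g nm)\n",
              nrow(x$reflectance), ncol(x$reflectance),
              x$grid$start_nm, x$grid$stop_nm))
  pots <- unique(x$metadata$pot_id)
  cat(sprintf("  pots: %d | metals: %s\n", length(pots),
              paste(sort(unique(x$metadata$metal)), collapse = ", ")))
  invisible(x)
}

#' Number of spectra in a library
#' @param lib A `spectral_library`.
#' @return Integer count of spectra.
#' @export
n_spectra <- function(lib) nrow(lib$reflectance)

#' Resample a spectrum onto a target grid
#'
#' Linear interpolation of reflectance at each target channel. The source
#' wavelengths must span the target grid: resampling never extrapolates.
#' Values already on-grid pass through unchanged.
#'
#' @param spectrum A [`spectrum`][new_spectrum], or a list with numeric fields
#'   `wavelength` and `reflectance`.
#' @param grid Target [`wavelength_grid`][build_grid].
#'
#' @return A `spectrum` on `grid`.
#' @export
resample_to_grid <- function(spectrum, grid) {
  stopifnot(inherits(grid, "wavelength_grid"))
  if (inherits(spectrum, "spectrum")) {
    wl <- spectrum$grid$channels
    rf <- spectrum$reflectance
    id <- spectrum$sample_id
  } else {
    wl <- spectrum$wavelength
    rf <- spectrum$reflectance
    id <- if (!is.null(spectrum$sample_id)) spectrum$sample_id else "sample"
  }
  if (min(wl) > min(grid$channels) || max(wl) < max(grid$channels)) {
    stop("source wavelengths (", min(wl), "-", max(wl),
         " nm) do not span the target grid (", grid$start_nm, "-",
         grid$stop_nm, " nm); refusing to extrapolate", call. = FALSE)
  }
  vals <- stats::approx(wl, rf, xout = grid$channels, method = "linear",
                        ties = mean)$y
  new_spectrum(vals, grid, id)
}

#' Read a two-column spectrometer text export
#'
#' Parses a plain-text export with two numeric columns (wavelength in nm,
#' reflectance fraction), whitespace- or comma-delimited, with optional
#' non-numeric header lines. Duplicate wavelengths (e.g. from detector seam
#' overlap) are averaged with a warning; the parsed values are then resampled
#' onto `grid` by linear interpolation.
#'
#' @param path Path to the text file.
#' @param grid Target grid (default: the canonical 350-2500 nm, 1 nm grid).
#' @param sample_id Sample identifier for the resulting spectrum (default:
#'   file name without extension).
#'
#' @return A [`spectrum`][new_spectrum] on `grid`.
#' @export
read_spectrum_text <- function(path, grid = canonical_grid(),
                               sample_id = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "[,;\t ]+")
  rows <- lapply(fields, function(f) suppressWarnings(as.numeric(f[1:2])))
  numeric_ok <- vapply(rows, function(r) length(r) == 2 && !anyNA(r), logical(1))
  # leading header lines are tolerated; non-numeric rows inside the data
  # block indicate a corrupt file
  first_data <- which(numeric_ok)[1]
  if (is.na(first_data)) stop("no numeric data rows in '", path, "'", call. = FALSE)
  if (any(!numeric_ok[seq(first_data, length(rows))])) {
    stop("non-numeric row(s) inside the data block of '", path, "'",
         call. = FALSE)
  }
  dat <- do.call(rbind, rows[numeric_ok])
  wl <- dat[, 1]; rf <- dat[, 2]
  if (any(rf < -0.05 | rf > 1.05)) {
    stop("reflectance outside [-0.05, 1.05] in '", path, "'", call. = FALSE)
  }
  if (anyDuplicated(wl)) {
    warning("averaging duplicate wavelength(s) in '", path, "'", call. = FALSE)
    agg <- tapply(rf, wl, mean)
    wl <- as.numeric(names(agg)); rf <- as.numeric(agg)
  }
  ord <- order(wl)
  if (is.null(sample_id)) sample_id <- sub("\\.[^.]*$", "", basename(path))
  resample_to_grid(list(wavelength = wl[ord], reflectance = rf[ord],
                        sample_id = sample_id), grid)
}

#' Read / write a spectral library as wide CSV
#'
#' The on-disk format is one row per spectrum with the metadata columns
#' `sample_id,pot_id,metal,level,replicate,leaf` followed by one reflectance
#' column per channel, named `R350`,...,`R2500`. Wavelengths are recovered
#' from the column names; if they differ from `grid`, spectra are resampled.
#'
#' @param path CSV file path.
#' @param grid Target grid (default canonical).
#' @return `read_library_csv()` returns a [`spectral_library`];
#'   `write_library_csv()` returns `path` invisibly.
#' @export
read_library_csv <- function(path, grid = canonical_grid()) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  wl_cols <- grep("^R[0-9.]+$", names(df), value = TRUE)
  if (!length(wl_cols)) stop("no reflectance columns (R<wavelength>) in '",
                             path, "'", call. = FALSE)
  wl <- as.numeric(sub("^R", "", wl_cols))
  refl <- as.matrix(df[wl_cols])
  meta <- tibble::as_tibble(df[intersect(.METADATA_COLS, names(df))])
  if (!identical(wl, grid$channels)) {
    refl <- t(apply(refl, 1, function(r) {
      resample_to_grid(list(wavelength = wl, reflectance = r), grid)$reflectance
    }))
  }
  spectral_library(refl, meta, grid)
}

#' @rdname read_library_csv
#' @param lib A [`spectral_library`].
#' @export
write_library_csv <- function(lib, path) {
  stopifnot(inherits(lib, "spectral_library"))
  df <- cbind(as.data.frame(lib$metadata),
              as.data.frame(lib$reflectance, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Aggregate a leaf-level library to pot level
#'
#' The modelling unit of the dosing experiment is the pot: the spectra of the
#' (typically five) leaves sampled from one pot are averaged channel-wise into
#' a single pot spectrum, and the metadata collapse to pot granularity (the
#' `leaf` index becomes `NA`, `sample_id` becomes the pot id).
#'
#' @param x A `spectral_library` at leaf level.
#' @param level Target granularity; only `"pot"` is supported.
#' @param ... Unused.
#'
#' @return A `spectral_library` with one spectrum per pot.
#' @export
aggregate.spectral_library <- function(x, level = "pot", ...) {
  level <- match.arg(level, "pot")
  pots <- unique(x$metadata$pot_id)
  if (!length(pots)) stop("library has no pots to aggregate", call. = FALSE)
  refl <- t(vapply(pots, function(p) {
    rows <- which(x$metadata$pot_id == p)
    if (!length(rows)) stop("pot '", p, "' has zero spectra", call. = FALSE)
    colMeans(x$reflectance[rows, , drop = FALSE])
  }, numeric(ncol(x$reflectance))))
  meta <- x$metadata[match(pots, x$metadata$pot_id), ]
  meta$sample_id <- meta$pot_id
  meta$leaf <- NA_integer_
  spectral_library(refl, meta, x$grid)
}
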