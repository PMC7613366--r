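#' Per-wavelength correlation between reflectance and metal concentration
#'
#' For each metal, the Pearson correlation between pot-level reflectance at
#' every channel and the measured concentration of that metal across pots --
#' the correlogram used to screen which spectral regions respond to which
#' metal. Censored (below-detection-limit) concentrations are excluded
#' pairwise by default, since their reported value is the detection limit,
#' not a measurement.
#'
#' @param lib A pot-level [`spectral_library`][spectral_library] (sample ids
#'   equal to pot ids; see [aggregate.spectral_library()]).
#' @param concentrations Concentration tibble (`pot_id`, `metal`,
#'   `concentration_mgkg`, `censored`), as from [generate_concentrations()].
#' @param drop_censored Exclude censored rows (default TRUE).
#'
#' @return A tibble `metal`, `wavelength_nm`, `r` with `r` in \[-1, 1\].
#' @export
compute_correlogram <- function(lib, concentrations, drop_censored = TRUE) {
  stopifnot(inherits(lib, "spectral_library"))
  metals <- unique(concentrations$metal)
  out <- lapply(metals, function(m) {
    rows <- concentrations[concentrations$metal == m, ]
    if (drop_censored) rows <- rows[!rows$censored, ]
    idx <- match(rows$pot_id, lib$metadata$sample_id)
    keep <- !is.na(idx) & !is.na(rows$concentration_mgkg)
    if (sum(keep) < 3) {
      stop("fewer than 3 aligned pots with usable ", m, " concentrations",
           call. = FALSE)
    }
    r <- suppressWarnings(
      as.numeric(stats::cor(lib$reflectance[idx[keep], , drop = FALSE],
                            rows$concentration_mgkg[keep]))
    )
    tibble::tibble(metal = m, wavelength_nm = lib$grid$channels, r = r)
  })
  do.call(rbind, out)
}

#' Channel-wise group-mean spectra
#'
#' Mean reflectance per channel for each group of spectra, with group sizes.
#' Grouping `"status"` contrasts healthy (control) pots against all stressed
#' pots, the classic stressed-vs-healthy mean-spectrum comparison; `"metal"`
#' and `"level"` group by dosing metal and treatment level.
#'
#' @param lib A [`spectral_library`][spectral_library].
#' @param grouping One of `"status"`, `"metal"`, `"level"`.
#'
#' @return A tibble `group`, `n`, `wavelength_nm`, `mean_reflectance`.
#' @export
mean_spectra_by_group <- function(lib,
                                  grouping = c("status", "metal", "level")) {
  stopifnot(inherits(lib, "spectral_library"))
  grouping <- match.arg(grouping)
  g <- switch(grouping,
              status = ifelse(lib$metadata$level == "C", "healthy", "stressed"),
              metal = lib$metadata$metal,
              level = lib$metadata$level)
  out <- lapply(unique(g), function(lev) {
    rows <- which(g == lev)
    if (!length(rows)) stop("empty group '", lev, "'", call. = FALSE)
    tibble::tibble(group = lev, n = length(rows),
                   wavelength_nm = lib$grid$channels,
                   mean_reflectance =
                     unname(colMeans(lib$reflectance[rows, , drop = FALSE])))
  })
  do.call(rbind, out)
}

#' Default experiment configuration
#'
#' The configuration tree consumed by [run_experiment()]. The `synthetic`
#' block parameterizes [default_design()], [stress_response()] and
#' [noise_model()]; the remaining blocks control the split, PLS, MLR and SVR
#' stages. `scale_before_split = FALSE` (the default) fits all min-max
#' scalers on the training set only and applies them to the test set,
#' avoiding information leakage; setting it `TRUE` scales on the pooled data
#' before splitting instead.
#'
#' @param seed Global integer seed; every random stage derives from it.
#' @return A nested list of class `experiment_config`.
#' @export
default_config <- function(seed = 1) {
  structure(list(
    seed = as.integer(seed),
    synthetic = list(design = list(), response = list(), noise = list()),
    metals = c("Cu", "Zn", "Pb", "Cr", "Cd"),
    tracks = c("wavelengths", "indices"),
    model_level = "pot",
    scale_before_split = FALSE,
    split = list(fraction = 0.7, stratify = TRUE),
    pls = list(k_max = 10, v_folds = 10),
    mlr = list(alpha_enter = 0.05),
    svr = list(grid = "full", v_folds = 5)
  ), class = "experiment_config")
}

#' Read an experiment configuration from YAML
#'
#' Reads a YAML file and merges it over [default_config()]; unknown keys are
#' rejected so typos fail loudly.
#'
#' @param path YAML file path.
#' @return An `experiment_config`.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  base <- default_config()
  unknown <- setdiff(names(user), names(base))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  merged <- utils::modifyList(unclass(base), user)
  merged$seed <- as.integer(merged$seed)
  structure(merged, class = "experiment_config")
}

.validate_config <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  stopifnot(is.integer(config$seed) || is.numeric(config$seed),
            config$split$fraction > 0, config$split$fraction < 1,
            config$pls$k_max >= 1, config$pls$v_folds >= 2,
            config$mlr$alpha_enter > 0, config$mlr$alpha_enter < 1,
            config$svr$v_folds >= 2,
            all(config$tracks %in% c("wavelengths", "indices")))
  invisible(config)
}

.msg <- function(quiet, ...) if (!quiet) message(sprintf(...))

#' Run the full estimation experiment
#'
#' End-to-end orchestration: generate the synthetic dosing dataset,
#' aggregate leaf spectra to pot level, build the two feature tracks (raw
#' wavelengths and the 32 spectral indices), min-max scale, split 70/30
#' (stratified by treatment cell), select features per metal by
#' cross-validated PLS1 with the max-loading rule, then fit and evaluate a
#' forward-selection MLR (with Durbin-Watson/VIF/significance gating) and a
#' grid-tuned epsilon-SVR on the selected features. Deterministic given the
#' config seed.
#'
#' @param config An [`experiment_config`][default_config].
#' @param out_dir Optional directory; if given, the report bundle is written
#'   there via [write_report_bundle()].
#' @param quiet Suppress stage-progress messages.
#'
#' @return An object of class `report_bundle`: tibbles `models` (one row per
#'   metal x track x method with structure, diagnostics and train/test
#'   metrics), `selection` (per-metal PLS summary), `correlogram`,
#'   `mean_spectra`, plus `sizes` and the resolved `config`.
#' @export
run_experiment <- function(config = default_config(), out_dir = NULL,
                           quiet = FALSE) {
  .validate_config(config)
  seed <- config$seed

  design <- do.call(default_design, config$synthetic$design)
  response <- do.call(stress_response, config$synthetic$response)
  noise_args <- config$synthetic$noise
  if (is.null(noise_args$seed)) noise_args$seed <- seed
  noise <- do.call(noise_model, noise_args)

  .msg(quiet, "[simulate] %d pots x %d leaves -> %d spectra, %d channels",
       nrow(design$pots), design$leaves_per_pot,
       nrow(design$pots) * design$leaves_per_pot,
       length(canonical_grid()$channels))
  ds <- generate_dataset(design, response, noise)
  pots <- aggregate(ds$library, level = "pot")
  .msg(quiet, "[aggregate] %d pot spectra", n_spectra(pots))

  features <- list()
  if ("wavelengths" %in% config$tracks) features$wavelengths <- pots$reflectance
  if ("indices" %in% config$tracks) {
    ft <- compute_feature_table(pots)
    .msg(quiet, "[indices] %d x %d feature table", nrow(ft), ncol(ft) - 1)
    features$indices <- as.matrix(ft[, -1])
    rownames(features$indices) <- ft$sample_id
  }

  correlogram <- compute_correlogram(pots, ds$concentrations)
  mean_spectra <- mean_spectra_by_group(ds$library, "status")

  strata <- if (isTRUE(config$split$stratify)) {
    paste(pots$metadata$metal, pots$metadata$level)
  } else NULL
  split <- split_train_test(pots$metadata$sample_id,
                            fraction = config$split$fraction,
                            seed = seed, strata = strata)
  .msg(quiet, "[split] %d train / %d test pots", length(split$train),
       length(split$test))

  svr_grid_df <- if (identical(config$svr$grid, "small")) svr_grid_small()
                 else if (identical(config$svr$grid, "full")) svr_grid()
                 else do.call(svr_grid, config$svr$grid)

  selection_rows <- list()
  model_rows <- list()
  for (metal in config$metals) {
    conc <- ds$concentrations[ds$concentrations$metal == metal, ]
    y_all <- conc$concentration_mgkg[match(pots$metadata$sample_id,
                                           conc$pot_id)]
    for (track in names(features)) {
      X_all <- features[[track]]
      tr <- match(split$train, rownames(X_all))
      te <- match(split$test, rownames(X_all))
      fit_rows <- if (isTRUE(config$scale_before_split)) seq_len(nrow(X_all)) else tr

      sx <- suppressWarnings(fit_minmax(X_all[fit_rows, , drop = FALSE]))
      sy <- fit_minmax(y_all[fit_rows])
      Xs <- suppressWarnings(transform_minmax(sx, X_all))
      ys <- transform_minmax(sy, y_all)

      cv <- choose_components(Xs[tr, , drop = FALSE], ys[tr],
                              k_max = config$pls$k_max,
                              v_folds = config$pls$v_folds, seed = seed)
      pls <- fit_pls1(Xs[tr, , drop = FALSE], ys[tr], cv$k)
      sel <- select_variables(pls)
      .msg(quiet, "[select] %s/%s: k = %d -> %s", metal, track, cv$k,
           paste(sel$variable, collapse = ", "))
      selection_rows[[paste(metal, track)]] <- tibble::tibble(
        metal = metal, track = track, k = cv$k,
        cumvar_x = sum(pls$explained_x), cumvar_y = sum(pls$explained_y),
        variables = paste(sel$variable, collapse = ", "),
        regions = paste(stats::na.omit(sel$region), collapse = ", ")
      )

      Xsel <- Xs[, sel$variable, drop = FALSE]
      for (method in c("mlr", "svr")) {
        model <- if (method == "mlr") {
          suppressWarnings(
            fit_mlr_forward(Xsel[tr, , drop = FALSE], ys[tr],
                            alpha_enter = config$mlr$alpha_enter)
          )
        } else {
          tune_and_fit_svr(Xsel[tr, , drop = FALSE], ys[tr],
                           grid = svr_grid_df,
                           v_folds = config$svr$v_folds, seed = seed)
        }
        m_train <- evaluate_model(model, Xsel[tr, , drop = FALSE], ys[tr], sy)
        m_test <- evaluate_model(model, Xsel[te, , drop = FALSE], ys[te], sy)
        row <- tibble::tibble(
          metal = metal, track = track, method = method,
          structure = if (method == "mlr") {
            equation_string(model, response = paste0("C_", metal))
          } else {
            sprintf("kernel=%s cost=%g epsilon=%g gamma=%s degree=%s coef0=%s",
                    model$config$kernel, model$config$cost,
                    model$config$epsilon, model$config$gamma,
                    model$config$degree, model$config$coef0)
          },
          kernel = if (method == "svr") model$config$kernel else NA_character_,
          n_support = if (method == "svr") model$n_support else NA_integer_,
          r2_train = m_train$r2, rmse_train = m_train$rmse,
          rmse_train_mgkg = m_train$rmse_original,
          r2_test = m_test$r2, rmse_test = m_test$rmse,
          rmse_test_mgkg = m_test$rmse_original
        )
        if (method == "mlr") {
          v <- validate_mlr(model)
          row$dw <- v$dw; row$max_vif <- v$max_vif; row$p_value <- v$p_value
          row$valid <- v$valid
        } else {
          row$dw <- NA_real_; row$max_vif <- NA_real_
          row$p_value <- NA_real_; row$valid <- NA
        }
        model_rows[[paste(metal, track, method)]] <- row
        .msg(quiet, "[fit] %s/%s/%s: test R2 = %.2f", metal, track, method,
             row$r2_test)
      }
    }
  }

  bundle <- structure(list(
    models = do.call(rbind, model_rows),
    selection = do.call(rbind, selection_rows),
    correlogram = correlogram,
    mean_spectra = mean_spectra,
    sizes = list(n_pots = nrow(design$pots),
                 n_spectra = n_spectra(ds$library),
                 n_channels = length(canonical_grid()$channels),
                 n_indices = length(index_registry()),
                 n_train = length(split$train), n_test = length(split$test)),
    config = config
  ), class = "report_bundle")
  if (!is.null(out_dir)) write_report_bundle(bundle, out_dir)
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("<report_bundle> %d model reports (%d metals x %d tracks x 2 methods)\n",
              nrow(x$models), length(unique(x$models$metal)),
              length(unique(x$models$track))))
  print(x$models[c("metal", "track", "method", "r2_test", "rmse_test_mgkg")])
  invisible(x)
}

# CSV with a provenance header line (seed + config hash), readable back with
# read.csv(..., comment.char = "#").
.write_csv_stamped <- function(df, path, stamp) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", stamp), con)
  utils::write.csv(df, con, row.names = FALSE)
}

#' Write a report bundle to disk
#'
#' Writes the model table, the PLS selection table, the correlogram and the
#' group-mean spectra as CSV (each stamped with the seed and a hash of the
#' resolved configuration), the full model table as JSON, and the resolved
#' configuration as YAML.
#'
#' @param bundle A [`report_bundle`][run_experiment].
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_report_bundle <- function(bundle, out_dir) {
  stopifnot(inherits(bundle, "report_bundle"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_yaml <- yaml::as.yaml(unclass(bundle$config))
  cfg_hash <- substr(.simple_hash(cfg_yaml), 1, 12)
  stamp <- sprintf("seed=%d config_sha=%s", bundle$config$seed, cfg_hash)
  .write_csv_stamped(bundle$models, file.path(out_dir, "models.csv"), stamp)
  .write_csv_stamped(bundle$selection, file.path(out_dir, "selection.csv"),
                     stamp)
  .write_csv_stamped(bundle$correlogram, file.path(out_dir, "correlogram.csv"),
                     stamp)
  .write_csv_stamped(bundle$mean_spectra,
                     file.path(out_dir, "mean_spectra.csv"), stamp)
  jsonlite::write_json(list(stamp = stamp, sizes = bundle$sizes,
                            models = bundle$models),
                       file.path(out_dir, "models.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  writeLines(cfg_yaml, file.path(out_dir, "config.yaml"))
  invisible(out_dir)
}

# Small dependency-free content fingerprint (polynomial rolling hash over
# UTF-8 bytes, hex); used only to stamp artifacts with their config.
.simple_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
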