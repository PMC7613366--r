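#' Default epsilon-SVR tuning grid
#'
#' Hyperparameter grid for [tune_and_fit_svr()], covering the four kernel
#' families (linear, radial basis function, polynomial, sigmoid). Parameters
#' irrelevant to a kernel (e.g. gamma for the linear kernel, degree for
#' anything but polynomial) are not expanded, so the grid holds one row per
#' distinct configuration.
#'
#' @param cost Cost (C) values.
#' @param epsilon Epsilon-tube widths.
#' @param gamma Kernel gamma values (radial, polynomial, sigmoid).
#' @param degree Polynomial degrees.
#' @param coef0 Kernel offset values (polynomial, sigmoid).
#' @param kernels Kernel families to include.
#'
#' @return A data frame with columns `kernel`, `cost`, `epsilon`, `gamma`,
#'   `degree`, `coef0` (NA where not applicable).
#' @export
svr_grid <- function(cost = c(0.1, 1, 10, 100),
                     epsilon = c(0.01, 0.1),
                     gamma = c(0.05, 0.1, 0.25, 0.5, 1),
                     degree = 2:11,
                     coef0 = c(0, 1),
                     kernels = c("linear", "radial", "polynomial", "sigmoid")) {
  blocks <- list()
  if ("linear" %in% kernels) {
    blocks$linear <- expand.grid(kernel = "linear", cost = cost,
                                 epsilon = epsilon, gamma = NA_real_,
                                 degree = NA_real_, coef0 = NA_real_,
                                 stringsAsFactors = FALSE)
  }
  if ("radial" %in% kernels) {
    blocks$radial <- expand.grid(kernel = "radial", cost = cost,
                                 epsilon = epsilon, gamma = gamma,
                                 degree = NA_real_, coef0 = NA_real_,
                                 stringsAsFactors = FALSE)
  }
  if ("polynomial" %in% kernels) {
    blocks$polynomial <- expand.grid(kernel = "polynomial", cost = cost,
                                     epsilon = epsilon, gamma = gamma,
                                     degree = degree, coef0 = coef0,
                                     stringsAsFactors = FALSE)
  }
  if ("sigmoid" %in% kernels) {
    blocks$sigmoid <- expand.grid(kernel = "sigmoid", cost = cost,
                                  epsilon = epsilon, gamma = gamma,
                                  degree = NA_real_, coef0 = coef0,
                                  stringsAsFactors = FALSE)
  }
  if (!length(blocks)) stop("empty kernel set", call. = FALSE)
  do.call(rbind, unname(blocks))
}

#' A reduced grid for quick runs
#'
#' Linear + RBF kernels over a coarse cost/gamma lattice; useful when the
#' full grid's polynomial block is not worth its runtime.
#'
#' @return A data frame as from [svr_grid()].
#' @export
svr_grid_small <- function() {
  svr_grid(cost = c(1, 10, 100), epsilon = 0.1,
           gamma = c(0.05, 0.25, 1), degree = 2:3, coef0 = 0,
           kernels = c("linear", "radial"))
}

.fit_svr_config <- function(cfg, X, y) {
  args <- list(x = X, y = y, type = "eps-regression", kernel = cfg$kernel,
               cost = cfg$cost, epsilon = cfg$epsilon, scale = FALSE)
  if (!is.na(cfg$gamma)) args$gamma <- cfg$gamma
  if (!is.na(cfg$degree)) args$degree <- cfg$degree
  if (!is.na(cfg$coef0)) args$coef0 <- cfg$coef0
  do.call(e1071::svm, args)
}

#' Grid-tuned epsilon support vector regression
#'
#' Tunes an epsilon-SVR ("regression SVM type 1") over a kernel/parameter
#' grid by seeded v-fold cross-validation on the training set, selecting the
#' configuration with the lowest cross-validated RMSE (ties broken by grid
#' order), then refits it on the full training set. Inputs are expected
#' already min-max scaled, so no internal standardization is applied.
#'
#' @param X_train Numeric predictor matrix (n x p), scaled.
#' @param y_train Numeric response, scaled.
#' @param grid Configuration grid, as from [svr_grid()].
#' @param v_folds Number of CV folds (default 5).
#' @param seed Integer RNG seed for the fold assignment.
#'
#' @return An object of class `svr_model`: the refitted `e1071::svm` `fit`,
#'   the winning `config` row, `cv_rmse` (vector over the whole grid),
#'   `n_support` (support-vector count) and the fold assignment seed.
#' @export
tune_and_fit_svr <- function(X_train, y_train, grid = svr_grid(),
                             v_folds = 5, seed = 1) {
  X_train <- as.matrix(X_train); y_train <- as.numeric(y_train)
  n <- nrow(X_train)
  stopifnot(length(y_train) == n, v_folds >= 2, n >= v_folds)
  if (is.null(grid) || nrow(grid) == 0) stop("empty tuning grid", call. = FALSE)
  folds <- .with_seed(seed, sample(rep(seq_len(v_folds), length.out = n)))
  cv_rmse <- vapply(seq_len(nrow(grid)), function(i) {
    cfg <- grid[i, ]
    sq <- numeric(n)
    for (v in seq_len(v_folds)) {
      hold <- folds == v
      fit <- tryCatch(
        .fit_svr_config(cfg, X_train[!hold, , drop = FALSE], y_train[!hold]),
        error = function(e) NULL
      )
      if (is.null(fit)) return(Inf)
      sq[hold] <- (y_train[hold] -
                     stats::predict(fit, X_train[hold, , drop = FALSE]))^2
    }
    sqrt(mean(sq))
  }, numeric(1))
  best <- which.min(cv_rmse)
  fit <- .fit_svr_config(grid[best, ], X_train, y_train)
  structure(list(fit = fit, config = grid[best, ], cv_rmse = cv_rmse,
                 n_support = fit$tot.nSV, v_folds = v_folds, seed = seed),
            class = "svr_model")
}

#' @export
print.svr_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<svr_model> kernel %s | cost %g, epsilon %g%s%s%s | %d support vectors\n",
              cfg$kernel, cfg$cost, cfg$epsilon,
              if (!is.na(cfg$gamma)) sprintf(", gamma %g", cfg$gamma) else "",
              if (!is.na(cfg$degree)) sprintf(", degree %g", cfg$degree) else "",
              if (!is.na(cfg$coef0)) sprintf(", coef0 %g", cfg$coef0) else "",
              x$n_support))
  invisible(x)
}

#' @export
predict.svr_model <- function(object, newdata, ...) {
  unname(stats::predict(object$fit, as.matrix(newdata)))
}
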