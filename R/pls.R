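#' Fit a single-response PLS (PLS1) model by NIPALS
#'
#' Classical NIPALS partial least squares with one response. Predictors and
#' response are mean-centred internally (inputs are normally already min-max
#' scaled to \[0, 1\]); per component the algorithm takes the unit-norm weight
#' vector `w` proportional to `X'y`, scores `t = X w`, X-loading
#' `p = X't/(t't)`, y-loading `q = y't/(t't)`, then deflates `X` and `y`.
#' Regression coefficients on the input scale are recovered as
#' `B = W (P'W)^{-1} q`.
#'
#' @param X Numeric matrix, samples x variables (n x p).
#' @param y Numeric response vector of length n with positive variance.
#' @param k Number of components, `1 <= k <= min(n - 1, p)`.
#'
#' @return An object of class `pls1_model`: weights `W` (p x k), X-loadings
#'   `P`, y-loadings `q`, scores `T`, centring offsets, input-scale
#'   `coefficients` and `intercept`, and `explained_x` / `explained_y`
#'   (percent variance captured per component).
#' @examples
#' X <- matrix(rnorm(40), 20, 2); y <- X[, 1] + rnorm(20, 0, 0.1)
#' m <- fit_pls1(X, y, k = 2)
#' m$explained_y
#' @export
fit_pls1 <- function(X, y, k) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n)
  if (stats::sd(y) == 0) stop("response has zero variance", call. = FALSE)
  if (k < 1 || k > min(n - 1, p)) {
    stop("`k` must lie in 1..min(n - 1, p) = ", min(n - 1, p), call. = FALSE)
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(p))
  x_mean <- colMeans(X); y_mean <- mean(y)
  E <- sweep(X, 2, x_mean); f <- y - y_mean
  ss_x <- sum(E^2); ss_y <- sum(f^2)
  W <- P <- matrix(0, p, k, dimnames = list(colnames(X), NULL))
  Tm <- matrix(0, n, k)
  q <- numeric(k)
  exp_x <- exp_y <- numeric(k)
  reached <- 0L
  for (a in seq_len(k)) {
    w <- drop(crossprod(E, f))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12 * max(1, sqrt(ss_x))) break  # nothing left to model
    w <- w / nw
    t_a <- drop(E %*% w)
    tt <- sum(t_a^2)
    if (tt < .Machine$double.eps) break
    p_a <- drop(crossprod(E, t_a)) / tt
    q_a <- sum(f * t_a) / tt
    E <- E - tcrossprod(t_a, p_a)
    f <- f - t_a * q_a
    W[, a] <- w; P[, a] <- p_a; Tm[, a] <- t_a; q[a] <- q_a
    exp_x[a] <- 100 * tt * sum(p_a^2) / ss_x
    exp_y[a] <- 100 * tt * q_a^2 / ss_y
    reached <- a
  }
  if (reached == 0L) stop("no PLS component could be extracted", call. = FALSE)
  if (reached < k) {
    warning("X was exhausted after ", reached, " components (", k,
            " requested)", call. = FALSE)
    W <- W[, seq_len(reached), drop = FALSE]
    P <- P[, seq_len(reached), drop = FALSE]
    Tm <- Tm[, seq_len(reached), drop = FALSE]
    q <- q[seq_len(reached)]
    exp_x <- exp_x[seq_len(reached)]; exp_y <- exp_y[seq_len(reached)]
  }
  coefs <- drop(W %*% solve(crossprod(P, W), q))
  names(coefs) <- colnames(X)
  structure(list(n_components = reached, W = W, P = P, q = q, scores = Tm,
                 x_mean = x_mean, y_mean = y_mean,
                 coefficients = coefs,
                 intercept = y_mean - sum(x_mean * coefs),
                 explained_x = exp_x, explained_y = exp_y),
            class = "pls1_model")
}

#' @export
print.pls1_model <- function(x, ...) {
  cat(sprintf("<pls1_model> %d component(s), %d variables\n", x$n_components,
              nrow(x$W)))
  cat(sprintf("  cumulative explained variance: X %.1f%%, y %.1f%%\n",
              sum(x$explained_x), sum(x$explained_y)))
  invisible(x)
}

#' Predict from a PLS1 model
#'
#' @param object A [`pls1_model`][fit_pls1].
#' @param newdata Numeric matrix with the same columns as the training `X`.
#' @param k Number of components to use (default: all fitted components).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.pls1_model <- function(object, newdata, k = object$n_components, ...) {
  stopifnot(k >= 1, k <= object$n_components)
  newdata <- as.matrix(newdata)
  b <- .pls1_coef_k(object, k)
  drop(sweep(newdata, 2, object$x_mean) %*% b) + object$y_mean
}

# Input-scale coefficient vector using the first k components only.
.pls1_coef_k <- function(model, k) {
  W <- model$W[, seq_len(k), drop = FALSE]
  P <- model$P[, seq_len(k), drop = FALSE]
  drop(W %*% solve(crossprod(P, W), model$q[seq_len(k)]))
}

#' Choose the PLS component count by v-fold cross-validation
#'
#' Computes the cross-validated RMSE (RMSECV) for each component count
#' `1..k_max` with a seeded v-fold partition and returns the count at the
#' global RMSECV minimum, breaking ties toward fewer components. The per-fold
#' RMSE spread is also reported as a standard error so callers can judge
#' whether extra components buy anything real.
#'
#' @inheritParams fit_pls1
#' @param k_max Largest component count to consider (capped at what the
#'   smallest training fold supports).
#' @param v_folds Number of folds (default 10, `>= 2`).
#' @param seed Integer RNG seed for the fold assignment.
#'
#' @return An object of class `pls_cv`: `k` (chosen count), `rmsecv`
#'   (length-`k_max` vector), `se` (per-count standard error over folds),
#'   `v_folds`, `seed`.
#' @export
choose_components <- function(X, y, k_max = 10, v_folds = 10, seed = 1) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (v_folds < 2) stop("`v_folds` must be >= 2", call. = FALSE)
  if (n < v_folds) stop("need at least `v_folds` samples", call. = FALSE)
  folds <- .with_seed(seed, sample(rep(seq_len(v_folds), length.out = n)))
  min_train <- min(tabulate(folds, v_folds))
  k_max <- min(k_max, n - min_train - 1, ncol(X))
  if (k_max < 1) stop("too few samples for even one component", call. = FALSE)
  sqerr <- matrix(NA_real_, n, k_max)
  for (v in seq_len(v_folds)) {
    hold <- folds == v
    fit <- fit_pls1(X[!hold, , drop = FALSE], y[!hold], k_max)
    for (k in seq_len(min(k_max, fit$n_components))) {
      pred <- predict(fit, X[hold, , drop = FALSE], k = k)
      sqerr[hold, k] <- (y[hold] - pred)^2
    }
    # if X was exhausted early, reuse the deepest available component count
    if (fit$n_components < k_max) {
      for (k in seq(fit$n_components + 1, k_max)) {
        sqerr[hold, k] <- sqerr[hold, fit$n_components]
      }
    }
  }
  rmsecv <- sqrt(colMeans(sqerr))
  fold_rmse <- vapply(seq_len(k_max), function(k) {
    vapply(seq_len(v_folds), function(v) sqrt(mean(sqerr[folds == v, k])),
           numeric(1))
  }, numeric(v_folds))
  se <- apply(fold_rmse, 2, stats::sd) / sqrt(v_folds)
  structure(list(k = which.min(rmsecv), rmsecv = rmsecv, se = se,
                 v_folds = v_folds, seed = seed),
            class = "pls_cv")
}

#' @export
print.pls_cv <- function(x, ...) {
  cat(sprintf("<pls_cv> chosen k = %d (RMSECV %.4g) of %d candidates, %d folds\n",
              x$k, x$rmsecv[x$k], length(x$rmsecv), x$v_folds))
  invisible(x)
}

#' Select one variable per PLS component by maximum factor loading
#'
#' The feature-selection rule of the pipeline: for each fitted component, in
#' order, pick the variable with the largest absolute factor loading; if that
#' variable was already selected by an earlier component, take the
#' next-highest loading instead (so the selected set has exactly one distinct
#' variable per component). "Factor loading" is read as the X-loading vector
#' `p` by default; the weight vector `w` can be used instead.
#'
#' Variables whose names encode wavelengths (`R<nm>` or bare numbers) are
#' annotated with the wavelength and its primary spectral region.
#'
#' @param model A fitted [`pls1_model`][fit_pls1].
#' @param dedupe Enforce distinct selections across components (default TRUE).
#' @param use `"loadings"` (default) or `"weights"`.
#'
#' @return A tibble with columns `component`, `variable`, `loading`,
#'   `wavelength_nm`, `region` (the latter two `NA` for non-wavelength
#'   variables such as spectral indices).
#' @export
select_variables <- function(model, dedupe = TRUE,
                             use = c("loadings", "weights")) {
  stopifnot(inherits(model, "pls1_model"))
  use <- match.arg(use)
  L <- if (use == "loadings") model$P else model$W
  vars <- rownames(L)
  chosen <- character(0)
  rows <- lapply(seq_len(ncol(L)), function(a) {
    ord <- order(abs(L[, a]), decreasing = TRUE)
    pick <- if (dedupe) ord[!(vars[ord] %in% chosen)][1] else ord[1]
    chosen <<- c(chosen, vars[pick])
    list(component = a, variable = vars[pick], loading = unname(L[pick, a]))
  })
  out <- tibble::tibble(
    component = vapply(rows, `[[`, numeric(1), "component"),
    variable = vapply(rows, `[[`, character(1), "variable"),
    loading = vapply(rows, `[[`, numeric(1), "loading")
  )
  wl <- suppressWarnings(as.numeric(sub("^R", "", out$variable)))
  out$wavelength_nm <- wl
  out$region <- NA_character_
  ok <- !is.na(wl) & wl >= 350 & wl <= 2500
  if (any(ok)) out$region[ok] <- primary_region(wl[ok])
  out
}
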