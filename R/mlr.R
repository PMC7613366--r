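#' Forward-selection multiple linear regression
#'
#' Builds the linear model `y = a0 + a1 x1 + ... + an xn` by forward
#' selection: at each step the candidate giving the largest R-squared
#' increase (equivalently the largest residual-sum-of-squares drop, assessed
#' with [stats::add1()] partial F-tests) is added, provided its partial-F
#' p-value is below `alpha_enter`; selection stops when no candidate
#' qualifies. The final model is an ordinary least-squares refit on the
#' selected predictors. An exact copy of an already-selected predictor can
#' never qualify (its partial F is 0), so collinear duplicates are excluded
#' by construction.
#'
#' @param X Numeric matrix or data frame of candidate predictors (named
#'   columns).
#' @param y Numeric response.
#' @param alpha_enter Entry threshold for the partial-F p-value (default
#'   0.05).
#' @param force_in Optional character vector of predictors included
#'   unconditionally before selection starts (use all columns to reproduce a
#'   plain OLS fit).
#'
#' @return An object of class `mlr_model`: the underlying `lm` fit,
#'   `selected` predictor names, `coefficients`, `residuals`, overall-F
#'   `p_value`, per-predictor `vif` and Durbin-Watson `dw`.
#' @examples
#' X <- data.frame(x1 = rnorm(50), x2 = rnorm(50))
#' m <- fit_mlr_forward(X, 1 + 2 * X$x1)
#' m$selected  # "x1"
#' @export
fit_mlr_forward <- function(X, y, alpha_enter = 0.05, force_in = NULL) {
  dat <- as.data.frame(X)
  stopifnot(nrow(dat) == length(y), alpha_enter > 0, alpha_enter < 1)
  names(dat) <- make.names(names(dat))
  candidates <- names(dat)
  force_in <- make.names(force_in %||% character(0))
  stopifnot(all(force_in %in% candidates))
  dat$.y <- as.numeric(y)
  selected <- force_in
  repeat {
    remaining <- setdiff(candidates, selected)
    if (!length(remaining)) break
    fml <- stats::reformulate(if (length(selected)) selected else "1",
                              response = ".y")
    fit <- stats::lm(fml, data = dat)
    # upper scope = current terms plus all remaining candidates
    tab <- stats::add1(fit, scope = stats::reformulate(candidates),
                       test = "F")
    tab <- tab[rownames(tab) %in% remaining, , drop = FALSE]
    ok <- !is.na(tab$`Pr(>F)`) & tab$`Pr(>F)` < alpha_enter
    if (!any(ok)) break
    best <- rownames(tab)[ok][which.min(tab$RSS[ok])]
    selected <- c(selected, best)
  }
  if (!length(selected)) {
    warning("no candidate qualified at alpha = ", alpha_enter,
            "; returning intercept-only model", call. = FALSE)
  }
  fml <- stats::reformulate(if (length(selected)) selected else "1",
                            response = ".y")
  fit <- stats::lm(fml, data = dat)
  sm <- summary(fit)
  p_value <- if (is.null(sm$fstatistic)) NA_real_ else {
    unname(stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                     lower.tail = FALSE))
  }
  vifs <- if (length(selected) >= 2) {
    vif(dat[selected])
  } else {
    stats::setNames(rep(NA_real_, length(selected)), selected)
  }
  structure(list(fit = fit, selected = selected,
                 coefficients = stats::coef(fit),
                 residuals = stats::residuals(fit),
                 r_squared = sm$r.squared,
                 p_value = p_value, vif = vifs,
                 dw = durbin_watson(stats::residuals(fit)),
                 alpha_enter = alpha_enter),
            class = "mlr_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.mlr_model <- function(x, ...) {
  cat("<mlr_model> ", equation_string(x), "\n", sep = "")
  cat(sprintf("  R2 %.3f | overall-F p %.3g | Durbin-Watson %.2f\n",
              x$r_squared, x$p_value, x$dw))
  invisible(x)
}

#' @export
predict.mlr_model <- function(object, newdata, ...) {
  nd <- as.data.frame(newdata)
  names(nd) <- make.names(names(nd))
  unname(stats::predict(object$fit, newdata = nd))
}

#' Human-readable equation of a fitted MLR model
#'
#' @param model An `mlr_model`.
#' @param response Label for the left-hand side (default `"C"`).
#' @param digits Coefficient digits.
#' @return A string such as `"C = -6.66 + (4.70 x SIPI) + (1.13 x DWSI)"`.
#' @export
equation_string <- function(model, response = "C", digits = 3) {
  co <- model$coefficients
  terms <- sprintf("(%s x %s)", format(co[-1], digits = digits, trim = TRUE),
                   names(co)[-1])
  paste0(response, " = ", format(co[1], digits = digits, trim = TRUE),
         if (length(terms)) paste0(" + ", paste(terms, collapse = " + ")) else "")
}

#' Durbin-Watson statistic of a residual series
#'
#' `d = sum_{t>=2} (e_t - e_{t-1})^2 / sum_t e_t^2`, computed on residuals in
#' observation (dataset row) order; values near 2 indicate no first-order
#' autocorrelation, with 1.5-2.5 taken as the acceptable band. The range of
#' `d` is \[0, 4\]. All-zero residuals leave `d` undefined (`NA` with a
#' warning).
#'
#' @param residuals Numeric vector of at least 3 residuals in observation
#'   order.
#' @return The statistic `d`, a single number in \[0, 4\] (or `NA`).
#' @examples
#' durbin_watson(c(1, -1, 1, -1))  # 3
#' @export
durbin_watson <- function(residuals) {
  e <- as.numeric(residuals)
  if (length(e) < 3) stop("need >= 3 residuals", call. = FALSE)
  denom <- sum(e^2)
  if (denom == 0) {
    warning("all residuals are zero; Durbin-Watson undefined", call. = FALSE)
    return(NA_real_)
  }
  sum(diff(e)^2) / denom
}

#' Variance inflation factors
#'
#' `VIF_j = 1/(1 - R2_j)` where `R2_j` is the coefficient of determination of
#' predictor j regressed on all other predictors. Values are `>= 1`; values
#' above 10 conventionally flag serious multicollinearity, and exactly
#' collinear predictors are reported as `Inf`.
#'
#' @param X Numeric matrix or data frame with at least two columns and more
#'   rows than columns.
#' @return Named numeric vector of VIFs.
#' @examples
#' vif(data.frame(a = c(1, 2, 3, 4), b = c(1, -1, 1, -1)))
#' @export
vif <- function(X) {
  dat <- as.data.frame(X)
  if (ncol(dat) < 2) stop("VIF needs >= 2 predictors", call. = FALSE)
  if (nrow(dat) <= ncol(dat)) stop("VIF needs n > number of predictors",
                                   call. = FALSE)
  vapply(names(dat), function(j) {
    fml <- stats::reformulate(setdiff(names(dat), j), response = j)
    r2 <- summary(stats::lm(fml, data = dat))$r.squared
    if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
}

#' Validity gates for an MLR model
#'
#' Applies the three standard regression-validity gates used to vet the
#' concentration models: residual independence (Durbin-Watson `d` within
#' 1.5-2.5), absence of serious multicollinearity (all VIF < 10) and overall
#' regression significance (F-test p < 0.05). A model failing any gate is
#' flagged invalid but still reported.
#'
#' @param model A fitted [`mlr_model`][fit_mlr_forward].
#' @return A tibble with logical columns `dw_ok`, `vif_ok`,
#'   `significance_ok`, `valid` and the underlying `dw`, `max_vif`,
#'   `p_value`.
#' @export
validate_mlr <- function(model) {
  stopifnot(inherits(model, "mlr_model"))
  dw_ok <- !is.na(model$dw) && model$dw >= 1.5 && model$dw <= 2.5
  max_vif <- if (length(model$vif) && any(!is.na(model$vif))) {
    max(model$vif, na.rm = TRUE)
  } else NA_real_
  vif_ok <- is.na(max_vif) || is.finite(max_vif) && max_vif < 10
  significance_ok <- !is.na(model$p_value) && model$p_value < 0.05
  tibble::tibble(dw_ok = dw_ok, vif_ok = vif_ok,
                 significance_ok = significance_ok,
                 valid = dw_ok && vif_ok && significance_ok,
                 dw = model$dw, max_vif = max_vif, p_value = model$p_value)
}

#' Goodness-of-fit metrics for a fitted model
#'
#' Computes `R2 = 1 - SSE/SST` and `RMSE = sqrt(mean((y - yhat)^2))` on the
#' supplied data, in the units of `y` (normally the 0-1 scaled
#' concentration). When the concentration scaler is supplied, predictions
#' and observations are also inverted to original units (mg/kg dry weight)
#' and the original-unit RMSE is reported alongside.
#'
#' @param model A fitted `mlr_model`, `svr_model` or `pls1_model`.
#' @param X Predictor matrix/data frame for the evaluation set.
#' @param y Observed response on the evaluation set (same scale the model
#'   was trained on).
#' @param scaler Optional [`minmax_scaler`][fit_minmax] fitted on the
#'   concentration, used to express RMSE in mg/kg.
#'
#' @return A tibble with columns `r2`, `rmse` and `rmse_original`
#'   (`NA` when no scaler is given). `r2` is `NA` with a warning when the
#'   observed values are constant (SST = 0).
#' @export
evaluate_model <- function(model, X, y, scaler = NULL) {
  pred <- stats::predict(model, X)
  y <- as.numeric(y)
  sse <- sum((y - pred)^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) {
    warning("observed values are constant; R2 undefined", call. = FALSE)
    NA_real_
  } else 1 - sse / sst
  rmse <- sqrt(mean((y - pred)^2))
  rmse_orig <- if (!is.null(scaler)) {
    sqrt(mean((invert_minmax(scaler, y) - invert_minmax(scaler, pred))^2))
  } else NA_real_
  tibble::tibble(r2 = r2, rmse = rmse, rmse_original = rmse_orig)
}
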