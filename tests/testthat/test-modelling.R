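test_that("forward selection recovers a noiseless linear model", {
  set.seed(1)
  X <- data.frame(x1 = rnorm(40), junk = rnorm(40))
  y <- 1 + 2 * X$x1
  # lm warns about the (intentionally) perfect fit
  m <- suppressWarnings(fit_mlr_forward(X, y))
  expect_equal(m$selected, "x1")
  expect_equal(unname(m$coefficients), c(1, 2), tolerance = 1e-10)
  expect_equal(m$r_squared, 1, tolerance = 1e-10)
})

test_that("forward selection resists pure noise", {
  # expected intercept-only rate is (1 - alpha)^2 ~ 0.90 for two candidates;
  # the bound below sits three binomial sigmas under it
  keep <- 0
  for (s in 1:50) {
    set.seed(s)
    X <- matrix(rnorm(400), 200, 2, dimnames = list(NULL, c("a", "b")))
    m <- suppressWarnings(fit_mlr_forward(X, rnorm(200)))
    if (length(m$selected) == 0) keep <- keep + 1
  }
  expect_gte(keep / 50, 0.78)
})

test_that("an exact duplicate predictor is never added twice", {
  set.seed(2)
  x1 <- rnorm(60)
  X <- data.frame(x1 = x1, copy = x1)
  y <- 2 * x1 + rnorm(60, 0, 0.05)
  m <- fit_mlr_forward(X, y)
  expect_length(m$selected, 1)
})

test_that("forcing all predictors in reproduces textbook least squares", {
  set.seed(3)
  X <- matrix(rnorm(80), 20, 4, dimnames = list(NULL, paste0("v", 1:4)))
  y <- rnorm(20)
  m <- fit_mlr_forward(X, y, force_in = colnames(X))
  # normal-equations oracle
  A <- cbind(1, X)
  beta <- solve(crossprod(A), crossprod(A, y))
  expect_equal(unname(m$coefficients), unname(drop(beta)), tolerance = 1e-8)
})

test_that("Durbin-Watson follows its defining formula", {
  expect_equal(durbin_watson(c(1, 1, 1)), 0)
  expect_equal(durbin_watson(c(1, -1, 1, -1)), 3)  # 12 / 4
  # scale invariance
  set.seed(4)
  e <- rnorm(50)
  expect_equal(durbin_watson(3.7 * e), durbin_watson(e))
  expect_equal(durbin_watson(-e), durbin_watson(e))
  expect_warning(d <- durbin_watson(c(0, 0, 0)), "undefined")
  expect_true(is.na(d))
  expect_error(durbin_watson(c(1, 2)), ">= 3")
})

test_that("Durbin-Watson agrees with the lmtest implementation", {
  set.seed(5)
  dat <- data.frame(x = rnorm(40))
  dat$y <- 1 + dat$x + rnorm(40)
  fit <- lm(y ~ x, data = dat)
  expect_equal(durbin_watson(residuals(fit)),
               unname(lmtest::dwtest(fit)$statistic), tolerance = 1e-10)
})

test_that("VIF is exact for orthogonal, collinear and near-collinear designs", {
  X <- data.frame(a = c(1, -1, 1, -1, 1, -1), b = c(1, 1, -1, -1, 1, 1))
  expect_equal(unname(vif(X)), c(1, 1), tolerance = 1e-10)

  x1 <- rnorm(30)
  expect_true(all(is.infinite(
    suppressWarnings(vif(data.frame(x1 = x1, dup = x1)))
  )))

  set.seed(6)
  z <- rnorm(500)
  near <- data.frame(x1 = z, x2 = z + rnorm(500, 0, 0.03))
  expect_true(all(vif(near) > 10))
  expect_error(vif(data.frame(a = 1:5)), ">= 2 predictors")
})

test_that("VIF agrees with the car implementation", {
  set.seed(7)
  dat <- data.frame(a = rnorm(50), b = rnorm(50), c = rnorm(50))
  dat$b <- dat$a + rnorm(50, 0, 0.5)
  dat$y <- rnorm(50)
  fit <- lm(y ~ a + b + c, data = dat)
  expect_equal(vif(dat[c("a", "b", "c")]), car::vif(fit), tolerance = 1e-8)
})

test_that("validity gates combine Durbin-Watson, VIF and significance", {
  good <- structure(list(dw = 2.0, vif = c(a = 1, b = 1), p_value = 0.001),
                    class = "mlr_model")
  v <- validate_mlr(good)
  expect_true(v$valid)

  low_dw <- structure(list(dw = 1.39, vif = c(a = 1, b = 1), p_value = 0.001),
                      class = "mlr_model")
  v <- validate_mlr(low_dw)
  expect_false(v$dw_ok)
  expect_false(v$valid)

  collinear <- structure(list(dw = 2, vif = c(a = Inf, b = 2), p_value = 0.001),
                         class = "mlr_model")
  expect_false(validate_mlr(collinear)$vif_ok)

  insig <- structure(list(dw = 2, vif = c(a = 1, b = 1), p_value = 0.2),
                     class = "mlr_model")
  expect_false(validate_mlr(insig)$significance_ok)
})

test_that("SVR tuning recovers a noiseless linear relationship", {
  set.seed(8)
  X <- matrix(runif(180), 60, 3)
  y <- 0.2 + 0.5 * X[, 1] - 0.3 * X[, 2]
  tr <- 1:42; te <- 43:60
  grid <- svr_grid(kernels = c("linear", "radial"), epsilon = c(0.01, 0.1),
                   gamma = c(0.1, 1))
  sv <- tune_and_fit_svr(X[tr, ], y[tr], grid = grid, v_folds = 5, seed = 1)
  met <- evaluate_model(sv, X[te, ], y[te])
  expect_gte(met$r2, 0.99)
  expect_lte(sv$n_support, length(tr))

  sv2 <- tune_and_fit_svr(X[tr, ], y[tr], grid = grid, v_folds = 5, seed = 1)
  expect_identical(sv$config, sv2$config)
  expect_error(tune_and_fit_svr(X[tr, ], y[tr], grid = grid[0, ], seed = 1),
               "empty")
})

test_that("metrics follow their definitions exactly", {
  m_ident <- structure(list(), class = "identity_model")
  predict.identity_model <<- function(object, newdata, ...) as.numeric(newdata)
  on.exit(rm("predict.identity_model", envir = globalenv()), add = TRUE)

  y <- c(0, 1, 2)
  met <- evaluate_model(m_ident, y, y)
  expect_equal(met$r2, 1)
  expect_equal(met$rmse, 0)

  met2 <- evaluate_model(m_ident, rep(1, 3), y)  # predicting the mean
  expect_equal(met2$r2, 0)

  met3 <- evaluate_model(m_ident, c(0, 1, 3), y)
  expect_equal(met3$rmse, sqrt(1 / 3))

  expect_warning(met4 <- evaluate_model(m_ident, y, rep(1, 3)), "constant")
  expect_true(is.na(met4$r2))
})

test_that("original-unit RMSE is the scaled RMSE times the fitted range", {
  set.seed(9)
  y_orig <- runif(20, 10, 110)
  sc <- fit_minmax(y_orig)
  ys <- transform_minmax(sc, y_orig)
  m_shift <- structure(list(), class = "shift_model")
  predict.shift_model <<- function(object, newdata, ...) {
    as.numeric(newdata) + 0.05
  }
  on.exit(rm("predict.shift_model", envir = globalenv()), add = TRUE)
  met <- evaluate_model(m_shift, ys, ys, scaler = sc)
  expect_equal(met$rmse_original, met$rmse * (max(y_orig) - min(y_orig)),
               tolerance = 1e-10)
})

test_that("equation strings mirror the fitted coefficients", {
  set.seed(10)
  X <- data.frame(SIPI = rnorm(30), DWSI = rnorm(30))
  y <- -6.66 + 4.70 * X$SIPI + 1.13 * X$DWSI
  m <- suppressWarnings(fit_mlr_forward(X, y))  # perfect-fit lm warning
  eq <- equation_string(m, response = "C_Cd")
  expect_match(eq, "^C_Cd = ")
  expect_match(eq, "SIPI")
  expect_match(eq, "DWSI")
})
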