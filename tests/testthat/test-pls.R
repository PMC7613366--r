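test_that("a single noiseless predictor is fit exactly with one component", {
  set.seed(1)
  x <- matrix(rnorm(30), 30, 1)
  y <- 2 * x[, 1]
  m <- fit_pls1(x, y, k = 1)
  expect_equal(unname(predict(m, x)), y, tolerance = 1e-10)
  expect_equal(sum(m$explained_y), 100, tolerance = 1e-8)
})

test_that("full-rank PLS reproduces ordinary least squares", {
  for (seed in 1:10) {
    set.seed(seed)
    X <- matrix(rnorm(100), 20, 5)
    y <- rnorm(20)
    m <- fit_pls1(X, y, k = 5)
    ols <- stats::lm.fit(cbind(1, X), y)
    expect_equal(unname(predict(m, X)), unname(ols$fitted.values),
                 tolerance = 1e-6, info = paste("seed", seed))
    # explained y-variance at full rank equals the OLS R-squared
    r2_ols <- 1 - sum(ols$residuals^2) / sum((y - mean(y))^2)
    expect_equal(sum(m$explained_y) / 100, r2_ols, tolerance = 1e-6)
  }
})

test_that("score vectors are mutually orthogonal", {
  set.seed(3)
  m <- fit_pls1(matrix(rnorm(300), 30, 10), rnorm(30), k = 6)
  G <- crossprod(m$scores)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8 * max(diag(G)))
})

test_that("explained variances are non-negative and bounded", {
  set.seed(4)
  m <- fit_pls1(matrix(rnorm(200), 20, 10), rnorm(20), k = 8)
  expect_true(all(m$explained_x >= 0))
  expect_true(all(m$explained_y >= 0))
  expect_lte(sum(m$explained_x), 100 + 1e-8)
  expect_lte(sum(m$explained_y), 100 + 1e-8)
})

test_that("degenerate inputs are rejected", {
  X <- matrix(rnorm(40), 20, 2)
  expect_error(fit_pls1(X, rep(1, 20), k = 1), "zero variance")
  expect_error(fit_pls1(X, rnorm(20), k = 3), "min")
})

test_that("cross-validation finds a single latent factor", {
  set.seed(5)
  n <- 100; p <- 20
  f <- rnorm(n)
  X <- outer(f, runif(p, 0.5, 1)) + matrix(rnorm(n * p, 0, 0.05), n, p)
  y <- 2 * f + rnorm(n, 0, 0.05)
  cv <- choose_components(X, y, k_max = 5, v_folds = 10, seed = 3)
  expect_equal(cv$k, 1)
})

test_that("cross-validation does not build spurious complexity on noise", {
  # on pure noise the chosen k's RMSECV stays within one standard error of
  # the one-component solution
  for (s in 1:10) {
    set.seed(s)
    X <- matrix(rnorm(500), 50, 10)
    y <- rnorm(50)
    cv <- choose_components(X, y, k_max = 5, v_folds = 10, seed = s)
    expect_gte(cv$rmsecv[cv$k], cv$rmsecv[1] - cv$se[1])
  }
})

test_that("component choice is deterministic given the seed", {
  set.seed(6)
  X <- matrix(rnorm(300), 30, 10); y <- rnorm(30)
  a <- choose_components(X, y, k_max = 5, v_folds = 5, seed = 11)
  b <- choose_components(X, y, k_max = 5, v_folds = 5, seed = 11)
  expect_identical(a$k, b$k)
  expect_identical(a$rmsecv, b$rmsecv)
})

test_that("max-loading selection finds a dominant driver first", {
  set.seed(7)
  n <- 40
  x1 <- rnorm(n)
  X <- cbind(big = 3 * x1, small1 = rnorm(n, 0, 0.1),
             small2 = rnorm(n, 0, 0.1))
  y <- x1
  m <- fit_pls1(X, y, k = 2)
  sel <- select_variables(m)
  expect_equal(sel$variable[1], "big")
})

test_that("duplicate maxima fall through to the runner-up variable", {
  mock <- structure(list(
    P = matrix(c(1.0, 0.2, 0.1,
                 0.9, 0.5, 0.05), 3, 2,
               dimnames = list(c("V1", "V2", "V3"), NULL)),
    W = matrix(0, 3, 2, dimnames = list(c("V1", "V2", "V3"), NULL))
  ), class = "pls1_model")
  sel <- select_variables(mock)
  expect_equal(sel$variable, c("V1", "V2"))
  sel_dup <- select_variables(mock, dedupe = FALSE)
  expect_equal(sel_dup$variable, c("V1", "V1"))
})

test_that("selection is invariant to variable order", {
  set.seed(8)
  X <- matrix(rnorm(200), 20, 10,
              dimnames = list(NULL, paste0("R", 401:410)))
  y <- X[, 3] + 0.5 * X[, 7] + rnorm(20, 0, 0.1)
  m <- fit_pls1(X, y, k = 3)
  sel <- select_variables(m)
  perm <- sample(10)
  m2 <- fit_pls1(X[, perm], y, k = 3)
  sel2 <- select_variables(m2)
  expect_setequal(sel2$variable, sel$variable)
})

test_that("selected wavelengths carry their primary region", {
  set.seed(9)
  X <- matrix(rnorm(60), 20, 3,
              dimnames = list(NULL, c("R550", "R700", "SIPI")))
  y <- X[, 1] + rnorm(20, 0, 0.1)
  m <- fit_pls1(X, y, k = 3)
  sel <- select_variables(m)
  expect_equal(sel$region[sel$variable == "R550"], "VIS")
  expect_equal(sel$region[sel$variable == "R700"], "RDE")
  expect_true(is.na(sel$region[sel$variable == "SIPI"]))
})
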