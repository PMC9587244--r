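test_that("differencing is exactly invertible", {
  p <- series_panel(cbind(x = c(1, 3, 6, 10)))
  d <- difference(p)
  expect_equal(unname(d$values[, 1]), c(2, 3, 4))
  expect_equal(de_difference(d)$values, p$values)

  # anchored forecast integration is the inverse of differencing the tail
  fc <- de_difference(d, forecast = matrix(c(5, 1), 2, 1), at = 3)
  expect_equal(unname(fc[, 1]), c(15, 16))

  set.seed(2)
  rp <- series_panel(matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c"))))
  expect_equal(de_difference(difference(rp))$values, rp$values)

  # grouped (per-patient) differencing round-trips too
  gp <- series_panel(matrix(rnorm(30), 10, 3), variables = c("a", "b", "c"),
                     groups = rep(1:5, each = 2))
  dg <- difference(gp)
  expect_identical(nrow(dg$values), 5L)   # one diff per 2-row block
  expect_equal(de_difference(dg)$values, gp$values)

  expect_error(de_difference(rp), "scale reference")
})

test_that("ADF test matches its published approximation and is calibrated", {
  # frozen oracle points for the MacKinnon constant-only p-value surface
  taus <- c(-3.5, -2.8612, -1.9, -1.33, -0.5, 0.3)
  ps <- c(0.00798709, 0.05004953, 0.33206111, 0.61533800, 0.89201650, 0.97734449)
  for (i in seq_along(taus)) {
    expect_equal(acrisk:::.mackinnon_p(taus[i]), ps[i], tolerance = 1e-6)
  }

  expect_error(adf_test(rep(2, 50)), "constant")
  expect_error(adf_test(rnorm(5)), "short")

  rej_wn <- rej_rw <- 0L
  for (s in 1:20) {
    set.seed(s)
    rej_rw <- rej_rw + (adf_test(cumsum(rnorm(500)))$p_value < 0.05)
    rej_wn <- rej_wn + (adf_test(rnorm(500))$p_value < 0.05)
  }
  expect_gte(rej_wn, 18L)   # power against stationary noise
  expect_lte(rej_rw, 4L)    # size under the unit-root null (5% nominal)
})

test_that("Granger F-test agrees with a restricted/unrestricted lm() oracle", {
  set.seed(11)
  x <- rnorm(300)
  y <- c(0, 0.8 * x[-300]) + rnorm(300)
  g <- granger_test(cbind(x = x, y = y), "x", "y", 1)
  o <- granger_oracle(x, y, 1)
  expect_equal(g$f_statistic, o$f, tolerance = 1e-10)
  expect_equal(g$p_value, o$p, tolerance = 1e-10)
  expect_lt(g$p_value, 0.01)

  set.seed(12)
  x2 <- rnorm(200); y2 <- 0.3 * c(0, 0, x2[-(199:200)]) + rnorm(200)
  g2 <- granger_test(cbind(x = x2, y = y2), "x", "y", 3)
  o2 <- granger_oracle(x2, y2, 3)
  expect_equal(g2$f_statistic, o2$f, tolerance = 1e-10)
})

test_that("Granger test keeps its nominal size and is affine invariant", {
  rej <- 0L
  for (s in 1:20) {
    set.seed(s + 100)
    g <- granger_test(cbind(x = rnorm(300), y = rnorm(300)), "x", "y", 1)
    rej <- rej + (g$p_value < 0.05)
  }
  expect_lte(rej / 20, 0.15)

  set.seed(13)
  x <- rnorm(150); y <- c(0, 0.5 * x[-150]) + rnorm(150)
  g1 <- granger_test(cbind(x = x, y = y), "x", "y", 2)
  g2 <- granger_test(cbind(x = 0.5 * x - 2, y = 3 * y + 5), "x", "y", 2)
  expect_equal(g1$f_statistic, g2$f_statistic, tolerance = 1e-8)

  expect_error(granger_test(cbind(x = x, y = x), "x", "y", 1), "collinear")
  expect_error(granger_test(cbind(x = x, y = y), "x", "y", 80), "too large")
})

test_that("cointegration screen separates shared trends from independent walks", {
  pass_co <- pass_ind <- 0L
  for (s in 1:20) {
    set.seed(s)
    w <- cumsum(rnorm(400))
    co <- cbind(a = w + rnorm(400, 0, 0.5), b = w + rnorm(400, 0, 0.5))
    pass_co <- pass_co + cointegration_screen(series_panel(co), list(c("a", "b")))$passes
    ind <- cbind(a = cumsum(rnorm(400)), b = cumsum(rnorm(400)))
    pass_ind <- pass_ind + cointegration_screen(series_panel(ind), list(c("a", "b")))$passes
  }
  expect_gte(pass_co, 18L)
  expect_lte(20L - pass_ind, 20L)  # bookkeeping guard
  expect_gte(20L - pass_ind, 16L)  # null behaviour: mostly fails the screen

  # decision rule is exactly statistic > critical value
  set.seed(1)
  w <- cumsum(rnorm(300))
  scr <- cointegration_screen(series_panel(cbind(a = w + rnorm(300, 0, 0.3),
                                                 b = w + rnorm(300, 0, 0.3))),
                              list(c("a", "b")))
  expect_identical(scr$passes, scr$statistic > scr$critical_value_95)

  # degenerate rank-deficient input is refused explicitly
  expect_error(cointegration_screen(series_panel(cbind(a = w, b = w)),
                                    list(c("a", "b"))), "rank-deficient")
  expect_error(cointegration_screen(series_panel(cbind(a = w, b = w)), list("a")),
               ">= 2 variables")
})

test_that("lag-order selection recovers known dynamics and prefers parsimony", {
  hit <- 0L
  for (s in 1:20) {
    set.seed(s)
    A1 <- matrix(c(0.5, 0.1, -0.1, 0.4), 2, 2)
    A2 <- matrix(c(-0.4, 0.1, 0.05, -0.35), 2, 2)
    Y <- matrix(0, 400, 2)
    for (t in 3:400) Y[t, ] <- A1 %*% Y[t - 1, ] + A2 %*% Y[t - 2, ] + rnorm(2)
    sel <- select_lag_order(series_panel(Y, c("a", "b")), 5)
    hit <- hit + (sel$order == 2L)
  }
  expect_gte(hit, 16L)

  wn1 <- 0L
  for (s in 1:20) {
    set.seed(s)
    sel <- select_lag_order(series_panel(matrix(rnorm(400), 200, 2,
                                                dimnames = list(NULL, c("a", "b")))), 4)
    wn1 <- wn1 + (sel$order == 1L)
  }
  expect_gte(wn1, 16L)

  set.seed(3)
  sel1 <- select_lag_order(series_panel(matrix(rnorm(200), 100, 2,
                                               dimnames = list(NULL, c("a", "b")))), 1)
  expect_identical(sel1$order, 1L)
  expect_identical(nrow(sel1$criteria), 1L)
})

test_that("VAR estimation equals independent least-squares oracles", {
  # exact identification from noiseless dynamics (transient keeps the design
  # matrix non-singular)
  A <- matrix(c(0.5, 0.1, -0.2, 0.3), 2, 2); a <- c(1, -0.5)
  Y <- matrix(0, 8, 2); Y[1, ] <- c(5, -3)
  for (t in 2:8) Y[t, ] <- a + A %*% Y[t - 1, ]
  fit <- fit_var(series_panel(Y, c("y1", "y2")), 1)
  expect_lt(max(abs(fit$coef_matrices[[1]] - A)), 1e-8)
  expect_lt(max(abs(fit$intercepts - a)), 1e-8)

  # brute-force normal equations on the same design matrix
  set.seed(6)
  Y <- matrix(rnorm(300), 100, 3)
  fit <- fit_var(series_panel(Y, c("a", "b", "c")), 2)
  idx <- 3:100
  X <- cbind(1, Y[idx - 1, ], Y[idx - 2, ])
  B <- solve(t(X) %*% X, t(X) %*% Y[idx, ])
  expect_lt(max(abs(fit$intercepts - B[1, ])), 1e-10)
  expect_lt(max(abs(fit$coef_matrices[[1]] - t(B[2:4, ]))), 1e-10)
  expect_lt(max(abs(fit$coef_matrices[[2]] - t(B[5:7, ]))), 1e-10)

  # residual means vanish for OLS with intercept
  expect_true(all(abs(colMeans(fit$residuals)) <
                    1e-8 * apply(fit$residuals, 2, stats::sd)))

  # univariate fit reproduces AR(p) OLS from lm()
  set.seed(7)
  y <- as.numeric(stats::arima.sim(list(ar = c(0.5, -0.3)), 150))
  fitu <- fit_var(series_panel(cbind(y = y)), 2)
  idx <- 3:150
  ref <- stats::lm(y[idx] ~ y[idx - 1] + y[idx - 2])
  expect_equal(unname(c(fitu$intercepts, fitu$coef_matrices[[1]],
                        fitu$coef_matrices[[2]])),
               unname(stats::coef(ref)), tolerance = 1e-10)

  expect_error(fit_var(series_panel(cbind(y = rnorm(4))), 3), "insufficient")
})

test_that("information criteria keep their definitional ordering", {
  set.seed(8)
  for (trial in 1:5) {
    Y <- matrix(rnorm(80 * 2), 80, 2, dimnames = list(NULL, c("a", "b")))
    fit <- fit_var(series_panel(Y), sample(1:3, 1))
    ic <- fit$information_criteria
    # log(T) > 2 for T >= 8, so the BIC penalty dominates the AIC penalty
    expect_gte(ic["bic"], ic["aic"])
    # HQIC penalty sits between AIC and BIC for T >= 16
    expect_gte(ic["hqic"], ic["aic"])
    expect_lte(ic["hqic"], ic["bic"])
    expect_gt(ic["fpe"], 0)
  }
})

test_that("Durbin-Watson stays near 2 for white-noise residual fits", {
  ok <- 0L
  for (s in 1:20) {
    set.seed(s)
    Y <- matrix(0, 400, 2)
    for (t in 2:400) {
      Y[t, ] <- c(0.3, 0.2) + matrix(c(0.4, 0.1, 0, 0.3), 2, 2) %*% Y[t - 1, ] + rnorm(2)
    }
    f <- fit_var(series_panel(Y, c("a", "b")), 1)
    ok <- ok + all(f$dw_statistics > 1.5 & f$dw_statistics < 2.5)
  }
  expect_gte(ok, 18L)
})

test_that("forecasting handles fixed points, perfection and beats naive holds", {
  # W = 0: every forecast equals the intercept
  set.seed(9)
  Y <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  fit <- fit_var(series_panel(Y), 1)
  fit$coef_matrices[[1]][] <- 0
  fit$intercepts <- c(2, -1)
  fc <- var_forecast(fit, series_panel(Y), 5)
  expect_true(all(apply(fc$forecast, 1, function(r) all(r == c(2, -1)))))

  # perfect forecast scores zero error
  acc <- forecast_accuracy(Y[1:5, ], Y[1:5, ])
  expect_equal(acc$rmse, c(0, 0))
  expect_equal(acc$mape, c(0, 0))

  expect_warning(forecast_accuracy(matrix(1, 2, 1), matrix(c(0, 2), 2, 1)),
                 "zero actual")
  expect_error(var_forecast(fit, series_panel(Y), 50), "horizon")

  skill <- 0L
  for (s in 1:20) {
    set.seed(s)
    Y <- sim_var2_oscillatory(400)
    k <- 10
    tr <- series_panel(Y[1:390, ])
    fit <- fit_var(tr, 2)
    fc <- var_forecast(fit, tr, k, actual = Y[391:400, ])
    naive <- matrix(rep(Y[390, ], each = k), k, 2)
    rmse_naive <- sqrt(colMeans((naive - Y[391:400, ])^2))
    skill <- skill + all(fc$accuracy$rmse < rmse_naive)
  }
  expect_gte(skill, 16L)
})

test_that("forecasts de-difference back to the original scale exactly", {
  set.seed(10)
  x <- cumsum(rnorm(50)) + 100
  panel <- series_panel(cbind(x = x))
  d <- difference(panel)
  k <- 5
  train <- d
  train$values <- d$values[1:(nrow(d$values) - k), , drop = FALSE]
  fit <- fit_var(train, 1)
  fc <- var_forecast(fit, train, k)
  # integrating the differenced forecast must anchor at the last training level
  expect_equal(unname(fc$forecast[1, 1]),
               unname(x[50 - k] + fc$forecast_differenced[1, 1]))
  expect_equal(unname(fc$forecast[k, 1]),
               unname(x[50 - k] + sum(fc$forecast_differenced[, 1])))
})
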