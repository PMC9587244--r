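#' Multivariate series panel
#'
#' A light container for a (timesteps x variables) numeric matrix together
#' with the bookkeeping needed to undo differencing: the differencing order
#' applied so far and the reference values (pre-differencing series) that
#' anchor reconstruction.
#'
#' @param values Numeric matrix, one column per variable.
#' @param variables Optional variable names (defaults to column names).
#' @param groups Optional grouping factor of length `nrow(values)` marking
#'   contiguous blocks (e.g. patients in a pooled cohort panel); differencing
#'   is then applied within blocks only.
#' @return An object of class `acr_panel`.
#' @export
series_panel <- function(values, variables = colnames(values), groups = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("'values' must be numeric", call. = FALSE)
  if (is.null(variables)) variables <- paste0("V", seq_len(ncol(values)))
  colnames(values) <- variables
  if (!is.null(groups)) {
    groups <- as.factor(groups)
    stopifnot(length(groups) == nrow(values))
  }
  structure(list(values = values, variables = variables,
                 differencing_order = 0L, scale_reference = NULL,
                 groups = groups),
            class = "acr_panel")
}

#' @export
print.acr_panel <- function(x, ...) {
  cat(sprintf("Series panel: %d timesteps x %d variables (%s), differenced %d time(s)\n",
              nrow(x$values), length(x$variables),
              paste(x$variables, collapse = ", "), x$differencing_order))
  invisible(x)
}

#' Pooled cohort panel
#'
#' Concatenates the per-patient three-timepoint series in patient-id order
#' into one pooled panel of the three variables (`scd31`, `pf_ratio`,
#' `resp_sofa`), 3 rows per patient. The patient structure is kept as the
#' panel's grouping so that differencing is applied within patients,
#' removing artificial inter-patient jumps.
#'
#' @param cohort An `acr_cohort`.
#' @param log_scd31 If `TRUE`, sCD31 enters on the natural-log scale.
#' @return An `acr_panel` with `3 * n` rows.
#' @export
pooled_panel <- function(cohort, log_scd31 = FALSE) {
  mats <- reshape_cohort(cohort)
  vals <- do.call(rbind, lapply(mats, t))  # each patient: 3 rows x 3 vars
  if (log_scd31) vals[, "scd31"] <- log(vals[, "scd31"])
  rownames(vals) <- NULL
  series_panel(vals, variables = c("scd31", "pf_ratio", "resp_sofa"),
               groups = rep(names(mats), each = 3L))
}

#' Difference and de-difference a panel
#'
#' `difference()` applies first differences `order` times (within groups when
#' the panel carries a grouping), recording the pre-differencing values so the
#' operation is exactly invertible. `de_difference()` undoes one level of
#' differencing: with `forecast = NULL` it reconstructs the original panel by
#' cumulative summation anchored at the stored group-leading values; given a
#' `forecast` matrix on the differenced scale it returns the forecast
#' integrated back to the scale of the stored series, anchored at the level
#' reached at row `at` (default: end of the training region).
#'
#' @param panel An `acr_panel`.
#' @param order Number of first-difference passes (>= 1).
#' @param forecast Optional (k x variables) matrix of differenced-scale
#'   forecasts to integrate to the original scale.
#' @param at Row index (in the differenced panel) after which the forecast
#'   starts; defaults to the last row.
#' @return `difference()` returns an `acr_panel`; `de_difference()` returns an
#'   `acr_panel` (when `forecast` is `NULL`) or a k x variables matrix.
#' @examples
#' p <- series_panel(cbind(x = c(1, 3, 6, 10)))
#' difference(p)$values           # 2, 3, 4
#' de_difference(difference(p))$values  # 1, 3, 6, 10
#' @export
difference <- function(panel, order = 1L) {
  stopifnot(inherits(panel, "acr_panel"), order >= 1L)
  out <- panel
  for (pass in seq_len(order)) {
    v <- out$values
    if (nrow(v) < 2L) stop("panel too short to difference", call. = FALSE)
    if (is.null(out$groups)) {
      dv <- diff(v)
      new_groups <- NULL
      level_index <- 2:nrow(v)
    } else {
      g <- out$groups
      keep <- which(duplicated(g))        # rows with a predecessor in-group
      if (length(keep) == 0L) stop("every group has a single row; cannot difference", call. = FALSE)
      dv <- v[keep, , drop = FALSE] - v[keep - 1L, , drop = FALSE]
      new_groups <- droplevels(g[keep])
      level_index <- keep
    }
    ref <- list(values = v, groups = out$groups, level_index = level_index,
                parent = out$scale_reference)
    out$values <- dv
    out$groups <- if (is.null(out$groups)) NULL else new_groups
    out$scale_reference <- ref
    out$differencing_order <- out$differencing_order + 1L
  }
  out
}

#' @rdname difference
#' @export
de_difference <- function(panel, forecast = NULL, at = NULL) {
  stopifnot(inherits(panel, "acr_panel"))
  ref <- panel$scale_reference
  if (is.null(ref)) stop("panel has no stored scale reference to de-difference with", call. = FALSE)
  if (is.null(forecast)) {
    # exact reconstruction: anchor each group's first stored level, cumulate
    v <- ref$values
    recon <- v
    recon[ref$level_index, ] <- NA_real_
    # cumulative sums per group over the differenced rows
    d <- panel$values
    for (j in seq_along(ref$level_index)) {
      i <- ref$level_index[j]
      recon[i, ] <- recon[i - 1L, ] + d[j, ]
    }
    out <- panel
    out$values <- recon
    out$groups <- ref$groups
    out$scale_reference <- ref$parent
    out$differencing_order <- panel$differencing_order - 1L
    return(out)
  }
  forecast <- as.matrix(forecast)
  if (panel$differencing_order > 1L) {
    stop("forecast de-differencing supports one level of differencing", call. = FALSE)
  }
  if (is.null(at)) at <- nrow(panel$values)
  anchor <- ref$values[ref$level_index[at], ]
  out <- matrix(apply(forecast, 2L, cumsum), nrow = nrow(forecast))
  out <- sweep(out, 2L, anchor, "+")
  colnames(out) <- colnames(forecast)
  out
}

# ---- Augmented Dickey-Fuller -------------------------------------------------

# MacKinnon (1994, 2010) response-surface coefficients for the approximate
# asymptotic p-value of the ADF tau statistic, constant-only regression,
# one series. The p-value is Phi(polynomial(tau)) on the relevant branch.
.adf_tau_star <- -1.61
.adf_tau_max <- 2.74
.adf_tau_min <- -18.83
.adf_smallp <- c(2.1659, 1.4412, 0.038269)
.adf_largep <- c(1.7339, 0.93202, -0.12745, -0.010368)

.mackinnon_p <- function(tau) {
  if (tau > .adf_tau_max) return(1)
  if (tau < .adf_tau_min) return(0)
  co <- if (tau <= .adf_tau_star) .adf_smallp else .adf_largep
  z <- sum(co * tau^(seq_along(co) - 1L))
  stats::pnorm(z)
}

.ols_fit <- function(X, y) {
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("singular design matrix", call. = FALSE)
  beta <- qr.coef(qx, y)
  resid <- y - X %*% beta
  list(beta = beta, resid = as.numeric(resid), ssr = sum(resid^2), qr = qx)
}

#' Augmented Dickey-Fuller unit-root test
#'
#' Tests the null of a unit root against stationarity using the auxiliary
#' regression \eqn{\Delta y_t = \alpha + \gamma y_{t-1} +
#' \sum_{i=1}^{k} \delta_i \Delta y_{t-i} + \varepsilon_t}
#' (constant, no trend). The number of lagged differences k is selected by
#' AIC over `0:max_lags` on a common estimation sample, then the chosen
#' specification is refitted on its full available sample. The p-value is
#' MacKinnon's asymptotic approximation for the constant-only case.
#'
#' @param series Numeric vector, length >= 10.
#' @param max_lags Upper bound for lag selection; default
#'   `floor(12 * (T/100)^0.25)` capped to leave enough observations.
#' @return A list of class `acr_adf` with `statistic`, `p_value`,
#'   `n_lags_used`, and the sample size used.
#' @export
adf_test <- function(series, max_lags = NULL) {
  series <- as.numeric(series)
  T <- length(series)
  if (T < 10L) stop("series too short for the ADF test (need >= 10)", call. = FALSE)
  if (stats::sd(series) == 0) {
    stop("constant series: the ADF regression is degenerate", call. = FALSE)
  }
  if (is.null(max_lags)) max_lags <- floor(12 * (T / 100)^0.25)
  max_lags <- max(0L, min(as.integer(max_lags), T %/% 2L - 2L))

  dy <- diff(series)
  build <- function(k, first) {
    # rows first..length(dy) of the auxiliary regression with k diff lags
    idx <- first:length(dy)
    X <- cbind(const = 1, ylag = series[idx])
    if (k > 0L) {
      for (i in seq_len(k)) X <- cbind(X, dy[idx - i])
    }
    list(X = X, y = dy[idx])
  }
  common_first <- max_lags + 1L
  aics <- vapply(0:max_lags, function(k) {
    d <- build(k, common_first)
    f <- .ols_fit(d$X, d$y)
    n <- length(d$y)
    n * log(f$ssr / n) + 2 * ncol(d$X)
  }, numeric(1))
  k_best <- (0:max_lags)[which.min(aics)]

  d <- build(k_best, k_best + 1L)
  f <- .ols_fit(d$X, d$y)
  n <- length(d$y)
  sigma2 <- f$ssr / (n - ncol(d$X))
  XtX_inv <- chol2inv(qr.R(f$qr))
  se_gamma <- sqrt(sigma2 * XtX_inv[2, 2])
  tau <- f$beta[2] / se_gamma
  structure(list(statistic = as.numeric(tau),
                 p_value = .mackinnon_p(as.numeric(tau)),
                 n_lags_used = k_best, n_obs = n,
                 differencing_applied = 0L),
            class = "acr_adf")
}

#' @export
print.acr_adf <- function(x, ...) {
  cat(sprintf("ADF test: tau = %.4f, p = %.4g (lags %d, n %d)\n",
              x$statistic, x$p_value, x$n_lags_used, x$n_obs))
  invisible(x)
}

# ---- Granger causality -------------------------------------------------------

#' Granger causality F-test
#'
#' Tests whether lags of `cause` improve the linear prediction of `effect`
#' beyond the effect's own lags: the restricted regression of the effect on
#' its own lags 1..m (plus a constant) is compared with the unrestricted
#' regression that adds the cause's lags 1..m, via
#' \eqn{F = \frac{(SSR_r - SSR_u)/m}{SSR_u/(T - 2m - 1)}} with
#' \eqn{(m, T - 2m - 1)} degrees of freedom (T = number of usable rows).
#' Stationarity of both series is the caller's responsibility.
#'
#' @param panel An `acr_panel` or a numeric matrix with named columns.
#' @param cause,effect Variable names (or indices).
#' @param max_lag Number of lags m (>= 1).
#' @return A list of class `acr_granger` with `f_statistic`, `p_value`,
#'   `cause`, `effect`, `max_lag`, and the degrees of freedom.
#' @export
granger_test <- function(panel, cause, effect, max_lag = 1L) {
  vals <- if (inherits(panel, "acr_panel")) panel$values else as.matrix(panel)
  max_lag <- as.integer(max_lag)
  if (max_lag < 1L) stop("'max_lag' must be >= 1", call. = FALSE)
  x <- as.numeric(vals[, cause])
  y <- as.numeric(vals[, effect])
  T <- length(y)
  if (T <= 2L * max_lag + 2L) stop("'max_lag' too large for series length", call. = FALSE)
  xc <- x - mean(x); yc <- y - mean(y)
  if (sum(xc^2) == 0 || sum(yc^2) == 0 ||
      abs(sum(xc * yc)) >= (1 - 1e-12) * sqrt(sum(xc^2) * sum(yc^2))) {
    stop("cause and effect series are perfectly collinear; the Granger test is undefined",
         call. = FALSE)
  }
  idx <- (max_lag + 1L):T
  lagmat <- function(v) sapply(seq_len(max_lag), function(i) v[idx - i])
  Xr <- cbind(1, lagmat(y))
  Xu <- cbind(Xr, lagmat(x))
  fr <- .ols_fit(Xr, y[idx])
  fu <- .ols_fit(Xu, y[idx])
  df2 <- length(idx) - ncol(Xu)
  f_stat <- ((fr$ssr - fu$ssr) / max_lag) / (fu$ssr / df2)
  f_stat <- max(f_stat, 0)
  structure(list(cause = cause, effect = effect, max_lag = max_lag,
                 f_statistic = f_stat,
                 p_value = stats::pf(f_stat, max_lag, df2, lower.tail = FALSE),
                 df = c(max_lag, df2)),
            class = "acr_granger")
}

#' @export
print.acr_granger <- function(x, ...) {
  cat(sprintf("Granger test %s -> %s (m = %d): F = %.4f, p = %.4g\n",
              x$cause, x$effect, x$max_lag, x$f_statistic, x$p_value))
  invisible(x)
}

# ---- Johansen cointegration screen ------------------------------------------

# 90/95/99% critical values for the Johansen trace statistic with an
# unrestricted constant, by number of remaining (non-cointegrated) variables
# k - r (MacKinnon-Haug-Michelis 1999).
.johansen_cv <- rbind(
  `1` = c(2.7055, 3.8415, 6.6349),
  `2` = c(13.4294, 15.4943, 19.9349),
  `3` = c(27.0669, 29.7961, 35.4628)
)

.johansen_trace <- function(Y, k_ar_diff = 1L) {
  Y <- as.matrix(Y)
  K <- ncol(Y); T <- nrow(Y)
  if (qr(sweep(Y, 2L, colMeans(Y)))$rank < K) {
    stop("rank-deficient input (duplicated or collinear series); the Johansen eigenproblem is singular",
         call. = FALSE)
  }
  dY <- diff(Y)
  rows <- (k_ar_diff + 1L):nrow(dY)
  if (length(rows) < K + k_ar_diff * K + 2L) {
    stop("series too short for the Johansen procedure", call. = FALSE)
  }
  Z0 <- dY[rows, , drop = FALSE]
  Z1 <- Y[rows, , drop = FALSE]                 # lagged level (one period back)
  Z2 <- cbind(1, do.call(cbind, lapply(seq_len(k_ar_diff),
                                       function(i) dY[rows - i, , drop = FALSE])))
  resid_on <- function(Z) Z - Z2 %*% qr.coef(qr(Z2), Z)
  R0 <- resid_on(Z0); R1 <- resid_on(Z1)
  n <- nrow(R0)
  S00 <- crossprod(R0) / n; S11 <- crossprod(R1) / n
  S01 <- crossprod(R0, R1) / n
  bad <- anyNA(S11) || anyNA(S00) ||
    tryCatch(rcond(S11) < 1e-12 || rcond(S00) < 1e-12, error = function(e) TRUE)
  if (bad) {
    stop("rank-deficient input (duplicated or collinear series); the Johansen eigenproblem is singular",
         call. = FALSE)
  }
  M <- solve(S11) %*% t(S01) %*% solve(S00) %*% S01
  lambda <- sort(pmin(pmax(Re(eigen(M, only.values = TRUE)$values), 0), 1 - 1e-12),
                 decreasing = TRUE)
  trace_stats <- vapply(0:(K - 1L), function(r) {
    -n * sum(log(1 - lambda[(r + 1L):K]))
  }, numeric(1))
  list(eigenvalues = lambda, trace = trace_stats, n = n)
}

#' Cointegration screen (Johansen trace test)
#'
#' For each requested subset of panel variables, computes the Johansen trace
#' statistic for the null of no cointegration (rank 0) with an unrestricted
#' constant, and compares it with the 95\% critical value. `passes = TRUE`
#' means the statistic exceeds the bound, i.e. the subset shows evidence of a
#' long-run (cointegrating) relationship; a variable set that fails the
#' screen is excluded from joint long-run modelling, mirroring how the
#' respiratory SOFA series is screened out before VAR construction.
#'
#' @param panel An `acr_panel` (levels, not differenced).
#' @param variable_subsets List of character vectors, each of length >= 2.
#' @param k_ar_diff Number of lagged differences in the auxiliary regressions.
#' @return A data frame with one row per subset: `variables`, `statistic`,
#'   `critical_value_95`, `passes`.
#' @export
cointegration_screen <- function(panel, variable_subsets, k_ar_diff = 1L) {
  stopifnot(inherits(panel, "acr_panel"))
  if (!is.list(variable_subsets)) variable_subsets <- list(variable_subsets)
  rows <- lapply(variable_subsets, function(vs) {
    if (length(vs) < 2L) stop("cointegration requires >= 2 variables per subset", call. = FALSE)
    K <- length(vs)
    if (K > nrow(.johansen_cv)) stop("critical values tabulated for up to 3 variables", call. = FALSE)
    jt <- .johansen_trace(panel$values[, vs, drop = FALSE], k_ar_diff)
    stat <- jt$trace[1]
    cv <- .johansen_cv[as.character(K), 2]
    data.frame(variables = paste(vs, collapse = "+"),
               statistic = stat, critical_value_95 = cv,
               passes = stat > cv, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# ---- VAR fitting, lag selection, forecasting --------------------------------

.durbin_watson <- function(e) sum(diff(e)^2) / sum(e^2)

#' Fit a vector autoregression by equationwise least squares
#'
#' Estimates \eqn{Y_t = a + W_1 Y_{t-1} + \dots + W_p Y_{t-p} + e_t} by OLS
#' (each equation regressed on a constant and p lags of all variables).
#' Residual diagnostics (per-equation Durbin-Watson) and the information
#' criteria AIC/BIC/HQIC/FPE (computed from the ML residual covariance) are
#' stored with the fit.
#'
#' @param panel An `acr_panel`, assumed stationary.
#' @param p Lag order (positive integer).
#' @return An object of class `acr_var` with elements `p`, `intercepts`,
#'   `coef_matrices` (list of K x K matrices, `coef_matrices[[j]][e, v]` is
#'   the effect of variable v at lag j on equation e), `residuals`,
#'   `dw_statistics`, `information_criteria`, `sigma_ml`, `nobs`, and the
#'   training values.
#' @export
fit_var <- function(panel, p) {
  stopifnot(inherits(panel, "acr_panel"))
  p <- as.integer(p)
  if (p < 1L) stop("'p' must be >= 1", call. = FALSE)
  Y <- panel$values
  K <- ncol(Y); T <- nrow(Y)
  if (T <= p * K + 1L) stop("insufficient timesteps for the requested lag order", call. = FALSE)
  idx <- (p + 1L):T
  X <- cbind(1, do.call(cbind, lapply(seq_len(p),
                                      function(j) Y[idx - j, , drop = FALSE])))
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("singular design matrix", call. = FALSE)
  B <- qr.coef(qx, Y[idx, , drop = FALSE])   # (1 + pK) x K
  E <- Y[idx, , drop = FALSE] - X %*% B
  T_eff <- length(idx)
  m_eq <- 1L + p * K          # parameters per equation
  q_tot <- K * m_eq
  sigma_ml <- crossprod(E) / T_eff
  ld <- as.numeric(determinant(sigma_ml, logarithm = TRUE)$modulus)
  ic <- c(aic = ld + 2 * q_tot / T_eff,
          bic = ld + log(T_eff) * q_tot / T_eff,
          hqic = ld + 2 * log(log(T_eff)) * q_tot / T_eff,
          fpe = ((T_eff + m_eq) / (T_eff - m_eq))^K * exp(ld))
  W <- lapply(seq_len(p), function(j) {
    t(B[1L + (j - 1L) * K + seq_len(K), , drop = FALSE])
  })
  structure(list(p = p, variables = panel$variables,
                 intercepts = as.numeric(B[1, ]),
                 coef_matrices = W,
                 residuals = E,
                 dw_statistics = apply(E, 2L, .durbin_watson),
                 information_criteria = ic,
                 sigma_ml = sigma_ml, nobs = T_eff,
                 training_values = Y),
            class = "acr_var")
}

#' @export
print.acr_var <- function(x, ...) {
  cat(sprintf("VAR(%d) on %d variables, %d observations\n",
              x$p, length(x$variables), x$nobs))
  cat("  Durbin-Watson:", paste(sprintf("%s %.2f", x$variables, x$dw_statistics),
                                collapse = ", "), "\n")
  cat(sprintf("  AIC %.3f  BIC %.3f  HQIC %.3f  FPE %.4g\n",
              x$information_criteria["aic"], x$information_criteria["bic"],
              x$information_criteria["hqic"], x$information_criteria["fpe"]))
  invisible(x)
}

#' Select the VAR lag order by the Hannan-Quinn criterion
#'
#' Fits VAR(1..max_order) and returns the order with the smallest HQIC,
#' ties broken toward the smaller (more parsimonious) order. The full
#' AIC/BIC/HQIC/FPE table for every candidate is returned alongside.
#'
#' @param panel An `acr_panel`, assumed stationary.
#' @param max_order Largest candidate order (>= 1).
#' @return A list with `order` (chosen) and `criteria` (data frame, one row
#'   per candidate order).
#' @export
select_lag_order <- function(panel, max_order) {
  stopifnot(inherits(panel, "acr_panel"), max_order >= 1L)
  tab <- lapply(seq_len(max_order), function(p) {
    fit <- fit_var(panel, p)
    data.frame(order = p, t(fit$information_criteria))
  })
  tab <- do.call(rbind, tab)
  best <- tab$order[which.min(tab$hqic)]   # which.min takes the first minimum
  list(order = best, criteria = tab)
}

#' Forecast from a fitted VAR and score against a held-out tail
#'
#' Produces `k` iterated one-step-ahead forecasts from the end of the
#' training data. If `panel` (the panel the model was fitted on) carries one
#' level of differencing, the forecast is integrated back to the original
#' scale, anchored at the level reached at the end of the training region,
#' and accuracy is assessed on that original scale. The held-out actuals are
#' taken from `actual` (a k x variables matrix on the original scale) when
#' supplied.
#'
#' @param model An `acr_var` fitted on `panel`.
#' @param panel The training `acr_panel` (possibly differenced once).
#' @param k Forecast horizon (>= 1).
#' @param actual Optional k x variables matrix of held-out values on the
#'   original scale, used to compute accuracy metrics.
#' @return A list of class `acr_forecast` with `horizon`, `forecast`
#'   (k x variables, original scale), `forecast_differenced` (the raw VAR
#'   output when the panel was differenced), and `accuracy` (per-variable
#'   rmse, mae, mape, corr; `NULL` without actuals).
#' @export
var_forecast <- function(model, panel, k, actual = NULL) {
  stopifnot(inherits(model, "acr_var"), inherits(panel, "acr_panel"), k >= 1L)
  Y <- model$training_values
  if (k >= nrow(Y)) {
    stop("forecast horizon k must be smaller than the training series length",
         call. = FALSE)
  }
  K <- ncol(Y); p <- model$p
  hist <- Y[(nrow(Y) - p + 1L):nrow(Y), , drop = FALSE]
  fc <- matrix(NA_real_, k, K, dimnames = list(NULL, model$variables))
  for (h in seq_len(k)) {
    yhat <- model$intercepts
    for (j in seq_len(p)) {
      yhat <- yhat + as.numeric(model$coef_matrices[[j]] %*% hist[nrow(hist) + 1L - j, ])
    }
    fc[h, ] <- yhat
    hist <- rbind(hist, yhat)
  }
  fc_level <- fc
  fc_diff <- NULL
  if (panel$differencing_order > 0L) {
    fc_diff <- fc
    fc_level <- de_difference(panel, forecast = fc)
  }
  acc <- NULL
  if (!is.null(actual)) {
    actual <- as.matrix(actual)
    stopifnot(nrow(actual) == k, ncol(actual) == K)
    acc <- forecast_accuracy(fc_level, actual)
  }
  structure(list(horizon = k, forecast = fc_level,
                 forecast_differenced = fc_diff, accuracy = acc),
            class = "acr_forecast")
}

#' Forecast accuracy metrics
#'
#' Per-variable root-mean-square error, mean absolute error, mean absolute
#' percentage error and Pearson correlation between forecast and actuals.
#' MAPE is undefined at zero actuals; zero entries are excluded from its
#' average with a warning.
#'
#' @param forecast,actual Matrices of identical shape (k x variables).
#' @return A data frame with one row per variable.
#' @export
forecast_accuracy <- function(forecast, actual) {
  forecast <- as.matrix(forecast); actual <- as.matrix(actual)
  stopifnot(identical(dim(forecast), dim(actual)))
  vars <- colnames(actual)
  if (is.null(vars)) vars <- paste0("V", seq_len(ncol(actual)))
  out <- lapply(seq_len(ncol(actual)), function(j) {
    e <- forecast[, j] - actual[, j]
    a <- actual[, j]
    nz <- a != 0
    if (any(!nz)) {
      warning("zero actual values excluded from the MAPE average for variable ",
              vars[j], call. = FALSE)
    }
    mape <- if (any(nz)) 100 * mean(abs(e[nz] / a[nz])) else NA_real_
    corr <- if (nrow(forecast) > 1L &&
                stats::sd(forecast[, j]) > 0 && stats::sd(a) > 0) {
      stats::cor(forecast[, j], a)
    } else NA_real_
    data.frame(variable = vars[j],
               rmse = sqrt(mean(e^2)), mae = mean(abs(e)),
               mape = mape, corr = corr, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
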