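#' Log-odds and inverse-logit transforms
#'
#' `logit()` maps a probability to the log-odds scale,
#' \eqn{z = \log(y / (1 - y))}; `expit()` is its exact inverse,
#' \eqn{p = e^z / (1 + e^z)}, implemented in an overflow-safe form that is
#' accurate for |z| far beyond 700.
#'
#' @param y Probability strictly inside (0, 1). Values of exactly 0 or 1 are
#'   an error: if clipping is wanted it must be the caller's explicit choice
#'   via `eps`.
#' @param eps Optional clipping half-width; when supplied, `y` is clamped to
#'   `[eps, 1 - eps]` before the transform.
#' @return `logit()` returns the log-odds; `expit()` the probability.
#' @examples
#' logit(0.5)          # 0
#' expit(1)            # 0.7310586
#' @export
logit <- function(y, eps = NULL) {
  if (!is.null(eps)) y <- pmin(pmax(y, eps), 1 - eps)
  if (any(y <= 0 | y >= 1)) {
    stop("'y' must lie strictly in (0, 1); pass 'eps' to clip explicitly",
         call. = FALSE)
  }
  log(y / (1 - y))
}

#' @rdname logit
#' @param z Finite numeric vector on the log-odds scale.
#' @export
expit <- function(z) {
  if (any(!is.finite(z))) stop("'z' must be finite", call. = FALSE)
  ifelse(z >= 0, 1 / (1 + exp(-z)), exp(z) / (1 + exp(z)))
}

#' Literal integrated-sigmoid value
#'
#' Evaluates \eqn{\int_0^z e^t / (1 + e^t)\, dt = \log((1 + e^z)/2)}
#' (a shifted softplus). This quantity is retained for fidelity with the
#' risk construction it originates from, but note it is not a proper
#' cumulative distribution function: it is unbounded above and negative for
#' z < 0. The cohort-referenced risk percentage used in practice is the
#' empirical CDF of [cohort_risk()].
#'
#' @param z Finite numeric vector.
#' @return `log((1 + exp(z)) / 2)`, computed without overflow.
#' @examples
#' eq3_literal(0)   # 0
#' eq3_literal(1)   # 0.620115
#' @export
eq3_literal <- function(z) {
  if (any(!is.finite(z))) stop("'z' must be finite", call. = FALSE)
  # softplus(z) - log(2), stable on both tails
  ifelse(z > 0, z + log1p(exp(-z)), log1p(exp(z))) - log(2)
}

#' Cohort-referenced ACR risk scores
#'
#' Converts per-patient head pre-activations (log-odds) into risk scores.
#' For each patient the function reports the pre-activation `z`, the sigmoid
#' probability `expit(z)`, the literal integrated-sigmoid value
#' [eq3_literal()], and the cohort-referenced cumulative risk percentage:
#' the empirical fraction of cohort z-values less than or equal to the
#' patient's own (weak-inequality convention), scaled to `[0, 100]`. The
#' percentile is a rank statistic -- invariant under any strictly increasing
#' transform of z and non-decreasing in z -- and when every patient shares
#' one z-value all percentiles are 100.
#'
#' @param z Named numeric vector of pre-activations (names = patient ids).
#' @return A data frame sorted by `patient_id` with columns `patient_id`,
#'   `z`, `probability`, `risk_percentile`, `f_literal`.
#' @examples
#' cohort_risk(c(a = -2, b = 0, c = 3))$risk_percentile  # 33.33 66.67 100
#' @export
cohort_risk <- function(z) {
  if (length(z) < 2L) stop("cohort risk needs at least 2 patients", call. = FALSE)
  ids <- names(z)
  if (is.null(ids)) ids <- sprintf("P%03d", seq_along(z))
  pct <- vapply(z, function(zi) 100 * mean(z <= zi), numeric(1))
  out <- data.frame(patient_id = ids, z = as.numeric(z),
                    probability = expit(as.numeric(z)),
                    risk_percentile = as.numeric(pct),
                    f_literal = eq3_literal(as.numeric(z)),
                    stringsAsFactors = FALSE)
  out[order(out$patient_id), , drop = FALSE]
}

#' Risk table for a trained classifier on a cohort
#'
#' Runs the classifier on standardized cohort segments, extracts the head
#' pre-activations and assembles the per-patient risk table of
#' [cohort_risk()] together with the outcome labels.
#'
#' @param model A trained `acr_classifier`.
#' @param mats Named list of raw patient matrices (see [reshape_cohort()]).
#' @param stats Standardization statistics to apply; fitted on `mats` when
#'   `NULL`.
#' @return A data frame: `patient_id`, `acr` (if available), `z`,
#'   `probability`, `risk_percentile`, `f_literal`.
#' @export
risk_table <- function(model, mats, stats = NULL) {
  std <- standardize_segments(mats, fit_stats = stats)
  z <- predict(model, std$segments, type = "z")
  tab <- cohort_risk(z)
  acr <- attr(mats, "acr")
  if (!is.null(acr)) tab$acr <- as.integer(acr[tab$patient_id])
  rownames(tab) <- NULL
  tab[, c("patient_id", intersect("acr", names(tab)),
          "z", "probability", "risk_percentile", "f_literal")]
}
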