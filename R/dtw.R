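#' Dependent multidimensional dynamic time warping
#'
#' Aligns two multivariate sequences with a single warping shared by all
#' dimensions ("dependent" DTW): the local cost between frames i and j is the
#' Euclidean norm of their difference across dimensions, and the accumulated
#' cost follows the classic recurrence
#' \eqn{D(i,j) = c(i,j) + \min\{D(i-1,j), D(i,j-1), D(i-1,j-1)\}}
#' with symmetric unit step weights and no warping window. The normalized
#' distance divides the raw distance by the optimal warping-path length,
#' which makes sequences of different lengths comparable.
#'
#' When `keep_matrix = FALSE` the recurrence runs over a two-row rolling
#' array (linear space); the full accumulated cost matrix and the optimal
#' path are materialized only on request.
#'
#' @param seq_a,seq_b Numeric matrices (frames x dimensions) with the same
#'   number of dimensions; plain vectors are treated as one-dimensional
#'   sequences. Standardize beforehand when variables live on different
#'   scales.
#' @param keep_matrix If `TRUE` (default), return the accumulated cost
#'   matrix (with an added boundary row/column of `Inf` sentinels) and the
#'   optimal warping path.
#' @return An object of class `acr_dtw`: `distance`, `normalized_distance`,
#'   `path` (two-column matrix of 1-based index pairs, `NULL` when
#'   `keep_matrix = FALSE`), `cost_matrix` ((n+1) x (m+1), `NULL` when not
#'   kept).
#' @examples
#' a <- cbind(c(0, 1, 2)); b <- cbind(c(0, 2))
#' dtw_dependent(a, b)$distance
#' @export
dtw_dependent <- function(seq_a, seq_b, keep_matrix = TRUE) {
  A <- if (is.matrix(seq_a)) seq_a else matrix(as.numeric(seq_a), ncol = 1)
  B <- if (is.matrix(seq_b)) seq_b else matrix(as.numeric(seq_b), ncol = 1)
  if (nrow(A) < 1L || nrow(B) < 1L) stop("empty sequence", call. = FALSE)
  if (ncol(A) != ncol(B)) stop("dimension mismatch between sequences", call. = FALSE)
  n <- nrow(A); m <- nrow(B)

  # local cost matrix: Euclidean norm between multidimensional frames
  local <- matrix(0, n, m)
  for (d in seq_len(ncol(A))) {
    local <- local + outer(A[, d], B[, d], "-")^2
  }
  local <- sqrt(local)

  if (!keep_matrix) {
    # two-row rolling arrays: accumulated cost plus the step count of the
    # optimal path reaching each cell (same diagonal-first tie-break as the
    # backtracking in the full variant)
    prev <- c(0, rep(Inf, m))        # boundary row: D(0, 0) = 0
    prev_len <- c(0L, rep(NA_integer_, m))
    for (i in seq_len(n)) {
      cur <- rep(Inf, m + 1L)
      cur_len <- rep(NA_integer_, m + 1L)
      for (j in seq_len(m)) {
        cand <- c(prev[j], prev[j + 1L], cur[j])          # diag, up, left
        pick <- which.min(cand)
        cur[j + 1L] <- local[i, j] + cand[pick]
        cur_len[j + 1L] <- 1L + switch(pick, prev_len[j], prev_len[j + 1L], cur_len[j])
      }
      prev <- cur
      prev_len <- cur_len
    }
    return(structure(list(distance = prev[m + 1L],
                          normalized_distance = prev[m + 1L] / prev_len[m + 1L],
                          path = NULL, cost_matrix = NULL),
                     class = "acr_dtw"))
  }

  D <- matrix(Inf, n + 1L, m + 1L)
  D[1, 1] <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      D[i + 1L, j + 1L] <- local[i, j] +
        min(D[i, j + 1L], D[i + 1L, j], D[i, j])
    }
  }
  # backtrack; ties prefer the diagonal step
  path <- matrix(NA_integer_, n + m, 2L)
  i <- n; j <- m; s <- 1L
  path[s, ] <- c(i, j)
  while (i > 1L || j > 1L) {
    choices <- c(D[i, j], D[i, j + 1L], D[i + 1L, j])   # diag, up, left
    step <- which.min(choices)
    if (step == 1L) { i <- i - 1L; j <- j - 1L }
    else if (step == 2L) { i <- i - 1L }
    else { j <- j - 1L }
    s <- s + 1L
    path[s, ] <- c(i, j)
  }
  path <- path[s:1, , drop = FALSE]
  colnames(path) <- c("a", "b")
  structure(list(distance = D[n + 1L, m + 1L],
                 normalized_distance = D[n + 1L, m + 1L] / nrow(path),
                 path = path, cost_matrix = D),
            class = "acr_dtw")
}

#' @export
print.acr_dtw <- function(x, ...) {
  cat(sprintf("Dependent DTW: distance %.6g, normalized %.6g", x$distance,
              x$normalized_distance))
  if (!is.null(x$path)) cat(sprintf(" (path length %d)", nrow(x$path)))
  cat("\n")
  invisible(x)
}

#' Export an accumulated cost matrix as CSV
#'
#' @param dtw An `acr_dtw` computed with `keep_matrix = TRUE`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cost_matrix <- function(dtw, path) {
  stopifnot(inherits(dtw, "acr_dtw"))
  if (is.null(dtw$cost_matrix)) stop("cost matrix was not kept", call. = FALSE)
  utils::write.table(dtw$cost_matrix, path, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Normalized DTW separation between outcome classes
#'
#' Quantifies how far apart the two outcome classes' temporal profiles are:
#' each patient's multivariate sequence (by default the 2-D
#' sCD31 / PaO2-FiO2 profile; the categorical respiratory SOFA channel is
#' excluded) is standardized per variable across the cohort, a representative
#' sequence per class is formed (pointwise mean by default, medoid
#' optionally), and the dependent-DTW normalized distance between the two
#' representatives is returned. Sequences may be raw cohort measurements or
#' VAR-forecast profiles -- the function is agnostic to their provenance.
#'
#' @param series_by_class A list of two lists of (timepoints x dims) numeric
#'   matrices, named by class (e.g. `list(non_acr = ..., acr = ...)`); all
#'   sequences must share dimensions.
#' @param representative `"mean"` (pointwise mean sequence) or `"medoid"`
#'   (the member sequence minimizing total DTW distance to its classmates).
#' @return A list with `normalized_distance`, `distance`, the two class
#'   `representatives`, and the `dtw` result object.
#' @export
class_separation <- function(series_by_class, representative = c("mean", "medoid")) {
  representative <- match.arg(representative)
  if (length(series_by_class) != 2L) {
    stop("'series_by_class' must contain exactly two classes", call. = FALSE)
  }
  if (any(vapply(series_by_class, length, integer(1)) == 0L)) {
    stop("each class must have at least one member", call. = FALSE)
  }
  all_seqs <- do.call(c, series_by_class)
  all_seqs <- lapply(all_seqs, function(s) if (is.matrix(s)) s else matrix(s, ncol = 1))
  dims <- unique(vapply(all_seqs, ncol, integer(1)))
  if (length(dims) != 1L) stop("sequences differ in dimension", call. = FALSE)

  # standardize each variable over all frames of the pooled cohort
  pooled <- do.call(rbind, all_seqs)
  mu <- colMeans(pooled)
  sdv <- apply(pooled, 2L, stats::sd)
  sdv[sdv == 0] <- 1
  std <- lapply(all_seqs, function(s) sweep(sweep(s, 2L, mu), 2L, sdv, "/"))
  sizes <- vapply(series_by_class, length, integer(1))
  cls <- rep(seq_along(series_by_class), sizes)

  rep_of <- function(seqs) {
    if (representative == "mean") {
      Reduce(`+`, seqs) / length(seqs)
    } else {
      if (length(seqs) == 1L) return(seqs[[1]])
      dmat <- vapply(seqs, function(a) {
        vapply(seqs, function(b) dtw_dependent(a, b, keep_matrix = FALSE)$distance,
               numeric(1))
      }, numeric(length(seqs)))
      seqs[[which.min(colSums(dmat))]]
    }
  }
  reps <- lapply(split(std, cls), rep_of)
  names(reps) <- names(series_by_class)
  d <- dtw_dependent(reps[[1]], reps[[2]])
  list(normalized_distance = d$normalized_distance, distance = d$distance,
       representatives = reps, dtw = d)
}

#' Per-class 2-D sequences from a cohort
#'
#' Convenience extractor for [class_separation()]: splits the cohort's
#' per-patient (timepoints x 2) sCD31 / PaO2-FiO2 sequences by outcome.
#'
#' @param cohort An `acr_cohort` containing both classes.
#' @param vars Variables to include (rows of the reshaped patient matrices).
#' @return A named list `list(non_acr = ..., acr = ...)` of lists of
#'   sequence matrices.
#' @export
cohort_class_series <- function(cohort, vars = c("scd31", "pf_ratio")) {
  mats <- reshape_cohort(cohort)
  acr <- attr(mats, "acr")
  seqs <- lapply(mats, function(m) t(m[vars, , drop = FALSE]))
  list(non_acr = seqs[acr == 0L], acr = seqs[acr == 1L])
}
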