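#' Temporal network specification
#'
#' Describes the compact temporal convolutional classifier used for outcome
#' prediction from the per-patient 3-channel x 3-timepoint segments. The
#' default architecture is: a time-distributed (time-independent) linear
#' dense layer mixing the 3 input channels into 16 ("linear spatial
#' filtering"), batch normalization, a 1-D convolution 16 -> 32 with kernel 3
#' (stride 1, same padding) followed by batch normalization and ReLU, a 1-D
#' convolution 32 -> 2 with kernel 3 followed by batch normalization and
#' ReLU, dropout (rate 0.25), global average pooling over time, and a single
#' sigmoid output unit on the 2 pooled channels. Trainable parameters:
#' 64 + 32 + 1568 + 64 + 194 + 4 + 3 = 1929.
#'
#' @param input_channels Number of input variables per timestep.
#' @param timesteps Number of timepoints per segment.
#' @param spatial_units Units of the linear spatial-filter dense layer.
#' @param conv1_filters,conv1_kernel First convolution: filters and kernel.
#' @param conv2_filters,conv2_kernel Second convolution: filters and kernel.
#' @param batch_norm Apply batch normalization after the dense and each conv.
#' @param dropout_rate Dropout rate before pooling (0 disables).
#' @param pooling `"global_average"` (mean over the full time axis) or
#'   `"strided_average"` (average pooling of size 3, stride 3, then mean).
#' @param head_units Output units of the sigmoid head (1 = binary score).
#' @return An object of class `acr_network_spec`.
#' @export
network_spec <- function(input_channels = 3L, timesteps = 3L,
                         spatial_units = 16L,
                         conv1_filters = 32L, conv1_kernel = 3L,
                         conv2_filters = 2L, conv2_kernel = 3L,
                         batch_norm = TRUE, dropout_rate = 0.25,
                         pooling = c("global_average", "strided_average"),
                         head_units = 1L) {
  pooling <- match.arg(pooling)
  for (k in c(conv1_kernel, conv2_kernel)) {
    if (k %% 2L == 0L) stop("convolution kernels must be odd (symmetric 'same' padding)", call. = FALSE)
    if (k > 2L * timesteps - 1L) {
      stop("kernel longer than the padded time axis", call. = FALSE)
    }
  }
  if (dropout_rate < 0 || dropout_rate >= 1) stop("'dropout_rate' must be in [0, 1)", call. = FALSE)
  spec <- list(input_channels = as.integer(input_channels),
               timesteps = as.integer(timesteps),
               spatial_units = as.integer(spatial_units),
               conv1_filters = as.integer(conv1_filters),
               conv1_kernel = as.integer(conv1_kernel),
               conv2_filters = as.integer(conv2_filters),
               conv2_kernel = as.integer(conv2_kernel),
               batch_norm = isTRUE(batch_norm),
               dropout_rate = dropout_rate, pooling = pooling,
               head_units = as.integer(head_units))
  class(spec) <- "acr_network_spec"
  spec
}

#' Per-layer trainable-parameter manifest
#'
#' Pure function of the specification: conv layers contribute
#' `kernel * in_channels * filters + filters`, dense layers
#' `(in + 1) * units`, batch normalization `2 * channels` (scale and shift).
#'
#' @param spec An `acr_network_spec`.
#' @return A data frame with columns `layer`, `type`, `params`, plus the
#'   grand total as attribute `total` (also the last row).
#' @export
parameter_manifest <- function(spec) {
  stopifnot(inherits(spec, "acr_network_spec"))
  rows <- list(
    c("spatial_dense", "dense", (spec$input_channels + 1L) * spec$spatial_units)
  )
  if (spec$batch_norm) rows <- c(rows, list(c("bn_spatial", "batch_norm", 2L * spec$spatial_units)))
  rows <- c(rows, list(
    c("conv1", "conv1d", spec$conv1_kernel * spec$spatial_units * spec$conv1_filters + spec$conv1_filters)
  ))
  if (spec$batch_norm) rows <- c(rows, list(c("bn_conv1", "batch_norm", 2L * spec$conv1_filters)))
  rows <- c(rows, list(
    c("conv2", "conv1d", spec$conv2_kernel * spec$conv1_filters * spec$conv2_filters + spec$conv2_filters)
  ))
  if (spec$batch_norm) rows <- c(rows, list(c("bn_conv2", "batch_norm", 2L * spec$conv2_filters)))
  rows <- c(rows, list(
    c("head", "dense", (spec$conv2_filters + 1L) * spec$head_units)
  ))
  df <- data.frame(layer = vapply(rows, `[`, "", 1L),
                   type = vapply(rows, `[`, "", 2L),
                   params = as.integer(vapply(rows, `[`, "", 3L)),
                   stringsAsFactors = FALSE)
  df <- rbind(df, data.frame(layer = "total", type = "",
                             params = sum(df$params)))
  attr(df, "total") <- df$params[nrow(df)]
  df
}

#' Total trainable parameters of a specification
#' @param spec An `acr_network_spec`.
#' @return Integer total.
#' @export
parameter_count <- function(spec) attr(parameter_manifest(spec), "total")

#' Output-bias initialization for imbalanced labels
#'
#' Initializing the sigmoid head's bias at \eqn{\log(pos/neg)} makes the
#' untrained network's mean predicted probability equal the positive-class
#' prevalence `pos/(pos+neg)` (when all weights are zero), which removes the
#' early epochs otherwise spent learning the base rate and improves initial
#' convergence on imbalanced cohorts.
#'
#' @param pos,neg Positive and negative class counts (both > 0).
#' @return The bias value `log(pos/neg)`.
#' @examples
#' init_output_bias(7, 33)   # about -1.5506
#' @export
init_output_bias <- function(pos, neg) {
  if (pos <= 0 || neg <= 0) {
    stop("'pos' and 'neg' must both be positive: log(pos/neg) is undefined otherwise",
         call. = FALSE)
  }
  log(pos / neg)
}

#' Balanced class weights
#'
#' Computes the standard balanced heuristic \eqn{w_c = n / (2 n_c)} for
#' binary labels, so that each class contributes equally to the weighted
#' binary cross entropy; with balanced classes both weights are 1 and the
#' weighted loss coincides with the unweighted one.
#'
#' @param labels Binary vector (0/1).
#' @return Named numeric vector `c("0" = w_neg, "1" = w_pos)`.
#' @examples
#' class_weights(rep(c(0, 1), c(33, 7)))
#' @export
class_weights <- function(labels) {
  labels <- as.integer(labels)
  n <- length(labels)
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes must be present to compute class weights", call. = FALSE)
  }
  c("0" = n / (2 * n_neg), "1" = n / (2 * n_pos))
}

# ---- standardization --------------------------------------------------------

#' Standardize per-patient segments
#'
#' Per-variable z-scoring of the 3 x 3 patient matrices (rows = variables).
#' Statistics are fitted on the supplied segments unless `fit_stats` is
#' given, in which case they are reused -- the mechanism that prevents
#' held-out information from leaking into training-fold standardization.
#'
#' @param mats Named list of (variables x timepoints) matrices.
#' @param fit_stats Optional statistics from a previous call.
#' @return A list with `segments` (standardized matrices, same shape) and
#'   `stats` (`mean`, `sd` per variable).
#' @export
standardize_segments <- function(mats, fit_stats = NULL) {
  stopifnot(is.list(mats), length(mats) > 0L)
  if (is.null(fit_stats)) {
    all_vals <- do.call(cbind, mats)          # variables x (3 * n)
    mu <- rowMeans(all_vals)
    sdv <- apply(all_vals, 1L, stats::sd)
    if (any(sdv == 0)) {
      stop("zero-variance variable in the fitting set; cannot standardize",
           call. = FALSE)
    }
    fit_stats <- list(mean = mu, sd = sdv)
  }
  segs <- lapply(mats, function(m) (m - fit_stats$mean) / fit_stats$sd)
  for (a in c("acr", "acr_grade")) attr(segs, a) <- attr(mats, a)
  list(segments = segs, stats = fit_stats)
}

#' @rdname standardize_segments
#' @param segments Standardized segments to map back to the original scale.
#' @param stats The `stats` element returned by [standardize_segments()].
#' @export
unstandardize_segments <- function(segments, stats) {
  lapply(segments, function(m) m * stats$sd + stats$mean)
}

#' Classifier-ready segments from a cohort
#'
#' Extracts the per-patient (variables x timepoints) matrices for
#' classification. Plasma sCD31 is log-transformed by default: the biomarker
#' is positively skewed (log-normal scale) and the class-discriminating
#' trend is multiplicative, so the relative decline that separates event
#' from non-event patients is an additive -- and learnable -- slope only on
#' the log scale. PaO2/FiO2 and respiratory SOFA are left untransformed.
#'
#' @param cohort An `acr_cohort`.
#' @param log_scd31 Log-transform the sCD31 channel (default `TRUE`).
#' @return Named list of matrices with `acr` / `acr_grade` attributes, as
#'   [reshape_cohort()].
#' @export
cohort_segments <- function(cohort, log_scd31 = TRUE) {
  mats <- reshape_cohort(cohort)
  if (log_scd31) {
    out <- lapply(mats, function(m) { m["scd31", ] <- log(m["scd31", ]); m })
    for (a in c("acr", "acr_grade")) attr(out, a) <- attr(mats, a)
    mats <- out
  }
  mats
}

# segments (list of vars x time matrices) -> array [N, T, C]
segments_to_array <- function(mats) {
  N <- length(mats)
  T <- ncol(mats[[1]]); C <- nrow(mats[[1]])
  x <- array(NA_real_, c(N, T, C))
  for (i in seq_len(N)) x[i, , ] <- t(mats[[i]])
  dimnames(x) <- list(names(mats), NULL, rownames(mats[[1]]))
  x
}

# ---- parameters, forward and backward passes --------------------------------

#' Build an untrained network from a specification
#'
#' Instantiates the layer graph with freshly initialized parameters (weights
#' N(0, `weight_init_sd`), zero biases, unit batch-norm scales) and attaches
#' the layerwise parameter manifest. The result is a valid classifier object
#' for [predict.acr_classifier()] and a starting point for
#' [train_classifier()] via its `init_params` argument.
#'
#' @param spec An `acr_network_spec`.
#' @param seed Seed for the weight draw.
#' @param weight_init_sd Standard deviation of the normal initializer.
#' @param output_bias Initial head bias (see [init_output_bias()]).
#' @return An `acr_classifier` with untrained parameters.
#' @export
build_network <- function(spec = network_spec(), seed = 1L,
                          weight_init_sd = 0.1, output_bias = 0) {
  set.seed(seed)
  structure(list(params = .init_params(spec, weight_init_sd, output_bias),
                 spec = spec, config = NULL,
                 bn_state = .init_bn_state(spec),
                 history = NULL, manifest = parameter_manifest(spec),
                 stopped_epoch = 0L, best_epoch = 0L),
            class = "acr_classifier")
}

.init_params <- function(spec, weight_init_sd = 0.1, output_bias = 0) {
  rn <- function(...) array(stats::rnorm(prod(c(...)), 0, weight_init_sd), c(...))
  p <- list(
    W_sp = rn(spec$input_channels, spec$spatial_units),
    b_sp = numeric(spec$spatial_units),
    W_c1 = rn(spec$conv1_kernel * spec$spatial_units, spec$conv1_filters),
    b_c1 = numeric(spec$conv1_filters),
    W_c2 = rn(spec$conv2_kernel * spec$conv1_filters, spec$conv2_filters),
    b_c2 = numeric(spec$conv2_filters),
    W_h = matrix(stats::rnorm(spec$conv2_filters * spec$head_units, 0, weight_init_sd),
                 spec$conv2_filters, spec$head_units),
    b_h = rep(output_bias, spec$head_units)
  )
  if (spec$batch_norm) {
    p$g1 <- rep(1, spec$spatial_units); p$be1 <- numeric(spec$spatial_units)
    p$g2 <- rep(1, spec$conv1_filters); p$be2 <- numeric(spec$conv1_filters)
    p$g3 <- rep(1, spec$conv2_filters); p$be3 <- numeric(spec$conv2_filters)
  }
  p
}

.init_bn_state <- function(spec) {
  if (!spec$batch_norm) return(NULL)
  list(m1 = numeric(spec$spatial_units), v1 = rep(1, spec$spatial_units),
       m2 = numeric(spec$conv1_filters), v2 = rep(1, spec$conv1_filters),
       m3 = numeric(spec$conv2_filters), v3 = rep(1, spec$conv2_filters))
}

.bn_eps <- 1e-3
.bn_momentum <- 0.99

# batch norm over rows of a 2-d matrix (rows = batch x time, cols = channels)
.bn_forward <- function(x, gamma, beta, training, run_m, run_v) {
  if (training) {
    mu <- colMeans(x)
    va <- colMeans(sweep(x, 2L, mu)^2)
    new_m <- .bn_momentum * run_m + (1 - .bn_momentum) * mu
    new_v <- .bn_momentum * run_v + (1 - .bn_momentum) * va
  } else {
    mu <- run_m; va <- run_v
    new_m <- run_m; new_v <- run_v
  }
  xhat <- sweep(sweep(x, 2L, mu), 2L, sqrt(va + .bn_eps), "/")
  y <- sweep(sweep(xhat, 2L, gamma, "*"), 2L, beta, "+")
  list(y = y, xhat = xhat, var = va, run_m = new_m, run_v = new_v)
}

.bn_backward <- function(dy, cache, gamma) {
  M <- nrow(dy)
  xhat <- cache$xhat
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2L, gamma, "*")
  inv_sd <- 1 / sqrt(cache$var + .bn_eps)
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * xhat)
  dx <- sweep(M * dxhat - matrix(s1, M, ncol(dy), byrow = TRUE) -
                xhat * matrix(s2, M, ncol(dy), byrow = TRUE),
              2L, inv_sd / M, "*")
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# 'same'-padded 1-D convolution on [N, T, C] -> [N, T, F]
.conv_forward <- function(x, W, b, kernel) {
  N <- dim(x)[1]; T <- dim(x)[2]; C <- dim(x)[3]
  pad <- (kernel - 1L) %/% 2L
  xp <- array(0, c(N, T + 2L * pad, C))
  xp[, pad + seq_len(T), ] <- x
  Fl <- length(b)
  y <- array(NA_real_, c(N, T, Fl))
  Z <- vector("list", T)
  for (t in seq_len(T)) {
    z <- matrix(xp[, t:(t + kernel - 1L), , drop = FALSE], N, kernel * C)
    Z[[t]] <- z
    y[, t, ] <- sweep(z %*% W, 2L, b, "+")
  }
  list(y = y, Z = Z, pad = pad, in_dim = dim(x))
}

.conv_backward <- function(dy, cache, W, kernel) {
  N <- cache$in_dim[1]; T <- cache$in_dim[2]; C <- cache$in_dim[3]
  pad <- cache$pad
  dW <- matrix(0, nrow(W), ncol(W))
  db <- numeric(ncol(W))
  dxp <- array(0, c(N, T + 2L * pad, C))
  for (t in seq_len(T)) {
    dyt <- matrix(dy[, t, ], N, ncol(W))
    dW <- dW + crossprod(cache$Z[[t]], dyt)
    db <- db + colSums(dyt)
    dz <- dyt %*% t(W)                        # N x (kernel * C)
    dxp[, t:(t + kernel - 1L), ] <- dxp[, t:(t + kernel - 1L), , drop = FALSE] +
      array(dz, c(N, kernel, C))
  }
  list(dx = dxp[, pad + seq_len(T), , drop = FALSE], dW = dW, db = db)
}

.forward <- function(params, spec, bn_state, x, training = FALSE,
                     dropout_mask = NULL) {
  N <- dim(x)[1]; T <- dim(x)[2]
  cache <- list()

  # time-distributed linear spatial filter
  x2 <- matrix(x, N * T, dim(x)[3])           # column-major: (n, t) pairs
  h <- sweep(x2 %*% params$W_sp, 2L, params$b_sp, "+")
  cache$x2 <- x2
  if (spec$batch_norm) {
    bn1 <- .bn_forward(h, params$g1, params$be1, training, bn_state$m1, bn_state$v1)
    cache$bn1 <- bn1
    h <- bn1$y
  }
  h3 <- array(h, c(N, T, spec$spatial_units))

  c1 <- .conv_forward(h3, params$W_c1, params$b_c1, spec$conv1_kernel)
  cache$c1 <- c1
  a1 <- matrix(c1$y, N * T, spec$conv1_filters)
  if (spec$batch_norm) {
    bn2 <- .bn_forward(a1, params$g2, params$be2, training, bn_state$m2, bn_state$v2)
    cache$bn2 <- bn2
    a1 <- bn2$y
  }
  cache$pre_relu1 <- a1
  r1 <- array(pmax(a1, 0), c(N, T, spec$conv1_filters))

  c2 <- .conv_forward(r1, params$W_c2, params$b_c2, spec$conv2_kernel)
  cache$c2 <- c2
  a2 <- matrix(c2$y, N * T, spec$conv2_filters)
  if (spec$batch_norm) {
    bn3 <- .bn_forward(a2, params$g3, params$be3, training, bn_state$m3, bn_state$v3)
    cache$bn3 <- bn3
    a2 <- bn3$y
  }
  cache$pre_relu2 <- a2
  r2 <- pmax(a2, 0)                           # (N*T) x F2

  if (training && spec$dropout_rate > 0) {
    if (is.null(dropout_mask)) {
      dropout_mask <- matrix(stats::runif(length(r2)) >= spec$dropout_rate,
                             nrow(r2), ncol(r2))
    }
    r2 <- r2 * dropout_mask / (1 - spec$dropout_rate)
  }
  cache$dropout_mask <- dropout_mask
  r2a <- array(r2, c(N, T, spec$conv2_filters))

  # pooling over the time axis
  pooled <- apply(r2a, c(1L, 3L), mean)       # N x F2 (global average pool)
  pooled <- matrix(pooled, N, spec$conv2_filters)
  cache$T <- T

  z <- sweep(pooled %*% params$W_h, 2L, params$b_h, "+")
  z <- as.numeric(z)
  p <- .sigmoid(z)
  cache$pooled <- pooled
  list(z = z, p = p, cache = cache,
       bn_state = if (spec$batch_norm && training) {
         list(m1 = cache$bn1$run_m, v1 = cache$bn1$run_v,
              m2 = cache$bn2$run_m, v2 = cache$bn2$run_v,
              m3 = cache$bn3$run_m, v3 = cache$bn3$run_v)
       } else bn_state)
}

.sigmoid <- function(z) ifelse(z >= 0, 1 / (1 + exp(-z)), exp(z) / (1 + exp(z)))

# gradient of the mean weighted BCE wrt all parameters
.backward <- function(params, spec, fw, y, w) {
  cache <- fw$cache
  N <- length(y); T <- cache$T
  dz <- w * (fw$p - y) / N                    # dL/dz, length N

  g <- list()
  g$W_h <- crossprod(cache$pooled, matrix(dz, N, 1L))
  g$b_h <- sum(dz)
  dpool <- matrix(dz, N, 1L) %*% t(params$W_h)       # N x F2

  # undo pooling: each time frame receives dpool / T
  dr2 <- matrix(0, N * T, spec$conv2_filters)
  for (t in seq_len(T)) {
    dr2[(t - 1L) * N + seq_len(N), ] <- dpool / T
  }
  if (!is.null(cache$dropout_mask)) {
    dr2 <- dr2 * cache$dropout_mask / (1 - spec$dropout_rate)
  }
  da2 <- dr2 * (cache$pre_relu2 > 0)
  if (spec$batch_norm) {
    bb <- .bn_backward(da2, cache$bn3, params$g3)
    g$g3 <- bb$dgamma; g$be3 <- bb$dbeta
    da2 <- bb$dx
  }
  cb2 <- .conv_backward(array(da2, c(N, T, spec$conv2_filters)),
                        cache$c2, params$W_c2, spec$conv2_kernel)
  g$W_c2 <- cb2$dW; g$b_c2 <- cb2$db

  dr1 <- matrix(cb2$dx, N * T, spec$conv1_filters)
  da1 <- dr1 * (cache$pre_relu1 > 0)
  if (spec$batch_norm) {
    bb <- .bn_backward(da1, cache$bn2, params$g2)
    g$g2 <- bb$dgamma; g$be2 <- bb$dbeta
    da1 <- bb$dx
  }
  cb1 <- .conv_backward(array(da1, c(N, T, spec$conv1_filters)),
                        cache$c1, params$W_c1, spec$conv1_kernel)
  g$W_c1 <- cb1$dW; g$b_c1 <- cb1$db

  dh <- matrix(cb1$dx, N * T, spec$spatial_units)
  if (spec$batch_norm) {
    bb <- .bn_backward(dh, cache$bn1, params$g1)
    g$g1 <- bb$dgamma; g$be1 <- bb$dbeta
    dh <- bb$dx
  }
  g$W_sp <- crossprod(cache$x2, dh)
  g$b_sp <- colSums(dh)
  g
}

.weighted_bce <- function(p, y, w) {
  eps <- 1e-12
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(w * (y * log(p) + (1 - y) * log(1 - p)))
}

# ---- Adam -------------------------------------------------------------------

.adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

.adam_step <- function(params, grads, state, lr, beta1, beta2, eps,
                       trainable = names(params)) {
  state$t <- state$t + 1L
  t <- state$t
  for (nm in intersect(trainable, names(grads))) {
    gr <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# ---- training configuration and loop ----------------------------------------

#' Training configuration
#'
#' Adam hyperparameters default to `lr = 1e-4`, `beta1 = 0.9`,
#' `beta2 = 0.999`, `epsilon = 1e-7`; batches of 32; early stopping on
#' validation loss with patience 10 (best weights restored); weights drawn
#' from N(0, 0.1); stratified 5-fold cross-validation; class weights and
#' output-bias initialization on by default. Optional within-class convex
#' mixing of patient segments (a mixup-style augmenter with coefficient
#' uniform on (0.2, 0.8)) is off by default.
#'
#' @param learning_rate,beta1,beta2,epsilon Adam parameters.
#' @param batch_size Mini-batch size.
#' @param epochs Maximum number of epochs.
#' @param patience Early-stopping patience on validation loss (ignored when
#'   no validation set is supplied).
#' @param folds Number of stratified cross-validation folds.
#' @param weight_init_sd Standard deviation of the normal weight initializer.
#' @param use_class_weights Weight the loss by [class_weights()].
#' @param output_bias_init Initialize the head bias at [init_output_bias()].
#' @param augment Number of augmented (within-class convex combination)
#'   segments to add to each training set; 0 disables augmentation.
#' @param seed Integer seed for weight init, shuffling, dropout and folds.
#' @return An object of class `acr_training_config`.
#' @export
training_config <- function(learning_rate = 1e-4, beta1 = 0.9, beta2 = 0.999,
                            epsilon = 1e-7, batch_size = 32L, epochs = 2000L,
                            patience = 10L, folds = 5L, weight_init_sd = 0.1,
                            use_class_weights = TRUE, output_bias_init = TRUE,
                            augment = 0L, seed = 1L) {
  cfg <- list(learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
              epsilon = epsilon, batch_size = as.integer(batch_size),
              epochs = as.integer(epochs), patience = as.integer(patience),
              folds = as.integer(folds), weight_init_sd = weight_init_sd,
              use_class_weights = isTRUE(use_class_weights),
              output_bias_init = isTRUE(output_bias_init),
              augment = as.integer(augment), seed = as.integer(seed))
  class(cfg) <- "acr_training_config"
  cfg
}

.sample_weights <- function(y, use_class_weights) {
  if (!use_class_weights) return(rep(1, length(y)))
  cw <- class_weights(y)
  unname(cw[as.character(as.integer(y))])
}

.augment_segments <- function(x, y, n_extra) {
  # within-class convex combinations, coefficient ~ U(0.2, 0.8)
  if (n_extra <= 0L) return(list(x = x, y = y))
  N <- dim(x)[1]
  xs <- list(); ys <- numeric(0)
  for (i in seq_len(n_extra)) {
    cls <- y[sample.int(N, 1L)]
    pool <- which(y == cls)
    if (length(pool) < 2L) next
    ij <- sample(pool, 2L)
    lam <- stats::runif(1, 0.2, 0.8)
    xs[[length(xs) + 1L]] <- lam * x[ij[1], , ] + (1 - lam) * x[ij[2], , ]
    ys <- c(ys, cls)
  }
  if (length(xs) == 0L) return(list(x = x, y = y))
  xa <- array(NA_real_, c(N + length(xs), dim(x)[2], dim(x)[3]))
  xa[seq_len(N), , ] <- x
  for (i in seq_along(xs)) xa[N + i, , ] <- xs[[i]]
  list(x = xa, y = c(y, ys))
}

#' Train the temporal classifier
#'
#' Minimizes the class-weighted binary cross entropy by mini-batch Adam.
#' Inputs are standardized per-patient segments (see
#' [standardize_segments()]); labels are 0/1 (1 = ACR event). When a
#' validation set is supplied, early stopping monitors the validation loss
#' with the configured patience and the best weights are restored.
#'
#' @param x Array `[n, timesteps, channels]` or a named list of
#'   (variables x timepoints) matrices.
#' @param y Binary label vector (both classes must be present).
#' @param spec An `acr_network_spec`.
#' @param config An `acr_training_config`.
#' @param x_val,y_val Optional validation set (same formats).
#' @param init_params Optional parameter list to start from (used to compare
#'   training runs from identical initial weights, and by the two-phase risk
#'   protocol).
#' @param trainable Names of parameter tensors to update; defaults to all.
#' @return An object of class `acr_classifier`: `params`, `spec`, `config`,
#'   `bn_state`, `history` (per-epoch data frame), `manifest`.
#' @export
train_classifier <- function(x, y, spec = network_spec(),
                             config = training_config(),
                             x_val = NULL, y_val = NULL,
                             init_params = NULL, trainable = NULL) {
  if (is.list(x)) x <- segments_to_array(x)
  y <- as.integer(y)
  if (length(unique(y)) < 2L) {
    stop("degenerate labels: training requires both classes", call. = FALSE)
  }
  if (sum(y == 1L) < 2L || sum(y == 0L) < 2L) {
    stop("need at least 2 patients per class to train", call. = FALSE)
  }
  if (!is.null(x_val) && is.list(x_val)) x_val <- segments_to_array(x_val)

  set.seed(config$seed)
  if (is.null(init_params)) {
    bias0 <- if (config$output_bias_init) init_output_bias(sum(y == 1L), sum(y == 0L)) else 0
    params <- .init_params(spec, config$weight_init_sd, bias0)
  } else {
    params <- init_params
  }
  if (is.null(trainable)) trainable <- names(params)
  bn_state <- .init_bn_state(spec)
  adam <- .adam_init(params)

  aug <- .augment_segments(x, y, config$augment)
  x_tr <- aug$x; y_tr <- aug$y
  w_tr <- .sample_weights(y_tr, config$use_class_weights)

  N <- dim(x_tr)[1]
  history <- list()
  best <- list(loss = Inf, params = params, bn_state = bn_state, epoch = 0L)
  wait <- 0L

  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(N)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    for (b in batches) {
      xb <- x_tr[b, , , drop = FALSE]
      fw <- .forward(params, spec, bn_state, xb, training = TRUE)
      bn_state <- fw$bn_state
      g <- .backward(params, spec, fw, y_tr[b], w_tr[b])
      upd <- .adam_step(params, g, adam, config$learning_rate, config$beta1,
                        config$beta2, config$epsilon, trainable)
      params <- upd$params; adam <- upd$state
    }
    ev <- .forward(params, spec, bn_state, x_tr, training = FALSE)
    m <- .threshold_metrics(ev$p, y_tr)
    row <- data.frame(epoch = epoch,
                      loss = .weighted_bce(ev$p, y_tr, w_tr),
                      accuracy = m["accuracy"], precision = m["precision"],
                      recall = m["recall"], row.names = NULL)
    if (!is.null(x_val)) {
      evv <- .forward(params, spec, bn_state, x_val, training = FALSE)
      wv <- .sample_weights_safe(y_val, config$use_class_weights, y_tr)
      row$val_loss <- .weighted_bce(evv$p, y_val, wv)
      row$val_accuracy <- mean((evv$p >= 0.5) == (y_val == 1L))
      if (row$val_loss < best$loss - 1e-12) {
        best <- list(loss = row$val_loss, params = params,
                     bn_state = bn_state, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
      }
    }
    history[[epoch]] <- row
    if (!is.null(x_val) && wait >= config$patience) break
  }
  history <- do.call(rbind, history)
  if (!is.null(x_val) && is.finite(best$loss)) {
    params <- best$params; bn_state <- best$bn_state
  }
  structure(list(params = params, spec = spec, config = config,
                 bn_state = bn_state, history = history,
                 manifest = parameter_manifest(spec),
                 stopped_epoch = nrow(history), best_epoch = best$epoch),
            class = "acr_classifier")
}

# validation-class weights: classes absent from training get weight 1
.sample_weights_safe <- function(y, use_class_weights, y_train) {
  if (!use_class_weights) return(rep(1, length(y)))
  cw <- class_weights(y_train)
  w <- cw[as.character(as.integer(y))]
  w[is.na(w)] <- 1
  unname(w)
}

.threshold_metrics <- function(p, y, threshold = 0.5) {
  pred <- as.integer(p >= threshold)
  tp <- sum(pred == 1L & y == 1L); fp <- sum(pred == 1L & y == 0L)
  fn <- sum(pred == 0L & y == 1L)
  c(accuracy = mean(pred == y),
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
}

#' @export
print.acr_classifier <- function(x, ...) {
  cat(sprintf("Temporal classifier: %d trainable parameters, trained %d epoch(s)\n",
              attr(x$manifest, "total"), x$stopped_epoch))
  invisible(x)
}

#' Predict from a trained classifier
#'
#' @param object An `acr_classifier`.
#' @param x Segments (array or list of matrices).
#' @param type `"prob"` for sigmoid probabilities, `"z"` for the head's
#'   pre-activation (log-odds scale).
#' @param ... Unused.
#' @return Numeric vector, named by patient when names are available.
#' @export
predict.acr_classifier <- function(object, x, type = c("prob", "z"), ...) {
  type <- match.arg(type)
  nms <- if (is.list(x)) names(x) else dimnames(x)[[1]]
  if (is.list(x)) x <- segments_to_array(x)
  fw <- .forward(object$params, object$spec, object$bn_state, x, training = FALSE)
  out <- if (type == "prob") fw$p else fw$z
  stats::setNames(out, nms)
}

#' Retrain only the sigmoid head (phase II of the risk protocol)
#'
#' Freezes the feature extractor (every tensor except the head weights and
#' bias) at the trained values and re-optimizes the head alone -- the second
#' phase of the two-phase risk-predictor construction. Extractor weights are
#' guaranteed untouched.
#'
#' @param model A trained `acr_classifier`.
#' @param x,y Training segments and labels.
#' @param config Training configuration (its seed drives the refit).
#' @return An `acr_classifier` with updated head parameters.
#' @export
refit_head <- function(model, x, y, config = model$config) {
  train_classifier(x, y, spec = model$spec, config = config,
                   init_params = model$params,
                   trainable = c("W_h", "b_h"))
}

# ---- evaluation -------------------------------------------------------------

#' Rank-based AUC
#'
#' Area under the ROC curve computed as the Mann-Whitney rank statistic
#' (ties shared equally).
#'
#' @param p Predicted scores.
#' @param y Binary labels.
#' @return AUC in `[0, 1]`; `NA` with a warning when only one class is present.
#' @export
rank_auc <- function(p, y) {
  y <- as.integer(y)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) {
    warning("AUC undefined: evaluation set contains a single class", call. = FALSE)
    return(NA_real_)
  }
  r <- rank(p)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cohen's kappa from a 2 x 2 confusion matrix
#' @param cm Confusion matrix (rows = actual, cols = predicted).
#' @return Kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(cm) {
  n <- sum(cm)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (pe == 1) return(0)
  (po - pe) / (1 - pe)
}

#' Evaluate a classifier (or raw predictions) on labelled segments
#'
#' Fills the standard evaluation report: 2 x 2 confusion matrix at threshold
#' 0.5, accuracy, per-class precision/recall/F1, rank-statistic AUC, Cohen's
#' kappa, Kullback-Leibler divergence of the predicted distribution from the
#' one-hot target (mean `-log p_true`), and the binary cross-entropy loss.
#'
#' @param model An `acr_classifier`, or `NULL` when `prob` is supplied.
#' @param x Segments (ignored when `prob` given).
#' @param y Binary labels.
#' @param prob Optional predicted probabilities, bypassing the model.
#' @return An object of class `acr_eval_report`.
#' @export
evaluate_classifier <- function(model, x = NULL, y, prob = NULL) {
  if (is.null(prob)) prob <- predict(model, x, type = "prob")
  y <- as.integer(y)
  if (length(y) == 0L) stop("empty evaluation set", call. = FALSE)
  pred <- as.integer(prob >= 0.5)
  cm <- matrix(0L, 2L, 2L, dimnames = list(actual = c("0", "1"),
                                           predicted = c("0", "1")))
  for (i in seq_along(y)) cm[y[i] + 1L, pred[i] + 1L] <- cm[y[i] + 1L, pred[i] + 1L] + 1L
  per_class <- lapply(c(0L, 1L), function(cl) {
    tp <- sum(pred == cl & y == cl); fp <- sum(pred == cl & y != cl)
    fn <- sum(pred != cl & y == cl)
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0) 2 * prec * rec / (prec + rec) else NA_real_
    c(precision = prec, recall = rec, f1 = f1)
  })
  names(per_class) <- c("class_0", "class_1")
  eps <- 1e-12
  pc <- pmin(pmax(prob, eps), 1 - eps)
  structure(list(confusion_matrix = cm,
                 accuracy = mean(pred == y),
                 per_class = per_class,
                 auc = rank_auc(prob, y),
                 cohen_kappa = cohen_kappa(cm),
                 kl_divergence = mean(-log(ifelse(y == 1L, pc, 1 - pc))),
                 loss = .weighted_bce(prob, y, rep(1, length(y))),
                 n = length(y)),
            class = "acr_eval_report")
}

#' @export
print.acr_eval_report <- function(x, ...) {
  cat(sprintf("Evaluation on %d patients: accuracy %.3f, AUC %s, kappa %.3f\n",
              x$n, x$accuracy,
              ifelse(is.na(x$auc), "NA", sprintf("%.3f", x$auc)), x$cohen_kappa))
  cat("Confusion matrix (rows = actual, cols = predicted):\n")
  print(x$confusion_matrix)
  invisible(x)
}

# ---- stratified cross-validation --------------------------------------------

#' Stratified fold assignment
#'
#' Shuffles indices within each class and deals them round-robin so every
#' fold's class mix matches the global mix to within one patient.
#'
#' @param y Binary label vector.
#' @param k Number of folds.
#' @return Integer vector of fold ids in `1:k`.
#' @export
stratified_folds <- function(y, k) {
  y <- as.integer(y)
  if (any(table(y) < k)) {
    stop("a class has fewer members than folds; stratification impossible",
         call. = FALSE)
  }
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Stratified k-fold cross-validation of the temporal classifier
#'
#' For each fold: standardization statistics are fitted on the training
#' folds only and applied to the held-out fold (no leakage); a fresh model
#' is trained with class weights and output-bias initialization per the
#' configuration; out-of-fold predicted probabilities are collected and
#' summarized in a single pooled evaluation report.
#'
#' By default each fold trains for the full configured epoch budget and the
#' held-out fold is used for evaluation only: letting the evaluation fold
#' also drive early stopping would leak held-out information into the
#' stopping decision and bias the cross-validated metrics optimistically.
#' Set `validation = "heldout"` to reproduce the monitored-training variant
#' (early stopping on the held-out fold's loss with the configured
#' patience).
#'
#' @param mats Named list of raw (unstandardized) patient matrices.
#' @param y Binary labels, same order as `mats`.
#' @param spec,config Network and training configuration.
#' @param validation `"none"` (default; full epoch budget per fold) or
#'   `"heldout"` (early-stop on the held-out fold).
#' @return A list of class `acr_cv`: `report` (pooled out-of-fold
#'   [evaluate_classifier()] result), `oof_prob` (named vector), `folds`,
#'   `fold_models`.
#' @export
cross_validate <- function(mats, y, spec = network_spec(),
                           config = training_config(),
                           validation = c("none", "heldout")) {
  validation <- match.arg(validation)
  y <- as.integer(y)
  stopifnot(length(mats) == length(y))
  set.seed(config$seed)
  fold <- stratified_folds(y, config$folds)
  oof <- rep(NA_real_, length(y))
  names(oof) <- names(mats)
  models <- vector("list", config$folds)
  for (f in seq_len(config$folds)) {
    tr <- which(fold != f); te <- which(fold == f)
    std <- standardize_segments(mats[tr])
    x_tr <- std$segments
    x_te <- standardize_segments(mats[te], fit_stats = std$stats)$segments
    cfg_f <- config
    cfg_f$seed <- config$seed + f            # fold-specific child seed
    mod <- if (validation == "heldout") {
      train_classifier(x_tr, y[tr], spec, cfg_f, x_val = x_te, y_val = y[te])
    } else {
      train_classifier(x_tr, y[tr], spec, cfg_f)
    }
    oof[te] <- predict(mod, x_te, type = "prob")
    models[[f]] <- mod
  }
  structure(list(report = evaluate_classifier(NULL, y = y, prob = oof),
                 oof_prob = oof, folds = fold, fold_models = models),
            class = "acr_cv")
}

#' @export
print.acr_cv <- function(x, ...) {
  cat(sprintf("%d-fold stratified cross-validation\n", max(x$folds)))
  print(x$report)
  invisible(x)
}
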