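test_that("the default architecture reproduces its layerwise parameter counts", {
  man <- parameter_manifest(network_spec())
  counts <- stats::setNames(man$params, man$layer)
  expect_identical(counts[["spatial_dense"]], 64L)
  expect_identical(counts[["conv1"]], 1568L)
  expect_identical(counts[["conv2"]], 194L)
  expect_identical(counts[["head"]], 3L)
  expect_identical(counts[["bn_spatial"]] + counts[["bn_conv1"]] + counts[["bn_conv2"]],
                   100L)
  expect_identical(counts[["total"]], 1929L)
  expect_identical(parameter_count(network_spec()), 1929L)
})

test_that("parameter counts follow the analytic formulas for arbitrary specs", {
  set.seed(21)
  for (trial in 1:10) {
    ic <- sample(1:4, 1); su <- sample(1:20, 1)
    f1 <- sample(1:16, 1); f2 <- sample(1:8, 1)
    k1 <- sample(c(1, 3), 1); k2 <- sample(c(1, 3), 1)
    bn <- sample(c(TRUE, FALSE), 1)
    spec <- network_spec(input_channels = ic, spatial_units = su,
                         conv1_filters = f1, conv1_kernel = k1,
                         conv2_filters = f2, conv2_kernel = k2,
                         batch_norm = bn)
    expected <- (ic + 1) * su + k1 * su * f1 + f1 + k2 * f1 * f2 + f2 +
      (f2 + 1) * 1 + if (bn) 2 * (su + f1 + f2) else 0
    expect_identical(parameter_count(spec), as.integer(expected))
    # the built model carries exactly that many trainable values
    params <- acrisk:::.init_params(spec)
    expect_identical(sum(lengths(params)), as.integer(expected))
  }
  # hand-verified minimal spec: 1-channel, all sizes 1, no batch norm
  tiny <- network_spec(input_channels = 1, spatial_units = 1,
                       conv1_filters = 1, conv1_kernel = 1,
                       conv2_filters = 1, conv2_kernel = 1, batch_norm = FALSE)
  expect_identical(parameter_count(tiny), 8L)
})

test_that("an untrained built network predicts valid probabilities", {
  net <- build_network(network_spec(), seed = 19)
  expect_identical(sum(lengths(net$params)), 1929L)
  expect_identical(attr(net$manifest, "total"), 1929L)
  set.seed(20)
  x <- array(rnorm(5 * 9), c(5, 3, 3))
  p <- predict(net, x)
  expect_true(all(p > 0 & p < 1))
  # the same seed rebuilds the same network
  expect_identical(build_network(network_spec(), seed = 19)$params, net$params)
})

test_that("specification guards reject impossible layouts", {
  expect_error(network_spec(conv1_kernel = 2), "odd")
  expect_error(network_spec(conv1_kernel = 7, timesteps = 3), "padded time axis")
  expect_error(network_spec(dropout_rate = 1), "dropout_rate")
})

test_that("standardization is leak-free and exactly invertible", {
  coh <- generate_cohort(generator_config(seed = 14))
  mats <- cohort_segments(coh)
  std <- standardize_segments(mats)
  all_vals <- do.call(cbind, std$segments)
  expect_lt(max(abs(rowMeans(all_vals))), 1e-10)
  expect_lt(max(abs(apply(all_vals, 1, stats::sd) - 1)), 1e-10)

  # held-out standardization reuses only fitting-set statistics
  tr <- mats[1:30]; te <- mats[31:40]
  fit <- standardize_segments(tr)
  held <- standardize_segments(te, fit_stats = fit$stats)
  manual <- (te[[1]] - fit$stats$mean) / fit$stats$sd
  expect_equal(held$segments[[1]], manual)

  back <- unstandardize_segments(std$segments, std$stats)
  expect_equal(back[[5]], mats[[5]], tolerance = 1e-10)

  flat <- lapply(mats, function(m) { m[2, ] <- 7; m })
  expect_error(standardize_segments(flat), "zero-variance")
})

test_that("output-bias initialization encodes the class base rate", {
  expect_equal(init_output_bias(5, 5), 0)
  expect_equal(init_output_bias(7, 33), log(7 / 33))
  expect_equal(init_output_bias(7, 33), -1.5505974, tolerance = 1e-6)
  expect_error(init_output_bias(0, 10), "positive")
  expect_error(init_output_bias(10, 0), "positive")

  # zero weights + base-rate bias: mean predicted probability = prevalence
  spec <- network_spec(dropout_rate = 0)
  params <- acrisk:::.init_params(spec, weight_init_sd = 0,
                                  output_bias = init_output_bias(7, 33))
  bn <- acrisk:::.init_bn_state(spec)
  set.seed(3)
  x <- array(rnorm(40 * 9), c(40, 3, 3))
  fw <- acrisk:::.forward(params, spec, bn, x, training = FALSE)
  expect_equal(mean(fw$p), 7 / 40, tolerance = 1e-12)
})

test_that("class weights follow the balanced heuristic", {
  expect_equal(unname(class_weights(rep(c(0, 1), each = 20))), c(1, 1))
  w <- class_weights(rep(c(1, 0), c(7, 33)))
  expect_equal(unname(w["1"]), 40 / 14)
  expect_equal(unname(w["0"]), 40 / 66)
  expect_error(class_weights(rep(1, 10)), "both classes")

  # weighted BCE agrees with hand-computed arithmetic on a toy batch
  p <- c(0.9, 0.2, 0.6, 0.4); y <- c(1, 0, 1, 0)
  w4 <- c(2, 0.5, 2, 0.5)
  by_hand <- -(2 * log(0.9) + 0.5 * log(0.8) + 2 * log(0.6) + 0.5 * log(0.6)) / 4
  expect_equal(acrisk:::.weighted_bce(p, y, w4), by_hand, tolerance = 1e-12)
  # unit weights reduce to the plain loss
  expect_equal(acrisk:::.weighted_bce(p, y, rep(1, 4)),
               -mean(y * log(p) + (1 - y) * log(1 - p)), tolerance = 1e-12)
})

test_that("analytic gradients match numerical differentiation", {
  spec <- network_spec(dropout_rate = 0)
  set.seed(3)
  params <- acrisk:::.init_params(spec, 0.1, 0.2)
  bn <- acrisk:::.init_bn_state(spec)
  N <- 6
  x <- array(rnorm(N * 9), c(N, 3, 3))
  y <- c(1, 0, 0, 1, 0, 1)
  w <- rep(c(2.1, 0.6), 3)
  loss_at <- function(p) {
    fw <- acrisk:::.forward(p, spec, bn, x, training = TRUE)
    acrisk:::.weighted_bce(fw$p, y, w)
  }
  fw <- acrisk:::.forward(params, spec, bn, x, training = TRUE)
  g <- acrisk:::.backward(params, spec, fw, y, w)
  numerical <- function(nm, i, eps) {
    p1 <- params; p1[[nm]][i] <- p1[[nm]][i] + eps
    p2 <- params; p2[[nm]][i] <- p2[[nm]][i] - eps
    (loss_at(p1) - loss_at(p2)) / (2 * eps)
  }
  checked <- 0L
  for (nm in names(g)) {
    idx <- sample(length(g[[nm]]), min(4, length(g[[nm]])))
    for (i in idx) {
      num1 <- numerical(nm, i, 1e-6)
      num2 <- numerical(nm, i, 1e-5)
      # two step sizes disagreeing flags a ReLU kink inside the stencil,
      # where a finite difference does not estimate the (sub)gradient
      if (abs(num1 - num2) > 1e-3 * (abs(num1) + abs(num2) + 1e-8)) next
      rel <- abs(num1 - g[[nm]][i]) / max(1e-8, abs(num1) + abs(g[[nm]][i]))
      expect_lt(rel, 1e-4)
      checked <- checked + 1L
    }
  }
  expect_gte(checked, 30L)   # the kink filter must not hollow out the check
})

test_that("pointwise networks are invariant to time permutation (pooling property)", {
  # with kernel-1 convolutions every layer before pooling acts per-timestep,
  # so global average pooling makes the whole network permutation invariant
  spec <- network_spec(conv1_kernel = 1, conv2_kernel = 1, dropout_rate = 0,
                       timesteps = 5)
  set.seed(22)
  params <- acrisk:::.init_params(spec, 0.3, 0.1)
  bn <- acrisk:::.init_bn_state(spec)
  x <- array(rnorm(4 * 5 * 3), c(4, 5, 3))
  perm <- sample(5)
  xp <- x[, perm, , drop = FALSE]
  f1 <- acrisk:::.forward(params, spec, bn, x, training = FALSE)
  f2 <- acrisk:::.forward(params, spec, bn, xp, training = FALSE)
  expect_equal(f1$p, f2$p, tolerance = 1e-12)
})

test_that("stratified folds preserve the class mix to within one patient", {
  y <- rep(c(1, 0), c(7, 33))
  set.seed(30)
  fold <- stratified_folds(y, 5)
  for (f in 1:5) {
    n_f <- sum(fold == f)
    pos_f <- sum(y[fold == f] == 1)
    expect_lte(abs(pos_f - n_f * 7 / 40), 1)
  }
  expect_error(stratified_folds(rep(c(1, 0), c(3, 37)), 5), "fewer members")
})

test_that("training is seed-deterministic and rejects degenerate labels", {
  coh <- generate_cohort(separable_config(2))
  mats <- cohort_segments(coh)
  y <- attr(mats, "acr")
  std <- standardize_segments(mats)
  cfg <- training_config(epochs = 30, seed = 5)
  m1 <- train_classifier(std$segments, y, config = cfg)
  m2 <- train_classifier(std$segments, y, config = cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)

  expect_error(train_classifier(std$segments, rep(1, 40), config = cfg),
               "degenerate labels")
  expect_error(train_classifier(std$segments, c(1, rep(0, 39)), config = cfg),
               "at least 2")
})

test_that("one epoch moves the loss and bias init improves the starting loss", {
  coh <- generate_cohort(separable_config(3))
  mats <- cohort_segments(coh)
  y <- attr(mats, "acr")
  std <- standardize_segments(mats)
  m1 <- train_classifier(std$segments, y, config = training_config(epochs = 1, seed = 6))
  fw0 <- acrisk:::.forward(acrisk:::.init_params(network_spec(), 0.1,
                                                 init_output_bias(7, 33)),
                           network_spec(), acrisk:::.init_bn_state(network_spec()),
                           acrisk:::segments_to_array(std$segments), training = FALSE)
  w <- acrisk:::.sample_weights(y, TRUE)
  loss0 <- acrisk:::.weighted_bce(fw0$p, y, w)
  expect_false(isTRUE(all.equal(m1$history$loss[1], loss0)))

  # base-rate bias beats a zero bias on an imbalanced cohort at initialization
  set.seed(7)
  p_bias <- acrisk:::.init_params(network_spec(), 0.1, init_output_bias(7, 33))
  set.seed(7)
  p_zero <- acrisk:::.init_params(network_spec(), 0.1, 0)
  bn <- acrisk:::.init_bn_state(network_spec())
  xa <- acrisk:::segments_to_array(std$segments)
  l_bias <- acrisk:::.weighted_bce(
    acrisk:::.forward(p_bias, network_spec(), bn, xa, training = FALSE)$p, y, rep(1, 40))
  l_zero <- acrisk:::.weighted_bce(
    acrisk:::.forward(p_zero, network_spec(), bn, xa, training = FALSE)$p, y, rep(1, 40))
  expect_lt(l_bias, l_zero)
})

test_that("head refitting never touches the frozen feature extractor", {
  coh <- generate_cohort(separable_config(4))
  mats <- cohort_segments(coh)
  y <- attr(mats, "acr")
  std <- standardize_segments(mats)
  base <- train_classifier(std$segments, y, config = training_config(epochs = 50, seed = 8))
  refit <- refit_head(base, std$segments, y,
                      config = training_config(epochs = 50, seed = 9))
  extractor <- setdiff(names(base$params), c("W_h", "b_h"))
  for (nm in extractor) expect_identical(refit$params[[nm]], base$params[[nm]])
  expect_false(identical(refit$params$W_h, base$params$W_h))
})

test_that("evaluation metrics match closed-form confusion-matrix arithmetic", {
  y <- rep(c(1, 0), c(7, 33))
  perfect <- evaluate_classifier(NULL, y = y, prob = ifelse(y == 1, 0.9, 0.1))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$cohen_kappa, 1)
  expect_equal(sum(perfect$confusion_matrix) - sum(diag(perfect$confusion_matrix)), 0)

  # constant majority-class predictor
  majority <- evaluate_classifier(NULL, y = y, prob = rep(0.2, 40))
  expect_equal(majority$accuracy, 33 / 40)
  expect_equal(majority$cohen_kappa, 0)
  expect_equal(unname(majority$per_class$class_1["recall"]), 0)
  expect_identical(sum(majority$confusion_matrix), 40L)

  # kappa for the matrix ((30, 3), (2, 5)), computed by hand
  prob <- c(rep(0.1, 30), rep(0.9, 3), rep(0.1, 2), rep(0.9, 5))
  yy <- rep(c(0, 1), c(33, 7))
  rep_k <- evaluate_classifier(NULL, y = yy, prob = prob)
  po <- 35 / 40
  pe <- (33 * 32 + 7 * 8) / 40^2
  expect_equal(rep_k$cohen_kappa, (po - pe) / (1 - pe))
  # f1 recomputable from the confusion matrix
  cm <- rep_k$confusion_matrix
  prec1 <- cm["1", "1"] / sum(cm[, "1"]); rec1 <- cm["1", "1"] / sum(cm["1", ])
  expect_equal(unname(rep_k$per_class$class_1["f1"]),
               2 * prec1 * rec1 / (prec1 + rec1))

  expect_error(evaluate_classifier(NULL, y = integer(0), prob = numeric(0)), "empty")
})

test_that("rank AUC handles ties and degenerate classes", {
  expect_equal(rank_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(rank_auc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  expect_warning(a <- rank_auc(c(0.2, 0.4), c(1, 1)), "single class")
  expect_true(is.na(a))
})

test_that("a separable cohort is fitted to perfect training accuracy", {
  coh <- generate_cohort(separable_config(11))
  mats <- cohort_segments(coh)
  y <- attr(mats, "acr")
  std <- standardize_segments(mats)
  mod <- train_classifier(std$segments, y, config = training_config(seed = 4))
  p <- predict(mod, std$segments)
  expect_equal(mean((p >= 0.5) == (y == 1)), 1)
  expect_identical(names(p), names(mats))
  # the loss history is (weakly) decreasing over the long run
  h <- mod$history$loss
  expect_lt(h[length(h)], h[1])
})
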