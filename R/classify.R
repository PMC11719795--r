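#' Training configuration for the maneuver/grade classifiers
#'
#' Both classifiers are single-hidden-layer feed-forward networks with a
#' softmax output, fitted by `nnet` with weight decay. With 5--7 inputs and
#' at most 8 classes this is the smallest standard architecture adequate for
#' the problem. A fraction of the rows is held out for validation metrics;
#' standardization statistics come from the training split only.
#'
#' @param seed Integer seed governing the validation split and weight
#'   initialisation.
#' @param hidden Hidden-layer size.
#' @param decay L2 weight decay.
#' @param maxit Maximum optimiser iterations.
#' @param val_fraction Fraction of rows held out for validation metrics.
#' @return List of class `train_config`.
#' @export
train_config <- function(seed = 1, hidden = 12, decay = 1e-3, maxit = 500,
                         val_fraction = 0.2) {
  if (val_fraction < 0 || val_fraction >= 1) {
    stop_usage("val_fraction must be in [0, 1)")
  }
  structure(list(seed = as.integer(seed), hidden = as.integer(hidden),
                 decay = decay, maxit = as.integer(maxit),
                 val_fraction = val_fraction),
            class = "train_config")
}

model_levels <- function(kind) if (kind == "class") as.character(1:8) else as.character(0:3)
model_feature_names <- function(kind) {
  if (kind == "class") class_feature_names() else grade_feature_names()
}

# Shared fitting path for both classifier kinds. Rows are put into a canonical
# order before the seeded split so the fit is invariant to input row
# permutation.
fit_mlp <- function(X, y, kind, cfg, klass = NULL) {
  X <- as.matrix(X)
  feats <- model_feature_names(kind)
  if (is.null(colnames(X)) || !setequal(colnames(X), feats)) {
    stop_usage(sprintf("feature columns must be exactly {%s}",
                       paste(feats, collapse = ", ")))
  }
  X <- X[, feats, drop = FALSE]
  if (nrow(X) == 0L) stop_usage("empty training set")
  if (nrow(X) != length(y)) stop_usage("nrow(X) must equal length(y)")
  if (any(!is.finite(X))) stop_usage("features must be finite")
  levels <- model_levels(kind)
  y <- factor(as.character(y), levels = levels)
  if (anyNA(y)) stop_usage("labels outside the registered label set")
  if (length(unique(y)) < 2L) {
    stop_usage("training data must contain at least 2 distinct labels")
  }
  ord <- do.call(order, c(as.data.frame(X), list(as.integer(y))))
  X <- X[ord, , drop = FALSE]
  y <- y[ord]
  n <- nrow(X)
  n_val <- floor(cfg$val_fraction * n)
  fit <- with_seed(cfg$seed, {
    val_idx <- if (n_val > 0) sample.int(n, n_val) else integer()
    tr_idx <- setdiff(seq_len(n), val_idx)
    if (length(unique(y[tr_idx])) < 2L) {
      stop_usage("training split has fewer than 2 distinct labels")
    }
    center <- colMeans(X[tr_idx, , drop = FALSE])
    scale_ <- apply(X[tr_idx, , drop = FALSE], 2, stats::sd)
    scale_[scale_ == 0] <- 1  # constant feature carries no information
    Xs <- sweep(sweep(X, 2, center), 2, scale_, "/")
    targets <- nnet::class.ind(y)
    net <- nnet::nnet(Xs[tr_idx, , drop = FALSE],
                      targets[tr_idx, , drop = FALSE],
                      size = cfg$hidden, softmax = TRUE, decay = cfg$decay,
                      maxit = cfg$maxit, trace = FALSE, MaxNWts = 5000)
    list(net = net, center = center, scale = scale_, val_idx = val_idx)
  })
  model <- structure(list(kind = kind, klass = klass,
                          feature_names = feats, levels = levels,
                          hidden = cfg$hidden,
                          center = fit$center, scale = fit$scale,
                          wts = fit$net$wts, n_units = fit$net$n,
                          seed = cfg$seed,
                          validation = list(n_val = n_val, accuracy = NA_real_)),
                     class = "psm_model")
  if (n_val > 0) {
    pred <- predict_labels(model, X[fit$val_idx, , drop = FALSE])
    model$validation$accuracy <- mean(pred$label == y[fit$val_idx])
  }
  model
}

#' Fit the maneuver-class classifier
#'
#' Learns the mapping from the five class features to the eight
#' maneuver-execution classes. Deterministic given `(X, y, cfg$seed)` and
#' invariant to row permutation of the training set.
#'
#' @param X Numeric matrix or data frame whose columns are exactly
#'   [class_feature_names()].
#' @param y Class labels 1--8, one per row of `X`.
#' @param cfg A [train_config()].
#' @return A `psm_model` with held-out validation accuracy recorded in
#'   `$validation`.
#' @export
fit_class_model <- function(X, y, cfg = train_config()) {
  fit_mlp(X, y, "class", cfg)
}

#' Fit one per-class injury-grade classifier
#'
#' Grade models are fitted separately within each standard maneuver class
#' (2--7), mirroring per-class grade evaluation; the model records which
#' class it belongs to.
#'
#' @param X Numeric matrix or data frame whose columns are exactly
#'   [grade_feature_names()]; all rows must belong to maneuver class `klass`.
#' @param y Grade labels 0--3.
#' @param klass Maneuver class 2--7 this model is specific to.
#' @param cfg A [train_config()].
#' @return A `psm_model`.
#' @export
fit_grade_model <- function(X, y, klass, cfg = train_config()) {
  if (!klass %in% 2:7) stop_usage("grade models are defined for classes 2..7")
  fit_mlp(X, y, "grade", cfg, klass = as.integer(klass))
}

# Forward pass through the serialized weights: logistic hidden layer,
# softmax output, matching nnet's layout (per hidden unit: bias then input
# weights; per output unit: bias then hidden weights).
mlp_forward <- function(model, X) {
  X <- as.matrix(X)[, model$feature_names, drop = FALSE]
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  p <- length(model$feature_names)
  h <- model$n_units[2]
  k <- model$n_units[3]
  w1 <- matrix(model$wts[seq_len((p + 1) * h)], nrow = p + 1)
  w2 <- matrix(model$wts[-seq_len((p + 1) * h)], nrow = h + 1)
  a <- 1 / (1 + exp(-(cbind(1, Xs) %*% w1)))
  z <- cbind(1, a) %*% w2
  z <- z - apply(z, 1, max)
  ez <- exp(z)
  probs <- ez / rowSums(ez)
  colnames(probs) <- model$levels
  probs
}

check_feature_names <- function(model, x) {
  nm <- if (is.matrix(x) || is.data.frame(x)) colnames(x) else names(x)
  if (is.null(nm) || !all(model$feature_names %in% nm)) {
    stop_usage(sprintf("input must carry the model's features: %s",
                       paste(model$feature_names, collapse = ", ")))
  }
}

#' Predict labels and class probabilities for a feature matrix
#'
#' @param model A `psm_model`.
#' @param X Matrix or data frame carrying (at least) the model's feature
#'   columns; one row per test.
#' @return List with `label` (integer vector) and `probabilities` (matrix,
#'   rows summing to 1; ties broken toward the lowest label).
#' @export
predict_labels <- function(model, X) {
  stopifnot(inherits(model, "psm_model"))
  if (is.null(dim(X))) X <- t(as.matrix(X))
  check_feature_names(model, X)
  probs <- mlp_forward(model, as.matrix(as.data.frame(X,
                                                      check.names = FALSE)))
  idx <- apply(probs, 1, which.max)  # which.max: lowest index on ties
  list(label = as.integer(model$levels[idx]), probabilities = probs)
}

#' Predict the maneuver class of one test
#' @param model A class-kind `psm_model`.
#' @param x Named feature vector (or 1-row data frame) over
#'   [class_feature_names()].
#' @return List with `label` (1--8) and `probabilities` (length 8, sums to 1).
#' @export
predict_class <- function(model, x) {
  if (model$kind != "class") stop_usage("model is not a class model")
  out <- predict_labels(model, x)
  list(label = out$label[1], probabilities = out$probabilities[1, ])
}

#' Predict the injury grade of one test
#' @param model A grade-kind `psm_model`.
#' @param x Named feature vector (or 1-row data frame) over
#'   [grade_feature_names()].
#' @return List with `label` (0--3) and `probabilities` (length 4, sums to 1).
#' @export
predict_grade <- function(model, x) {
  if (model$kind != "grade") stop_usage("model is not a grade model")
  out <- predict_labels(model, x)
  list(label = out$label[1], probabilities = out$probabilities[1, ])
}

#' Which maneuver classes are gradable
#'
#' Classes 1 and 8 are the executions furthest from the standardized
#' maneuver; their injury-grade results are discarded. A test is gradable
#' iff its class label is in 2--7.
#'
#' @param labels Integer class labels 1--8.
#' @return Logical vector.
#' @export
gradable_mask <- function(labels) {
  if (!all(labels %in% 1:8)) stop_usage("labels must be 1..8")
  labels %in% 2:7
}

#' Serialize a fitted model to JSON
#' @param model A `psm_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "psm_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a model serialized by [write_model()]
#' @param path JSON file path.
#' @return A `psm_model`.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$center <- stats::setNames(as.numeric(obj$center), obj$feature_names)
  obj$scale <- stats::setNames(as.numeric(obj$scale), obj$feature_names)
  structure(obj, class = "psm_model")
}
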