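# Two-layer fine-grained classification: layer 1 separates species, layer 2
# separates diel periods within each species. Deep networks are out of
# scope here; the framework (routing, stratified split, metrics) is what
# matters, with pluggable lightweight classifiers on pooled second-order
# MFCC features.

#' Pool an MFCC matrix into a fixed-length feature vector
#'
#' Per row of the coefficient, delta and delta-delta matrices, computes
#' the mean and standard deviation across frames, giving a
#' `n_coeffs * 3 * 2` vector (78 under the 13-coefficient default) that is
#' comparable across recordings of different lengths.
#'
#' @param m An `mfcc_matrix` from [second_order_mfcc()] with at least one
#'   frame.
#' @return Named numeric vector with a `pooling_spec` attribute.
#' @export
pool_features <- function(m) {
  stopifnot(inherits(m, "mfcc_matrix"))
  if (ncol(m$coeffs) < 1) stopf("empty MFCC matrix")
  pool1 <- function(mat, tag) {
    mu <- rowMeans(mat)
    s <- apply(mat, 1, stats::sd)
    stats::setNames(c(mu, s),
                    c(sprintf("%s%d_mean", tag, seq_len(nrow(mat)) - 1L),
                      sprintf("%s%d_sd", tag, seq_len(nrow(mat)) - 1L)))
  }
  v <- c(pool1(m$coeffs, "c"), pool1(m$delta, "d"), pool1(m$delta2, "dd"))
  attr(v, "pooling_spec") <- "per-row mean and sd of coeffs/delta/delta2"
  v
}

#' Build a pooled-feature dataset from labeled recordings
#'
#' Runs [second_order_mfcc()] and [pool_features()] on every recording.
#'
#' @param recordings Tibble with list-column `signal` and columns
#'   `species`, `period` (e.g. from [gen_diel_dataset()]).
#' @param params A [frame_params()] object.
#' @param ... Passed to [second_order_mfcc()].
#' @return A tibble with list-column `features` plus `species`, `period`.
#' @export
build_feature_dataset <- function(recordings, params = frame_params(), ...) {
  recordings <- tibble::as_tibble(recordings)
  feats <- lapply(recordings$signal,
                  function(s) pool_features(second_order_mfcc(s, params, ...)))
  tibble::tibble(features = feats,
                 species = recordings$species,
                 period = recordings$period)
}

#' Stratified train/validation split
#'
#' Splits the dataset at `train_fraction` within every (species, period)
#' cell, so both classifier layers see every class in both parts.
#'
#' @param dataset A tibble with columns `species` and `period` (and
#'   typically `features`), at least 2 rows per cell.
#' @param train_fraction Fraction assigned to training (default 0.8, the
#'   usual 8:2 split).
#' @param seed Integer seed.
#' @return A list with disjoint tibbles `train` and `val` whose union is
#'   the input.
#' @export
split_train_val <- function(dataset, train_fraction = 0.8, seed = 1L) {
  dataset <- tibble::as_tibble(dataset)
  if (train_fraction <= 0 || train_fraction >= 1) {
    stopf("`train_fraction` must be strictly between 0 and 1")
  }
  cell <- paste(dataset$species, dataset$period, sep = "/")
  sizes <- table(cell)
  if (any(sizes < 2)) {
    stopf("class cell(s) with a single sample cannot be split: %s",
          paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  train_idx <- with_seed(seed, {
    unlist(lapply(split(seq_len(nrow(dataset)), cell), function(idx) {
      n_tr <- max(1L, min(length(idx) - 1L, round(train_fraction * length(idx))))
      sample(idx, n_tr)
    }), use.names = FALSE)
  })
  list(train = dataset[sort(train_idx), ],
       val = dataset[setdiff(seq_len(nrow(dataset)), train_idx), ])
}

# --- pluggable classifiers ---------------------------------------------

# Deterministic 1-nearest-neighbor: exact distance ties are broken toward
# the lexicographically lowest label.
fit_nn <- function(X, y) list(kind = "nn", X = X, y = as.character(y))

predict_nn <- function(model, X) {
  d2 <- outer(rowSums(X^2), rep(1, nrow(model$X))) +
    outer(rep(1, nrow(X)), rowSums(model$X^2)) - 2 * X %*% t(model$X)
  apply(d2, 1, function(row) {
    best <- which(row <= min(row) + 1e-12)
    sort(model$y[best])[1]
  })
}

fit_linear <- function(X, y) {
  df <- data.frame(.y = factor(y), X)
  list(kind = "linear",
       model = nnet::multinom(.y ~ ., data = df, trace = FALSE),
       levels = levels(df$.y))
}

predict_linear <- function(model, X) {
  if (length(model$levels) == 1) return(rep(model$levels, nrow(X)))
  as.character(stats::predict(model$model, newdata = data.frame(X)))
}

fit_any <- function(classifier, X, y) {
  if (is.list(classifier) && !is.null(classifier$fit)) {
    list(kind = "custom", model = classifier$fit(X, y), predict = classifier$predict)
  } else if (identical(classifier, "nn")) {
    fit_nn(X, y)
  } else if (identical(classifier, "linear")) {
    fit_linear(X, y)
  } else {
    stopf("`classifier` must be \"nn\", \"linear\", or list(fit=, predict=)")
  }
}

predict_any <- function(model, X) {
  switch(model$kind,
    nn = predict_nn(model, X),
    linear = predict_linear(model, X),
    custom = as.character(model$predict(model$model, X))
  )
}

features_matrix <- function(dataset) {
  do.call(rbind, dataset$features)
}

#' Train the two-layer species / diel-period model
#'
#' Layer 1 classifies species over the whole training set; layer 2 holds
#' one per-species classifier of diel period, fitted on that species'
#' recordings only. At prediction time a sample is routed through layer 1
#' and then through the layer-2 model of the predicted species.
#'
#' @param dataset A tibble with list-column `features` and columns
#'   `species`, `period`; every (species, period) cell needs at least 2
#'   samples.
#' @param classifier `"nn"` (deterministic 1-nearest-neighbor, default),
#'   `"linear"` (multinomial logistic), or a `list(fit = function(X, y),
#'   predict = function(model, X))` pair.
#' @return An object of class `two_layer_model`.
#' @export
train_two_layer <- function(dataset, classifier = "nn") {
  dataset <- tibble::as_tibble(dataset)
  cell <- table(paste(dataset$species, dataset$period, sep = "/"))
  expected <- as.vector(outer(unique(dataset$species), unique(dataset$period), paste, sep = "/"))
  missing <- setdiff(expected, names(cell))
  small <- names(cell)[cell < 2]
  if (length(missing) || length(small)) {
    stopf("every (species, period) cell needs >= 2 samples; offending cell(s): %s",
          paste(c(missing, small), collapse = ", "))
  }
  X <- features_matrix(dataset)
  layer1 <- fit_any(classifier, X, dataset$species)
  layer2 <- lapply(split(seq_len(nrow(dataset)), dataset$species), function(idx) {
    fit_any(classifier, X[idx, , drop = FALSE], dataset$period[idx])
  })
  structure(
    list(layer1 = layer1, layer2 = layer2,
         classifier_kind = if (is.list(classifier)) "custom" else classifier,
         n_features = ncol(X)),
    class = "two_layer_model"
  )
}

#' @export
print.two_layer_model <- function(x, ...) {
  cat(sprintf("<two_layer_model> %s classifier, %d species, %d features\n",
              x$classifier_kind, length(x$layer2), x$n_features))
  invisible(x)
}

#' Predict species and diel period with a two-layer model
#'
#' @param model A `two_layer_model`.
#' @param features A single feature vector, a feature matrix (rows =
#'   samples), or a dataset tibble with a `features` list-column.
#' @return A tibble with one row per sample: predicted `species`,
#'   `period`, and `layer2_model` (which species' period model was used —
#'   equal to `species`, recorded so misroutings are auditable).
#' @export
predict_two_layer <- function(model, features) {
  stopifnot(inherits(model, "two_layer_model"))
  X <- if (is.data.frame(features)) {
    features_matrix(features)
  } else if (is.matrix(features)) {
    features
  } else {
    matrix(features, nrow = 1)
  }
  if (ncol(X) != model$n_features) {
    stopf("feature length %d does not match the model's %d", ncol(X), model$n_features)
  }
  species <- predict_any(model$layer1, X)
  period <- character(length(species))
  for (sp in unique(species)) {
    idx <- which(species == sp)
    period[idx] <- predict_any(model$layer2[[sp]], X[idx, , drop = FALSE])
  }
  tibble::tibble(species = species, period = period, layer2_model = species)
}

#' Evaluate a two-layer model on a labeled dataset
#'
#' Layer-1 accuracy is the species hit rate. Layer-2 accuracy is scored
#' against the true period only (`mode = "period"`, default); with
#' `mode = "strict"` a sample counts as correct only when both the species
#' routing and the period are right.
#'
#' @param model A `two_layer_model`.
#' @param dataset Labeled tibble (as for [train_two_layer()]).
#' @param mode `"period"` or `"strict"`.
#' @return A one-row tibble: `layer1_accuracy`, `layer2_accuracy`, `mode`,
#'   `n`.
#' @export
evaluate_two_layer <- function(model, dataset, mode = c("period", "strict")) {
  mode <- match.arg(mode)
  pred <- predict_two_layer(model, dataset)
  l1 <- mean(pred$species == dataset$species)
  l2 <- if (mode == "period") {
    mean(pred$period == dataset$period)
  } else {
    mean(pred$period == dataset$period & pred$species == dataset$species)
  }
  tibble::tibble(layer1_accuracy = l1, layer2_accuracy = l2,
                 mode = mode, n = nrow(pred))
}
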