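#' FCN training configuration
#'
#' Hyperparameters of the fully connected classifier: three hidden layers of
#' 30 rectified-linear units, a single sigmoid output giving the probability
#' of the positive (wiry) class, binary cross-entropy loss and the Adam
#' optimizer.
#'
#' @param hidden Integer vector of hidden-layer sizes.
#' @param epochs Training epochs.
#' @param learning_rate Adam step size.
#' @param batch_size Minibatch size.
#' @param seed Seed controlling weight initialization and batch shuffling.
#' @return An `fcn_config` list.
#' @export
fcn_config <- function(hidden = c(30, 30, 30), epochs = 40,
                       learning_rate = 1e-3, batch_size = 32, seed = 1) {
  stopifnot(is.numeric(hidden), length(hidden) >= 1L, all(hidden >= 1))
  check_number(epochs, "epochs", lower = 0)
  check_number(learning_rate, "learning_rate", lower = 0)
  check_number(batch_size, "batch_size", lower = 0)
  structure(list(hidden = as.integer(hidden), epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "fcn_config")
}

feature_columns_of <- function(rows) {
  attr(rows, "feature_cols") %||%
    setdiff(names(rows)[vapply(rows, is.numeric, logical(1))],
            c("segment_index", "start_s", "n_beats_used", "heart_rate_bpm",
              "base_frequency"))
}

#' Train the fully connected classifier
#'
#' Fits the FCN on segment rows. Features are z-score standardized with
#' parameters estimated from the supplied (training) rows only; the fitted
#' scaler travels with the model so held-out data are transformed with the
#' training statistics, never their own.
#'
#' @param rows Tibble of training rows: a `label` factor (positive class =
#'   `"wiry"`, last level) plus numeric feature columns (e.g. from
#'   [build_feature_matrix()]).
#' @param config An [fcn_config()].
#' @return An `fcn_fit` object with [predict()][predict.fcn_fit()],
#'   [tidy()] and [glance()] methods.
#' @export
train_fcn <- function(rows, config = fcn_config()) {
  if (!"label" %in% names(rows)) {
    abort("`rows` must contain a `label` column.",
          class = "pulsefusion_config_error")
  }
  feature_cols <- feature_columns_of(rows)
  if (length(feature_cols) == 0L) {
    abort("No feature columns found.", class = "pulsefusion_config_error")
  }
  y <- as.numeric(rows$label == levels(factor(rows$label))[
    nlevels(factor(rows$label))])
  if (length(unique(y)) < 2L) {
    abort("Training rows contain a single class.",
          class = "pulsefusion_config_error")
  }
  X <- as.matrix(rows[, feature_cols])
  if (anyNA(X)) {
    abort("Training rows contain missing feature values.",
          class = "pulsefusion_config_error")
  }
  mu <- colMeans(X)
  sdev <- apply(X, 2, sd)
  sdev[sdev == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sdev, "/")

  sizes <- c(ncol(X), config$hidden, 1L)
  init <- with_seed(config$seed, {
    lapply(seq_len(length(sizes) - 1L), function(l) {
      list(W = matrix(rnorm(sizes[l] * sizes[l + 1L],
                            sd = sqrt(2 / sizes[l])),
                      nrow = sizes[l]),
           b = rep(0, sizes[l + 1L]))
    })
  })
  fit <- fcn_train_cpp(Xs, y,
                       lapply(init, `[[`, "W"),
                       lapply(init, function(z) matrix(z$b, nrow = 1)),
                       epochs = config$epochs,
                       batch_size = config$batch_size,
                       lr = config$learning_rate,
                       seed = config$seed)
  structure(list(weights = fit$weights, biases = fit$biases,
                 loss = as.numeric(fit$loss),
                 scaler = list(mean = mu, sd = sdev),
                 feature_cols = feature_cols,
                 positive_class = levels(factor(rows$label))[
                   nlevels(factor(rows$label))],
                 config = config, n_train = nrow(rows)),
            class = "fcn_fit")
}

#' Predict wiry-pulse probabilities
#'
#' @param object An `fcn_fit`.
#' @param newdata Tibble containing the model's feature columns.
#' @param ... Unused.
#' @return Numeric vector of probabilities of the positive class.
#' @export
predict.fcn_fit <- function(object, newdata, ...) {
  missing_cols <- setdiff(object$feature_cols, names(newdata))
  if (length(missing_cols)) {
    abort(sprintf("`newdata` lacks feature columns: %s.",
                  paste(missing_cols, collapse = ", ")),
          class = "pulsefusion_config_error")
  }
  X <- as.matrix(newdata[, object$feature_cols])
  Xs <- sweep(sweep(X, 2, object$scaler$mean), 2, object$scaler$sd, "/")
  as.numeric(fcn_predict_cpp(Xs, object$weights, object$biases))
}

#' @export
print.fcn_fit <- function(x, ...) {
  cat(sprintf("<fcn_fit> %d features -> %s -> 1 (sigmoid); %d rows, final loss %.4f\n",
              length(x$feature_cols),
              paste(x$config$hidden, collapse = "-"),
              x$n_train, tail(x$loss, 1)))
  invisible(x)
}

#' @rdname train_fcn
#' @param x An `fcn_fit`.
#' @param ... Unused.
#' @export
tidy.fcn_fit <- function(x, ...) {
  sizes <- c(length(x$feature_cols), x$config$hidden, 1L)
  tibble(layer = seq_len(length(sizes) - 1L),
         n_in = sizes[-length(sizes)],
         n_out = sizes[-1],
         n_parameters = sizes[-length(sizes)] * sizes[-1] + sizes[-1],
         activation = c(rep("relu", length(sizes) - 2L), "sigmoid"))
}

#' @rdname train_fcn
#' @export
glance.fcn_fit <- function(x, ...) {
  tibble(n_features = length(x$feature_cols), n_train = x$n_train,
         epochs = x$config$epochs, final_loss = tail(x$loss, 1))
}
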