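#' Architecture configuration for the window classifier
#'
#' The classifier is a small ResNet-flavoured CNN over 5 x 400 input
#' matrices: seven convolutional layers with squeeze-and-excitation (SE)
#' channel gates between them, two max-pooling layers, and two dense layers
#' ending in a sigmoid.  Layer 1 is a 2D 5 x 10 convolution with 'same'
#' padding (it keeps the five assay rows, so its Grad-CAM map is natively
#' 5 x 400); layer 2 is a 2D 5 x 10 convolution with the height padding
#' removed, collapsing the assay axis so all later layers are 1D over the
#' genomic axis; layers 3-7 are 1D 1 x 4 convolutions with 'same' padding.
#' A 1 x 4 max-pool sits between the two 2D convolutions and another after
#' layer 7.
#'
#' @param n_filters convolution filters per layer (default 32).
#' @param dense_units width of the first dense layer (default 64).
#' @param dropout dropout rate after the first dense layer (default 0.3).
#' @param se_reduction SE bottleneck reduction ratio (default 4).
#' @param width input bins per window (default 400 = 4 kb / 10 bp).
#' @return a list of class `"model_config"`.
#' @export
model_config <- function(n_filters = 32L, dense_units = 64L, dropout = 0.3,
                         se_reduction = 4L, width = 400L) {
  if (width %/% 16L < 1L) stop("width must be >= 16 bins")
  structure(list(n_filters = as.integer(n_filters),
                 dense_units = as.integer(dense_units),
                 dropout = dropout,
                 se_reduction = as.integer(se_reduction),
                 width = as.integer(width)),
            class = "model_config")
}

#' Training configuration
#'
#' Defaults follow the reference training setup: Adam at learning rate
#' 5e-5, up to 100 epochs with early stopping on validation loss, an 80-20
#' stratified train-validation split, and inverse-frequency class weights
#' to counter the 1:10 positive:negative imbalance.
#'
#' @param learning_rate Adam learning rate (default 5e-5).
#' @param epochs maximum training epochs (default 100).
#' @param batch_size minibatch size (default 64).
#' @param val_fraction held-out validation fraction (default 0.2).
#' @param patience early-stopping patience in epochs (default 10); the best
#'   weights are restored.
#' @param class_weights `"balanced"` for `w_c = N / (2 * N_c)`, or a named
#'   numeric vector with elements `"0"` and `"1"`.
#' @param seed integer seed controlling the split, shuffling and dropout.
#' @return a list of class `"train_config"`.
#' @export
train_config <- function(learning_rate = 5e-5, epochs = 100L, batch_size = 64L,
                         val_fraction = 0.2, patience = 10L,
                         class_weights = "balanced", seed = 1L) {
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  if (val_fraction <= 0 || val_fraction >= 1)
    stop("val_fraction must be in (0, 1)")
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 val_fraction = val_fraction, patience = as.integer(patience),
                 class_weights = class_weights, seed = as.integer(seed)),
            class = "train_config")
}

he_init <- function(nr, nc, fan_in) matrix(rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
xavier_init <- function(nr, nc, fan_in) matrix(rnorm(nr * nc, sd = sqrt(1 / fan_in)), nr, nc)
zeros_mat <- function(nr, nc = 1L) matrix(0, nr, nc)

#' Build an untrained window classifier
#'
#' Initialises all parameters (He initialisation for ReLU layers, Xavier
#' for the SE excitation and output layers, zero biases) under the given
#' seed.
#'
#' @param config a [model_config()].
#' @param panel the [assay_panel()] the model expects.
#' @param seed integer seed for parameter initialisation.
#' @return object of class `"enhancer_cnn"`.
#' @export
build_model <- function(config = model_config(), panel = assay_panel(),
                        seed = 1L) {
  nf <- config$n_filters
  nfr <- max(1L, nf %/% config$se_reduction)
  W1p <- config$width %/% 4L
  W2p <- W1p %/% 4L
  flat <- nf * W2p
  du <- config$dense_units
  params <- withr::with_seed(seed, {
    p <- list(conv1_W = he_init(50L, nf, 50), conv1_b = zeros_mat(nf))
    for (l in 1:6) {
      p[[sprintf("se%d_Wr", l)]] <- he_init(nfr, nf, nf)
      p[[sprintf("se%d_br", l)]] <- zeros_mat(nfr)
      p[[sprintf("se%d_We", l)]] <- xavier_init(nf, nfr, nfr)
      p[[sprintf("se%d_be", l)]] <- zeros_mat(nf)
    }
    p$conv2_W <- he_init(50L * nf, nf, 50 * nf)
    p$conv2_b <- zeros_mat(nf)
    for (l in 3:7) {
      p[[sprintf("conv%d_W", l)]] <- he_init(4L * nf, nf, 4 * nf)
      p[[sprintf("conv%d_b", l)]] <- zeros_mat(nf)
    }
    p$dense1_W <- he_init(flat, du, flat)
    p$dense1_b <- zeros_mat(du)
    p$dense2_w <- xavier_init(du, 1L, du)
    p$dense2_b <- zeros_mat(1L)
    p
  })
  structure(list(params = params, config = config, panel = panel,
                 seed = as.integer(seed), trained = FALSE, history = NULL,
                 fit = NULL),
            class = "enhancer_cnn")
}

#' @export
print.enhancer_cnn <- function(x, ...) {
  np <- sum(vapply(x$params, length, 0L))
  cat("<enhancer_cnn>", x$config$n_filters, "filters/layer,",
      format(np, big.mark = ","), "parameters,",
      if (x$trained) "trained" else "untrained", "\n")
  invisible(x)
}

#' Number of trainable parameters
#' @param model an `enhancer_cnn`.
#' @return integer parameter count.
#' @export
n_parameters <- function(model) sum(vapply(model$params, length, 0L))

# coerce accepted input forms to the n x (5*width) matrix the backend wants
as_input_matrix <- function(newdata) {
  if (inherits(newdata, "labeled_dataset")) return(dataset_matrix(newdata))
  if (is.matrix(newdata) && nrow(newdata) == 5L)
    return(window_matrix_row(newdata))
  if (is.array(newdata) && length(dim(newdata)) == 3L) {
    d <- dim(newdata)
    return(t(matrix(newdata, nrow = d[1L] * d[2L], ncol = d[3L])))
  }
  if (is.matrix(newdata)) return(newdata)  # already flattened, one row/window
  stop("cannot interpret 'newdata' as window matrices")
}

#' Predict enhancer probabilities
#'
#' @param object a (trained) `enhancer_cnn`.
#' @param newdata a single 5 x 400 window matrix, a `5 x 400 x n` array, or
#'   a `labeled_dataset`.
#' @param type `"prob"` for sigmoid probabilities (default) or `"logit"`.
#' @param ... unused.
#' @return numeric vector, one value per window; probabilities lie in (0, 1).
#' @export
predict.enhancer_cnn <- function(object, newdata, type = c("prob", "logit"), ...) {
  type <- match.arg(type)
  X <- as_input_matrix(newdata)
  if (ncol(X) != 5L * object$config$width)
    stop("input width does not match the model (expected 5 x ",
         object$config$width, ")")
  logit <- as.numeric(nn_forward(object$params, X))
  if (type == "logit") logit else 1 / (1 + exp(-logit))
}

# stratified train/validation split: within each class the indices are
# permuted and the first val_fraction share goes to validation
stratified_split <- function(label, val_fraction, seed) {
  withr::with_seed(seed, {
    val <- integer(0)
    for (cl in unique(label)) {
      i <- which(label == cl)
      n_val <- max(1L, round(val_fraction * length(i)))
      if (n_val >= length(i)) n_val <- length(i) - 1L
      val <- c(val, sample(i)[seq_len(max(n_val, 0L))])
    }
    val
  })
}

class_weight_vector <- function(label, class_weights) {
  if (identical(class_weights, "balanced")) {
    n <- length(label)
    w1 <- n / (2 * sum(label == 1L))
    w0 <- n / (2 * sum(label == 0L))
    ifelse(label == 1L, w1, w0)
  } else {
    unname(class_weights[as.character(label)])
  }
}

#' Train the window classifier
#'
#' Splits the dataset 80-20 (stratified by label, seeded), weights the
#' binary cross-entropy loss by inverse class frequency, and optimises with
#' Adam.  Training stops early when validation loss has not improved for
#' `patience` epochs; the best-epoch weights are restored.  Runs are
#' bit-reproducible for a fixed seed on a single thread.
#'
#' @param model an `enhancer_cnn` from [build_model()].
#' @param dataset a `labeled_dataset` containing both classes.
#' @param config a [train_config()].
#' @return the trained model; `$history` holds per-epoch train/validation
#'   loss, `$fit` the split indices and resolved class weights.
#' @export
train_model <- function(model, dataset, config = train_config()) {
  y <- dataset$label
  if (length(unique(y)) < 2L)
    stop("dataset must contain both positive and negative windows")
  if (config$epochs == 0L) {
    model$history <- data.frame(epoch = integer(), train_loss = numeric(),
                                val_loss = numeric())
    model$fit <- list(config = config, val_idx = integer())
    return(model)
  }
  X <- dataset_matrix(dataset)
  w <- class_weight_vector(y, config$class_weights)
  val <- stratified_split(y, config$val_fraction, config$seed)
  tr <- setdiff(seq_along(y), val)
  res <- nn_train(model$params,
                  X[tr, , drop = FALSE], y[tr], w[tr],
                  X[val, , drop = FALSE], y[val], w[val],
                  config$learning_rate, config$epochs, config$batch_size,
                  config$patience, config$seed, model$config$dropout)
  model$params <- res$params
  model$trained <- TRUE
  model$history <- data.frame(epoch = seq_along(res$train_loss),
                              train_loss = res$train_loss,
                              val_loss = res$val_loss)
  model$fit <- list(config = config, train_idx = tr, val_idx = val,
                    class_weights = c(`0` = w[y == 0L][1L], `1` = w[y == 1L][1L]),
                    best_epoch = res$best_epoch, epochs_run = res$epochs_run)
  model
}

MODEL_FORMAT <- "encore_cnn/1"

#' Save / load a classifier
#'
#' The archive stores the parameters, architecture, assay panel order,
#' training seed and history; a reloaded model predicts bitwise-identically.
#'
#' @param model an `enhancer_cnn`.
#' @param path file path.
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  obj <- list(format = MODEL_FORMAT, params = model$params,
              config = unclass(model$config), panel = unclass(model$panel),
              accessibility = attr(model$panel, "accessibility"),
              seed = model$seed, trained = model$trained,
              history = model$history, fit = model$fit)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e)
    stop("cannot read model file (corrupt or wrong format): ", conditionMessage(e)))
  if (!is.list(obj) || !identical(obj$format, MODEL_FORMAT))
    stop("not a saved classifier (missing format tag)")
  structure(list(params = obj$params,
                 config = structure(obj$config, class = "model_config"),
                 panel = assay_panel(obj$panel, obj$accessibility),
                 seed = obj$seed, trained = obj$trained,
                 history = obj$history, fit = obj$fit),
            class = "enhancer_cnn")
}
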