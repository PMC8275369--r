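#' Grad-CAM importance maps for positive predictions
#'
#' Grad-CAM weights each convolutional filter's activation map by the
#' global-average-pooled gradient of the positive-class score with respect
#' to that map, sums the weighted maps, rectifies, and (for the 1D layers)
#' interpolates back to the 400-bin input resolution.  The map from the
#' last 1D convolutional layer is the *position-wise* score (importance per
#' 10 bp bin); the map from the first convolutional layer, which still
#' carries the five assay rows, is the *feature-wise* score (importance per
#' assay x bin).
#'
#' @name gradcam
NULL

# forward + backward pass caching activations and d(score)/d(activation)
# for all 7 conv layers
model_saliency <- function(model, m, post_sigmoid = FALSE) {
  x <- window_matrix_row(m)
  if (ncol(x) != 5L * model$config$width)
    stop("window matrix does not match the model input width")
  nn_gradcam(model$params, x[1L, ], post_sigmoid)
}

check_layer <- function(layer) {
  if (!(is.numeric(layer) && length(layer) == 1L && layer %in% 1:7))
    stop("layer must be a convolutional layer id in 1..7")
  as.integer(layer)
}

#' Per-filter Grad-CAM channel weights
#'
#' Computes `a_k`, the mean over all spatial positions of the gradient of
#' the positive-class score with respect to filter `k`'s activation map at
#' the given convolutional layer.  By default the score is the pre-sigmoid
#' logit (standard Grad-CAM practice); set `post_sigmoid = TRUE` to
#' differentiate the sigmoid probability instead.
#'
#' @param model a trained `enhancer_cnn`.
#' @param m a 5 x 400 window matrix.
#' @param layer convolutional layer id (1-7).
#' @param post_sigmoid differentiate the probability rather than the logit.
#' @return numeric vector, one weight per filter.
#' @export
channel_importance <- function(model, m, layer, post_sigmoid = FALSE) {
  layer <- check_layer(layer)
  sal <- model_saliency(model, m, post_sigmoid)
  colMeans(sal$gradients[[layer]])
}

# interpolate a pooled-resolution score vector back to input bins; pooled
# cell p (0-based) covers bins 4p..4p+3, so its center sits at 4p + 1.5
interp_to_bins <- function(v, width) {
  p <- seq_along(v) - 1
  approx(x = 4 * p + 1.5, y = v, xout = seq_len(width) - 1, rule = 2)$y
}

#' Grad-CAM map for one convolutional layer
#'
#' Element-wise weighted sum of the layer's activation maps with the
#' [channel_importance()] weights, rectified (ReLU), then brought to input
#' resolution: layer 1 yields a 5 x 400 matrix directly, layers 2-7 yield a
#' length-400 vector by linear interpolation from the pooled grid.
#'
#' @inheritParams channel_importance
#' @return list of class `"gradcam_map"` with elements `values` (matrix or
#'   vector, all entries >= 0), `kind` (`"feature-wise"` or
#'   `"position-wise"`) and `layer`.
#' @export
gradcam_map <- function(model, m, layer, post_sigmoid = FALSE) {
  layer <- check_layer(layer)
  sal <- model_saliency(model, m, post_sigmoid)
  A <- sal$activations[[layer]]
  a <- colMeans(sal$gradients[[layer]])
  v <- pmax(as.numeric(A %*% a), 0)
  width <- model$config$width
  if (layer == 1L) {
    values <- matrix(v, ncol = width, byrow = TRUE)
    rownames(values) <- unclass(model$panel)
    kind <- "feature-wise"
  } else {
    values <- interp_to_bins(v, width)
    kind <- "position-wise"
  }
  structure(list(values = values, kind = kind, layer = layer),
            class = "gradcam_map")
}

#' @export
print.gradcam_map <- function(x, ...) {
  cat("<gradcam_map>", x$kind, "from conv layer", x$layer, "|",
    if (is.matrix(x$values)) paste(dim(x$values), collapse = " x ")
    else length(x$values), "scores\n")
  invisible(x)
}

#' Position-wise importance scores
#'
#' Grad-CAM on the last 1D convolutional layer (layer 7), interpolated to
#' the 400 genomic bins; score `b` describes 10 bp bin `b` of the window.
#'
#' @inheritParams channel_importance
#' @return numeric vector of length 400, all entries >= 0.
#' @export
positionwise_scores <- function(model, m, post_sigmoid = FALSE) {
  gradcam_map(model, m, 7L, post_sigmoid)$values
}

#' Feature-wise importance scores
#'
#' Grad-CAM on the first convolutional layer, whose activations retain the
#' five assay rows; row `r` is interpretable as the importance of assay `r`
#' along the window.
#'
#' @inheritParams channel_importance
#' @return 5 x 400 matrix with assay rownames, all entries >= 0.
#' @export
featurewise_scores <- function(model, m, post_sigmoid = FALSE) {
  gradcam_map(model, m, 1L, post_sigmoid)$values
}

#' Mean feature-wise profile over a set of windows
#'
#' Averages the feature-wise Grad-CAM map across windows (e.g. all positive
#' training samples) to show which assays and positions the classifier
#' relies on.
#'
#' @param model a trained `enhancer_cnn`.
#' @param windows a `labeled_dataset` or `5 x 400 x n` array.
#' @return 5 x 400 matrix of mean scores.
#' @export
mean_featurewise_profile <- function(model, windows) {
  x <- if (inherits(windows, "labeled_dataset")) windows$x else windows
  n <- dim(x)[3L]
  acc <- matrix(0, dim(x)[1L], dim(x)[2L])
  for (i in seq_len(n)) acc <- acc + featurewise_scores(model, x[, , i])
  acc / n
}
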