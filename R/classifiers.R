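# Base classifiers under a uniform probability contract.  The extreme
# learning machine is implemented in full (random input layer, hidden
# matrix H, minimum-norm least-squares output weights via the
# Moore-Penrose pseudoinverse); SVM and random forest delegate to e1071
# and randomForest.

elm_activations <- list(
  sigmoid = function(z) 1 / (1 + exp(-z)),
  tanh = tanh,
  relu = function(z) pmax(z, 0))

#' Fit an extreme learning machine
#'
#' Single-hidden-layer feedforward network whose input weights `W` and
#' biases `b` are drawn uniformly from [-1, 1] and never trained.  The
#' hidden matrix is `H = g(X W + b)` and the output weights solve
#' `H beta = T` in the minimum-norm least-squares sense,
#' `beta = pinv(H) T`.  With `L >= n` and a full-rank `H` the network
#' interpolates the training targets exactly.
#'
#' @param x n x d numeric matrix of training samples.
#' @param y Class labels (length n) or an n x m one-hot target matrix.
#' @param L Number of hidden nodes.
#' @param activation `"sigmoid"`, `"tanh"` or `"relu"`.
#' @param seed Integer seed for the random input layer.
#' @return An object of class `elm`.
#' @export
#' @examples
#' x <- matrix(rnorm(40), 20)
#' y <- rep(c("normal", "abnormal"), each = 10)
#' fit <- elm_fit(x, y, L = 25, seed = 1)
elm_fit <- function(x, y, L = 100L, activation = "sigmoid", seed = 1L) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 training samples", call. = FALSE)
  if (ncol(x) < 1L) stop("x must have at least one column", call. = FALSE)
  if (L < 1L) stop("L must be >= 1", call. = FALSE)
  if (is.matrix(y)) {
    T <- y
    classes <- colnames(T)
    if (is.null(classes)) classes <- paste0("class", seq_len(ncol(T)))
  } else {
    f <- as_class_factor(y)
    classes <- levels(f)
    T <- matrix(0, nrow(x), length(classes),
                dimnames = list(NULL, classes))
    T[cbind(seq_len(nrow(x)), as.integer(f))] <- 1
  }
  g <- elm_activations[[match.arg(activation, names(elm_activations))]]
  d <- ncol(x)
  wb <- with_seed(seed, stats::runif(d * L + L, -1, 1))
  W <- matrix(wb[seq_len(d * L)], d, L)
  b <- wb[d * L + seq_len(L)]
  H <- g(x %*% W + matrix(b, nrow(x), L, byrow = TRUE))
  beta <- MASS::ginv(H) %*% T
  structure(list(W = W, b = b, beta = beta, activation = activation,
                 L = as.integer(L), d = d, classes = classes, seed = seed,
                 train_residual = sqrt(sum((H %*% beta - T)^2))),
            class = "elm")
}

#' @export
print.elm <- function(x, ...) {
  cat(sprintf("extreme learning machine: %d hidden nodes (%s), d = %d\n",
              x$L, x$activation, x$d))
  cat(sprintf("  training residual ||H beta - T|| = %.3g\n",
              x$train_residual))
  invisible(x)
}

#' Predict from an extreme learning machine
#'
#' @param object An `elm` fit.
#' @param newdata n x d matrix with the training column count.
#' @param type `"prob"` (softmax of the raw outputs; rows sum to 1),
#'   `"raw"`, or `"class"`.
#' @param ... Unused.
#' @return Matrix of probabilities or raw outputs, or a class vector.
#' @export
predict.elm <- function(object, newdata, type = c("prob", "raw", "class"),
                        ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$d) {
    stop(sprintf("newdata has %d columns; model expects %d",
                 ncol(newdata), object$d), call. = FALSE)
  }
  g <- elm_activations[[object$activation]]
  H <- g(newdata %*% object$W +
           matrix(object$b, nrow(newdata), object$L, byrow = TRUE))
  raw <- H %*% object$beta
  colnames(raw) <- object$classes
  if (type == "raw") return(raw)
  p <- exp(raw - apply(raw, 1, max))
  p <- p / rowSums(p)
  if (type == "prob") return(p)
  object$classes[max.col(p, ties.method = "first")]
}

#' Train a base classifier under the uniform probability contract
#'
#' @param name `"elm"`, `"svm"` (linear kernel, probability model) or
#'   `"rf"` (class probability = fraction of trees voting the class).
#' @param x n x d training matrix.
#' @param y Class labels.
#' @param params Named list of backend parameters: `L`, `activation` (elm);
#'   `cost`, `kernel` (svm); `ntree` (rf).
#' @param seed Integer seed (controls the ELM input layer, the SVM
#'   probability calibration folds and the forest bootstrap).
#' @return An object of class `patch_classifier`.
#' @export
train_classifier <- function(name = c("elm", "svm", "rf"), x, y,
                             params = list(), seed = 1L) {
  name <- match.arg(name)
  x <- as.matrix(x)
  y <- as_class_factor(y)
  fit <- switch(
    name,
    elm = elm_fit(x, y, L = params$L %||% 100L,
                  activation = params$activation %||% "sigmoid", seed = seed),
    svm = with_seed(seed, e1071::svm(
      x, y, kernel = params$kernel %||% "linear", cost = params$cost %||% 1,
      probability = TRUE, scale = FALSE)),
    rf = with_seed(seed, randomForest::randomForest(
      x, y, ntree = params$ntree %||% 100L)))
  structure(list(name = name, fit = fit, classes = .class_levels, seed = seed),
            class = "patch_classifier")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Class probabilities from a trained classifier
#'
#' @param object A `patch_classifier`.
#' @param x n x d matrix of samples.
#' @return n x 2 matrix with columns `normal`, `abnormal`; rows sum to 1.
#' @export
predict_proba <- function(object, x) {
  stopifnot(inherits(object, "patch_classifier"))
  x <- as.matrix(x)
  p <- switch(
    object$name,
    elm = predict(object$fit, x, type = "prob"),
    svm = {
      pr <- predict(object$fit, x, probability = TRUE)
      attr(pr, "probabilities")
    },
    rf = predict(object$fit, x, type = "prob"))
  p <- p[, .class_levels, drop = FALSE]
  rownames(p) <- rownames(x)
  p
}

#' Initial predictions in the adjustable form
#'
#' The argmax label plus the probability assigned to that label
#' (`p_initial >= 0.5` by construction for two classes).
#'
#' @param object A `patch_classifier`.
#' @param x n x d matrix of samples.
#' @param ids Optional sample ids.
#' @return Data frame with `id`, `initial_label`, `p_initial`,
#'   `p_abnormal`.
#' @export
initial_predictions <- function(object, x, ids = NULL) {
  p <- predict_proba(object, x)
  lab <- .class_levels[max.col(p, ties.method = "first")]
  if (is.null(ids)) {
    ids <- rownames(x) %||% sprintf("s%04d", seq_len(nrow(p)))
  }
  data.frame(id = ids,
             initial_label = factor(lab, levels = .class_levels),
             p_initial = p[cbind(seq_len(nrow(p)),
                                 match(lab, .class_levels))],
             p_abnormal = p[, "abnormal"],
             row.names = NULL)
}
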