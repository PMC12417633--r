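# Trainable readout heads over reservoir states. The linear head is a
# multinomial softmax with L2 penalty, fit by deterministic quasi-Newton
# optimisation of the (convex) penalised cross-entropy; the CNN head lives
# in cnn.R. Both share the feature standardisation, prediction, CAM and
# conductance-quantisation machinery here.

#' Bundle reservoir states with class labels
#'
#' @param states list of `fibrc_state_vector`s (or a numeric matrix, one row
#'   per state).
#' @param labels character or factor class labels, one per state.
#' @param label_mode one of "stage3", "snore2", "joint6" (or "custom").
#' @return an object of class `fibrc_labeled_states` with the design matrix
#'   `X` (rows = states), `y` (factor) and the state grid `layout`.
#' @export
labeled_states <- function(states, labels, label_mode = "custom") {
  if (is.list(states)) {
    layout <- attr(states[[1]], "layout")
    X <- do.call(rbind, lapply(states, function(s) as.numeric(s)))
  } else {
    X <- as.matrix(states)
    layout <- attr(states, "layout") %||% c(1L, ncol(X))
  }
  if (nrow(X) != length(labels)) stop_input("states and labels lengths differ")
  y <- factor(labels)
  n_class <- switch(label_mode, stage3 = 3L, snore2 = 2L, joint6 = 6L, nlevels(y))
  if (nlevels(y) > n_class) stop_input("more label levels than the mode allows")
  structure(list(X = X, y = y, label_mode = label_mode, layout = layout),
            class = "fibrc_labeled_states")
}

#' @export
print.fibrc_labeled_states <- function(x, ...) {
  cat(sprintf("<labeled states: %d x %d, %d classes (%s)>\n",
              nrow(x$X), ncol(x$X), nlevels(x$y), x$label_mode))
  invisible(x)
}

#' Stratified train/validation split
#'
#' @param data a `fibrc_labeled_states`.
#' @param p training fraction (default 0.8).
#' @param seed integer seed.
#' @return list with `train` and `val` `fibrc_labeled_states`.
#' @export
stratified_split <- function(data, p = 0.8, seed = 1L) {
  idx <- with_seed(seed, {
    unlist(lapply(levels(data$y), function(cl) {
      i <- which(data$y == cl)
      sample(i, max(1L, round(p * length(i))))
    }))
  })
  subset_ls <- function(i) {
    out <- data
    out$X <- data$X[i, , drop = FALSE]
    out$y <- droplevels(data$y[i])
    out$y <- factor(out$y, levels = levels(data$y))
    out
  }
  list(train = subset_ls(sort(idx)), val = subset_ls(setdiff(seq_len(nrow(data$X)), idx)))
}

.standardize_fit <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  list(center = ctr, scale = scl)
}
.standardize_apply <- function(X, sc) sweep(sweep(X, 2, sc$center), 2, sc$scale, "/")

.softmax <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# penalised multinomial loss and gradient; theta = c(W (p*C), b (C))
.lin_obj <- function(theta, X, Y, l2) {
  n <- nrow(X); p <- ncol(X); C <- ncol(Y)
  W <- matrix(theta[1:(p * C)], p, C)
  b <- theta[p * C + 1:C]
  P <- .softmax(sweep(X %*% W, 2, -b))
  loss <- -sum(Y * log(pmax(P, 1e-300))) / n + l2 / 2 * sum(W^2)
  D <- (P - Y) / n
  grad <- c(as.numeric(crossprod(X, D) + l2 * W), colSums(D))
  list(value = loss, gradient = grad)
}

#' Train the linear (softmax) readout
#'
#' Multinomial logistic regression with an L2 penalty on the weights (not
#' the biases), fit by L-BFGS from a zero start -- deterministic, and convex
#' so the optimum is unique. Features are standardised internally; the
#' scaler is stored in the model.
#'
#' @param data a `fibrc_labeled_states` with at least two classes present.
#' @param l2 L2 penalty strength (default 1e-3).
#' @param maxit optimiser iteration cap.
#' @return an object of class `fibrc_readout` (`kind = "linear"`) with
#'   weights `W` (features x classes), biases `b`, the training accuracy
#'   `train_accuracy`, and the converged gradient norm `grad_norm`.
#' @export
train_linear <- function(data, l2 = 1e-3, maxit = 500) {
  if (!inherits(data, "fibrc_labeled_states")) stop_input("data must come from labeled_states()")
  present <- levels(droplevels(data$y))
  if (length(present) < 2) stop_input("need at least two classes present")
  sc <- .standardize_fit(data$X)
  X <- .standardize_apply(data$X, sc)
  y <- droplevels(data$y)
  C <- nlevels(y); p <- ncol(X)
  Y <- diag(C)[as.integer(y), , drop = FALSE]
  fn <- function(th) .lin_obj(th, X, Y, l2)$value
  gr <- function(th) .lin_obj(th, X, Y, l2)$gradient
  opt <- stats::optim(rep(0, p * C + C), fn, gr, method = "L-BFGS-B",
                      control = list(maxit = maxit, factr = 10))
  W <- matrix(opt$par[1:(p * C)], p, C)
  b <- opt$par[p * C + 1:C]
  model <- structure(list(kind = "linear", W = W, b = b,
                          classes = levels(y), scaler = sc, layout = data$layout,
                          l2 = l2, grad_norm = sqrt(sum(gr(opt$par)^2))),
                     class = "fibrc_readout")
  model$train_accuracy <- mean(predict(model, data)$labels == as.character(data$y))
  model
}

#' @export
print.fibrc_readout <- function(x, ...) {
  np <- if (x$kind == "linear") length(x$W) + length(x$b) else x$n_params
  cat(sprintf("<%s readout: %d classes (%s), %d parameters%s>\n", x$kind,
              length(x$classes), paste(x$classes, collapse = "/"), np,
              if (!is.null(x$train_accuracy)) sprintf(", train acc %.3f", x$train_accuracy) else ""))
  invisible(x)
}

# coerce predict() input to a design matrix
.as_design <- function(states, model) {
  X <- if (inherits(states, "fibrc_labeled_states")) states$X
  else if (is.list(states)) do.call(rbind, lapply(states, as.numeric))
  else if (is.matrix(states)) states
  else matrix(as.numeric(states), nrow = 1)
  if (ncol(X) != length(model$scaler$center)) stop_input("state dimension does not match the model")
  X
}

#' Predict classes and per-class scores from a trained readout
#'
#' @param object a `fibrc_readout` (linear or cnn) or `fibrc_quantized_readout`.
#' @param states a `fibrc_labeled_states`, list of state vectors, matrix, or
#'   single state vector.
#' @param ... unused.
#' @return list with `labels` (character) and `scores` (n x classes softmax
#'   probabilities, rows summing to 1).
#' @export
predict.fibrc_readout <- function(object, states, ...) {
  X <- .as_design(states, object)
  Xs <- .standardize_apply(X, object$scaler)
  P <- if (object$kind == "linear") {
    .softmax(sweep(Xs %*% object$W, 2, -object$b))
  } else {
    .cnn_forward(object, Xs)$probs
  }
  colnames(P) <- object$classes
  list(labels = object$classes[max.col(P, ties.method = "first")], scores = P)
}

#' @export
predict.fibrc_quantized_readout <- function(object, states, ...) {
  predict.fibrc_readout(object$model, states, ...)
}

#' Class activation map of a readout for one state
#'
#' For the linear head the CAM of class c is the class-c weight vector
#' reshaped to the reservoir grid, multiplied elementwise by the
#' (standardised) state grid, so that the map plus the class bias sums
#' exactly to the class logit. For the CNN head it is the standard
#' global-average-pooling CAM: the class-weighted sum of the final
#' convolutional maps, bilinearly upsampled to the grid.
#'
#' @param model a trained `fibrc_readout`.
#' @param state one state vector (or single-row matrix).
#' @param class class name or index (default: the predicted class).
#' @return numeric `n_rows` x `n_frames` matrix.
#' @export
cam <- function(model, state, class = NULL) {
  X <- .as_design(state, model)[1, , drop = FALSE]
  pr <- predict(model, X)
  ci <- if (is.null(class)) which.max(pr$scores[1, ])
  else if (is.character(class)) match(class, model$classes)
  else as.integer(class)
  if (is.na(ci)) stop_input("unknown class")
  ly <- model$layout
  if (model$kind == "linear") {
    # fold the feature scaler into the weights so the CAM acts on the raw
    # state: logit_c = sum(CAM_c) + effective bias_c
    we <- model$W[, ci] / model$scaler$scale
    be <- model$b[ci] - sum(model$W[, ci] * model$scaler$center / model$scaler$scale)
    out <- matrix(we * X[1, ], ly[1], ly[2], byrow = TRUE)
    attr(out, "bias") <- be
    out
  } else {
    xs <- .standardize_apply(X, model$scaler)
    fw <- .cnn_forward(model, xs, keep_maps = TRUE)
    maps <- fw$final_maps[[1]]                      # H' x W' x C2
    wts <- model$params$Wd[, ci]
    cam_small <- Reduce(`+`, lapply(seq_along(wts), function(ch) wts[ch] * maps[, , ch]))
    .bilinear_upsample(cam_small, ly[1], ly[2])
  }
}

.bilinear_upsample <- function(m, H, W) {
  h <- nrow(m); w <- ncol(m)
  if (h == H && w == W) return(m)
  ri <- if (h == 1) rep(1, H) else seq(1, h, length.out = H)
  ci <- if (w == 1) rep(1, W) else seq(1, w, length.out = W)
  r0 <- pmin(floor(ri), h - 1 + (h == 1)); r1 <- pmin(r0 + 1, h); fr <- ri - r0
  c0 <- pmin(floor(ci), w - 1 + (w == 1)); c1 <- pmin(c0 + 1, w); fc <- ci - c0
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    out[i, j] <- (1 - fr[i]) * (1 - fc[j]) * m[r0[i], c0[j]] +
      fr[i] * (1 - fc[j]) * m[r1[i], c0[j]] +
      (1 - fr[i]) * fc[j] * m[r0[i], c1[j]] +
      fr[i] * fc[j] * m[r1[i], c1[j]]
  }
  out
}

# symmetric uniform quantiser: magnitudes onto seq(0, max|w|, n_levels),
# sign carried separately (differential device pair)
.quantize_tensor <- function(w, n_levels) {
  mx <- max(abs(w))
  if (mx == 0) return(list(q = w, levels = numeric(n_levels)))
  levels <- seq(0, mx, length.out = n_levels)
  step <- levels[2] - levels[1]
  q <- sign(w) * levels[pmin(n_levels, 1L + round(abs(w) / step))]
  list(q = q, levels = levels)
}

#' Quantize readout weights onto discrete conductance levels
#'
#' Per-tensor symmetric uniform quantisation of the weight magnitudes onto
#' `n_levels` levels (including zero), with the sign carried separately --
#' the differential-pair convention for mapping signed weights onto
#' non-negative physical conductances. Biases stay full-precision (they are
#' applied digitally, not as conductances).
#'
#' @param model a trained `fibrc_readout`.
#' @param n_levels number of conductance levels (default 16; >= 2).
#' @param eval_data optional `fibrc_labeled_states` on which to measure the
#'   accuracy change.
#' @return a `fibrc_quantized_readout`: `model` (quantised copy),
#'   `level_values` per tensor, and when `eval_data` is given,
#'   `accuracy_before`, `accuracy_after`, `accuracy_delta` (after - before).
#' @export
quantize_weights <- function(model, n_levels = 16, eval_data = NULL) {
  if (n_levels < 2) stop_config("n_levels must be >= 2")
  qm <- model
  level_values <- list()
  if (model$kind == "linear") {
    qt <- .quantize_tensor(model$W, n_levels)
    qm$W <- qt$q
    level_values$W <- qt$levels
  } else {
    for (nm in names(model$params)) {
      if (nm %in% c("b1", "b2", "bd")) next
      qt <- .quantize_tensor(model$params[[nm]], n_levels)
      qm$params[[nm]] <- qt$q
      level_values[[nm]] <- qt$levels
    }
  }
  out <- structure(list(model = qm, base = model, n_levels = as.integer(n_levels),
                        level_values = level_values),
                   class = "fibrc_quantized_readout")
  if (!is.null(eval_data)) {
    acc <- function(m) mean(predict(m, eval_data)$labels == as.character(eval_data$y))
    out$accuracy_before <- acc(model)
    out$accuracy_after <- acc(qm)
    out$accuracy_delta <- out$accuracy_after - out$accuracy_before
  }
  out
}

#' @export
print.fibrc_quantized_readout <- function(x, ...) {
  cat(sprintf("<quantized %s readout: %d conductance levels%s>\n", x$model$kind, x$n_levels,
              if (!is.null(x$accuracy_delta)) sprintf(", accuracy delta %+.3f", x$accuracy_delta) else ""))
  invisible(x)
}
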