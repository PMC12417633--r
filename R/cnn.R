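# Lightweight convolutional readout, implemented directly on base-R linear
# algebra (im2col convolutions, BLAS matrix products). Default architecture:
# conv 3x3x8 -> ReLU -> maxpool 2 -> conv 3x3x16 -> ReLU -> global average
# pool -> dense softmax; under 1.5k parameters. Training is deterministic
# full-batch gradient descent (heavy-ball momentum) from a seeded He-normal
# initialisation.

# linear indices of 3x3 patches (pad 1) into a flattened padded sample
# of shape (H+2, W+2, C); rows ordered (di, dj, channel), cols = H*W pixels
.im2col_idx <- function(H, W, C) {
  Hp <- H + 2; Wp <- W + 2
  pix <- expand.grid(i = 1:H, j = 1:W)
  off <- expand.grid(di = 0:2, dj = 0:2, c = 0:(C - 1))
  outer(seq_len(nrow(off)), seq_len(nrow(pix)), function(r, p)
    off$c[r] * Hp * Wp + (pix$j[p] + off$dj[r] - 1) * Hp + (pix$i[p] + off$di[r]))
}

# A: array (H, W, C, N) -> padded flat matrix ((H+2)*(W+2)*C) x N
.pad_flat <- function(A) {
  d <- dim(A)
  Ap <- array(0, c(d[1] + 2, d[2] + 2, d[3], d[4]))
  Ap[2:(d[1] + 1), 2:(d[2] + 1), , ] <- A
  dim(Ap) <- c((d[1] + 2) * (d[2] + 2) * d[3], d[4])
  Ap
}

# conv forward: returns array (H, W, F, N); K is (9*C) x F
.conv_fwd <- function(A, K, b, idx) {
  d <- dim(A); H <- d[1]; W <- d[2]; N <- d[4]
  Ap <- .pad_flat(A)
  cols <- matrix(Ap[as.vector(idx), , drop = FALSE], nrow = nrow(idx))  # (9C) x (HW*N)
  Z <- crossprod(K, cols) + b                                           # F x (HW*N)
  list(out = aperm(array(Z, c(ncol(K), H, W, N)), c(2, 3, 1, 4)), cols = cols)
}

# conv backward: dOut array (H, W, F, N) -> grads and input gradient
.conv_bwd <- function(dOut, cols, K, idx, in_dim) {
  d <- dim(dOut); H <- d[1]; W <- d[2]; Fm <- d[3]; N <- d[4]
  dZ <- matrix(aperm(dOut, c(3, 1, 2, 4)), nrow = Fm)   # F x (HW*N)
  dK <- cols %*% t(dZ)                                  # (9C) x F
  db <- rowSums(dZ)
  dcols <- K %*% dZ                                     # (9C) x (HW*N)
  # scatter-add back into the padded input
  Hp <- in_dim[1] + 2; Wp <- in_dim[2] + 2; C <- in_dim[3]
  L <- Hp * Wp * C
  dmat <- matrix(dcols, nrow = nrow(idx) * ncol(idx))   # (9C*HW) x N
  rs <- rowsum(dmat, group = as.vector(idx))
  dAp <- matrix(0, L, N)
  dAp[as.integer(rownames(rs)), ] <- rs
  dAp <- array(dAp, c(Hp, Wp, C, N))
  list(dK = dK, db = db,
       dA = dAp[2:(in_dim[1] + 1), 2:(in_dim[2] + 1), , , drop = FALSE])
}

.maxpool_fwd <- function(A) {
  d <- dim(A); H2 <- floor(d[1] / 2); W2 <- floor(d[2] / 2)
  ii <- seq_len(H2) * 2; jj <- seq_len(W2) * 2
  s <- list(A[ii - 1, jj - 1, , , drop = FALSE], A[ii, jj - 1, , , drop = FALSE],
            A[ii - 1, jj, , , drop = FALSE], A[ii, jj, , , drop = FALSE])
  M <- pmax(s[[1]], s[[2]], s[[3]], s[[4]])
  taken <- array(FALSE, dim(M))
  masks <- vector("list", 4)
  for (k in 1:4) {                       # first-wins tie break
    masks[[k]] <- (s[[k]] == M) & !taken
    taken <- taken | masks[[k]]
  }
  list(out = M, masks = masks, in_dim = d)
}

.maxpool_bwd <- function(dM, pool) {
  d <- pool$in_dim
  H2 <- dim(dM)[1]; W2 <- dim(dM)[2]
  ii <- seq_len(H2) * 2; jj <- seq_len(W2) * 2
  dA <- array(0, d)
  dA[ii - 1, jj - 1, , ] <- dM * pool$masks[[1]]
  dA[ii, jj - 1, , ] <- dA[ii, jj - 1, , , drop = FALSE] + dM * pool$masks[[2]]
  dA[ii - 1, jj, , ] <- dA[ii - 1, jj, , , drop = FALSE] + dM * pool$masks[[3]]
  dA[ii, jj, , ] <- dA[ii, jj, , , drop = FALSE] + dM * pool$masks[[4]]
  dA
}

# full forward pass; X is the standardised design matrix (N x p)
.cnn_forward <- function(model, X, keep_maps = FALSE, cache = FALSE) {
  ly <- model$layout; H <- ly[1]; W <- ly[2]
  N <- nrow(X)
  A0 <- array(0, c(H, W, 1, N))
  for (n in seq_len(N)) A0[, , 1, n] <- matrix(X[n, ], H, W, byrow = TRUE)
  pm <- model$params
  c1 <- .conv_fwd(A0, pm$K1, pm$b1, model$idx1)
  R1 <- pmax(c1$out, 0)
  if (model$arch$single) {
    maps <- R1
    pool <- NULL; c2 <- NULL; R2 <- NULL
  } else {
    pool <- .maxpool_fwd(R1)
    c2 <- .conv_fwd(pool$out, pm$K2, pm$b2, model$idx2)
    R2 <- pmax(c2$out, 0)
    maps <- R2
  }
  dmap <- dim(maps)
  feat <- array(aperm(maps, c(3, 1, 2, 4)), c(dmap[3], dmap[1] * dmap[2], dmap[4]))
  gap <- apply(feat, c(1, 3), mean)                           # F x N
  if (is.null(dim(gap))) gap <- matrix(gap, nrow = dmap[3])
  logits <- t(crossprod(gap, pm$Wd)) + pm$bd                  # C x N
  out <- list(probs = .softmax(t(logits)), logits = t(logits))
  if (keep_maps) out$final_maps <- lapply(seq_len(N), function(n) maps[, , , n, drop = TRUE])
  if (cache) out$cache <- list(A0 = A0, c1 = c1, R1 = R1, pool = pool, c2 = c2, R2 = R2,
                               maps = maps, gap = gap)
  out
}

#' Train the lightweight CNN readout
#'
#' States are reshaped to their reservoir grid and passed through a small
#' convolutional network (conv 3x3x8, ReLU, maxpool 2, conv 3x3x16, ReLU,
#' global average pooling, dense softmax). Grids too small to pool fall back
#' to a single conv (with a message). Training is full-batch gradient
#' descent with heavy-ball momentum and a fixed step -- deterministic given
#' `seed`.
#'
#' @param data a `fibrc_labeled_states`.
#' @param n_filters1,n_filters2 filters in the two conv layers.
#' @param epochs training epochs (default 200).
#' @param lr learning rate (default 0.1).
#' @param momentum heavy-ball momentum (default 0.9; set 0 for plain
#'   gradient descent).
#' @param seed seed for the weight initialisation.
#' @return a `fibrc_readout` of kind "cnn" with the per-epoch `loss_curve`
#'   and `train_accuracy`.
#' @export
train_cnn <- function(data, n_filters1 = 8, n_filters2 = 16, epochs = 200,
                      lr = 0.1, momentum = 0.9, seed = 7L) {
  if (!inherits(data, "fibrc_labeled_states")) stop_input("data must come from labeled_states()")
  ly <- data$layout; H <- ly[1]; W <- ly[2]
  single <- floor(H / 2) < 1 || floor(W / 2) < 1
  if (single) message("grid too small for a pooled second conv; using a single conv layer")
  sc <- .standardize_fit(data$X)
  Xs <- .standardize_apply(data$X, sc)
  y <- droplevels(data$y)
  C <- nlevels(y); N <- nrow(Xs)
  Y <- t(diag(C)[as.integer(y), , drop = FALSE])   # C x N
  f_out <- if (single) n_filters1 else n_filters2
  params <- with_seed(substream_seed(seed, "cnn-init"), {
    he <- function(nr, nc) matrix(stats::rnorm(nr * nc, 0, sqrt(2 / nr)), nr, nc)
    p <- list(K1 = he(9, n_filters1), b1 = rep(0, n_filters1))
    if (!single) { p$K2 <- he(9 * n_filters1, n_filters2); p$b2 <- rep(0, n_filters2) }
    p$Wd <- he(f_out, C) * 0.5; p$bd <- rep(0, C)
    p
  })
  model <- structure(list(kind = "cnn", params = params, classes = levels(y),
                          scaler = sc, layout = ly,
                          arch = list(single = single, n_filters1 = n_filters1,
                                      n_filters2 = n_filters2),
                          idx1 = .im2col_idx(H, W, 1)),
                     class = "fibrc_readout")
  if (!single) model$idx2 <- .im2col_idx(floor(H / 2), floor(W / 2), n_filters1)
  vel <- lapply(params, function(p) p * 0)
  loss_curve <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    fw <- .cnn_forward(model, Xs, cache = TRUE)
    P <- t(fw$probs)                                 # C x N
    loss_curve[ep] <- -mean(log(pmax(P[cbind(as.integer(y), seq_len(N))], 1e-300)))
    g <- .cnn_backward(model, fw$cache, P, Y)
    for (nm in names(g)) {
      vel[[nm]] <- momentum * vel[[nm]] - lr * g[[nm]]
      model$params[[nm]] <- model$params[[nm]] + vel[[nm]]
    }
  }
  model$loss_curve <- loss_curve
  model$n_params <- sum(vapply(model$params, length, integer(1)))
  model$train_accuracy <- mean(predict(model, data)$labels == as.character(data$y))
  model$training <- list(epochs = epochs, lr = lr, momentum = momentum, seed = seed)
  model
}

.cnn_backward <- function(model, cache, P, Y) {
  N <- ncol(P)
  maps <- cache$maps; dmap <- dim(maps)
  hw <- dmap[1] * dmap[2]
  dlogits <- (P - Y) / N                              # C x N
  g <- list()
  g$Wd <- cache$gap %*% t(dlogits)
  g$bd <- rowSums(dlogits)
  dgap <- model$params$Wd %*% dlogits                 # F x N
  dmaps <- array(0, dmap)
  for (f in seq_len(dmap[3])) for (n in seq_len(N))
    dmaps[, , f, n] <- dgap[f, n] / hw
  if (model$arch$single) {
    dR1 <- dmaps * (cache$c1$out > 0)
    cb <- .conv_bwd(dR1, cache$c1$cols, model$params$K1, model$idx1,
                    c(model$layout[1], model$layout[2], 1))
    g$K1 <- cb$dK; g$b1 <- cb$db
  } else {
    dR2 <- dmaps * (cache$c2$out > 0)
    in2 <- dim(cache$pool$out)[1:3]
    cb2 <- .conv_bwd(dR2, cache$c2$cols, model$params$K2, model$idx2, in2)
    g$K2 <- cb2$dK; g$b2 <- cb2$db
    dP <- .maxpool_bwd(cb2$dA, cache$pool)
    dR1 <- dP * (cache$c1$out > 0)
    cb1 <- .conv_bwd(dR1, cache$c1$cols, model$params$K1, model$idx1,
                     c(model$layout[1], model$layout[2], 1))
    g$K1 <- cb1$dK; g$b1 <- cb1$db
  }
  g[names(model$params)]
}
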