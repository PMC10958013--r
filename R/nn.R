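## Minimal CNN machinery for the Siamese perception network.
##
## Activations between conv layers live in "matrix form": an (H*W*N) x C
## matrix whose row index is h + H*(w + W*n), so that a whole mini-batch
## goes through each layer as a single im2col + GEMM. All tensors are
## plain numeric matrices; gradients are computed layer by layer in
## reverse. This is deliberately small: three layer types (conv, flatten,
## fc), ReLU, log-softmax, Adam.

convOutSize <- function(H, k, stride, pad) (H + 2L * pad - k) %/% stride + 1L

## 2x2 stride-2 average pooling on matrix-form activations (square maps);
## rows are indexed h + H*(w + W*n). Odd trailing row/column is dropped,
## matching the k = 2, stride = 2, pad = 0 convolution geometry.
avgPool2 <- function(A, H, N) {
  Ho <- H %/% 2L
  H2 <- 2L * Ho
  C <- ncol(A)
  out <- matrix(0, Ho * Ho * N, C)
  rowOdd <- seq_len(H2) %% 2L == 1L
  wKeep <- rep(c(rep(TRUE, H2), rep(FALSE, H - H2)), N)
  colOdd <- rep(rep(c(TRUE, FALSE), length.out = H2), N)
  for (c in seq_len(C)) {
    M <- matrix(A[, c], H, H * N)[seq_len(H2), wKeep, drop = FALSE]
    Mh <- M[rowOdd, , drop = FALSE] + M[!rowOdd, , drop = FALSE]
    out[, c] <- as.vector(Mh[, colOdd, drop = FALSE] +
                            Mh[, !colOdd, drop = FALSE]) / 4
  }
  out
}

## He/Xavier-initialised layer constructors ---------------------------------

mkConv <- function(cin, cout, k = 3L, stride = 1L, pad = 1L,
                   frozen = FALSE, act = "relu") {
  fanin <- k * k * cin
  gain <- if (act == "relu") sqrt(2 / fanin) else sqrt(1 / fanin)
  list(type = "conv", k = k, stride = stride, pad = pad, cin = cin,
       cout = cout, frozen = frozen, act = act,
       W = matrix(rnorm(fanin * cout) * gain, fanin, cout),
       b = numeric(cout))
}

## k x k stride-2 average pooling as a frozen fixed-weight convolution;
## k = 3 gives overlapping (smoother) windows
mkAvgPool <- function(C, k = 2L) {
  pad <- if (k == 3L) 1L else 0L
  W <- matrix(0, k * k * C, C)
  for (c in seq_len(C)) W[(c - 1L) * k * k + seq_len(k * k), c] <- 1 / (k * k)
  list(type = "conv", k = k, stride = 2L, pad = pad, cin = C, cout = C,
       frozen = TRUE, act = "linear", pool = TRUE, W = W, b = numeric(C))
}

mkFc <- function(nin, nout, act = "relu", frozen = FALSE) {
  gain <- if (act == "relu") sqrt(2 / nin) else sqrt(1 / nin)
  list(type = "fc", act = act, frozen = frozen,
       W = matrix(rnorm(nin * nout) * gain, nin, nout),
       b = numeric(nout))
}

addBias <- function(Z, b) Z + rep(b, each = nrow(Z))

applyAct <- function(Z, act) {
  if (act == "relu") Z * (Z > 0) else Z
}

## Forward pass through a stack of layers.
## X: images as (H, W, N) array (first layer conv) or an N x p matrix
## (first layer fc). Returns list(out, caches) when cache = TRUE.
stackForward <- function(layers, X, imageSize = NULL, cache = FALSE) {
  caches <- if (cache) vector("list", length(layers)) else NULL
  if (is.array(X) && length(dim(X)) == 3L) {
    H <- dim(X)[1]
    N <- dim(X)[3]
    A <- matrix(as.numeric(X), ncol = 1L)  # (H*W*N) x 1, row h + H*(w + W*n)
  } else {
    A <- X
    H <- imageSize
    N <- nrow(X)
  }
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (ly$type == "conv" && isTRUE(ly$pool) && ly$k == 2L) {
      # fast path: 2x2 stride-2 average pooling by reshaping, no GEMM
      A <- avgPool2(A, H, N)
      if (cache) caches[[i]] <- list(H = H)
      H <- H %/% 2L
    } else if (ly$type == "conv" && isTRUE(ly$frozen) && ly$k == 3L &&
               ly$stride == 1L && ly$pad == 1L) {
      # frozen layers are forward-only: fused direct convolution
      A <- nn_conv3_direct(A, H, H, N, ly$W, ly$b, ly$act == "relu")
      if (cache) caches[[i]] <- list(H = H)
    } else if (ly$type == "conv") {
      cols <- nn_im2col(A, H, H, N, ly$k, ly$stride, ly$pad)
      Z <- addBias(cols %*% ly$W, ly$b)
      Z <- applyAct(Z, ly$act)
      if (cache) {
        # frozen layers never receive gradients; keep only the geometry
        caches[[i]] <- if (isTRUE(ly$frozen)) list(H = H) else
          list(cols = cols, mask = (Z > 0), H = H)
      }
      H <- convOutSize(H, ly$k, ly$stride, ly$pad)
      A <- Z
    } else if (ly$type == "flatten") {
      # (H*W*N) x C matrix form -> N x (H*W*C) per-image rows
      C <- ncol(A)
      hw <- H * H
      Fm <- matrix(0, N, hw * C)
      for (c in seq_len(C)) {
        Fm[, ((c - 1L) * hw + 1L):(c * hw)] <- t(matrix(A[, c], hw, N))
      }
      if (cache) caches[[i]] <- list(H = H, C = C)
      A <- Fm
    } else if (ly$type == "gap") {
      # global average pooling: (H*W*N) x C -> N x C
      hw <- H * H
      Fm <- matrix(0, N, ncol(A))
      for (c in seq_len(ncol(A))) {
        Fm[, c] <- colMeans(matrix(A[, c], hw, N))
      }
      if (cache) caches[[i]] <- list(H = H, C = ncol(A))
      A <- Fm
    } else {  # fc
      Z <- addBias(A %*% ly$W, ly$b)
      Z <- applyAct(Z, ly$act)
      if (cache) caches[[i]] <- list(Ain = A, mask = if (ly$act == "relu") (Z > 0))
      A <- Z
    }
  }
  list(out = A, caches = caches, N = N)
}

## Backward pass. dOut matches the stack output. Returns list(grads, dIn);
## grads[[i]] is list(W, b) for trainable layers, NULL otherwise. dIn is
## only propagated down to the lowest trainable layer (everything below
## is frozen and needs no gradient).
stackBackward <- function(layers, caches, dOut, N, needInputGrad = FALSE) {
  grads <- vector("list", length(layers))
  lowest <- which(!vapply(layers,
                          function(l) isTRUE(l$frozen) || l$type %in% c("flatten", "gap"),
                          logical(1)))
  lowest <- if (length(lowest)) min(lowest) else 1L
  dA <- dOut
  for (i in rev(seq_along(layers))) {
    ly <- layers[[i]]
    ch <- caches[[i]]
    if (ly$type == "fc") {
      if (ly$act == "relu") dA <- dA * ch$mask
      if (!isTRUE(ly$frozen)) {
        grads[[i]] <- list(W = crossprod(ch$Ain, dA), b = colSums(dA))
      }
      if (i > lowest || needInputGrad) dA <- tcrossprod(dA, ly$W)
    } else if (ly$type == "flatten") {
      # N x (H*W*C) -> matrix form (H*W*N) x C
      hw <- ch$H * ch$H
      C <- ch$C
      M <- matrix(0, hw * N, C)
      for (c in seq_len(C)) {
        M[, c] <- as.vector(t(dA[, ((c - 1L) * hw + 1L):(c * hw), drop = FALSE]))
      }
      dA <- M
    } else if (ly$type == "gap") {
      hw <- ch$H * ch$H
      M <- matrix(0, hw * N, ch$C)
      for (c in seq_len(ch$C)) {
        M[, c] <- rep(dA[, c], each = hw) / hw
      }
      dA <- M
    } else {  # conv
      if (i < lowest && !needInputGrad) break
      if (ly$act == "relu") dA <- dA * ch$mask
      if (!isTRUE(ly$frozen)) {
        grads[[i]] <- list(W = crossprod(ch$cols, dA), b = colSums(dA))
      }
      if (i > lowest || needInputGrad) {
        dcols <- tcrossprod(dA, ly$W)
        dA <- nn_col2im(dcols, ch$H, ch$H, N, ly$k, ly$stride, ly$pad)
      } else {
        break
      }
    }
  }
  list(grads = grads, dIn = dA)
}

logSoftmax <- function(logits) {
  m <- apply(logits, 1L, max)
  z <- logits - m
  z - log(rowSums(exp(z)))
}

## mean NLL over rows; labels in 1..K
nllLoss <- function(logp, labels) {
  -mean(logp[cbind(seq_along(labels), labels)])
}

## gradient of mean NLL w.r.t. logits: (softmax - onehot) / n
nllGrad <- function(logp, labels) {
  g <- exp(logp)
  g[cbind(seq_along(labels), labels)] <-
    g[cbind(seq_along(labels), labels)] - 1
  g / length(labels)
}

## Adam ---------------------------------------------------------------------

adamInit <- function(layers) {
  lapply(layers, function(ly) {
    if (ly$type == "flatten" || isTRUE(ly$frozen)) return(NULL)
    list(mW = ly$W * 0, vW = ly$W * 0, mb = ly$b * 0, vb = ly$b * 0)
  })
}

adamStep <- function(layers, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (i in seq_along(layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    s <- state[[i]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    layers[[i]]$W <- layers[[i]]$W - lr * (s$mW / bc1) / (sqrt(s$vW / bc2) + eps)
    layers[[i]]$b <- layers[[i]]$b - lr * (s$mb / bc1) / (sqrt(s$vb / bc2) + eps)
    state[[i]] <- s
  }
  list(layers = layers, state = state)
}
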