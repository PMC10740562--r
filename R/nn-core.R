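# Minimal neural-network toolkit: dense / 2-D convolution / transposed
# 1-D convolution layers with hand-derived backward passes, leaky-ReLU,
# dropout, softmax cross-entropy and Adam. Batch-major layout throughout:
# activations are (batch x features) matrices, images are
# (batch, height, width, channels) arrays. Correctness of every backward
# pass is pinned by finite-difference tests.

sigmoid <- function(x) 1 / (1 + exp(-x))

lrelu <- function(x, a = 0.1) {
  neg <- x < 0
  x[neg] <- a * x[neg]
  x
}

lrelu_grad <- function(dy, x, a = 0.1) {
  g <- dy
  g[x < 0] <- a * g[x < 0]
  g
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

# ---- dense ------------------------------------------------------------

dense_init <- function(d_in, d_out) {
  list(W = glorot(d_in, d_out), b = numeric(d_out))
}

dense_forward <- function(X, p) {
  sweep(X %*% p$W, 2, p$b, "+")
}

dense_backward <- function(dY, X, p) {
  list(dX = dY %*% t(p$W),
       grads = list(W = crossprod(X, dY), b = colSums(dY)))
}

# ---- 2-D convolution (valid/padded, strided) via im2col ----------------

conv_geom <- function(H, W, C, kh, kw, ph, pw, sh, sw) {
  Hp <- H + 2L * ph; Wp <- W + 2L * pw
  Hout <- (Hp - kh) %/% sh + 1L
  Wout <- (Wp - kw) %/% sw + 1L
  if (Hout < 1 || Wout < 1) abort("convolution geometry collapses to nothing.")
  P <- Hout * Wout
  K <- kh * kw * C
  # idx[pos, k]: flat index into a (Hp, Wp, C) volume
  oi <- rep(seq_len(Hout), times = Wout)
  oj <- rep(seq_len(Wout), each = Hout)
  ki <- rep(seq_len(kh), times = kw * C)
  kj <- rep(rep(seq_len(kw), each = kh), times = C)
  kc <- rep(seq_len(C), each = kh * kw)
  ii <- outer((oi - 1L) * sh, ki, "+")              # P x (kh*kw*C): row index
  jj <- outer((oj - 1L) * sw, kj, "+")              # col index
  cc <- matrix(kc, nrow = P, ncol = K, byrow = TRUE)
  idx <- ii + Hp * (jj - 1L) + Hp * Wp * (cc - 1L)
  # per-spatial-offset views for the shift-and-matmul path: weight-matrix
  # rows and padded-input rows/cols touched by each (ki, kj)
  offs <- vector("list", kh * kw)
  o <- 0L
  for (kjj in seq_len(kw)) {
    for (kii in seq_len(kh)) {
      o <- o + 1L
      offs[[o]] <- list(
        wrows = kii + kh * (kjj - 1L) + kh * kw * (seq_len(C) - 1L),
        ii = (seq_len(Hout) - 1L) * sh + kii,
        jj = (seq_len(Wout) - 1L) * sw + kjj
      )
    }
  }
  list(idx = idx, offs = offs, H = H, W = W, C = C, Hp = Hp, Wp = Wp,
       Hout = Hout, Wout = Wout, P = P, K = K,
       kh = kh, kw = kw, ph = ph, pw = pw, sh = sh, sw = sw)
}

pad_input <- function(X, g, flat = TRUE) {
  B <- dim(X)[1]
  if (g$ph == 0 && g$pw == 0) {
    Xp <- X
    dim(Xp) <- c(B, g$Hp, g$Wp, g$C)
  } else {
    Xp <- array(0, c(B, g$Hp, g$Wp, g$C))
    Xp[, g$ph + seq_len(g$H), g$pw + seq_len(g$W), ] <- X
  }
  if (flat) dim(Xp) <- c(B, g$Hp * g$Wp * g$C)
  Xp
}

im2col <- function(X, g) {
  Xp <- pad_input(X, g)                 # B x (Hp*Wp*C)
  B <- nrow(Xp)
  Xcol <- Xp[, as.vector(g$idx), drop = FALSE]   # B x (P*K)
  dim(Xcol) <- c(B * g$P, g$K)
  Xcol
}

col2im <- function(dXcol, g, B) {
  # adjoint of im2col: scatter-add patch gradients onto the padded input,
  # one kernel offset at a time (indices are collision-free within an offset)
  dim(dXcol) <- c(B, g$P, g$K)
  dXp <- matrix(0, B, g$Hp * g$Wp * g$C)
  for (k in seq_len(g$K)) {
    cols <- g$idx[, k]
    dXp[, cols] <- dXp[, cols] + dXcol[, , k]
  }
  dim(dXp) <- c(B, g$Hp, g$Wp, g$C)
  if (g$ph == 0 && g$pw == 0) return(dXp)
  dXp[, g$ph + seq_len(g$H), g$pw + seq_len(g$W), , drop = FALSE]
}

conv2d_init <- function(g, C_out) {
  list(W = glorot(g$K, C_out), b = numeric(C_out))
}

# forward/backward via shift-and-matmul over the kh*kw spatial offsets:
# avoids materializing the (B*P) x K patch matrix
conv2d_forward <- function(X, p, g) {
  B <- dim(X)[1]
  C_out <- ncol(p$W)
  Xp <- pad_input(X, g, flat = FALSE)   # B x Hp x Wp x C
  Y <- matrix(rep(p$b, each = B * g$P), B * g$P, C_out)
  for (o in g$offs) {
    slab <- Xp[, o$ii, o$jj, , drop = FALSE]
    dim(slab) <- c(B * g$P, g$C)
    Y <- Y + slab %*% p$W[o$wrows, , drop = FALSE]
  }
  dim(Y) <- c(B, g$Hout, g$Wout, C_out)
  list(Y = Y, Xp = Xp)
}

conv2d_backward <- function(dY, cache, p, g, need_dx = TRUE) {
  B <- dim(dY)[1]
  C_out <- ncol(p$W)
  dim(dY) <- c(B * g$P, C_out)
  dW <- p$W * 0
  dXp <- if (need_dx) array(0, c(B, g$Hp, g$Wp, g$C))
  for (o in g$offs) {
    slab <- cache$Xp[, o$ii, o$jj, , drop = FALSE]
    dim(slab) <- c(B * g$P, g$C)
    dW[o$wrows, ] <- crossprod(slab, dY)
    if (need_dx) {
      dslab <- dY %*% t(p$W[o$wrows, , drop = FALSE])
      dim(dslab) <- c(B, g$Hout, g$Wout, g$C)
      dXp[, o$ii, o$jj, ] <- dXp[, o$ii, o$jj, , drop = FALSE] + dslab
    }
  }
  grads <- list(W = dW, b = colSums(dY))
  dX <- NULL
  if (need_dx) {
    dX <- if (g$ph == 0 && g$pw == 0) dXp
          else dXp[, g$ph + seq_len(g$H), g$pw + seq_len(g$W), , drop = FALSE]
  }
  list(dX = dX, grads = grads)
}

# ---- transposed 1-D convolution ---------------------------------------
# Maps length L_in -> L_out = (L_in - 1) * s - 2 p + k using the adjoint of
# the convolution that maps L_out -> L_in. Weight matrix: (k * C_out) x C_in.

convT1d_geom <- function(L_in, C_in, C_out, k, s, p) {
  g <- conv_geom(H = (L_in - 1L) * s - 2L * p + k, W = 1L, C = C_out,
                 kh = k, kw = 1L, ph = p, pw = 0L, sh = s, sw = 1L)
  if (g$Hout != L_in) abort("inconsistent transposed-convolution geometry.")
  c(g, list(L_in = L_in, L_out = g$H, C_in = C_in, C_out_T = C_out))
}

convT1d_init <- function(g) {
  list(W = glorot(g$K, g$C_in), b = numeric(g$C_out_T))
}

convT1d_forward <- function(X, p, g) {
  # X: B x L_in x C_in  ->  Y: B x L_out x C_out
  B <- dim(X)[1]
  U <- X
  dim(U) <- c(B * g$L_in, g$C_in)
  V <- col2im(U %*% t(p$W), g, B)       # B x L_out x 1 x C_out
  dim(V) <- c(B, g$L_out, g$C_out_T)
  V <- sweep(V, 3, p$b, "+")
  V
}

convT1d_backward <- function(dY, X, p, g) {
  B <- dim(dY)[1]
  db <- apply(dY, 3, sum)
  dV <- dY
  dim(dV) <- c(B, g$L_out, 1L, g$C_out_T)
  dVcol <- im2col(dV, g)                # (B*L_in) x K
  U <- X
  dim(U) <- c(B * g$L_in, g$C_in)
  dW <- crossprod(dVcol, U)             # K x C_in
  dX <- dVcol %*% p$W                   # (B*L_in) x C_in
  dim(dX) <- c(B, g$L_in, g$C_in)
  list(dX = dX, grads = list(W = dW, b = db))
}

# ---- dropout, softmax, losses ------------------------------------------

dropout_forward <- function(X, prob, training) {
  if (!training || prob <= 0) return(list(Y = X, mask = NULL))
  mask <- array((runif(length(X)) >= prob) / (1 - prob), dim = dim(X) %||% length(X))
  list(Y = X * mask, mask = mask)
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

softmax_xent <- function(logits, y) {
  # y: integer labels 1..m; returns loss and dlogits (already / batch)
  B <- nrow(logits)
  P <- softmax_rows(logits)
  picked <- P[cbind(seq_len(B), y)]
  loss <- -mean(log(pmax(picked, 1e-300)))
  dZ <- P
  dZ[cbind(seq_len(B), y)] <- dZ[cbind(seq_len(B), y)] - 1
  list(loss = loss, dlogits = dZ / B, probs = P)
}

# ---- Adam ---------------------------------------------------------------

zero_like <- function(params) lapply(params, function(p) {
  if (is.list(p)) zero_like(p) else p * 0
})

adam_init <- function(params) list(m = zero_like(params), v = zero_like(params), t = 0L)

adam_step <- function(params, grads, state, lr = 2e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8, clip = 5) {
  # global-norm gradient clipping for stability of recurrent nets
  sq <- function(g) if (is.list(g)) sum(vapply(g, sq, numeric(1))) else sum(g^2)
  gn <- sqrt(sq(grads))
  scale <- if (is.finite(gn) && gn > clip) clip / gn else 1
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- purrr::pmap(list(p, g, m, v), upd)
      return(list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    g <- g * scale
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    p <- p - lr * (m / corr1) / (sqrt(v / corr2) + eps)
    list(p = p, m = m, v = v)
  }
  out <- purrr::pmap(list(params, grads, state$m, state$v), upd)
  list(params = lapply(out, `[[`, "p"),
       state = list(m = lapply(out, `[[`, "m"),
                    v = lapply(out, `[[`, "v"), t = state$t))
}

n_params <- function(params) {
  if (is.list(params)) sum(vapply(params, n_params, numeric(1))) else length(params)
}
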