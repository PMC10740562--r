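# Recurrent cells (GRU, unidirectional and bidirectional LSTM) with full
# backpropagation through time. Sequences are (batch, time, features)
# arrays; hidden states are (batch x n) matrices. Gate blocks are stored
# column-concatenated in the conventional order -- GRU: [reset, update,
# candidate]; LSTM: [input, forget, cell-candidate, output] -- matching
# the stacked-parameter layout Wx = [Wr; Wz; Wc], Wx = [Wi; Wf; Wc; Wo]
# of the reference architecture tables (which are row-stacked, i.e. the
# transpose of the internal layout).

seq_slice <- function(X, t) matrix(X[, t, ], nrow = dim(X)[1])

gru_init <- function(d, n) {
  list(Wx = glorot(d, 3L * n), Wh = glorot(n, 3L * n), b = numeric(3L * n))
}

gru_forward <- function(X, p, n) {
  B <- dim(X)[1]; T_ <- dim(X)[2]; d <- dim(X)[3]
  i1 <- seq_len(n); i2 <- n + i1; i3 <- 2L * n + i1
  h <- matrix(0, B, n)
  Xmat <- X; dim(Xmat) <- c(B * T_, d)
  Gx_all <- sweep(Xmat %*% p$Wx, 2, p$b, "+")   # input-side preactivations, all t
  H <- vector("list", T_); cache <- vector("list", T_)
  for (t in seq_len(T_)) {
    Xt <- seq_slice(X, t)
    Gx <- Gx_all[(t - 1L) * B + seq_len(B), , drop = FALSE]
    Gh <- h %*% p$Wh
    r <- sigmoid(Gx[, i1, drop = FALSE] + Gh[, i1, drop = FALSE])
    z <- sigmoid(Gx[, i2, drop = FALSE] + Gh[, i2, drop = FALSE])
    hc_rec <- Gh[, i3, drop = FALSE]
    c_ <- tanh(Gx[, i3, drop = FALSE] + r * hc_rec)
    h_new <- (1 - z) * h + z * c_
    cache[[t]] <- list(Xt = Xt, h_prev = h, r = r, z = z, c = c_, hc_rec = hc_rec)
    h <- h_new
    H[[t]] <- h
  }
  list(H = H, cache = cache)
}

gru_backward <- function(dH, fwd, p, n) {
  # dH: list over t of (B x n) gradients flowing into h_t from the head
  T_ <- length(fwd$cache)
  i1 <- seq_len(n); i2 <- n + i1; i3 <- 2L * n + i1
  B <- nrow(fwd$cache[[1]]$Xt)
  d <- ncol(fwd$cache[[1]]$Xt)
  dWh <- matrix(0, n, 3L * n)
  dh <- matrix(0, B, n)
  dG_all <- matrix(0, B * T_, 3L * n)
  X_all <- matrix(0, B * T_, d)
  dX <- vector("list", T_)
  for (t in rev(seq_len(T_))) {
    cc <- fwd$cache[[t]]
    dh <- dh + (dH[[t]] %||% 0)
    dz <- dh * (cc$c - cc$h_prev) * cc$z * (1 - cc$z)
    dc <- dh * cc$z * (1 - cc$c^2)
    dr <- dc * cc$hc_rec * cc$r * (1 - cc$r)
    dG <- cbind(dr, dz, dc)                      # grads wrt Gx blocks
    rows <- (t - 1L) * B + seq_len(B)
    dG_all[rows, ] <- dG
    X_all[rows, ] <- cc$Xt
    dX[[t]] <- dG %*% t(p$Wx)
    dGh <- cbind(dr, dz, dc * cc$r)              # grads wrt Gh blocks
    dWh <- dWh + crossprod(cc$h_prev, dGh)
    dh <- dGh %*% t(p$Wh) + dh * (1 - cc$z)
  }
  list(grads = list(Wx = crossprod(X_all, dG_all), Wh = dWh,
                    b = colSums(dG_all)), dX = dX)
}

lstm_init <- function(d, n) {
  p <- list(Wx = glorot(d, 4L * n), Wh = glorot(n, 4L * n), b = numeric(4L * n))
  p$b[n + seq_len(n)] <- 1   # forget-gate bias init
  p
}

lstm_forward <- function(X, p, n, reverse = FALSE) {
  B <- dim(X)[1]; T_ <- dim(X)[2]
  i1 <- seq_len(n); i2 <- n + i1; i3 <- 2L * n + i1; i4 <- 3L * n + i1
  h <- matrix(0, B, n); cs <- matrix(0, B, n)
  d <- dim(X)[3]
  Xmat <- X; dim(Xmat) <- c(B * T_, d)
  Gx_all <- sweep(Xmat %*% p$Wx, 2, p$b, "+")
  ord <- if (reverse) rev(seq_len(T_)) else seq_len(T_)
  H <- vector("list", T_); cache <- vector("list", T_)
  for (t in ord) {
    Xt <- seq_slice(X, t)
    G <- Gx_all[(t - 1L) * B + seq_len(B), , drop = FALSE] + h %*% p$Wh
    i <- sigmoid(G[, i1, drop = FALSE])
    f <- sigmoid(G[, i2, drop = FALSE])
    g <- tanh(G[, i3, drop = FALSE])
    o <- sigmoid(G[, i4, drop = FALSE])
    c_new <- i * g + f * cs
    tc <- tanh(c_new)
    h_new <- o * tc
    cache[[t]] <- list(Xt = Xt, h_prev = h, c_prev = cs, i = i, f = f,
                       g = g, o = o, tc = tc)
    h <- h_new; cs <- c_new
    H[[t]] <- h
  }
  list(H = H, cache = cache, order = ord)
}

lstm_backward <- function(dH, fwd, p, n) {
  ord <- fwd$order
  i1 <- seq_len(n)
  B <- nrow(fwd$cache[[ord[1]]]$Xt)
  d <- ncol(fwd$cache[[ord[1]]]$Xt)
  T_ <- length(ord)
  dWh <- matrix(0, n, 4L * n)
  dh <- matrix(0, B, n); dc <- matrix(0, B, n)
  dG_all <- matrix(0, B * T_, 4L * n)
  X_all <- matrix(0, B * T_, d)
  dX <- vector("list", T_)
  for (t in rev(ord)) {
    cc <- fwd$cache[[t]]
    dh <- dh + (dH[[t]] %||% 0)
    do_ <- dh * cc$tc * cc$o * (1 - cc$o)
    dc <- dc + dh * cc$o * (1 - cc$tc^2)
    di <- dc * cc$g * cc$i * (1 - cc$i)
    df <- dc * cc$c_prev * cc$f * (1 - cc$f)
    dg <- dc * cc$i * (1 - cc$g^2)
    dG <- cbind(di, df, dg, do_)
    rows <- (t - 1L) * B + seq_len(B)
    dG_all[rows, ] <- dG
    X_all[rows, ] <- cc$Xt
    dWh <- dWh + crossprod(cc$h_prev, dG)
    dX[[t]] <- dG %*% t(p$Wx)
    dh <- dG %*% t(p$Wh)
    dc <- dc * cc$f
  }
  list(grads = list(Wx = crossprod(X_all, dG_all), Wh = dWh,
                    b = colSums(dG_all)), dX = dX)
}

# Bidirectional LSTM: parameters are a forward and a backward cell; the
# stacked ledger shapes (Wx: 8n x d) concatenate the two directions.
blstm_init <- function(d, n) {
  list(fwd = lstm_init(d, n), bwd = lstm_init(d, n))
}

blstm_forward <- function(X, p, n) {
  f <- lstm_forward(X, p$fwd, n, reverse = FALSE)
  b <- lstm_forward(X, p$bwd, n, reverse = TRUE)
  H <- purrr::map2(f$H, b$H, cbind)
  list(H = H, f = f, b = b)
}

blstm_backward <- function(dH, fwd, p, n) {
  dHf <- lapply(dH, function(m) if (is.null(m)) NULL else m[, seq_len(n), drop = FALSE])
  dHb <- lapply(dH, function(m) if (is.null(m)) NULL else m[, n + seq_len(n), drop = FALSE])
  gf <- lstm_backward(dHf, fwd$f, p$fwd, n)
  gb <- lstm_backward(dHb, fwd$b, p$bwd, n)
  dX <- purrr::map2(gf$dX, gb$dX, `+`)
  list(grads = list(fwd = gf$grads, bwd = gb$grads), dX = dX)
}

rnn_init <- function(variant, d, n) {
  switch(variant,
    GRU = gru_init(d, n),
    ULSTM = lstm_init(d, n),
    BLSTM = blstm_init(d, n),
    abort(paste0("unknown recurrent variant: ", variant))
  )
}

rnn_forward <- function(variant, X, p, n) {
  switch(variant,
    GRU = gru_forward(X, p, n),
    ULSTM = lstm_forward(X, p, n),
    BLSTM = blstm_forward(X, p, n)
  )
}

rnn_backward <- function(variant, dH, fwd, p, n) {
  switch(variant,
    GRU = gru_backward(dH, fwd, p, n),
    ULSTM = lstm_backward(dH, fwd, p, n),
    BLSTM = blstm_backward(dH, fwd, p, n)
  )
}

rnn_out_width <- function(variant, n) if (variant == "BLSTM") 2L * n else n
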