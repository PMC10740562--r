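#' Reparameterized sampling layer
#'
#' Splits the encoder's output vector into the posterior mean and
#' log-variance halves, and draws a latent sample by the reparameterization
#' trick: `sigma_z = exp(log_var / 2)` and `Z = epsilon * sigma_z + mu_z`.
#'
#' @param concat_input numeric vector of even length `m` (or a
#'   `batch x m` matrix): the concatenation of `mu_z` and the
#'   log-variance vector.
#' @param epsilon standard-normal draw of length `m / 2` (or matrix);
#'   drawn internally when `NULL`.
#' @return a list with `mu_z`, `log_var`, `sigma_z`, `z` and `epsilon`.
#' @examples
#' s <- sampling_layer(c(1, 2, 0, 0), epsilon = c(0, 0))
#' s$z  # equals mu_z
#' @export
sampling_layer <- function(concat_input, epsilon = NULL) {
  vec <- is.null(dim(concat_input))
  X <- if (vec) matrix(concat_input, nrow = 1) else concat_input
  m <- ncol(X)
  if (m %% 2 != 0) abort("sampling-layer input length must be even.")
  h <- m %/% 2
  mu <- X[, seq_len(h), drop = FALSE]
  lv <- X[, h + seq_len(h), drop = FALSE]
  if (is.null(epsilon)) epsilon <- matrix(rnorm(nrow(X) * h), nrow(X), h)
  eps <- if (is.null(dim(epsilon))) matrix(epsilon, nrow(X), h, byrow = TRUE) else epsilon
  sig <- exp(lv / 2)
  z <- eps * sig + mu
  if (vec) {
    list(mu_z = as.vector(mu), log_var = as.vector(lv),
         sigma_z = as.vector(sig), z = as.vector(z), epsilon = as.vector(eps))
  } else {
    list(mu_z = mu, log_var = lv, sigma_z = sig, z = z, epsilon = eps)
  }
}

#' Bounded scaling layer
#'
#' `fs(x) = alpha * tanh(x)`, the generative decoder's output layer: it
#' maps any real input strictly inside `(-alpha, alpha)`, matching the
#' range of the z-scored data being imitated (`alpha = 1.5` for normal
#' segments, `alpha = 5` for anomaly segments).
#'
#' @param x numeric vector, matrix or array.
#' @param alpha positive output half-range.
#' @return same shape as `x`, bounded by `alpha` in magnitude.
#' @examples
#' max(abs(scaling_layer(c(-1e6, 1e6), 1.5)))  # < 1.5
#' @export
scaling_layer <- function(x, alpha) {
  if (alpha <= 0) abort("`alpha` must be positive.")
  alpha * tanh(x)
}

#' Evidence-lower-bound loss
#'
#' The training objective of the variational generators, as a minimized
#' quantity: the closed-form KL divergence of the diagonal-Gaussian
#' posterior from the standard-normal prior,
#' `0.5 * sum(exp(log_var) + mu^2 - 1 - log_var)`, plus a Gaussian
#' reconstruction term (mean squared error). For batch inputs the KL is
#' averaged over the batch.
#'
#' @param mu_z,log_var posterior mean and log-variance (vectors or
#'   `batch x latent` matrices).
#' @param reconstruction,target decoder output and training target.
#' @param label optional class label (recorded, CVAE bookkeeping).
#' @param beta KL weight (default 1).
#' @return a list with `kl_term`, `recon_term`, `total` and `label`.
#' @examples
#' elbo_loss(c(1, 0), c(0, 0), 1:3, 1:3)$kl_term  # 0.5
#' @export
elbo_loss <- function(mu_z, log_var, reconstruction, target,
                      label = NULL, beta = 1) {
  mu <- rbind(mu_z); lv <- rbind(log_var)
  kl <- mean(0.5 * rowSums(exp(lv) + mu^2 - 1 - lv))
  recon <- mse(as.numeric(target), as.numeric(reconstruction))
  list(kl_term = kl, recon_term = recon, total = beta * kl + recon, label = label)
}

#' Generative model descriptor
#'
#' Describes a segment generator: a label-conditioned CVAE for normal
#' segments or an unconditional VAE for anomaly segments. The encoder
#' compresses a segment (plus, for the CVAE, an embedded class-label
#' channel) through a strided convolution ladder -- 500 to 250 to 125 to 63
#' samples for 500-sample segments, 300 to 150 to 75 to 38 for 300-sample
#' segments, with residual refinement blocks -- down to a 64-unit vector
#' feeding the [sampling_layer()] (latent width 32). The decoder mirrors it
#' with transposed convolutions (63 to 125 to 249 to 500, or 38 to 75 to
#' 150 to 300) and ends in the bounded [scaling_layer()].
#'
#' @param flavor `"cvae_normal"` or `"vae_anomaly"`.
#' @param input_length segment length (300 or 500).
#' @param n_classes number of condition classes (CVAE only).
#' @param latent_dim latent width (default 32).
#' @param label_embedding_dim class-embedding width (default 32, CVAE).
#' @param scaling_alpha output half-range (default 1.5 for normal data,
#'   5 for anomaly data).
#' @param dropout dropout probability inside the ladders (default 0.25).
#' @return an object of class `generative_model_spec`.
#' @export
generative_model_spec <- function(flavor = c("cvae_normal", "vae_anomaly"),
                                  input_length = 300L,
                                  n_classes = 6L,
                                  latent_dim = 32L,
                                  label_embedding_dim = 32L,
                                  scaling_alpha = NULL,
                                  dropout = 0.25) {
  flavor <- match.arg(flavor)
  if (!input_length %in% c(300L, 500L)) abort("`input_length` must be 300 or 500.")
  scaling_alpha <- scaling_alpha %||% if (flavor == "cvae_normal") 1.5 else 5
  if (scaling_alpha <= 0) abort("`scaling_alpha` must be positive.")
  structure(list(flavor = flavor, input_length = as.integer(input_length),
                 n_classes = as.integer(n_classes),
                 latent_dim = as.integer(latent_dim),
                 label_embedding_dim = as.integer(label_embedding_dim),
                 scaling_alpha = scaling_alpha, dropout = dropout),
            class = "generative_model_spec")
}

# ladder geometry per working length
gen_ladder <- function(L) {
  if (L == 500L) {
    list(enc = c(500L, 250L, 125L, 63L), dec_s0 = 64L,
         dec = list(list(len = 63L, k = 2L, s = 1L, p = 1L),
                    list(len = 125L, k = 3L, s = 2L, p = 1L),
                    list(len = 249L, k = 3L, s = 2L, p = 1L),
                    list(len = 500L, k = 6L, s = 2L, p = 1L)))
  } else {
    list(enc = c(300L, 150L, 75L, 38L), dec_s0 = 32L,
         dec = list(list(len = 38L, k = 7L, s = 1L, p = 0L),
                    list(len = 75L, k = 3L, s = 2L, p = 1L),
                    list(len = 150L, k = 4L, s = 2L, p = 1L),
                    list(len = 300L, k = 4L, s = 2L, p = 1L)))
  }
}

#' Layer ledger of a generative model
#'
#' Tabulates the realized per-stage output sizes (spatial length x
#' channels) of the encoder and decoder ladders for a given working
#' length and flavor.
#'
#' @param input_length 300 or 500.
#' @param flavor `"cvae_normal"` or `"vae_anomaly"`.
#' @return a tibble with `module`, `stage`, `spatial`, `channels`.
#' @export
generative_layer_ledger <- function(input_length = 300L,
                                    flavor = c("cvae_normal", "vae_anomaly")) {
  flavor <- match.arg(flavor)
  lad <- gen_ladder(as.integer(input_length))
  cvae <- flavor == "cvae_normal"
  enc <- tibble::tibble(
    module = "encoder",
    stage = c("input", if (cvae) "label_concat", "conv1", "conv_block2",
              "conv_block3", "fc", "sampling"),
    spatial = c(lad$enc[1], if (cvae) lad$enc[1], lad$enc[2], lad$enc[3],
                lad$enc[4], 1L, 1L),
    channels = c(1L, if (cvae) 2L, 16L, 16L, 16L, 64L, 32L)
  )
  dec_lens <- vapply(lad$dec, `[[`, integer(1), "len")
  dec <- tibble::tibble(
    module = "decoder",
    stage = c("latent", "reshape", if (cvae) "label_concat", "deconv1",
              "deconv_block2", "deconv_block3", "deconv_out", "scaling"),
    spatial = c(1L, lad$dec_s0, if (cvae) lad$dec_s0, dec_lens, dec_lens[4]),
    channels = c(32L, 64L, if (cvae) 65L, 16L, 16L, 16L, 1L, 1L)
  )
  dplyr::bind_rows(enc, dec)
}

# ---- network construction ----------------------------------------------

build_generator <- function(spec, seed = 1L) {
  set.seed(seed)
  L <- spec$input_length
  lad <- gen_ladder(L)
  cvae <- spec$flavor == "cvae_normal"
  C_in <- if (cvae) 2L else 1L
  g1 <- conv_geom(lad$enc[1], 1L, C_in, 5L, 1L, 2L, 0L, 2L, 1L)
  g2a <- conv_geom(lad$enc[2], 1L, 16L, 5L, 1L, 2L, 0L, 2L, 1L)
  g2b <- conv_geom(lad$enc[3], 1L, 16L, 5L, 1L, 2L, 0L, 1L, 1L)
  g3a <- conv_geom(lad$enc[3], 1L, 16L, 5L, 1L, 2L, 0L, 2L, 1L)
  g3b <- conv_geom(lad$enc[4], 1L, 16L, 5L, 1L, 2L, 0L, 1L, 1L)
  stopifnot(g1$Hout == lad$enc[2], g2a$Hout == lad$enc[3], g3a$Hout == lad$enc[4])
  s0 <- lad$dec_s0
  dC_in <- if (cvae) 65L else 64L
  d1 <- c(convT1d_geom(s0, dC_in, 16L, lad$dec[[1]]$k, lad$dec[[1]]$s, lad$dec[[1]]$p))
  d2a <- convT1d_geom(lad$dec[[1]]$len, 16L, 16L, lad$dec[[2]]$k, lad$dec[[2]]$s, lad$dec[[2]]$p)
  d2b <- conv_geom(lad$dec[[2]]$len, 1L, 16L, 5L, 1L, 2L, 0L, 1L, 1L)
  d3a <- convT1d_geom(lad$dec[[2]]$len, 16L, 16L, lad$dec[[3]]$k, lad$dec[[3]]$s, lad$dec[[3]]$p)
  d3b <- conv_geom(lad$dec[[3]]$len, 1L, 16L, 5L, 1L, 2L, 0L, 1L, 1L)
  d4 <- convT1d_geom(lad$dec[[3]]$len, 16L, 1L, lad$dec[[4]]$k, lad$dec[[4]]$s, lad$dec[[4]]$p)
  stopifnot(d1$L_out == lad$dec[[1]]$len, d2a$L_out == lad$dec[[2]]$len,
            d3a$L_out == lad$dec[[3]]$len, d4$L_out == L)
  params <- list(
    e_fc0 = dense_init(L, L),
    e_conv1 = conv2d_init(g1, 16L),
    e_conv2a = conv2d_init(g2a, 16L), e_conv2b = conv2d_init(g2b, 16L),
    e_conv3a = conv2d_init(g3a, 16L), e_conv3b = conv2d_init(g3b, 16L),
    e_fc = dense_init(lad$enc[4] * 16L, 2L * spec$latent_dim),
    d_fc_z = dense_init(spec$latent_dim, s0 * 64L),
    d_1 = convT1d_init(d1),
    d_2a = convT1d_init(d2a), d_2b = conv2d_init(d2b, 16L),
    d_3a = convT1d_init(d3a), d_3b = conv2d_init(d3b, 16L),
    d_4 = convT1d_init(d4)
  )
  if (cvae) {
    params$e_emb <- glorot(spec$n_classes, spec$label_embedding_dim)
    params$e_lab_fc <- dense_init(spec$label_embedding_dim, L)
    params$d_emb <- glorot(spec$n_classes, spec$label_embedding_dim)
    params$d_lab_fc <- dense_init(spec$label_embedding_dim, s0)
  }
  geoms <- list(g1 = g1, g2a = g2a, g2b = g2b, g3a = g3a, g3b = g3b,
                d1 = d1, d2a = d2a, d2b = d2b, d3a = d3a, d3b = d3b, d4 = d4,
                s0 = s0, enc = lad$enc)
  list(spec = spec, params = params, geoms = geoms)
}

as_img <- function(X3) { # B x L x C -> B x L x 1 x C
  d <- dim(X3); dim(X3) <- c(d[1], d[2], 1L, d[3]); X3
}
as_seq <- function(X4) { # B x L x 1 x C -> B x L x C
  d <- dim(X4); dim(X4) <- c(d[1], d[2], d[4]); X4
}

res_block_enc_forward <- function(X, pa, pb, ga, gb, a, prob, training) {
  ca <- conv2d_forward(X, pa, ga)
  cb <- conv2d_forward(ca$Y, pb, gb)
  S <- ca$Y + cb$Y
  A <- lrelu(S, a)
  dp <- dropout_forward(A, prob, training)
  list(Y = dp$Y, ca = ca, cb = cb, S = S, mask = dp$mask)
}

res_block_enc_backward <- function(dY, cache, pa, pb, ga, gb, a) {
  if (!is.null(cache$mask)) dY <- dY * cache$mask
  dS <- lrelu_grad(dY, cache$S, a)
  bb <- conv2d_backward(dS, cache$cb, pb, gb, need_dx = TRUE)
  dA_out <- dS + bb$dX
  ba <- conv2d_backward(dA_out, cache$ca, pa, ga, need_dx = TRUE)
  list(dX = ba$dX, ga_grads = ba$grads, gb_grads = bb$grads)
}

encoder_forward <- function(model, x, labels, training, eps = NULL) {
  p <- model$params; g <- model$geoms; spec <- model$spec
  a <- 0.1; prob <- spec$dropout
  B <- nrow(x)
  xf <- dense_forward(x, p$e_fc0)                       # B x L
  chans <- array(xf, c(B, ncol(x), 1L, 1L))
  lab_cache <- NULL
  if (spec$flavor == "cvae_normal") {
    E <- p$e_emb[labels, , drop = FALSE]                 # B x 32
    lab <- dense_forward(E, p$e_lab_fc)                  # B x L
    both <- array(0, c(B, ncol(x), 1L, 2L))
    both[, , 1L, 1L] <- xf
    both[, , 1L, 2L] <- lab
    chans <- both
    lab_cache <- list(E = E)
  }
  c1 <- conv2d_forward(chans, p$e_conv1, g$g1)
  a1 <- lrelu(c1$Y, a)
  dp1 <- dropout_forward(a1, prob, training)
  b2 <- res_block_enc_forward(dp1$Y, p$e_conv2a, p$e_conv2b, g$g2a, g$g2b, a, prob, training)
  b3 <- res_block_enc_forward(b2$Y, p$e_conv3a, p$e_conv3b, g$g3a, g$g3b, a, prob, training)
  flat <- b3$Y
  dim(flat) <- c(B, g$enc[4] * 16L)
  enc_out <- dense_forward(flat, p$e_fc)                 # B x 64
  samp <- sampling_layer(enc_out, epsilon = eps)
  list(samp = samp, enc_out = enc_out, cache = list(
    x = x, xf = xf, chans = chans, lab = lab_cache, c1 = c1, a1_pre = c1$Y,
    mask1 = dp1$mask, b2 = b2, b3 = b3, flat = flat, labels = labels
  ))
}

encoder_backward <- function(model, denc_out, cache) {
  p <- model$params; g <- model$geoms; spec <- model$spec
  a <- 0.1
  B <- nrow(denc_out)
  grads <- list()
  bk_fc <- dense_backward(denc_out, cache$flat, p$e_fc)
  grads$e_fc <- bk_fc$grads
  dflat <- bk_fc$dX
  dim(dflat) <- c(B, g$enc[4], 1L, 16L)
  b3 <- res_block_enc_backward(dflat, cache$b3, p$e_conv3a, p$e_conv3b, g$g3a, g$g3b, a)
  grads$e_conv3a <- b3$ga_grads; grads$e_conv3b <- b3$gb_grads
  b2 <- res_block_enc_backward(b3$dX, cache$b2, p$e_conv2a, p$e_conv2b, g$g2a, g$g2b, a)
  grads$e_conv2a <- b2$ga_grads; grads$e_conv2b <- b2$gb_grads
  d1 <- b2$dX
  if (!is.null(cache$mask1)) d1 <- d1 * cache$mask1
  dPre1 <- lrelu_grad(d1, cache$a1_pre, a)
  bc1 <- conv2d_backward(dPre1, cache$c1, p$e_conv1, g$g1, need_dx = TRUE)
  grads$e_conv1 <- bc1$grads
  dchan <- bc1$dX                                        # B x L x 1 x C
  dxf <- matrix(dchan[, , 1L, 1L], nrow = B)
  if (spec$flavor == "cvae_normal") {
    dlab <- matrix(dchan[, , 1L, 2L], nrow = B)
    bk_lab <- dense_backward(dlab, cache$lab$E, p$e_lab_fc)
    grads$e_lab_fc <- bk_lab$grads
    dE <- bk_lab$dX
    demb <- matrix(0, spec$n_classes, spec$label_embedding_dim)
    agg <- rowsum(dE, group = cache$labels)
    demb[as.integer(rownames(agg)), ] <- agg
    grads$e_emb <- demb
  }
  bk0 <- dense_backward(dxf, cache$x, p$e_fc0)
  grads$e_fc0 <- bk0$grads
  grads
}

decoder_forward <- function(model, z, labels, training) {
  p <- model$params; g <- model$geoms; spec <- model$spec
  a <- 0.1; prob <- spec$dropout
  B <- nrow(z)
  s0 <- g$s0
  hz <- dense_forward(z, p$d_fc_z)                      # B x (s0*64)
  cur <- array(hz, c(B, s0, 64L))
  lab_cache <- NULL
  if (spec$flavor == "cvae_normal") {
    E <- p$d_emb[labels, , drop = FALSE]
    lab <- dense_forward(E, p$d_lab_fc)                 # B x s0
    full <- array(0, c(B, s0, 65L))
    full[, , seq_len(64L)] <- cur
    full[, , 65L] <- lab
    cur <- full
    lab_cache <- list(E = E)
  }
  y1 <- convT1d_forward(cur, p$d_1, g$d1)
  a1 <- lrelu(y1, a)
  dp1 <- dropout_forward(a1, prob, training)
  # residual refinement block 2
  u2 <- convT1d_forward(dp1$Y, p$d_2a, g$d2a)
  c2 <- conv2d_forward(as_img(u2), p$d_2b, g$d2b)
  s2 <- u2 + as_seq(c2$Y)
  a2 <- lrelu(s2, a)
  dp2 <- dropout_forward(a2, prob, training)
  # residual refinement block 3
  u3 <- convT1d_forward(dp2$Y, p$d_3a, g$d3a)
  c3 <- conv2d_forward(as_img(u3), p$d_3b, g$d3b)
  s3 <- u3 + as_seq(c3$Y)
  a3 <- lrelu(s3, a)
  dp3 <- dropout_forward(a3, prob, training)
  pre <- convT1d_forward(dp3$Y, p$d_4, g$d4)            # B x L x 1
  pre <- matrix(pre, nrow = B)
  out <- scaling_layer(pre, spec$scaling_alpha)
  list(out = out, cache = list(
    z = z, lab = lab_cache, labels = labels, cur0 = cur,
    y1 = y1, mask1 = dp1$mask, x1 = dp1$Y,
    u2 = u2, c2 = c2, s2 = s2, mask2 = dp2$mask, x2 = dp2$Y,
    u3 = u3, c3 = c3, s3 = s3, mask3 = dp3$mask, x3 = dp3$Y,
    pre = pre
  ))
}

decoder_backward <- function(model, dout, cache) {
  p <- model$params; g <- model$geoms; spec <- model$spec
  a <- 0.1
  B <- nrow(dout)
  grads <- list()
  th <- tanh(cache$pre)
  dpre <- dout * spec$scaling_alpha * (1 - th^2)
  dpre3 <- array(dpre, c(B, ncol(dpre), 1L))
  bk4 <- convT1d_backward(dpre3, cache$x3, p$d_4, g$d4)
  grads$d_4 <- bk4$grads
  dx3 <- bk4$dX
  if (!is.null(cache$mask3)) dx3 <- dx3 * cache$mask3
  ds3 <- lrelu_grad(dx3, cache$s3, a)
  bc3 <- conv2d_backward(as_img(ds3), cache$c3, p$d_3b, g$d3b, need_dx = TRUE)
  grads$d_3b <- bc3$grads
  du3 <- ds3 + as_seq(bc3$dX)
  bk3a <- convT1d_backward(du3, cache$x2, p$d_3a, g$d3a)
  grads$d_3a <- bk3a$grads
  dx2 <- bk3a$dX
  if (!is.null(cache$mask2)) dx2 <- dx2 * cache$mask2
  ds2 <- lrelu_grad(dx2, cache$s2, a)
  bc2 <- conv2d_backward(as_img(ds2), cache$c2, p$d_2b, g$d2b, need_dx = TRUE)
  grads$d_2b <- bc2$grads
  du2 <- ds2 + as_seq(bc2$dX)
  bk2a <- convT1d_backward(du2, cache$x1, p$d_2a, g$d2a)
  grads$d_2a <- bk2a$grads
  dx1 <- bk2a$dX
  if (!is.null(cache$mask1)) dx1 <- dx1 * cache$mask1
  dy1 <- lrelu_grad(dx1, cache$y1, a)
  bk1 <- convT1d_backward(dy1, cache$cur0, p$d_1, g$d1)
  grads$d_1 <- bk1$grads
  dcur <- bk1$dX                                        # B x s0 x C
  if (spec$flavor == "cvae_normal") {
    dlab <- matrix(dcur[, , 65L], nrow = B)
    bk_lab <- dense_backward(dlab, cache$lab$E, p$d_lab_fc)
    grads$d_lab_fc <- bk_lab$grads
    demb <- matrix(0, spec$n_classes, spec$label_embedding_dim)
    agg <- rowsum(bk_lab$dX, group = cache$labels)
    demb[as.integer(rownames(agg)), ] <- agg
    grads$d_emb <- demb
    dcur <- dcur[, , seq_len(64L), drop = FALSE]
  }
  dhz <- dcur
  dim(dhz) <- c(B, g$s0 * 64L)
  bkz <- dense_backward(dhz, cache$z, p$d_fc_z)
  grads$d_fc_z <- bkz$grads
  list(grads = grads, dz = bkz$dX)
}

generator_step <- function(model, x, labels, beta, training = TRUE, eps = NULL) {
  spec <- model$spec
  B <- nrow(x)
  enc <- encoder_forward(model, x, labels, training, eps = eps)
  samp <- enc$samp
  dec <- decoder_forward(model, samp$z, labels, training)
  L <- ncol(x)
  kl <- mean(0.5 * rowSums(exp(samp$log_var) + samp$mu_z^2 - 1 - samp$log_var))
  recon <- mean((dec$out - x)^2)
  loss <- beta * kl + recon
  if (!training) return(list(loss = loss, kl = kl, recon = recon, out = dec$out))
  dout <- 2 * (dec$out - x) / (B * L)
  bk_dec <- decoder_backward(model, dout, dec$cache)
  dz <- bk_dec$dz
  dmu <- dz + beta * samp$mu_z / B
  dlv <- dz * samp$epsilon * samp$sigma_z / 2 + beta * (exp(samp$log_var) - 1) / (2 * B)
  denc_out <- cbind(dmu, dlv)
  grads_enc <- encoder_backward(model, denc_out, enc$cache)
  grads <- c(grads_enc, bk_dec$grads)[names(model$params)]
  list(loss = loss, kl = kl, recon = recon, out = dec$out, grads = grads)
}

#' Training configuration for the generative stage
#'
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param learning_rate Adam learning rate.
#' @param beta KL weight in the minimized objective.
#' @param val_fraction fraction held out for validation (default 0.2).
#' @return an object of class `gen_train_config`.
#' @export
gen_train_config <- function(epochs = 60L, batch_size = 64L,
                             learning_rate = 2e-3, beta = 1,
                             val_fraction = 0.2) {
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, beta = beta,
                 val_fraction = val_fraction),
            class = "gen_train_config")
}

#' Train a segment generator
#'
#' Trains the CVAE (label-conditioned, normal segments) or VAE (anomaly
#' segments) of a [generative_model_spec()] by minibatch Adam on the
#' evidence-lower-bound objective ([elbo_loss()]). A validation fraction
#' is held out and its reconstruction error recorded per epoch.
#' Deterministic given `seed`.
#'
#' @param spec a [generative_model_spec()].
#' @param segments an `apta_segments` tibble whose `values` all have
#'   length `spec$input_length`, or a numeric matrix (rows = segments).
#' @param labels integer class labels in `1..n_classes`; required for the
#'   CVAE, forbidden for the VAE.
#' @param config a [gen_train_config()].
#' @param seed integer seed.
#' @return an object of class `apta_generator` with elements `spec`,
#'   `params`, `history` (tibble of epoch, train loss, KL, reconstruction,
#'   validation MSE) and `label_info` (per-label metadata when trained
#'   from a segment table).
#' @export
train_generator <- function(spec, segments, labels = NULL,
                            config = gen_train_config(), seed = 1L) {
  stopifnot(inherits(spec, "generative_model_spec"))
  label_info <- NULL
  if (is.matrix(segments)) {
    x <- segments
  } else {
    x <- do.call(rbind, segments$values)
    if (!is.null(labels) && !is.null(segments$concentration)) {
      label_info <- dplyr::distinct(tibble::tibble(
        label = labels,
        concentration = segments$concentration,
        dataset_id = segments$dataset_id
      ))
    }
  }
  if (nrow(x) == 0) abort("empty training set.")
  if (ncol(x) != spec$input_length) {
    abort("segment length does not match `spec$input_length`.")
  }
  cvae <- spec$flavor == "cvae_normal"
  if (cvae && is.null(labels)) abort("the CVAE requires class `labels`.")
  if (!cvae && !is.null(labels)) abort("the VAE is unconditional; do not pass `labels`.")
  if (cvae && (any(labels < 1) || any(labels > spec$n_classes))) {
    abort("labels must lie in 1..n_classes.")
  }
  set.seed(seed)
  model <- build_generator(spec, seed = seed)
  opt <- adam_init(model$params)
  B <- nrow(x)
  n_val <- max(1L, min(B - 1L, round(config$val_fraction * B)))
  val_idx <- sample.int(B, n_val)
  tr_idx <- setdiff(seq_len(B), val_idx)
  hist <- list()
  for (e in seq_len(config$epochs)) {
    ord <- sample(tr_idx)
    ep <- c(loss = 0, kl = 0, recon = 0); nb <- 0L
    for (start in seq(1L, length(ord), by = config$batch_size)) {
      rows <- ord[start:min(start + config$batch_size - 1L, length(ord))]
      st <- generator_step(model, x[rows, , drop = FALSE],
                           if (cvae) labels[rows], config$beta, training = TRUE)
      upd <- adam_step(model$params, st$grads, opt, lr = config$learning_rate)
      model$params <- upd$params
      opt <- upd$state
      ep <- ep + c(st$loss, st$kl, st$recon); nb <- nb + 1L
    }
    vl <- generator_step(model, x[val_idx, , drop = FALSE],
                         if (cvae) labels[val_idx], config$beta, training = FALSE)
    hist[[e]] <- tibble::tibble(epoch = e, loss = ep[1] / nb, kl = ep[2] / nb,
                                recon = ep[3] / nb, val_recon = vl$recon)
  }
  structure(list(spec = spec, params = model$params, geoms = model$geoms,
                 history = dplyr::bind_rows(hist), label_info = label_info,
                 seed = seed),
            class = "apta_generator")
}

#' Reconstruct segments with a trained generator
#'
#' Encodes and decodes segments (posterior mean, no sampling noise);
#' useful for reporting reconstruction error on held-out data.
#'
#' @param model an `apta_generator`.
#' @param x numeric matrix of segments (rows).
#' @param labels integer labels (CVAE only).
#' @return matrix of reconstructions, same shape as `x`.
#' @export
reconstruct_segments <- function(model, x, labels = NULL) {
  cvae <- model$spec$flavor == "cvae_normal"
  eps <- matrix(0, nrow(x), model$spec$latent_dim)
  enc <- encoder_forward(model, x, if (cvae) labels, training = FALSE, eps = eps)
  dec <- decoder_forward(model, enc$samp$z, if (cvae) labels, training = FALSE)
  dec$out
}

#' Generate new segments from a trained generator
#'
#' Drives the decoder with standard-normal latent draws (plus the class
#' embedding for the CVAE). Because the decoder ends in the bounded
#' [scaling_layer()], every generated value lies strictly inside
#' `(-alpha, alpha)`.
#'
#' @param model an `apta_generator` from [train_generator()].
#' @param label integer class label (required for a CVAE model, forbidden
#'   for a VAE model).
#' @param count number of segments to generate.
#' @param seed integer seed.
#' @return an `apta_segments` tibble of `count` rows flagged
#'   `augmented = TRUE`.
#' @export
generate_segments <- function(model, label = NULL, count, seed = 1L) {
  stopifnot(inherits(model, "apta_generator"))
  cvae <- model$spec$flavor == "cvae_normal"
  if (cvae && is.null(label)) abort("a CVAE model needs a `label`.")
  if (!cvae && !is.null(label)) abort("a VAE model takes no `label`.")
  if (cvae && (label < 1 || label > model$spec$n_classes)) {
    abort("label out of range.")
  }
  if (count == 0) {
    out <- tibble::tibble(segment_id = character(), signal_id = character(),
                          dataset_id = character(), concentration = numeric(),
                          is_anomaly = logical(), augmented = logical(),
                          extrapolated = logical(), n = integer(),
                          values = list())
    class(out) <- c("apta_segments", class(out))
    return(out)
  }
  set.seed(seed)
  z <- matrix(rnorm(count * model$spec$latent_dim), count)
  labs <- if (cvae) rep(as.integer(label), count)
  dec <- decoder_forward(model, z, labs, training = FALSE)
  conc <- NA_real_; dsid <- NA_character_
  if (!is.null(model$label_info) && cvae) {
    hit <- model$label_info[model$label_info$label == label, ]
    if (nrow(hit) >= 1) { conc <- hit$concentration[1]; dsid <- hit$dataset_id[1] }
  }
  out <- tibble::tibble(
    segment_id = sprintf("aug_%s_%d_%03d",
                         if (cvae) paste0("c", label) else "anom", seed, seq_len(count)),
    signal_id = NA_character_,
    dataset_id = dsid,
    concentration = conc,
    is_anomaly = !cvae,
    augmented = TRUE,
    extrapolated = FALSE,
    n = model$spec$input_length,
    values = lapply(seq_len(count), function(i) dec$out[i, ])
  )
  class(out) <- c("apta_segments", class(out))
  out
}

#' Top up every class to a fixed total with generated segments
#'
#' For each class present in `labels`, generates enough segments from the
#' CVAE so that original plus augmented counts reach `total_per_class`.
#'
#' @param segments the original `apta_segments` tibble.
#' @param labels integer class labels parallel to `segments`.
#' @param model a trained CVAE `apta_generator`.
#' @param total_per_class target per-class total (reference setting 200).
#' @param seed integer seed.
#' @return the combined `apta_segments` tibble with a `label` column.
#' @export
augment_to_total <- function(segments, labels, model, total_per_class = 200L,
                             seed = 1L) {
  segments$label <- labels
  parts <- list(segments)
  for (cl in sort(unique(labels))) {
    need <- total_per_class - sum(labels == cl)
    if (need > 0) {
      gen <- generate_segments(model, label = cl, count = need, seed = seed + cl)
      gen$label <- cl
      parts[[length(parts) + 1L]] <- gen
    }
  }
  out <- dplyr::bind_rows(parts)
  class(out) <- c("apta_segments", setdiff(class(out), "apta_segments"))
  out
}

#' @rdname train_generator
#' @param x an `apta_generator`.
#' @param ... unused.
#' @exportS3Method
glance.apta_generator <- function(x, ...) {
  h <- x$history
  tibble::tibble(flavor = x$spec$flavor, input_length = x$spec$input_length,
                 scaling_alpha = x$spec$scaling_alpha,
                 n_learnable = n_params(x$params),
                 epochs = nrow(h),
                 final_val_recon = if (nrow(h)) h$val_recon[nrow(h)] else NA_real_)
}

#' @rdname train_generator
#' @exportS3Method
tidy.apta_generator <- function(x, ...) x$history
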