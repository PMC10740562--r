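#' Output length of a 1-D convolution
#'
#' Standard valid-convolution arithmetic
#' `floor((l_prev + 2 p - filter_size) / s) + 1`: the number of filter
#' placements along an axis of length `l_prev` with padding `p` and stride
#' `s`.
#'
#' @param l_prev input length.
#' @param filter_size filter length.
#' @param p padding per side.
#' @param s stride.
#' @return integer output length.
#' @examples
#' conv_output_length(300, 5, 1, 1)  # 298
#' @export
conv_output_length <- function(l_prev, filter_size, p = 1L, s = 1L) {
  if (s < 1) abort("stride must be >= 1.")
  if (l_prev + 2 * p < filter_size) abort("filter does not fit the padded input.")
  as.integer((l_prev + 2 * p - filter_size) %/% s + 1L)
}

#' Classifier architecture descriptor
#'
#' Describes one of the seven classification networks: three plain
#' recurrent networks (`GRU`, `ULSTM`, `BLSTM`: sequence input, recurrent
#' layer with `n` hidden units, fully connected layer to `m` classes,
#' softmax); three convolutional-recurrent hybrids (`ConvGRU`,
#' `ConvULSTM`, `ConvBLSTM`: a 2-D convolution with `n_filters` filters
#' and leaky-ReLU in front, flattened to width `k = lc x nf` feeding the
#' recurrent layer); and a pure `CNN` (a first convolution plus five
#' ConvBlocks -- convolution, leaky-ReLU, dropout -- with the filter-count
#' ladder 32, 16, 8, 8, 16, 32, then a fully connected softmax head).
#'
#' Input adaptation: raw sequences enter the recurrent networks as scalar
#' sequences (input width 1) and the convolutional networks as `ls x 1`
#' single-channel images with 5 x 1 kernels. Spectrograms enter the
#' recurrent networks as 128-feature frame sequences, the ConvRNNs as
#' `128 x F` images with 5 x 5 kernels, and the CNN with a time-axis
#' kernel width that adapts per layer (the full 5 while the short frame
#' axis supports it, collapsing that axis to one, then 1-D kernels); the
#' frequency axis follows the printed `lc` arithmetic, shrinking by two
#' rows per layer, so the head width is `k = lc6 x nf1`.
#'
#' @param arch one of `"GRU"`, `"ULSTM"`, `"BLSTM"`, `"ConvGRU"`,
#'   `"ConvULSTM"`, `"ConvBLSTM"`, `"CNN"`.
#' @param input_mode `"raw_sequence"` or `"spectrogram"`.
#' @param segment_length working segment length `ls` (300 or 500).
#' @param n_classes number of classes `m` (6 for C1, 12 for C2).
#' @param hidden_units recurrent hidden units `n` (default 128).
#' @param filter_size convolution filter size `sf` (default 5).
#' @param n_filters ConvRNN filter count `nf` (default 32).
#' @param cnn_filters CNN filter ladder (default `c(32,16,8,8,16,32)`).
#' @param padding convolution padding `p` (default 1).
#' @param stride convolution stride `s` (default 1).
#' @param lrelu_slope leaky-ReLU negative slope (default 0.1).
#' @param dropout CNN dropout probability (default 0.25).
#' @param n_freq spectrogram frequency rows (default 128).
#' @return an object of class `classifier_spec`.
#' @export
classifier_spec <- function(arch = c("GRU", "ULSTM", "BLSTM", "ConvGRU",
                                     "ConvULSTM", "ConvBLSTM", "CNN"),
                            input_mode = c("raw_sequence", "spectrogram"),
                            segment_length = 300L,
                            n_classes = 6L,
                            hidden_units = 128L,
                            filter_size = 5L,
                            n_filters = 32L,
                            cnn_filters = c(32L, 16L, 8L, 8L, 16L, 32L),
                            padding = 1L,
                            stride = 1L,
                            lrelu_slope = 0.1,
                            dropout = 0.25,
                            n_freq = 128L) {
  arch <- match.arg(arch)
  input_mode <- match.arg(input_mode)
  if (!segment_length %in% c(166L, 300L, 500L)) {
    warn("unusual `segment_length`; the working lengths are 166, 300 and 500.")
  }
  structure(list(arch = arch, input_mode = input_mode,
                 segment_length = as.integer(segment_length),
                 n_classes = as.integer(n_classes),
                 hidden_units = as.integer(hidden_units),
                 filter_size = as.integer(filter_size),
                 n_filters = as.integer(n_filters),
                 cnn_filters = as.integer(cnn_filters),
                 padding = as.integer(padding), stride = as.integer(stride),
                 lrelu_slope = lrelu_slope, dropout = dropout,
                 n_freq = as.integer(n_freq)),
            class = "classifier_spec")
}

spec_n_frames <- function(spec) {
  1L + (spec$segment_length - 128L) %/% 64L
}

input_image_dims <- function(spec) {
  if (spec$input_mode == "raw_sequence") {
    c(spec$segment_length, 1L)
  } else {
    c(spec$n_freq, spec_n_frames(spec))
  }
}

rnn_variant_of <- function(arch) sub("^Conv", "", arch)

#' Build a classifier
#'
#' Instantiates the network described by a [classifier_spec()] with
#' seed-controlled Glorot initialization and resolves all layer
#' geometries.
#'
#' @param spec a [classifier_spec()].
#' @param seed integer seed.
#' @return an object of class `apta_classifier`.
#' @export
build_classifier <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "classifier_spec"))
  set.seed(seed)
  n <- spec$hidden_units
  m <- spec$n_classes
  sf <- spec$filter_size
  model <- list(spec = spec, opt = NULL, history = numeric(0))
  if (spec$arch %in% c("GRU", "ULSTM", "BLSTM")) {
    d <- if (spec$input_mode == "raw_sequence") 1L else spec$n_freq
    v <- spec$arch
    model$params <- list(
      rnn = rnn_init(v, d, n),
      fc = dense_init(rnn_out_width(v, n), m)
    )
  } else if (spec$arch %in% c("ConvGRU", "ConvULSTM", "ConvBLSTM")) {
    hw <- input_image_dims(spec)
    kw <- if (spec$input_mode == "raw_sequence") 1L else sf
    pw <- if (kw == 1L) 0L else spec$padding
    g <- conv_geom(hw[1], hw[2], 1L, sf, kw, spec$padding, pw,
                   spec$stride, spec$stride)
    k <- g$Hout * g$Wout * spec$n_filters
    v <- rnn_variant_of(spec$arch)
    model$geom <- g
    model$k <- k
    model$params <- list(
      conv = conv2d_init(g, spec$n_filters),
      rnn = rnn_init(v, k, n),
      fc = dense_init(rnn_out_width(v, n), m)
    )
  } else { # CNN
    hw <- input_image_dims(spec)
    geoms <- vector("list", 6L)
    params <- vector("list", 6L)
    H <- hw[1]; W <- hw[2]; C <- 1L
    for (i in seq_len(6L)) {
      if (spec$input_mode == "raw_sequence" || W == 1L) {
        kw <- 1L; pw <- 0L
      } else {
        # time axis: full 5-wide kernel while it fits (collapsing the short
        # axis, after which kernels are 1-D); frequency axis follows the
        # printed lc arithmetic throughout
        kw <- min(sf, W + 2L)
        pw <- 1L
      }
      g <- conv_geom(H, W, C, sf, kw, spec$padding, pw, spec$stride, spec$stride)
      geoms[[i]] <- g
      params[[i]] <- conv2d_init(g, spec$cnn_filters[i])
      H <- g$Hout; W <- g$Wout; C <- spec$cnn_filters[i]
    }
    names(params) <- paste0("conv", seq_len(6L))
    k <- H * W * C
    model$geoms <- geoms
    model$k <- k
    model$params <- c(params, list(fc = dense_init(k, m)))
  }
  structure(model, class = "apta_classifier")
}

classifier_forward <- function(model, X, training = FALSE) {
  spec <- model$spec
  n <- spec$hidden_units
  a <- spec$lrelu_slope
  cache <- list()
  # image-input networks standardize each input element with its training
  # mean and spread
  if (!is.null(model$input_mean)) {
    B <- dim(X)[1]
    X <- (X - array(rep(model$input_mean, each = B), dim(X))) /
      array(rep(model$input_sd, each = B), dim(X))
  }
  if (spec$arch %in% c("GRU", "ULSTM", "BLSTM")) {
    if (spec$input_mode == "raw_sequence") {
      X <- array(X, c(nrow(X), ncol(X), 1L))
    } else {
      X <- aperm(X, c(1L, 3L, 2L))   # frames become time, 128 freq features
    }
    fwd <- rnn_forward(spec$arch, X, model$params$rnn, n)
    T_ <- dim(X)[2]
    h_last <- if (spec$arch == "BLSTM") {
      cbind(fwd$f$H[[T_]], fwd$b$H[[1L]])
    } else fwd$H[[T_]]
    logits <- dense_forward(h_last, model$params$fc)
    cache <- list(kind = "rnn", fwd = fwd, h_last = h_last, T_ = T_)
  } else if (spec$arch %in% c("ConvGRU", "ConvULSTM", "ConvBLSTM")) {
    B <- dim(X)[1]
    if (length(dim(X)) == 3L) dim(X) <- c(dim(X), 1L)
    if (spec$input_mode == "raw_sequence") dim(X) <- c(B, ncol(X), 1L, 1L)
    cv <- conv2d_forward(X, model$params$conv, model$geom)
    A <- lrelu(cv$Y, a)
    F_ <- A
    dim(F_) <- c(B, model$k)
    S <- array(F_, c(B, 1L, model$k))
    v <- rnn_variant_of(spec$arch)
    fwd <- rnn_forward(v, S, model$params$rnn, n)
    h <- if (v == "BLSTM") cbind(fwd$f$H[[1L]], fwd$b$H[[1L]]) else fwd$H[[1L]]
    h_act <- lrelu(h, a)
    logits <- dense_forward(h_act, model$params$fc)
    cache <- list(kind = "convrnn", conv = cv, conv_pre = cv$Y, Fmat = F_,
                  fwd = fwd, h = h, h_act = h_act, v = v)
  } else { # CNN
    B <- dim(X)[1]
    if (spec$input_mode == "raw_sequence") {
      dim(X) <- c(B, ncol(X), 1L, 1L)
    } else if (length(dim(X)) == 3L) {
      dim(X) <- c(dim(X), 1L)
    }
    acts <- vector("list", 6L)
    cur <- X
    for (i in seq_len(6L)) {
      cv <- conv2d_forward(cur, model$params[[paste0("conv", i)]], model$geoms[[i]])
      A <- lrelu(cv$Y, a)
      dp <- dropout_forward(A, spec$dropout, training)
      acts[[i]] <- list(conv = cv, pre = cv$Y, mask = dp$mask)
      cur <- dp$Y
    }
    Fmat <- cur
    dim(Fmat) <- c(B, model$k)
    logits <- dense_forward(Fmat, model$params$fc)
    cache <- list(kind = "cnn", acts = acts, Fmat = Fmat)
  }
  list(logits = logits, cache = cache)
}

classifier_backward <- function(model, X, fwd, dlogits) {
  spec <- model$spec
  n <- spec$hidden_units
  a <- spec$lrelu_slope
  cache <- fwd$cache
  if (cache$kind == "rnn") {
    bk_fc <- dense_backward(dlogits, cache$h_last, model$params$fc)
    T_ <- cache$T_
    dH <- vector("list", T_)
    if (spec$arch == "BLSTM") {
      dH[[T_]] <- cbind(bk_fc$dX[, seq_len(n), drop = FALSE], matrix(0, nrow(dlogits), n))
      dH[[1L]] <- cbind(matrix(0, nrow(dlogits), n), bk_fc$dX[, n + seq_len(n), drop = FALSE])
      if (T_ == 1L) dH[[1L]] <- bk_fc$dX
    } else {
      dH[[T_]] <- bk_fc$dX
    }
    bk <- rnn_backward(spec$arch, dH, cache$fwd, model$params$rnn, n)
    list(rnn = bk$grads, fc = bk_fc$grads)
  } else if (cache$kind == "convrnn") {
    bk_fc <- dense_backward(dlogits, cache$h_act, model$params$fc)
    dh <- lrelu_grad(bk_fc$dX, cache$h, a)
    v <- cache$v
    dH <- list(if (v == "BLSTM") dh else dh)
    bk_rnn <- rnn_backward(v, dH, cache$fwd, model$params$rnn, n)
    dS <- bk_rnn$dX[[1L]]                    # B x k
    dA <- dS
    dim(dA) <- dim(cache$conv_pre)
    dPre <- lrelu_grad(dA, cache$conv_pre, a)
    bk_conv <- conv2d_backward(dPre, cache$conv, model$params$conv,
                               model$geom, need_dx = FALSE)
    list(conv = bk_conv$grads, rnn = bk_rnn$grads, fc = bk_fc$grads)
  } else { # cnn
    bk_fc <- dense_backward(dlogits, cache$Fmat, model$params$fc)
    dcur <- bk_fc$dX
    dim(dcur) <- dim(cache$acts[[6L]]$pre)
    grads <- vector("list", 6L)
    for (i in rev(seq_len(6L))) {
      ac <- cache$acts[[i]]
      if (!is.null(ac$mask)) dcur <- dcur * ac$mask
      dPre <- lrelu_grad(dcur, ac$pre, a)
      bk <- conv2d_backward(dPre, ac$conv, model$params[[paste0("conv", i)]],
                            model$geoms[[i]], need_dx = i > 1L)
      grads[[i]] <- bk$grads
      if (i > 1L) dcur <- bk$dX
    }
    names(grads) <- paste0("conv", seq_len(6L))
    c(grads, list(fc = bk_fc$grads))
  }
}

#' Train a classifier
#'
#' Minibatch Adam on the softmax cross-entropy; dropout (CNN) is active
#' during training only. Deterministic given `seed`.
#'
#' @param model an `apta_classifier` from [build_classifier()].
#' @param x inputs: a `(batch x ls)` matrix for raw sequences or a
#'   `(batch x 128 x F)` array for spectrograms.
#' @param y integer labels in `1..m`.
#' @param epochs training epochs.
#' @param batch_size minibatch size (default 128).
#' @param learning_rate Adam learning rate (default 0.002).
#' @param seed integer seed for shuffling and dropout.
#' @return the trained `apta_classifier` (per-epoch mean loss in
#'   `$history`).
#' @export
fit_classifier <- function(model, x, y, epochs = 30L, batch_size = 128L,
                           learning_rate = 2e-3, seed = 1L) {
  stopifnot(inherits(model, "apta_classifier"))
  set.seed(seed)
  if (is.null(model$opt)) model$opt <- adam_init(model$params)
  # standardize image inputs (ConvRNN / CNN) per element on the training
  # set -- linear spectrogram powers span orders of magnitude and would
  # otherwise destabilize training; sequence inputs are fed as-is
  if (model$spec$arch %in% c("ConvGRU", "ConvULSTM", "ConvBLSTM", "CNN") &&
      is.null(model$input_mean)) {
    model$input_mean <- apply(x, seq_along(dim(x))[-1], mean)
    sdv <- apply(x, seq_along(dim(x))[-1], sd)
    sdv[!is.finite(sdv) | sdv < 1e-12] <- 1
    model$input_sd <- sdv
  }
  B <- if (is.matrix(x)) nrow(x) else dim(x)[1]
  slice_x <- function(rows) {
    if (is.matrix(x)) x[rows, , drop = FALSE]
    else {
      d <- dim(x)
      out <- x[rows, , , drop = FALSE]
      dim(out) <- c(length(rows), d[2], d[3])
      out
    }
  }
  for (e in seq_len(epochs)) {
    ord <- sample.int(B)
    losses <- c()
    for (start in seq(1L, B, by = batch_size)) {
      rows <- ord[start:min(start + batch_size - 1L, B)]
      fwd <- classifier_forward(model, slice_x(rows), training = TRUE)
      sx <- softmax_xent(fwd$logits, y[rows])
      grads <- classifier_backward(model, NULL, fwd, sx$dlogits)
      st <- adam_step(model$params, grads, model$opt, lr = learning_rate)
      model$params <- st$params
      model$opt <- st$state
      losses <- c(losses, sx$loss)
    }
    model$history <- c(model$history, mean(losses))
  }
  model
}

#' Predict classes and class probabilities
#'
#' @param object an `apta_classifier`.
#' @param x inputs in the model's mode (matrix or spectrogram array).
#' @param ... unused.
#' @return a tibble with `.pred_class` (integer argmax label) and one
#'   `.pred_<k>` probability column per class; rows sum to 1.
#' @export
predict.apta_classifier <- function(object, x, ...) {
  fwd <- classifier_forward(object, x, training = FALSE)
  P <- softmax_rows(fwd$logits)
  out <- tibble::as_tibble(as.data.frame(P, optional = TRUE),
                           .name_repair = ~ paste0(".pred_", seq_len(ncol(P))))
  dplyr::bind_cols(tibble::tibble(.pred_class = max.col(P, ties.method = "first")), out)
}

#' Parameter-shape ledger of a classifier
#'
#' Realized learnable-parameter shapes in the row-stacked convention of
#' the architecture tables (recurrent `Wx: 3n x k` / `4n x k` / `8n x k`,
#' fully connected `m x n`, convolution filter ladder).
#'
#' @param model an `apta_classifier`.
#' @return a tibble with `layer`, `param`, `rows`, `cols`, `count`.
#' @export
classifier_shapes <- function(model) {
  p <- model$params
  rows <- list()
  add <- function(layer, param, r, c) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(layer = layer, param = param,
                                                 rows = as.integer(r),
                                                 cols = as.integer(c))
  }
  if (!is.null(p$conv)) {
    add("conv", "W", nrow(p$conv$W), ncol(p$conv$W))
    add("conv", "b", 1L, length(p$conv$b))
  }
  for (i in seq_len(6L)) {
    nm <- paste0("conv", i)
    if (!is.null(p[[nm]])) {
      add(nm, "W", nrow(p[[nm]]$W), ncol(p[[nm]]$W))
      add(nm, "b", 1L, length(p[[nm]]$b))
    }
  }
  if (!is.null(p$rnn)) {
    stack <- function(pp) list(Wx = t(pp$Wx), Wh = t(pp$Wh), b = matrix(pp$b))
    r <- if (!is.null(p$rnn$fwd)) {
      f <- stack(p$rnn$fwd); b <- stack(p$rnn$bwd)
      list(Wx = rbind(f$Wx, b$Wx), Wh = rbind(f$Wh, b$Wh), b = rbind(f$b, b$b))
    } else stack(p$rnn)
    add("recurrent", "Wx", nrow(r$Wx), ncol(r$Wx))
    add("recurrent", "Wh", nrow(r$Wh), ncol(r$Wh))
    add("recurrent", "b", nrow(r$b), 1L)
  }
  add("fc", "W", ncol(p$fc$W), nrow(p$fc$W))   # m x k convention
  add("fc", "b", ncol(p$fc$W), 1L)
  out <- dplyr::bind_rows(rows)
  out$count <- out$rows * out$cols
  out
}

#' Training configuration for the classification stage
#'
#' @param epochs training epochs (reference setting 100).
#' @param minibatch minibatch size (reference setting 128).
#' @param learning_rate Adam learning rate (reference setting 0.002).
#' @param k_folds folds for cross-validation over the non-test data
#'   (reference setting 10).
#' @param split train/validation/test fractions summing to 1.
#' @param seed integer seed.
#' @return an object of class `train_config`.
#' @export
train_config <- function(epochs = 100L, minibatch = 128L, learning_rate = 2e-3,
                         k_folds = 10L, split = c(0.6, 0.2, 0.2), seed = 1L) {
  if (abs(sum(split) - 1) > 1e-9) abort("`split` fractions must sum to 1.")
  structure(list(epochs = as.integer(epochs), minibatch = as.integer(minibatch),
                 learning_rate = learning_rate, k_folds = as.integer(k_folds),
                 split = split, seed = as.integer(seed)),
            class = "train_config")
}

stratified_assign <- function(y, fractions, seed) {
  set.seed(seed)
  grp <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    cuts <- round(cumsum(fractions) * length(idx))
    lo <- c(0L, cuts[-length(cuts)])
    for (j in seq_along(fractions)) {
      if (cuts[j] > lo[j]) grp[idx[(lo[j] + 1L):cuts[j]]] <- j
    }
  }
  # anything unassigned by rounding goes to the first group
  grp[grp == 0L] <- 1L
  grp
}

#' K-fold training with a held-out test set
#'
#' Holds out the test fraction of `split` once (stratified by class),
#' partitions the remaining data into `k_folds` stratified folds, trains
#' one model per fold on the other folds (recording validation accuracy),
#' then trains a final model on all non-test data and evaluates it on the
#' held-out test set with [confusion_and_metrics()].
#'
#' @param spec a [classifier_spec()].
#' @param x,y inputs and integer labels as for [fit_classifier()].
#' @param config a [train_config()].
#' @return a list with `final_model`, `test_metrics` (an `apta_metrics`),
#'   `fold_results` (tibble of fold, validation accuracy) and the index
#'   vectors `test_idx`, `fold_assign`.
#' @export
train_classifier_kfold <- function(spec, x, y, config = train_config()) {
  m <- spec$n_classes
  if (!all(seq_len(m) %in% y)) abort("every class 1..m must be present in `y`.")
  test_frac <- config$split[3]
  grp <- stratified_assign(y, c(1 - test_frac, test_frac), config$seed)
  test_idx <- which(grp == 2L)
  rest_idx <- which(grp == 1L)
  slice_x <- function(rows) {
    if (is.matrix(x)) x[rows, , drop = FALSE]
    else {
      d <- dim(x)
      out <- x[rows, , , drop = FALSE]
      dim(out) <- c(length(rows), d[2], d[3])
      out
    }
  }
  folds <- stratified_assign(y[rest_idx], rep(1 / config$k_folds, config$k_folds),
                             config$seed + 1L)
  fold_acc <- numeric(config$k_folds)
  for (f in seq_len(config$k_folds)) {
    tr <- rest_idx[folds != f]
    va <- rest_idx[folds == f]
    mod <- build_classifier(spec, seed = config$seed + f)
    mod <- fit_classifier(mod, slice_x(tr), y[tr], epochs = config$epochs,
                          batch_size = config$minibatch,
                          learning_rate = config$learning_rate,
                          seed = config$seed + f)
    pr <- predict(mod, slice_x(va))
    fold_acc[f] <- mean(pr$.pred_class == y[va])
  }
  final <- build_classifier(spec, seed = config$seed)
  final <- fit_classifier(final, slice_x(rest_idx), y[rest_idx],
                          epochs = config$epochs, batch_size = config$minibatch,
                          learning_rate = config$learning_rate, seed = config$seed)
  pr <- predict(final, slice_x(test_idx))
  list(final_model = final,
       test_metrics = confusion_and_metrics(y[test_idx], pr$.pred_class, m),
       fold_results = tibble::tibble(fold = seq_len(config$k_folds),
                                     val_accuracy = fold_acc),
       test_idx = test_idx,
       fold_assign = folds)
}

#' Assemble model inputs from a segment table
#'
#' @param segments an `apta_segments` tibble (with a `spectrogram` column
#'   when `input_mode = "spectrogram"`, see [add_spectrograms()]).
#' @param input_mode `"raw_sequence"` or `"spectrogram"`.
#' @return a `(batch x ls)` matrix or `(batch x 128 x F)` array.
#' @export
classifier_inputs <- function(segments, input_mode = c("raw_sequence", "spectrogram")) {
  input_mode <- match.arg(input_mode)
  if (input_mode == "raw_sequence") {
    do.call(rbind, segments$values)
  } else {
    if (is.null(segments$spectrogram)) abort("no `spectrogram` column; run add_spectrograms().")
    sp <- segments$spectrogram
    d <- dim(sp[[1]])
    out <- array(0, c(length(sp), d[1], d[2]))
    for (i in seq_along(sp)) out[i, , ] <- sp[[i]]
    out
  }
}

#' @rdname classifier_shapes
#' @param x an `apta_classifier`.
#' @param ... unused.
#' @exportS3Method
tidy.apta_classifier <- function(x, ...) classifier_shapes(x)

#' @rdname classifier_shapes
#' @exportS3Method
glance.apta_classifier <- function(x, ...) {
  tibble::tibble(arch = x$spec$arch, input_mode = x$spec$input_mode,
                 n_classes = x$spec$n_classes,
                 n_learnable = n_params(x$params),
                 final_loss = if (length(x$history)) tail(x$history, 1) else NA_real_)
}
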