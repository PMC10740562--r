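#' Forecaster network descriptor
#'
#' The extrapolation networks have four layers: sequence input (width 1),
#' one recurrent layer (GRU, unidirectional LSTM or bidirectional LSTM
#' with `n` hidden units), a fully connected layer down to one output, and
#' a regression output. Stacked parameter shapes follow the conventional
#' ledger: GRU `Wx 3n x 1, Wh 3n x n, b 3n x 1`; ULSTM `4n x ...`; BLSTM
#' `8n x ...` (forward and backward directions concatenated), with the
#' fully connected input width `n` (`2n` for BLSTM).
#'
#' @param variant `"GRU"`, `"ULSTM"` or `"BLSTM"`.
#' @param hidden_units number of hidden units `n` (default 128).
#' @param input_size input feature width (1 for scalar sequences).
#' @return an object of class `forecast_net_spec`.
#' @export
forecast_net_spec <- function(variant = c("GRU", "ULSTM", "BLSTM"),
                              hidden_units = 128L, input_size = 1L) {
  variant <- match.arg(variant)
  structure(list(variant = variant, hidden_units = as.integer(hidden_units),
                 input_size = as.integer(input_size)),
            class = "forecast_net_spec")
}

#' Build a sequence forecaster
#'
#' Instantiates the four-layer forecaster of [forecast_net_spec()] with
#' Glorot-initialized weights (reproducible given `seed`). The network is
#' sequence-to-sequence with a one-sample head: its output at position `t`
#' estimates the input `time_step` samples ahead.
#'
#' @param spec a [forecast_net_spec()].
#' @param seed integer seed for the initialization.
#' @return an object of class `apta_forecaster`.
#' @export
build_forecaster <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "forecast_net_spec"))
  set.seed(seed)
  n <- spec$hidden_units
  params <- list(
    rnn = rnn_init(spec$variant, spec$input_size, n),
    head = dense_init(rnn_out_width(spec$variant, n), 1L)
  )
  structure(list(spec = spec, params = params, opt = NULL, history = numeric(0)),
            class = "apta_forecaster")
}

#' Parameter-shape ledger of a forecaster
#'
#' Reports the realized learnable-parameter shapes in the stacked
#' row-major convention of the architecture tables (`Wx: 3n x d` etc.).
#'
#' @param model an `apta_forecaster`.
#' @return a tibble with columns `layer`, `param`, `rows`, `cols`, `count`.
#' @export
forecaster_shapes <- function(model) {
  p <- model$params
  v <- model$spec$variant
  stack <- function(pp) list(Wx = t(pp$Wx), Wh = t(pp$Wh), b = matrix(pp$b))
  r <- if (v == "BLSTM") {
    f <- stack(p$rnn$fwd); b <- stack(p$rnn$bwd)
    list(Wx = rbind(f$Wx, b$Wx), Wh = rbind(f$Wh, b$Wh), b = rbind(f$b, b$b))
  } else stack(p$rnn)
  tibble::tibble(
    layer = c(rep("recurrent", 3), "fc", "fc"),
    param = c("Wx", "Wh", "b", "W", "b"),
    rows = c(nrow(r$Wx), nrow(r$Wh), nrow(r$b), ncol(p$head$W), 1L),
    cols = c(ncol(r$Wx), ncol(r$Wh), 1L, nrow(p$head$W), 1L),
    count = .data$rows * .data$cols
  )
}

#' Extrapolation configuration
#'
#' Parameters of the iterative sliding-window extension procedure: the
#' desired final length `L`, the forecast block size `time_step`, the
#' per-iteration window-offset increment, and the first predictor start
#' index.
#'
#' @param L desired segment length in samples (default 500).
#' @param time_step samples appended per iteration (default 15).
#' @param step_offset_increment window advance per iteration (default 10).
#' @param start_point 1-based index where the first predictor window
#'   starts (default 40).
#' @param epochs_first,epochs_update training epochs for the first and for
#'   subsequent (warm-started) iterations.
#' @param learning_rate Adam learning rate.
#' @param batch_size minibatch size for window training.
#' @param update_learning_rate Adam learning rate for warm refits after the
#'   first iteration.
#' @param input_jitter standard deviation of Gaussian noise added to the
#'   predictor windows during training (z-score units). This denoising
#'   regularizer counters exposure bias: during closed-loop extension the
#'   network consumes its own smooth predictions, a distribution it never
#'   saw if trained only on noisy observations.
#' @param center logical; mean-center each predictor/target window before
#'   training and add the window mean back to predictions. Makes the
#'   learned dynamics level-invariant, which prevents extended segments
#'   from drifting toward the concentration-class mean levels.
#' @param val_fraction fraction of window rows held out during the first
#'   (long) training stage for early stopping; the best-validation
#'   checkpoint is kept. An overfitted shift map destabilizes the closed
#'   loop, so the stopping point matters more than the epoch budget.
#' @param refit `"warm"` (default; fine-tune each iteration), `"fresh"`
#'   (reinitialize and retrain each iteration) or `"none"` (train once at
#'   the first iteration only).
#' @return an object of class `extrap_config`.
#' @export
extrap_config <- function(L = 500L, time_step = 15L,
                          step_offset_increment = 10L, start_point = 40L,
                          epochs_first = 300L, epochs_update = 15L,
                          learning_rate = 5e-3, update_learning_rate = 1e-3,
                          batch_size = 256L,
                          input_jitter = 0.04, center = TRUE,
                          val_fraction = 0.15,
                          refit = c("warm", "fresh", "none")) {
  if (time_step <= 0) abort("`time_step` must be positive.")
  structure(list(L = as.integer(L), time_step = as.integer(time_step),
                 step_offset_increment = as.integer(step_offset_increment),
                 start_point = as.integer(start_point),
                 epochs_first = as.integer(epochs_first),
                 epochs_update = as.integer(epochs_update),
                 learning_rate = learning_rate,
                 update_learning_rate = update_learning_rate,
                 batch_size = as.integer(batch_size),
                 input_jitter = input_jitter, center = isTRUE(center),
                 val_fraction = val_fraction,
                 refit = match.arg(refit)),
            class = "extrap_config")
}

#' Build predictor/target windows for one extension iteration
#'
#' For current series length `l` and window offset `step_offset`, each
#' series contributes the predictor window
#' `[start_point + step_offset, l - time_step]` and the target window
#' shifted forward by `time_step` (ending at `l`), both 1-based inclusive.
#' At the first iteration on a 300-sample segment with the defaults the
#' predictor covers samples 40-285 and the target samples 55-300.
#'
#' @param series a numeric matrix (one row per series, current length `l`
#'   columns) or a list of equal-length numeric vectors.
#' @param config an [extrap_config()].
#' @param step_offset current window offset (0 at the first iteration).
#' @return a list with matrices `predictor` and `target` (rows = series)
#'   and the index vectors `predictor_idx`, `target_idx`.
#' @export
make_training_windows <- function(series, config, step_offset = 0L) {
  if (is.list(series)) series <- do.call(rbind, series)
  l <- ncol(series)
  p_start <- config$start_point + step_offset
  p_end <- l - config$time_step
  if (p_end <= p_start) abort("degenerate window: predictor end <= start.")
  pi <- p_start:p_end
  ti <- pi + config$time_step
  list(predictor = series[, pi, drop = FALSE],
       target = series[, ti, drop = FALSE],
       predictor_idx = pi, target_idx = ti)
}

forecaster_loss_grad <- function(model, P, Tg) {
  spec <- model$spec
  n <- spec$hidden_units
  B <- nrow(P); Tw <- ncol(P)
  X <- array(P, c(B, Tw, 1L))
  fwd <- rnn_forward(spec$variant, X, model$params$rnn, n)
  H <- fwd$H
  Y <- vapply(H, function(h) as.vector(dense_forward(h, model$params$head)), numeric(B))
  if (B == 1) Y <- matrix(Y, nrow = 1)
  E <- Y - Tg
  loss <- mean(E^2)
  dY <- 2 * E / length(E)
  dH <- vector("list", Tw)
  dheadW <- model$params$head$W * 0
  dheadb <- model$params$head$b * 0
  for (t in seq_len(Tw)) {
    bk <- dense_backward(matrix(dY[, t], ncol = 1), H[[t]], model$params$head)
    dH[[t]] <- bk$dX
    dheadW <- dheadW + bk$grads$W
    dheadb <- dheadb + bk$grads$b
  }
  bk <- rnn_backward(spec$variant, dH, fwd, model$params$rnn, n)
  list(loss = loss,
       grads = list(rnn = bk$grads, head = list(W = dheadW, b = dheadb)))
}

forecaster_train <- function(model, P, Tg, epochs, lr = 2e-3, batch_size = 64L,
                             input_jitter = 0, val_fraction = 0,
                             patience = 8L, check_every = 5L) {
  if (epochs <= 0) return(model)
  if (is.null(model$opt)) model$opt <- adam_init(model$params)
  B <- nrow(P)
  val_rows <- integer(0)
  if (val_fraction > 0 && B >= 10L) {
    val_rows <- sample.int(B, max(2L, round(val_fraction * B)))
  }
  tr_rows <- setdiff(seq_len(B), val_rows)
  best <- list(loss = Inf, params = model$params, opt = model$opt)
  bad <- 0L
  for (e in seq_len(epochs)) {
    ord <- sample(tr_rows)
    for (start in seq(1L, length(ord), by = batch_size)) {
      rows <- ord[start:min(start + batch_size - 1L, length(ord))]
      Pb <- P[rows, , drop = FALSE]
      if (input_jitter > 0) Pb <- Pb + matrix(rnorm(length(Pb), 0, input_jitter), nrow(Pb))
      lg <- forecaster_loss_grad(model, Pb, Tg[rows, , drop = FALSE])
      st <- adam_step(model$params, lg$grads, model$opt, lr = lr)
      model$params <- st$params
      model$opt <- st$state
      model$history <- c(model$history, lg$loss)
    }
    # early stopping on held-out windows: closed-loop extension is
    # sensitive to an overfitted shift map, so validate by rolling the
    # model out closed-loop over the last 60 observed samples of each
    # held-out window and keep the best checkpoint
    if (length(val_rows) && (e %% check_every == 0L || e == epochs)) {
      Pv <- P[val_rows, , drop = FALSE]
      Tw <- ncol(Pv)
      horizon <- min(60L, Tw %/% 3L)
      rounds <- ceiling(horizon / 15L)
      cur <- Pv[, seq_len(Tw - horizon), drop = FALSE]
      for (r in seq_len(rounds)) {
        Yr <- forecaster_predict_seq(model, cur)
        cur <- cbind(cur, Yr[, (ncol(cur) - 14L):ncol(cur), drop = FALSE])
      }
      vl <- mean((cur[, (Tw - horizon + 1L):Tw] -
                    Pv[, (Tw - horizon + 1L):Tw])^2)
      if (vl < best$loss - 1e-6) {
        best <- list(loss = vl, params = model$params, opt = model$opt)
        bad <- 0L
      } else {
        bad <- bad + 1L
        if (bad >= patience) break
      }
    }
  }
  if (length(val_rows) && is.finite(best$loss)) {
    model$params <- best$params
    model$opt <- best$opt
  }
  model
}

forecaster_predict_seq <- function(model, series) {
  spec <- model$spec
  B <- nrow(series); Tw <- ncol(series)
  X <- array(series, c(B, Tw, 1L))
  fwd <- rnn_forward(spec$variant, X, model$params$rnn, spec$hidden_units)
  Y <- vapply(fwd$H, function(h) as.vector(dense_forward(h, model$params$head)), numeric(B))
  if (B == 1) Y <- matrix(Y, nrow = 1) else Y
}

#' Iterative sliding-window signal extension
#'
#' Extends every series to length `L` by the iterative procedure: at each
#' iteration, predictor/target window pairs ([make_training_windows()])
#' are built from the current (already partially extended) training
#' series; the shared forecaster is (re)trained on them; the network's
#' outputs at the last `time_step` positions of each series -- which, by
#' the 15-sample-shift training objective, estimate the next `time_step`
#' samples -- are appended; and the window offset advances by
#' `step_offset_increment`. The loop overshoots by construction
#' (e.g. 300 + 14 x 15 = 510), so the result is truncated to exactly `L`.
#'
#' @param model an `apta_forecaster` from [build_forecaster()].
#' @param series numeric matrix, one row per series (all the same length,
#'   shorter than `L`). Rows named in `train_rows` provide the training
#'   windows; all rows are extended.
#' @param config an [extrap_config()].
#' @param train_rows integer indices of rows used for training windows
#'   (default: all rows).
#' @param seed integer seed controlling minibatch order.
#' @return a list with `series` (matrix, `L` columns), `model` (the
#'   trained forecaster) and `n_iterations`.
#' @export
extrapolate_segments <- function(model, series, config = extrap_config(),
                                 train_rows = seq_len(nrow(series)),
                                 seed = 1L) {
  stopifnot(inherits(model, "apta_forecaster"))
  if (is.list(series)) series <- do.call(rbind, series)
  l0 <- ncol(series)
  if (l0 >= config$L) {
    return(list(series = series[, seq_len(config$L), drop = FALSE],
                model = model, n_iterations = 0L))
  }
  set.seed(seed)
  offset <- 0L
  iter <- 0L
  cur <- series
  while (ncol(cur) < config$L) {
    iter <- iter + 1L
    w <- make_training_windows(cur[train_rows, , drop = FALSE], config, offset)
    epochs <- if (iter == 1L) config$epochs_first
              else switch(config$refit, warm = config$epochs_update,
                          fresh = config$epochs_first, none = 0L)
    if (config$refit == "fresh" && iter > 1L && epochs > 0) {
      model <- build_forecaster(model$spec, seed = seed + iter)
    }
    P <- w$predictor; Tg <- w$target
    if (config$center) {
      m <- rowMeans(P)
      P <- P - m; Tg <- Tg - m
    }
    model <- forecaster_train(model, P, Tg, epochs,
                              lr = if (iter == 1L) config$learning_rate
                                   else config$update_learning_rate,
                              batch_size = config$batch_size,
                              input_jitter = config$input_jitter,
                              val_fraction = if (iter == 1L) config$val_fraction else 0)
    if (config$center) {
      wi <- (config$start_point + offset):(ncol(cur) - config$time_step)
      mall <- rowMeans(cur[, wi, drop = FALSE])
      Y <- forecaster_predict_seq(model, cur - mall) + mall
    } else {
      Y <- forecaster_predict_seq(model, cur)
    }
    block <- Y[, (ncol(cur) - config$time_step + 1L):ncol(cur), drop = FALSE]
    cur <- cbind(cur, block)
    offset <- offset + config$step_offset_increment
  }
  list(series = cur[, seq_len(config$L), drop = FALSE],
       model = model, n_iterations = iter)
}

#' Extend a single segment
#'
#' Single-segment convenience wrapper around [extrapolate_segments()]:
#' trains on the segment's own windows and flags the extended region.
#'
#' @param model an `apta_forecaster`.
#' @param segment numeric vector (z-scored segment, length `< L`).
#' @param config an [extrap_config()].
#' @param seed integer seed.
#' @return numeric vector of length `config$L` with attribute
#'   `extrapolated_from` (the original length).
#' @export
extrapolate_segment <- function(model, segment, config = extrap_config(), seed = 1L) {
  n0 <- length(segment)
  out <- extrapolate_segments(model, matrix(segment, nrow = 1), config, seed = seed)
  structure(as.vector(out$series), extrapolated_from = min(n0, config$L))
}

#' Tail forecast error
#'
#' Mean squared error between the true continuation of a segment and its
#' extrapolated tail (by default the final 200 samples of a 300-to-500
#' extension).
#'
#' @param actual_tail,extrapolated_tail equal-length numeric vectors.
#' @return nonnegative scalar MSE.
#' @export
forecast_error <- function(actual_tail, extrapolated_tail) {
  mse(actual_tail, extrapolated_tail)
}

#' Persistence (last-value) forecast baseline
#'
#' Repeats the last observed sample; the conventional floor against which
#' forecaster quality is judged.
#'
#' @param segment numeric vector of observed samples.
#' @param horizon number of future samples.
#' @return numeric vector of length `horizon`.
#' @export
persistence_forecast <- function(segment, horizon) {
  rep(segment[length(segment)], horizon)
}

#' @rdname forecaster_shapes
#' @param x an `apta_forecaster`.
#' @param ... unused.
#' @exportS3Method
tidy.apta_forecaster <- function(x, ...) forecaster_shapes(x)

#' @rdname forecaster_shapes
#' @exportS3Method
glance.apta_forecaster <- function(x, ...) {
  tibble::tibble(variant = x$spec$variant, hidden_units = x$spec$hidden_units,
                 n_learnable = n_params(x$params),
                 final_loss = if (length(x$history)) tail(x$history, 1) else NA_real_)
}
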