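# brute-force filter-placement counter: the oracle for conv arithmetic
count_placements <- function(l, f, p, s) {
  padded <- l + 2 * p
  n <- 0L
  start <- 1L
  while (start + f - 1L <= padded) {
    n <- n + 1L
    start <- start + s
  }
  n
}

test_that("conv output length equals exhaustive filter placement", {
  expect_equal(conv_output_length(300, 5, 1, 1), 298L)
  expect_equal(conv_output_length(500, 5, 1, 1), 498L)
  expect_equal(conv_output_length(77, 1, 0, 1), 77L)
  for (l in c(10L, 33L, 128L)) {
    for (f in c(1L, 3L, 5L, 9L)) {
      for (p in 0:2) for (s in 1:3) {
        if (l + 2 * p >= f) {
          expect_equal(conv_output_length(l, f, p, s), count_placements(l, f, p, s))
        }
      }
    }
  }
  expect_error(conv_output_length(4, 9, 0, 1), "fit")
})

test_that("recurrent classifier shapes match the stacked ledger at n = 128", {
  n <- 128L
  mult <- c(GRU = 3L, ULSTM = 4L, BLSTM = 8L)
  for (arch in names(mult)) {
    for (m in c(6L, 12L)) {
      mod <- build_classifier(classifier_spec(arch, "raw_sequence",
                                              segment_length = 300L,
                                              n_classes = m), seed = 1)
      sh <- classifier_shapes(mod)
      expect_equal(sh$rows[sh$param == "Wx"], mult[[arch]] * n)
      expect_equal(sh$cols[sh$param == "Wx"], 1L)        # scalar sequence input
      expect_equal(sh$rows[sh$param == "Wh"], mult[[arch]] * n)
      expect_equal(sh$cols[sh$param == "Wh"], n)
      fcw <- sh[sh$layer == "fc" & sh$param == "W", ]
      expect_equal(fcw$rows, m)
      expect_equal(fcw$cols, if (arch == "BLSTM") 2L * n else n)
    }
  }
})

test_that("ConvRNN flatten width k = lc x nf feeds the recurrent layer", {
  n <- 128L
  for (arch in c("ConvGRU", "ConvULSTM", "ConvBLSTM")) {
    mod <- build_classifier(classifier_spec(arch, "raw_sequence",
                                            segment_length = 300L,
                                            n_classes = 6L), seed = 1)
    lc <- conv_output_length(300, 5, 1, 1)
    expect_equal(mod$k, lc * 32L)
    sh <- classifier_shapes(mod)
    expect_equal(sh$cols[sh$param == "Wx"], lc * 32L)
    mult <- c(ConvGRU = 3L, ConvULSTM = 4L, ConvBLSTM = 8L)[[arch]]
    expect_equal(sh$rows[sh$param == "Wx"], mult * n)
  }
})

test_that("the CNN realizes the 32/16/8/8/16/32 filter ladder and lc arithmetic", {
  mod <- build_classifier(classifier_spec("CNN", "raw_sequence",
                                          segment_length = 300L, n_classes = 6L),
                          seed = 1)
  sh <- classifier_shapes(mod)
  convw <- sh[grepl("^conv", sh$layer) & sh$param == "W", ]
  expect_equal(convw$cols, c(32L, 16L, 8L, 8L, 16L, 32L))
  # frequency/length axis shrinks by 2 per layer: 300 -> 288 after 6 layers
  lc <- Reduce(function(l, i) conv_output_length(l, 5, 1, 1), 1:6, accumulate = FALSE,
               init = 300)
  expect_equal(lc, 288L)
  expect_equal(mod$k, 288L * 32L)
  fcw <- sh[sh$layer == "fc" & sh$param == "W", ]
  expect_equal(fcw$cols, 288L * 32L)
})

test_that("C1 and C2 heads emit 6 and 12 classes for every architecture", {
  set.seed(30)
  x <- array(rnorm(2 * 128 * 3), c(2, 128, 3))
  for (arch in c("GRU", "ULSTM", "BLSTM", "ConvGRU", "ConvULSTM", "ConvBLSTM", "CNN")) {
    for (m in c(6L, 12L)) {
      mod <- build_classifier(classifier_spec(arch, "spectrogram",
                                              segment_length = 300L, n_classes = m,
                                              hidden_units = 8L, n_filters = 4L,
                                              cnn_filters = rep(4L, 6L)), seed = 2)
      pr <- predict(mod, x)
      expect_equal(sum(grepl("^\\.pred_[0-9]+$", names(pr))), m)
      expect_true(all(pr$.pred_class %in% seq_len(m)))
    }
  }
})

test_that("softmax rows normalize, argmax matches, and batching is consistent", {
  set.seed(31)
  mod <- build_classifier(classifier_spec("ConvGRU", "spectrogram",
                                          segment_length = 300L, n_classes = 4L,
                                          hidden_units = 8L, n_filters = 4L), seed = 3)
  x <- array(rnorm(5 * 128 * 3), c(5, 128, 3))
  pr <- predict(mod, x)
  probs <- as.matrix(pr[, paste0(".pred_", 1:4)])
  expect_true(all(abs(rowSums(probs) - 1) < 1e-6))
  expect_equal(pr$.pred_class, max.col(probs, ties.method = "first"))
  # a batch of one equals the corresponding row of the larger batch
  x1 <- x[2, , , drop = FALSE]
  dim(x1) <- c(1, 128, 3)
  pr1 <- predict(mod, x1)
  expect_equal(as.numeric(pr1[1, paste0(".pred_", 1:4)]),
               as.numeric(pr[2, paste0(".pred_", 1:4)]), tolerance = 1e-12)
})

test_that("a trivially separable two-cluster task is classified perfectly", {
  set.seed(32)
  n <- 30
  x <- array(0, c(2 * n, 128, 3))
  for (i in seq_len(n)) x[i, , ] <- 5 + rnorm(128 * 3, 0, 0.2)
  for (i in n + seq_len(n)) x[i, , ] <- -5 + rnorm(128 * 3, 0, 0.2)
  y <- rep(1:2, each = n)
  mod <- build_classifier(classifier_spec("ConvGRU", "spectrogram",
                                          segment_length = 300L, n_classes = 2L,
                                          hidden_units = 8L, n_filters = 4L), seed = 4)
  mod <- fit_classifier(mod, x, y, epochs = 5L, batch_size = 16L, seed = 5)
  pr <- predict(mod, x)
  expect_equal(mean(pr$.pred_class == y), 1)
})

test_that("k-fold training partitions the non-test data and is deterministic", {
  set.seed(33)
  n <- 24
  x <- array(rnorm(2 * n * 128 * 3), c(2 * n, 128, 3))
  x[seq_len(n), , ] <- x[seq_len(n), , ] + 4
  y <- rep(1:2, each = n)
  spec <- classifier_spec("ConvGRU", "spectrogram", segment_length = 300L,
                          n_classes = 2L, hidden_units = 4L, n_filters = 2L)
  cfg <- train_config(epochs = 2L, minibatch = 16L, k_folds = 3L, seed = 6)
  res <- train_classifier_kfold(spec, x, y, cfg)
  expect_equal(length(res$test_idx), round(0.2 * 2 * n))
  expect_equal(length(res$fold_assign), 2 * n - length(res$test_idx))
  expect_true(all(res$fold_assign %in% 1:3))          # every item in exactly one fold
  expect_equal(nrow(res$fold_results), 3L)
  expect_s3_class(res$test_metrics, "apta_metrics")
  res2 <- train_classifier_kfold(spec, x, y, cfg)
  expect_identical(res$test_metrics$accuracy, res2$test_metrics$accuracy)
  expect_error(train_classifier_kfold(spec, x, rep(1L, 2 * n), cfg), "every class")
})

test_that("STFT inputs beat raw sequences for plain recurrent nets on tonal classes", {
  # two classes distinguished by oscillation frequency; at a tiny training
  # budget the 3-frame spectrogram sequence is learnable while the
  # 300-step scalar sequence is not
  set.seed(34)
  n <- 20
  len <- 300
  segs <- c(lapply(seq_len(n), function(i) sin(2 * pi * 10 * seq_len(len) / 128 + runif(1, 0, 2 * pi)) + rnorm(len, 0, 0.1)),
            lapply(seq_len(n), function(i) sin(2 * pi * 45 * seq_len(len) / 128 + runif(1, 0, 2 * pi)) + rnorm(len, 0, 0.1)))
  y <- rep(1:2, each = n)
  raw <- do.call(rbind, segs)
  sp <- array(0, c(2 * n, 128, 3))
  # decibel scale keeps the recurrent gates out of saturation
  for (i in seq_along(segs)) sp[i, , ] <- compute_spectrogram(segs[[i]], stft_config(db = TRUE))
  test_i <- c(1:5, n + 1:5)
  train_i <- setdiff(seq_len(2 * n), test_i)
  accs <- c()
  for (mode in c("raw_sequence", "spectrogram")) {
    mod <- build_classifier(classifier_spec("GRU", mode, segment_length = 300L,
                                            n_classes = 2L, hidden_units = 16L),
                            seed = 7)
    xin <- if (mode == "raw_sequence") raw[train_i, ] else {
      o <- sp[train_i, , , drop = FALSE]; dim(o) <- c(length(train_i), 128, 3); o
    }
    xte <- if (mode == "raw_sequence") raw[test_i, ] else {
      o <- sp[test_i, , , drop = FALSE]; dim(o) <- c(length(test_i), 128, 3); o
    }
    mod <- fit_classifier(mod, xin, y[train_i], epochs = 8L, batch_size = 16L, seed = 8)
    pr <- predict(mod, xte)
    accs[mode] <- mean(pr$.pred_class == y[test_i])
  }
  expect_gte(accs["spectrogram"], accs["raw_sequence"])
  expect_gte(accs[["spectrogram"]], 0.9)
})
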