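# two well-separated synthetic classes used for generator training tests
two_class_segments <- function(n_per_class = 20, len = 300, seed = 1) {
  set.seed(seed)
  vals <- c(
    lapply(seq_len(n_per_class), function(i) -0.8 + 0.1 * sin(seq_len(len) / 15) + rnorm(len, 0, 0.05)),
    lapply(seq_len(n_per_class), function(i) 0.9 + 0.2 * cos(seq_len(len) / 40) + rnorm(len, 0, 0.05))
  )
  tibble::tibble(
    segment_id = sprintf("s%03d", seq_along(vals)),
    signal_id = "syn", dataset_id = "oestradiol31",
    concentration = rep(c(0, 1e-9), each = n_per_class),
    is_anomaly = FALSE, augmented = FALSE, extrapolated = FALSE,
    n = len, values = vals
  )
}

test_that("sampling layer implements the reparameterization identities", {
  s <- sampling_layer(c(3, -1, 0, 0), epsilon = c(0, 0))
  expect_equal(s$sigma_z, c(1, 1))
  expect_equal(s$z, c(3, -1))                      # z = mu at eps = 0, logvar = 0
  s2 <- sampling_layer(c(0, 0, 2 * log(2), 2 * log(2)), epsilon = c(1, -1))
  expect_equal(s2$sigma_z, c(2, 2))
  expect_equal(s2$z, c(2, -2))
  # independent recomputation oracle on random inputs
  set.seed(5)
  mu <- rnorm(32); lv <- rnorm(32); eps <- rnorm(32)
  s3 <- sampling_layer(c(mu, lv), epsilon = eps)
  expect_equal(s3$z, eps * exp(lv / 2) + mu)
  expect_error(sampling_layer(rnorm(5)), "even")
})

test_that("latent draws reproduce the posterior moments over many epsilons", {
  set.seed(8)
  mu <- c(1.5, -0.5); lv <- c(0.6, -1.2)
  n <- 1e4
  eps <- matrix(rnorm(n * 2), n, 2)
  Z <- sampling_layer(cbind(matrix(mu, n, 2, byrow = TRUE),
                            matrix(lv, n, 2, byrow = TRUE)), epsilon = eps)$z
  sd_true <- exp(lv / 2)
  se_mean <- sd_true / sqrt(n)
  expect_true(all(abs(colMeans(Z) - mu) < 3 * se_mean))
  se_sd <- sd_true / sqrt(2 * (n - 1))
  expect_true(all(abs(apply(Z, 2, sd) - sd_true) < 3 * se_sd))
})

test_that("the scaling layer is bounded by alpha for arbitrarily extreme inputs", {
  extreme <- c(-1e6, -1e3, -5, -1, 0, 1, 5, 1e3, 1e6)
  expect_equal(scaling_layer(0, 1.5), 0)
  expect_true(all(abs(scaling_layer(extreme, 1.5)) <= 1.5))
  expect_true(all(abs(scaling_layer(extreme, 5)) <= 5))
  expect_lt(max(abs(scaling_layer(extreme, 1.5))), 1.5 + 1e-12)
  expect_error(scaling_layer(1, -1), "positive")
})

test_that("ELBO terms follow the closed form and stay nonnegative", {
  expect_equal(elbo_loss(rep(0, 4), rep(0, 4), 1:3, 1:3)$kl_term, 0)
  expect_equal(elbo_loss(rep(0, 4), rep(0, 4), 1:3, 1:3)$recon_term, 0)
  expect_equal(elbo_loss(c(1, 0, 0), c(0, 0, 0), 1, 1)$kl_term, 0.5)
  set.seed(9)
  for (i in 1:20) {
    mu <- rnorm(8); lv <- rnorm(8)
    expect_gte(elbo_loss(mu, lv, 0, 0)$kl_term, 0)
  }
  # KL matches direct evaluation
  mu <- c(0.3, -1); lv <- c(0.2, 0.7)
  expect_equal(elbo_loss(mu, lv, 0, 0)$kl_term,
               0.5 * sum(exp(lv) + mu^2 - 1 - lv))
})

test_that("the generative layer ledger reproduces the working ladder sizes", {
  l3 <- generative_layer_ledger(300, "cvae_normal")
  enc <- l3[l3$module == "encoder", ]
  expect_equal(enc$spatial[enc$stage %in% c("input", "conv1", "conv_block2", "conv_block3")],
               c(300L, 150L, 75L, 38L))
  dec <- l3[l3$module == "decoder", ]
  expect_equal(dec$spatial[dec$stage %in% c("deconv1", "deconv_block2",
                                            "deconv_block3", "deconv_out")],
               c(38L, 75L, 150L, 300L))
  l5 <- generative_layer_ledger(500, "vae_anomaly")
  expect_equal(l5$spatial[l5$stage %in% c("input", "conv1", "conv_block2", "conv_block3")],
               c(500L, 250L, 125L, 63L))
  expect_equal(max(l5$spatial[l5$module == "decoder"]), 500L)
  expect_equal(l3$channels[l3$stage == "sampling"], 32L)
  # CVAE has label-conditioning stages, the VAE does not
  expect_true("label_concat" %in% l3$stage)
  expect_false("label_concat" %in% generative_layer_ledger(300, "vae_anomaly")$stage)
})

test_that("CVAE training reduces validation reconstruction error and is deterministic", {
  segs <- two_class_segments(n_per_class = 12, seed = 3)
  spec <- generative_model_spec("cvae_normal", input_length = 300L, n_classes = 2L)
  cfg <- gen_train_config(epochs = 8L, batch_size = 16L)
  gen <- train_generator(spec, segs, labels = rep(1:2, each = 12),
                         config = cfg, seed = 11)
  h <- gen$history
  expect_lt(tail(h$val_recon, 1), h$val_recon[1])
  gen2 <- train_generator(spec, segs, labels = rep(1:2, each = 12),
                          config = cfg, seed = 11)
  expect_identical(tail(gen$history$loss, 1), tail(gen2$history$loss, 1))
  # decoder output length equals the working segment length
  out <- generate_segments(gen, label = 1L, count = 3, seed = 2)
  expect_true(all(out$n == 300L))
  expect_true(all(lengths(out$values) == 300L))
})

test_that("label handling is enforced per flavor", {
  segs <- two_class_segments(n_per_class = 4, seed = 4)
  cvae <- generative_model_spec("cvae_normal", 300L, n_classes = 2L)
  vae <- generative_model_spec("vae_anomaly", 300L)
  expect_error(train_generator(cvae, segs, labels = NULL,
                               config = gen_train_config(epochs = 1L)), "labels")
  expect_error(train_generator(vae, segs, labels = rep(1L, 8),
                               config = gen_train_config(epochs = 1L)),
               "unconditional")
  expect_error(train_generator(cvae, segs, labels = rep(5L, 8),
                               config = gen_train_config(epochs = 1L)), "1..n_classes")
})

test_that("generated segments are strictly inside the scaling bounds", {
  segs <- two_class_segments(n_per_class = 6, seed = 6)
  cvae <- generative_model_spec("cvae_normal", 300L, n_classes = 2L)
  gen <- train_generator(cvae, segs, labels = rep(1:2, each = 6),
                         config = gen_train_config(epochs = 2L, batch_size = 8L),
                         seed = 12)
  out <- generate_segments(gen, label = 2L, count = 5, seed = 3)
  expect_true(all(abs(unlist(out$values)) < 1.5))
  expect_true(all(out$augmented))
  expect_equal(nrow(generate_segments(gen, label = 1L, count = 0)), 0L)
  expect_error(generate_segments(gen, label = 7L, count = 1), "out of range")
  expect_error(generate_segments(gen, count = 1), "needs a `label`")

  vae <- generative_model_spec("vae_anomaly", 300L)
  segs$is_anomaly <- TRUE
  genv <- train_generator(vae, segs,
                          config = gen_train_config(epochs = 2L, batch_size = 8L),
                          seed = 13)
  outv <- generate_segments(genv, count = 4, seed = 4)
  expect_true(all(abs(unlist(outv$values)) < 5))
  expect_true(all(outv$is_anomaly))
  expect_error(generate_segments(genv, label = 1L, count = 1), "no `label`")
})

test_that("augment_to_total tops every class up to the requested census", {
  segs <- two_class_segments(n_per_class = 5, seed = 7)
  cvae <- generative_model_spec("cvae_normal", 300L, n_classes = 2L)
  gen <- train_generator(cvae, segs, labels = rep(1:2, each = 5),
                         config = gen_train_config(epochs = 2L, batch_size = 8L),
                         seed = 14)
  aug <- augment_to_total(segs, rep(1:2, each = 5), gen,
                          total_per_class = 12L, seed = 15)
  expect_equal(as.vector(table(aug$label)), c(12L, 12L))
  expect_equal(sum(aug$augmented), 14L)
})

test_that("a CVAE trained on separated classes generates class-faithful samples", {
  segs <- two_class_segments(n_per_class = 20, seed = 8)
  cvae <- generative_model_spec("cvae_normal", 300L, n_classes = 2L)
  gen <- train_generator(cvae, segs, labels = rep(1:2, each = 20),
                         config = gen_train_config(epochs = 60L, batch_size = 32L),
                         seed = 16)
  means <- rbind(colMeans(do.call(rbind, segs$values[1:20])),
                 colMeans(do.call(rbind, segs$values[21:40])))
  hits <- 0L; total <- 0L
  for (cl in 1:2) {
    out <- generate_segments(gen, label = cl, count = 15, seed = 20 + cl)
    X <- do.call(rbind, out$values)
    d1 <- rowMeans((X - matrix(means[1, ], 15, 300, byrow = TRUE))^2)
    d2 <- rowMeans((X - matrix(means[2, ], 15, 300, byrow = TRUE))^2)
    hits <- hits + sum((ifelse(d1 < d2, 1L, 2L)) == cl)
    total <- total + 15L
  }
  expect_gte(hits / total, 0.9)
})
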