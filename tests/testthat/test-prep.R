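make_signal <- function(...) generate_signal(tiny_adenosine(), kinetics_params(...))

test_that("z-score normalization is definitional and records mu/sigma", {
  sig <- make_signal(seed = 2)
  z <- zscore_normalize(sig)
  expect_lt(abs(mean(z$current)), 1e-9)
  expect_lt(abs(sqrt(mean((z$current - mean(z$current))^2)) - 1), 1e-9)
  expect_equal(attr(z, "mu"), mean(sig$current))
  # hand example [2, 4, 6]
  toy <- sig
  toy$current <- rep(c(2, 4, 6), length.out = nrow(toy))
  zt <- zscore_normalize(toy)
  expect_equal(attr(zt, "mu"), mean(toy$current))
  # constant signal is degenerate
  toy$current <- rep(5, nrow(toy))
  expect_error(zscore_normalize(toy), "zero variance")
})

test_that("segmentation copies boundary slices verbatim", {
  z <- zscore_normalize(make_signal(seed = 3))
  segs <- segmentize(z)
  expect_equal(segs$n, c(1000L, 500L, 500L))
  expect_identical(segs$values[[2]], z$current[1001:1500])
  expect_identical(unlist(segs$values), z$current)
})

test_that("a single all-covering boundary yields one whole-record segment", {
  sig <- make_signal(seed = 4)
  attr(sig, "boundaries") <- tibble::tibble(start = 0L, end = nrow(sig),
                                            concentration = 0)
  segs <- segmentize(zscore_normalize(sig))
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$n, nrow(sig))
})

test_that("resampling hits the target length, keeps endpoints, preserves ramps", {
  v <- sin(seq_len(166) / 9)
  out <- resample_segment(v, 300)
  expect_length(out, 300L)
  expect_equal(out[1], v[1])
  expect_equal(out[300], v[166])
  ramp <- seq(0, 1, length.out = 166)
  expect_equal(resample_segment(ramp, 300), seq(0, 1, length.out = 300),
               tolerance = 1e-9)
  expect_identical(resample_segment(v, 166), v)
  expect_error(resample_segment(v, 1), "at least 2")
})

test_that("label maps follow the two-scheme convention and invert cleanly", {
  grid <- tidyr::expand_grid(
    dataset_id = c("adenosine35", "oestradiol31", "oestradiol35"),
    concentration = c(0, 1e-9, 1e-8, 1e-7, 1e-6, 1e-5)
  )
  grid$is_anomaly <- FALSE
  expect_equal(assign_labels(grid, "C1"), rep(1:6, 3))
  c2 <- assign_labels(grid, "C2")
  expect_equal(c2[grid$dataset_id == "adenosine35"], 1:6)
  expect_equal(c2[grid$dataset_id == "oestradiol31"], c(1L, 7:11))
  expect_equal(c2[grid$dataset_id == "oestradiol35"], c(1L, 7:11))
  # anomalies: class 12 under C2, rejected under C1
  anom <- grid[c(1, 8, 16), ]
  anom$is_anomaly <- TRUE
  expect_equal(assign_labels(anom, "C2"), rep(12L, 3))
  expect_error(assign_labels(anom, "C1"), "no C1 label")
  # C2 is invertible to (dataset group, concentration-or-anomaly)
  key <- paste(ifelse(grepl("^oest", grid$dataset_id), "oest", "aden"),
               grid$concentration)
  expect_equal(length(unique(paste(c2, ifelse(grepl("^oest", grid$dataset_id),
                                              "oest", "aden")))),
               length(unique(key)))
})

test_that("Blackman window endpoints, peak and range follow the closed form", {
  w <- blackman_window(128)
  expect_equal(w[1], 0)
  expect_equal(w[65], 1)           # n = N/2
  expect_true(all(w >= -1e-12 & w <= 1 + 1e-12))
  # brute-force evaluation of the three-term cosine sum
  n <- 0:127
  ref <- 0.42 - 0.5 * cos(2 * pi * n / 128) + 0.08 * cos(4 * pi * n / 128)
  expect_equal(w, ref)
})

test_that("spectrogram shapes reproduce the 300->3 and 500->6 frame counts", {
  s300 <- compute_spectrogram(rnorm(300), stft_config())
  expect_equal(dim(s300), c(128L, 3L))
  s500 <- compute_spectrogram(rnorm(500), stft_config())
  expect_equal(dim(s500), c(128L, 6L))
  expect_true(all(s300 >= 0))
  expect_equal(attr(s300, "frame_hop"), 64L)
  expect_error(compute_spectrogram(rnorm(100), stft_config()), "shorter")
  # zero input, zero output
  expect_true(all(compute_spectrogram(numeric(300), stft_config()) == 0))
})

test_that("frame-count formula matches exhaustive window placement", {
  wl <- 128L; hop <- 64L
  for (L in seq(128L, 600L, by = 7L)) {
    n_direct <- 0L
    start <- 1L
    while (start + wl - 1L <= L) {
      n_direct <- n_direct + 1L
      start <- start + hop
    }
    expect_equal(ncol(compute_spectrogram(numeric(L), stft_config())), n_direct)
    expect_equal(1L + (L - wl) %/% hop, n_direct)
  }
})

test_that("a bin-centred sinusoid concentrates energy at its symmetric bins", {
  # brute-force DFT oracle on one windowed frame
  k <- 16
  x <- cos(2 * pi * k * (0:299) / 128)
  S <- compute_spectrogram(x, stft_config())
  w <- blackman_window(128)
  frame <- x[1:128] * w
  ref <- vapply(0:127, function(f) {
    Mod(sum(frame * exp(-2i * pi * f * (0:127) / 128)))^2
  }, numeric(1))
  expect_equal(S[, 1], ref, tolerance = 1e-8)
  peak <- order(S[, 1], decreasing = TRUE)[1:2]
  expect_setequal(peak, c(k + 1L, 128L - k + 1L))
  # the Blackman main lobe spans about two bins either side of the centre
  lobe <- c(k + 1L + (-2:2), 128L - k + 1L + (-2:2))
  expect_gt(sum(S[lobe, 1]) / sum(S[, 1]), 0.99)
})

test_that("standardize_segments trims long segments to their tail and upsamples short ones", {
  segs <- tibble::tibble(
    segment_id = c("a", "b"), signal_id = "s", dataset_id = "oestradiol31",
    concentration = c(0, 1e-9), is_anomaly = FALSE, augmented = FALSE,
    extrapolated = FALSE, n = c(555L, 166L),
    values = list(seq_len(555) * 1.0, seq_len(166) * 1.0)
  )
  out <- standardize_segments(segs, 300L)
  expect_equal(out$n, c(300L, 300L))
  expect_equal(out$values[[1]], 256:555 * 1.0)   # trailing window
  expect_equal(out$values[[2]][c(1, 300)], c(1, 166))
})

test_that("signals and segment tables round-trip through CSV + JSON", {
  dir <- withr::local_tempdir()
  sig <- zscore_normalize(make_signal(seed = 9))
  p <- file.path(dir, "sig.csv")
  write_signal_csv(sig, p)
  back <- read_signal_csv(p)
  expect_equal(back$current, sig$current)
  expect_equal(signal_boundaries(back)$end, signal_boundaries(sig)$end)
  expect_equal(signal_protocol(back)$dataset_id, "adenosine35")

  segs <- segmentize(sig)
  sp <- file.path(dir, "segs.csv")
  write_segments_csv(segs, sp)
  back2 <- read_segments_csv(sp)
  expect_equal(back2$values, segs$values)
  expect_equal(back2$concentration, segs$concentration)
})
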