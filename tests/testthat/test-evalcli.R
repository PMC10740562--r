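# independent brute-force metric oracle used in several tests
oracle_metrics <- function(truth, pred, m) {
  acc <- mean(truth == pred)
  f1s <- numeric(m)
  prec <- numeric(m); rec <- numeric(m)
  for (k in seq_len(m)) {
    tp <- sum(truth == k & pred == k)
    fp <- sum(truth != k & pred == k)
    fn <- sum(truth == k & pred != k)
    prec[k] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec[k] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1s[k] <- if (prec[k] + rec[k] > 0) 2 * prec[k] * rec[k] / (prec[k] + rec[k]) else 0
  }
  list(accuracy = acc, precision = prec, recall = rec, f1 = f1s,
       macro_f1 = mean(f1s))
}

test_that("mse is definitional and symmetric", {
  expect_equal(mse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mse(c(0, 0), c(3, 4)), 12.5)
  x <- rnorm(50); y <- rnorm(50)
  expect_equal(mse(x, y), mse(y, x))
  expect_equal(mse(x, y), sum((x - y)^2) / 50)
  expect_error(mse(1:3, 1:4), "equal length")
})

test_that("the worked confusion-matrix example computes by hand", {
  # rows (8,2) / (3,7): accuracy 15/20, class-1 precision 8/11, recall 0.8
  truth <- rep(c(1, 2), times = c(10, 10))
  pred <- c(rep(1, 8), rep(2, 2), rep(1, 3), rep(2, 7))
  rep_ <- confusion_and_metrics(truth, pred, 2)
  expect_equal(rep_$confusion, matrix(c(8L, 3L, 2L, 7L), 2))
  expect_equal(rep_$accuracy, 0.75)
  expect_equal(rep_$per_class$precision[1], 8 / 11)
  expect_equal(rep_$per_class$recall[1], 0.8)
})

test_that("perfect prediction yields accuracy and macro-F1 of 1", {
  y <- sample(1:5, 40, replace = TRUE)
  y[1:5] <- 1:5
  rep_ <- confusion_and_metrics(y, y, 5)
  expect_equal(rep_$accuracy, 1)
  expect_equal(rep_$macro_f1, 1)
})

test_that("a class absent from truth and prediction contributes F1 = 0", {
  rep_ <- confusion_and_metrics(c(1, 1, 2), c(1, 1, 2), m = 3)
  expect_equal(rep_$per_class$f1[3], 0)
  expect_equal(rep_$macro_f1, mean(c(1, 1, 0)))
  expect_error(confusion_and_metrics(c(1, 4), c(1, 1), m = 3), "1..m")
})

test_that("metrics agree exactly with the brute-force oracle on random labelings", {
  for (s in 1:25) {
    set.seed(s)
    m <- sample(2:12, 1)
    N <- sample(20:400, 1)
    truth <- sample(seq_len(m), N, replace = TRUE)
    pred <- sample(seq_len(m), N, replace = TRUE)
    rep_ <- confusion_and_metrics(truth, pred, m)
    orc <- oracle_metrics(truth, pred, m)
    expect_equal(rep_$accuracy, orc$accuracy)
    expect_equal(rep_$per_class$precision, orc$precision)
    expect_equal(rep_$per_class$recall, orc$recall)
    expect_equal(rep_$macro_f1, orc$macro_f1)
  }
})

test_that("accuracy equals micro-averaged recall and the trace identity holds", {
  set.seed(33)
  truth <- sample(1:6, 200, replace = TRUE)
  pred <- sample(1:6, 200, replace = TRUE)
  rep_ <- confusion_and_metrics(truth, pred, 6)
  cm <- rep_$confusion
  micro_recall <- sum(diag(cm)) / sum(cm)
  expect_equal(rep_$accuracy, micro_recall)
  expect_equal(rep_$accuracy, mean(truth == pred))
})

test_that("macro-F1 is invariant under class relabeling", {
  set.seed(34)
  truth <- sample(1:5, 150, replace = TRUE)
  pred <- sample(1:5, 150, replace = TRUE)
  perm <- sample(1:5)
  a <- confusion_and_metrics(truth, pred, 5)
  b <- confusion_and_metrics(perm[truth], perm[pred], 5)
  expect_equal(a$macro_f1, b$macro_f1)
  expect_equal(a$accuracy, b$accuracy)
})

test_that("tidy/glance methods return the expected tables", {
  rep_ <- confusion_and_metrics(c(1, 2, 2), c(1, 2, 1), 2)
  td <- tidy(rep_)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("class", "support", "precision", "recall", "f1"))
  gl <- glance(rep_)
  expect_equal(gl$n, 3)
})

test_that("a minimal pipeline produces segment and spectrogram artifacts only", {
  dir <- withr::local_tempdir()
  cfg <- pipeline_config(stages = c("simulate", "preprocess"),
                         n_normal_per_class = 2, seed = 5, out_dir = dir)
  run_pipeline(cfg)
  expect_true(file.exists(file.path(dir, "segments.csv")))
  expect_true(file.exists(file.path(dir, "example_signal.csv")))
  expect_false(file.exists(file.path(dir, "metrics.json")))
  log <- readLines(file.path(dir, "pipeline.log.jsonl"))
  expect_length(log, 2L)
  expect_match(log[2], "\"stage\":\"preprocess\"")
})

test_that("pipeline stages abort when their dependency has not run", {
  cfg <- pipeline_config(stages = "classify", out_dir = withr::local_tempdir())
  expect_error(run_pipeline(cfg), "preprocess")
  cfg2 <- pipeline_config(stages = "preprocess", out_dir = withr::local_tempdir())
  expect_error(run_pipeline(cfg2), "simulate")
})

test_that("a tiny end-to-end pipeline run is reproducible and reports all classes", {
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  base <- list(stages = c("simulate", "preprocess", "classify", "evaluate"),
               dataset_id = "oestradiol31", n_normal_per_class = 4L,
               clf_epochs = 2L, seed = 9L)
  r1 <- do.call(pipeline_config, c(base, list(out_dir = dir1)))
  r2 <- do.call(pipeline_config, c(base, list(out_dir = dir2)))
  run_pipeline(r1); run_pipeline(r2)
  m1 <- jsonlite::read_json(file.path(dir1, "metrics.json"), simplifyVector = TRUE)
  m2 <- jsonlite::read_json(file.path(dir2, "metrics.json"), simplifyVector = TRUE)
  expect_identical(m1$accuracy, m2$accuracy)
  expect_equal(dim(m1$confusion), c(6L, 6L))
})

test_that("pipeline configs round-trip through YAML", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "cfg.yml")
  yaml::write_yaml(list(stages = c("simulate", "preprocess"),
                        dataset_id = "adenosine35", n_normal_per_class = 3,
                        seed = 7, out_dir = file.path(dir, "out")), p)
  cfg <- read_pipeline_config(p)
  expect_s3_class(cfg, "pipeline_config")
  expect_equal(cfg$dataset_id, "adenosine35")
  expect_equal(cfg$seed, 7L)
})
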