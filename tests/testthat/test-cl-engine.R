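test_that("split_classes partitions with larger stages first", {
  s3 <- split_classes(1:13, 3)
  expect_equal(s3$m_k, c(5L, 4L, 4L))
  expect_equal(unlist(s3$stages), 1:13)
  s5 <- split_classes(1:13, 5)
  expect_equal(s5$m_k, c(3L, 3L, 3L, 2L, 2L))
  s13 <- split_classes(1:13, 13)
  expect_true(all(s13$m_k == 1L))
  expect_error(split_classes(1:5, 6), "class count")
  # shuffled splits are seeded-deterministic and still a partition
  a <- split_classes(1:13, 3, seed = 4, shuffle = TRUE)
  b <- split_classes(1:13, 3, seed = 4, shuffle = TRUE)
  expect_identical(a$stages, b$stages)
  expect_setequal(unlist(a$stages), 1:13)
  expect_false(identical(a$classes, 1:13))
})

test_that("run_stage enforces the zero-exemplar and label guards", {
  cfg <- tiny_config()
  m <- vit_model(cfg, 4, seed = 1)
  x <- tiny_batch(4, cfg)
  tc <- train_config(epochs_per_stage = 1L, batch_size = 4L)
  expect_error(run_stage(m, NULL, x, c(1L, 2L, 3L, 9L), 1:4, tc),
               "invalid label")
  expect_error(run_stage(m, NULL, x, c(1L, 2L, 3L, 4L), 3:4, tc),
               "zero-exemplar")
})

test_that("freezing keeps every non-head parameter fixed after stage 1", {
  ds <- small_dataset()
  m <- vit_model(tiny_config(), 4, seed = 2)
  tc <- train_config(epochs_per_stage = 2L, batch_size = 8L,
                     strategy = "freezing")
  backbone_sum <- function(mod) {
    fl <- vitalign:::flatten_params(mod$params)
    sum(vapply(fl[setdiff(names(fl), c("head_W", "head_b"))],
               function(w) sum(as.numeric(w)), 0.0))
  }
  before <- backbone_sum(m)
  head_before <- sum(m$params$head_W)
  fit <- run_stage(m, snapshot(m), ds$train$x, ds$train$y, 1:4, tc,
                   stage_index = 2L)
  expect_identical(backbone_sum(fit$model), before)
  expect_false(isTRUE(all.equal(sum(fit$model$params$head_W), head_before)))
  # at stage 1 freezing trains everything
  fit1 <- run_stage(m, NULL, ds$train$x, ds$train$y, 1:4, tc,
                    stage_index = 1L)
  expect_false(isTRUE(all.equal(backbone_sum(fit1$model), before)))
})

test_that("zero training steps leave the model untouched", {
  ds <- small_dataset()
  m <- vit_model(tiny_config(), 4, seed = 3)
  tc <- train_config(epochs_per_stage = 1L, batch_size = 8L)
  tc$epochs_per_stage <- 0L
  fit <- run_stage(m, NULL, ds$train$x, ds$train$y, 1:4, tc)
  expect_identical(vitalign:::param_checksum(fit$model$params),
                   vitalign:::param_checksum(m$params))
  expect_equal(nrow(fit$log), 0L)
})

test_that("finetuning equals attention alignment with lambda zero", {
  ds <- small_dataset()
  m <- vit_model(tiny_config(), 4, seed = 4)
  snap <- snapshot(m)
  tc_ft <- train_config(epochs_per_stage = 2L, batch_size = 8L,
                        strategy = "finetuning", seed = 5L)
  tc_l0 <- train_config(epochs_per_stage = 2L, batch_size = 8L,
                        strategy = "attention_alignment", seed = 5L,
                        alignment = alignment_config("tv", lambda = 0))
  fit_ft <- run_stage(m, snap, ds$train$x, ds$train$y, 1:4, tc_ft,
                      stage_index = 2L)
  fit_l0 <- run_stage(m, snap, ds$train$x, ds$train$y, 1:4, tc_l0,
                      stage_index = 2L)
  expect_equal(vitalign:::flatten_params(fit_ft$model$params),
               vitalign:::flatten_params(fit_l0$model$params),
               tolerance = 1e-12)
})

test_that("experiments are reproducible and reports well-formed", {
  ds <- small_dataset(n_classes = 4L, train = 6L, test = 3L)
  sq <- split_classes(1:4, 2)
  tc <- train_config(epochs_per_stage = 1L, batch_size = 8L,
                     strategy = "attention_alignment", seed = 9L,
                     learning_rate = 1e-3)
  r1 <- run_experiment(ds, sq, tc, model_config = tiny_config())
  r2 <- run_experiment(ds, sq, tc, model_config = tiny_config())
  expect_length(r1, 2L)
  for (t in 1:2) {
    expect_equal(r1[[t]]$accuracy, r2[[t]]$accuracy, tolerance = 1e-6)
    expect_equal(r1[[t]]$average_accuracy, r2[[t]]$average_accuracy,
                 tolerance = 1e-6)
    # confusion spans exactly the classes seen so far
    expect_equal(dim(r1[[t]]$confusion), rep(sum(sq$m_k[1:t]), 2L))
    expect_equal(sum(r1[[t]]$confusion), 3L * sum(sq$m_k[1:t]))
    expect_true(all(is.finite(r1[[t]]$loss_log$total)))
    expect_gte(r1[[t]]$average_accuracy, 0)
    expect_lte(r1[[t]]$average_accuracy, 1)
  }
  # snapshot chain: stage-2 report exists only after stage-1 training
  expect_equal(r1[[2]]$stage, 2L)
  expect_error(run_experiment(ds, split_classes(1:3, 2), tc,
                              model_config = tiny_config()),
               "classes")
})

test_that("single-stage sequence reduces to joint training", {
  ds <- small_dataset(n_classes = 3L, train = 6L, test = 3L)
  sq <- split_classes(1:3, 1)
  tc <- train_config(epochs_per_stage = 2L, batch_size = 8L,
                     optimizer = "adamw", strategy = "finetuning", seed = 2L)
  rep <- run_experiment(ds, sq, tc, model_config = tiny_config())
  expect_length(rep, 1L)
  expect_equal(rep[[1]]$average_accuracy, rep[[1]]$accuracy,
               tolerance = 1e-6)
})

test_that("stage outputs are written when out_dir is given", {
  ds <- small_dataset(n_classes = 3L, train = 6L, test = 3L)
  sq <- split_classes(1:3, 2)
  tc <- train_config(epochs_per_stage = 1L, batch_size = 8L, seed = 3L)
  out <- tempfile("run")
  run_experiment(ds, sq, tc, model_config = tiny_config(), out_dir = out)
  expect_true(file.exists(file.path(out, "stage_01.json")))
  expect_true(file.exists(file.path(out, "stage_02.json")))
  expect_true(file.exists(file.path(out, "average_accuracy.csv")))
  expect_true(file.exists(file.path(out, "stage_02.rds")))
  curve <- utils::read.csv(file.path(out, "average_accuracy.csv"))
  expect_equal(nrow(curve), 2L)
  j <- jsonlite::read_json(file.path(out, "stage_01.json"),
                           simplifyVector = TRUE)
  expect_equal(j$stage, 1L)
  unlink(out, recursive = TRUE)
})
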