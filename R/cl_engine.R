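#' Partition class labels into an incremental task sequence
#'
#' Splits the (optionally shuffled) class order contiguously into `K` stages
#' with sizes as equal as possible, larger stages first — e.g. 13 classes
#' give stage sizes (5, 4, 4) for K = 3 and (3, 3, 3, 2, 2) for K = 5.
#'
#' @param class_labels Ordered vector of class labels (names or indices).
#' @param K Number of stages; must not exceed the class count.
#' @param seed Seed for the shuffle (ignored when `shuffle = FALSE`).
#' @param shuffle Randomize the class order before partitioning.
#' @return An object of class `task_sequence`: list with `stages` (list of
#'   label vectors), `K`, `m_k` (per-stage counts), and `classes` (the
#'   concatenated order defining head indices).
#' @export
split_classes <- function(class_labels, K, seed = NULL, shuffle = FALSE) {
  n <- length(class_labels)
  if (!is_count(K) || K > n) {
    stop(sprintf("split_classes: K (%s) must be a positive integer <= class count (%d)",
                 format(K), n), call. = FALSE)
  }
  order_labels <- if (shuffle) {
    with_seed(seed, sample(class_labels))
  } else {
    class_labels
  }
  base <- n %/% K
  extra <- n %% K
  m_k <- rep(base, K) + c(rep(1L, extra), rep(0L, K - extra))
  ends <- cumsum(m_k)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  stages <- Map(function(s, e) order_labels[s:e], starts, ends)
  structure(list(stages = stages, K = as.integer(K), m_k = as.integer(m_k),
                 classes = order_labels),
            class = "task_sequence")
}

#' @export
print.task_sequence <- function(x, ...) {
  cat(sprintf("<task_sequence> %d classes in %d stages (%s)\n",
              length(x$classes), x$K, paste(x$m_k, collapse = ", ")))
  invisible(x)
}

#' Training configuration for the incremental engine
#'
#' @param epochs_per_stage Epochs per incremental stage (default 10; joint
#'   runs conventionally use 20).
#' @param batch_size Minibatch size.
#' @param optimizer `"adamax"` (default for incremental runs) or `"adamw"`
#'   (joint runs).
#' @param learning_rate Base learning rate; decayed with a cosine schedule
#'   within each stage.
#' @param seed Experiment seed; fans out deterministically to data
#'   shuffling, initialization and dropout.
#' @param strategy `"attention_alignment"` (regularize toward the frozen
#'   previous-stage snapshot), `"finetuning"` (no mechanism; the
#'   catastrophic-forgetting lower bound — forces `lambda = 0`), or
#'   `"freezing"` (backbone weights halt after the first stage; only the
#'   head keeps training).
#' @param alignment An [alignment_config()].
#' @param incremental_lr_factor Multiplier on `learning_rate` for stages
#'   after the first (default 0.3). The first stage trains from scratch and
#'   needs the full rate; later stages adapt an already-trained model, where
#'   the full rate lets moment optimizers rewrite the network wholesale
#'   within a few epochs regardless of strategy. The factor applies to every
#'   strategy identically, so comparisons remain matched.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs_per_stage = 10L, batch_size = 32L,
                         optimizer = c("adamax", "adamw"),
                         learning_rate = 5e-4, seed = 1L,
                         strategy = c("attention_alignment", "finetuning",
                                      "freezing"),
                         alignment = alignment_config(),
                         incremental_lr_factor = 0.3) {
  optimizer <- match.arg(optimizer)
  strategy <- match.arg(strategy)
  if (!is_count(epochs_per_stage)) {
    stop("train_config: epochs_per_stage must be >= 1", call. = FALSE)
  }
  if (!is_count(batch_size)) {
    stop("train_config: batch_size must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(learning_rate) || learning_rate <= 0) {
    stop("train_config: learning_rate must be > 0", call. = FALSE)
  }
  if (!is.numeric(incremental_lr_factor) || incremental_lr_factor <= 0 ||
      incremental_lr_factor > 1) {
    stop("train_config: incremental_lr_factor must be in (0, 1]",
         call. = FALSE)
  }
  stopifnot(inherits(alignment, "alignment_config"))
  structure(list(epochs_per_stage = as.integer(epochs_per_stage),
                 batch_size = as.integer(batch_size), optimizer = optimizer,
                 learning_rate = learning_rate, seed = as.integer(seed),
                 strategy = strategy, alignment = alignment,
                 incremental_lr_factor = incremental_lr_factor),
            class = "train_config")
}

# Names of head parameters (the only ones updated under freezing, t >= 2).
head_param_names <- c("head_W", "head_b")

#' Train the model on one incremental stage
#'
#' Minimizes the composite objective on the current stage's data only (the
#' zero-exemplar contract: no stored samples from past stages; a guard
#' rejects any sample whose label falls outside `stage_classes`). Under
#' `attention_alignment` with a snapshot present, each batch is also
#' forwarded through the frozen snapshot to produce the reference attention
#' stack. Under `freezing` (stage index >= 2) only the head is updated;
#' under `finetuning` the alignment weight is forced to 0.
#'
#' @param model The live [vit_model()], head already expanded to cover the
#'   current stage's labels.
#' @param snap Frozen [snapshot()] of the previous stage, or `NULL` on the
#'   first stage.
#' @param x Image array `(B, C, S, S)` for the current stage only.
#' @param y Integer head-index labels for `x`.
#' @param stage_classes Integer head indices belonging to the current stage.
#' @param config A [train_config()].
#' @param stage_index 1-based stage number (controls freezing).
#' @return List with the trained `model` and a per-step `log` data frame
#'   (columns: step, epoch, cross_entropy, attention, total).
#' @export
run_stage <- function(model, snap, x, y, stage_classes, config,
                      stage_index = 1L) {
  if (any(y > model$k_classes | y < 1L)) {
    stop(sprintf("run_stage: invalid label %d for a %d-class head",
                 y[y > model$k_classes | y < 1L][1L], model$k_classes),
         call. = FALSE)
  }
  if (any(!y %in% stage_classes)) {
    stop(sprintf(
      "run_stage: zero-exemplar violation — label %d is outside the current stage classes {%s}",
      y[!y %in% stage_classes][1L], paste(stage_classes, collapse = ",")),
      call. = FALSE)
  }
  acfg <- config$alignment
  if (config$strategy == "finetuning") acfg$lambda <- 0
  use_ref <- config$strategy == "attention_alignment" && !is.null(snap) &&
    acfg$lambda > 0
  freeze <- config$strategy == "freezing" && stage_index >= 2L
  mask <- if (freeze) head_param_names else NULL

  base_lr <- config$learning_rate *
    if (stage_index >= 2L) config$incremental_lr_factor %||% 1 else 1
  n <- length(y)
  n_batches <- max(1L, ceiling(n / config$batch_size))
  total_steps <- config$epochs_per_stage * n_batches
  flat <- flatten_params(model$params)
  state <- opt_init(flat)
  log <- vector("list", total_steps)
  step <- 0L

  if (config$epochs_per_stage >= 1L) {
    for (epoch in seq_len(config$epochs_per_stage)) {
      ord <- with_seed(
        derive_seed(config$seed, sprintf("stage%d-epoch%d", stage_index,
                                         epoch)),
        sample.int(n))
      for (bi in seq_len(n_batches)) {
        step <- step + 1L
        take <- ord[((bi - 1L) * config$batch_size + 1L):
                      min(bi * config$batch_size, n)]
        xb <- x[take, , , , drop = FALSE]
        yb <- y[take]
        model$params <- unflatten_params(flat, model$params)
        fw <- with_seed(
          derive_seed(config$seed, sprintf("drop%d-%d", stage_index, step)),
          vit_forward(model, xb, train = TRUE, keep_cache = !freeze))
        ce <- softmax_xent(fw$logits, yb)
        att_val <- 0
        dattn <- NULL
        if (use_ref) {
          ref <- vit_forward(snap, xb)$attn
          ag <- attention_alignment_grad(fw$attn, ref, acfg)
          att_val <- ag$value
          dattn <- lapply(ag$dattn, function(d) {
            if (is.null(d)) NULL else d * acfg$lambda
          })
        }
        total <- ce$loss + acfg$lambda * att_val
        if (!is.finite(total)) {
          stop(sprintf("run_stage: training diverged (non-finite loss) at stage %d step %d",
                       stage_index, step), call. = FALSE)
        }
        gflat <- if (freeze) {
          # only the head moves: its gradient needs no backward pass
          list(head_W = crossprod(fw$features, ce$dlogits),
               head_b = colSums(ce$dlogits))
        } else {
          flatten_params(vit_backward(model, fw$cache, ce$dlogits, dattn))
        }
        lr <- cosine_lr(base_lr, step, total_steps)
        res <- opt_step(state, flat, gflat, lr, config$optimizer,
                        mask = mask)
        state <- res$state
        flat <- res$flat
        log[[step]] <- data.frame(step = step, epoch = epoch,
                                  cross_entropy = ce$loss,
                                  attention = att_val, total = total)
      }
    }
  }
  model$params <- unflatten_params(flat, model$params)
  list(model = model,
       log = if (step > 0L) do.call(rbind, log[seq_len(step)]) else
         data.frame(step = integer(), epoch = integer(),
                    cross_entropy = numeric(), attention = numeric(),
                    total = numeric()))
}

# Accuracy of `model` on (x, y) plus predictions; y are head indices.
eval_accuracy <- function(model, x, y, batch_size = 64L) {
  pr <- model_predict(model, x, batch_size)
  list(accuracy = mean(pr$pred == y), pred = pr$pred)
}

#' Run a full class-incremental experiment
#'
#' For each stage: grow the classification head, train on the stage's
#' training data only, freeze a snapshot for the next stage, and evaluate on
#' the union of test data of all classes seen so far. Evaluation reports
#' top-1 accuracy over seen classes, per-class precision/sensitivity/F1, the
#' confusion matrix, per-stage accuracies, and the Average Accuracy (the
#' unweighted mean over stages learned so far of the model's test accuracy
#' on each stage's classes).
#'
#' @param dataset A dataset split as produced by [generate_dataset()] or
#'   [load_folder()].
#' @param sequence A [split_classes()] task sequence over
#'   `dataset$class_names` indices (1-based).
#' @param config A [train_config()].
#' @param model_config A [vit_config()] for the backbone.
#' @param out_dir Optional directory: per-stage JSON reports, the
#'   average-accuracy curve CSV, and per-stage checkpoints are written there.
#' @param verbose Print a one-line summary per stage.
#' @return List of `stage_report` objects, one per stage.
#' @export
run_experiment <- function(dataset, sequence, config,
                           model_config = vit_config(), out_dir = NULL,
                           verbose = FALSE) {
  stopifnot(inherits(sequence, "task_sequence"),
            inherits(config, "train_config"))
  if (any(lengths(sequence$stages) == 0L)) {
    stop("run_experiment: invalid sequence — empty stage", call. = FALSE)
  }
  n_classes <- length(dataset$class_names)
  if (!setequal(sequence$classes, seq_len(n_classes))) {
    stop(sprintf("run_experiment: sequence covers %d classes but the dataset has %d",
                 length(sequence$classes), n_classes), call. = FALSE)
  }
  # head index of original class c is its position in the stage order
  head_of <- match(seq_len(n_classes), sequence$classes)
  y_train <- head_of[dataset$train$y]
  y_test <- head_of[dataset$test$y]
  seen_ends <- cumsum(sequence$m_k)

  model <- NULL
  snap <- NULL
  reports <- vector("list", sequence$K)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  }

  for (t in seq_len(sequence$K)) {
    k_seen <- seen_ends[t]
    stage_classes <- (c(0L, seen_ends)[t] + 1L):k_seen
    if (is.null(model)) {
      model <- vit_model(model_config, n_classes = k_seen,
                         seed = derive_seed(config$seed, "init"))
    } else {
      model <- expand_head(model, k_seen,
                           seed = derive_seed(config$seed,
                                              sprintf("expand%d", t)))
    }
    tr_idx <- which(y_train %in% stage_classes)
    if (length(tr_idx) == 0L) {
      stop(sprintf("run_experiment: stage %d has no training data", t),
           call. = FALSE)
    }
    fit <- run_stage(model,
                     snap = snap,
                     x = dataset$train$x[tr_idx, , , , drop = FALSE],
                     y = y_train[tr_idx],
                     stage_classes = stage_classes,
                     config = config, stage_index = t)
    model <- fit$model
    snap <- snapshot(model)

    te_idx <- which(y_test <= k_seen)
    ev <- eval_accuracy(model, dataset$test$x[te_idx, , , , drop = FALSE],
                        y_test[te_idx])
    per_stage_acc <- vapply(seq_len(t), function(j) {
      jc <- (c(0L, seen_ends)[j] + 1L):seen_ends[j]
      sel <- y_test[te_idx] %in% jc
      mean(ev$pred[sel] == y_test[te_idx][sel])
    }, 0.0)
    cm <- confusion(y_test[te_idx], ev$pred, seq_len(k_seen))
    rownames(cm) <- colnames(cm) <-
      dataset$class_names[sequence$classes[seq_len(k_seen)]]
    mets <- classification_metrics(cm)
    reports[[t]] <- structure(list(
      stage = t,
      classes_seen = sequence$classes[seq_len(k_seen)],
      class_names = dataset$class_names[sequence$classes[seq_len(k_seen)]],
      accuracy = ev$accuracy,
      per_stage_accuracy = per_stage_acc,
      average_accuracy = average_accuracy(per_stage_acc),
      confusion = cm,
      per_class = mets$per_class,
      macro = mets$macro,
      loss_log = fit$log
    ), class = "stage_report")
    if (verbose) {
      cat(sprintf("stage %d/%d [%s]: acc %.4f  avg-acc %.4f\n", t,
                  sequence$K, config$strategy, ev$accuracy,
                  reports[[t]]$average_accuracy))
    }
    if (!is.null(out_dir)) {
      write_stage_report(reports[[t]], out_dir)
      save_checkpoint(model, file.path(out_dir,
                                       sprintf("stage_%02d.rds", t)))
    }
  }
  if (!is.null(out_dir)) {
    write_accuracy_curve(reports, file.path(out_dir, "average_accuracy.csv"))
  }
  reports
}

#' @export
print.stage_report <- function(x, ...) {
  cat(sprintf(
    "<stage_report> stage %d: %d classes seen, accuracy %.4f, average accuracy %.4f\n",
    x$stage, length(x$classes_seen), x$accuracy, x$average_accuracy))
  invisible(x)
}

write_stage_report <- function(report, dir) {
  obj <- list(
    stage = report$stage,
    classes_seen = report$classes_seen,
    class_names = report$class_names,
    accuracy = report$accuracy,
    per_stage_accuracy = report$per_stage_accuracy,
    average_accuracy = report$average_accuracy,
    confusion = unclass(report$confusion),
    per_class = report$per_class,
    macro = report$macro
  )
  jsonlite::write_json(obj, file.path(dir, sprintf("stage_%02d.json",
                                                   report$stage)),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(report$loss_log,
                   file.path(dir, sprintf("stage_%02d_loss.csv",
                                          report$stage)),
                   row.names = FALSE)
  invisible(NULL)
}

write_accuracy_curve <- function(reports, path) {
  df <- data.frame(
    stage = vapply(reports, function(r) r$stage, 0L),
    classes_seen = vapply(reports, function(r) length(r$classes_seen), 0L),
    accuracy = vapply(reports, function(r) r$accuracy, 0.0),
    average_accuracy = vapply(reports, function(r) r$average_accuracy, 0.0)
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
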