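#' Normalization factor of the Hellinger distance
#'
#' The Hellinger distance used here is `hellinger_norm * ||sqrt(p) -
#' sqrt(q)||_2` with `hellinger_norm = 1/sqrt(2)`, so that disjoint supports
#' give a distance of exactly 1.
#' @export
hellinger_norm <- 1 / sqrt(2)

#' Attention-alignment loss configuration
#'
#' @param distance Which distributional distance to apply per attention row:
#'   `"tv"` (total variation, the default and recommended choice), `"js"`
#'   (Jensen–Shannon divergence, natural log), `"hellinger"`, or
#'   `"bhattacharyya"`.
#' @param lambda Non-negative weight of the attention term in the composite
#'   objective `total = cross_entropy + lambda * attention`. The default 200
#'   is set by scale balancing: with `reduction = "mean"` the attention term
#'   on the default backbone is of order 5e-3 while the stage cross-entropy
#'   is of order 1, so a weight of order 1e2 makes the two terms comparable
#'   at the start of a stage.
#' @param reduction `"mean"` (default; average over all attention rows, so
#'   the signal is batch-size invariant) or `"sum"` (the literal accumulation
#'   over rows and blocks).
#' @param epsilon Small positive guard for logs, square roots and divisions;
#'   must lie in `(0, 1e-3]`.
#' @param blocks Integer vector of transformer-block indices contributing to
#'   the loss; `NULL` means all blocks.
#' @return An object of class `alignment_config`.
#' @export
alignment_config <- function(distance = c("tv", "js", "hellinger",
                                          "bhattacharyya"),
                             lambda = 200, reduction = c("mean", "sum"),
                             epsilon = 1e-8, blocks = NULL) {
  distance <- match.arg(distance)
  reduction <- match.arg(reduction)
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0) {
    stop("alignment_config: lambda must be a non-negative scalar",
         call. = FALSE)
  }
  if (!is.numeric(epsilon) || epsilon <= 0 || epsilon > 1e-3) {
    stop("alignment_config: epsilon must be in (0, 1e-3]", call. = FALSE)
  }
  if (!is.null(blocks)) {
    blocks <- as.integer(blocks)
    if (any(blocks < 1L)) {
      stop("alignment_config: blocks must be positive indices", call. = FALSE)
    }
  }
  structure(list(distance = distance, lambda = lambda, reduction = reduction,
                 epsilon = epsilon, blocks = blocks),
            class = "alignment_config")
}

#' Normalize attention rows into probability distributions
#'
#' Takes absolute values elementwise and divides each row by its sum (with an
#' epsilon guard), so every row becomes a probability vector. A row of exact
#' zeros is mapped to the uniform distribution.
#'
#' @param x Numeric matrix (rows are treated as unnormalized distributions)
#'   or a vector (treated as one row).
#' @param epsilon Division guard.
#' @return Row-stochastic matrix (or vector, matching the input shape).
#' @export
normalize_rows <- function(x, epsilon = 1e-8) {
  vec <- is.null(dim(x))
  m <- if (vec) matrix(x, nrow = 1L) else x
  if (!all(is.finite(m))) {
    stop("normalize_rows: input must be finite", call. = FALSE)
  }
  a <- abs(m)
  s <- rowSums(a)
  zero <- s == 0
  out <- a / (s + epsilon)
  if (any(zero)) {
    if (isTRUE(getOption("vitalign.debug"))) {
      message(sprintf("normalize_rows: %d all-zero row(s) set to uniform",
                      sum(zero)))
    }
    out[zero, ] <- 1 / ncol(m)
  }
  if (vec) out[1L, ] else out
}

check_pair <- function(p, q, caller) {
  if (length(p) != length(q)) {
    stop_dim("%s: length mismatch (%d vs %d)", caller, length(p), length(q))
  }
}

# ---- vectorized per-row distances (rows of P vs rows of Q) -----------------

row_tv <- function(P, Q) 0.5 * rowSums(abs(P - Q))

row_js <- function(P, Q, epsilon = 1e-8) {
  M <- (P + Q) / 2
  0.5 * rowSums(P * (log(P + epsilon) - log(M + epsilon))) +
    0.5 * rowSums(Q * (log(Q + epsilon) - log(M + epsilon)))
}

row_hellinger <- function(P, Q) {
  hellinger_norm * sqrt(rowSums((sqrt(P) - sqrt(Q))^2))
}

row_bhattacharyya <- function(P, Q, epsilon = 1e-8) {
  -log(pmax(rowSums(sqrt(P * Q)), epsilon))
}

row_distance <- function(P, Q, distance, epsilon = 1e-8) {
  switch(distance,
         tv = row_tv(P, Q),
         js = row_js(P, Q, epsilon),
         hellinger = row_hellinger(P, Q),
         bhattacharyya = row_bhattacharyya(P, Q, epsilon),
         stop("unknown distance: ", distance, call. = FALSE))
}

# d(distance)/dP for each row; P carries the gradient (the current model),
# Q is the frozen reference. Guards mirror the value functions so
# finite-difference checks agree.
row_distance_grad <- function(P, Q, distance, epsilon = 1e-8) {
  switch(
    distance,
    tv = 0.5 * sign(P - Q),
    js = {
      M <- (P + Q) / 2
      0.5 * (log(P + epsilon) - log(M + epsilon)) +
        0.5 * P / (P + epsilon) - 0.25 * (P + Q) / (M + epsilon)
    },
    hellinger = {
      S <- sqrt(rowSums((sqrt(P) - sqrt(Q))^2))
      sp <- sqrt(P + epsilon)
      (hellinger_norm * (sp - sqrt(Q + epsilon)) / sp) / (2 * pmax(S, epsilon))
    },
    bhattacharyya = {
      bc <- pmax(rowSums(sqrt(P * Q)), epsilon)
      -0.5 * sqrt((Q + epsilon) / (P + epsilon)) / bc
    },
    stop("unknown distance: ", distance, call. = FALSE))
}

# ---- scalar (probability-vector) API ---------------------------------------

#' Distributional distances between probability vectors
#'
#' Distances between two discrete probability distributions, applied per
#' attention row by the alignment loss:
#' * `tv_distance`: total variation, `0.5 * sum(|p - q|)`, in `[0, 1]`.
#' * `js_divergence`: Jensen–Shannon divergence with natural logarithm,
#'   `0.5 KL(p||m) + 0.5 KL(q||m)` with `m = (p+q)/2`, in `[0, ln 2]`.
#' * `hellinger_distance`: `1/sqrt(2) * ||sqrt(p) - sqrt(q)||_2`, in
#'   `[0, 1]`.
#' * `bhattacharyya_distance`: `-log(sum(sqrt(p*q)))`, non-negative; the
#'   coefficient is clamped below by `epsilon` so disjoint supports give the
#'   finite value `-log(epsilon)`.
#'
#' @param p,q Probability vectors of equal length (non-negative, summing
#'   to 1).
#' @param epsilon Stability guard for logarithms and the Bhattacharyya clamp.
#' @return A single non-negative number.
#' @export
tv_distance <- function(p, q) {
  check_pair(p, q, "tv_distance")
  row_tv(matrix(p, 1L), matrix(q, 1L))[1L]
}

#' @rdname tv_distance
#' @export
js_divergence <- function(p, q, epsilon = 1e-8) {
  check_pair(p, q, "js_divergence")
  row_js(matrix(p, 1L), matrix(q, 1L), epsilon)[1L]
}

#' @rdname tv_distance
#' @export
hellinger_distance <- function(p, q) {
  check_pair(p, q, "hellinger_distance")
  row_hellinger(matrix(p, 1L), matrix(q, 1L))[1L]
}

#' @rdname tv_distance
#' @export
bhattacharyya_distance <- function(p, q, epsilon = 1e-8) {
  check_pair(p, q, "bhattacharyya_distance")
  row_bhattacharyya(matrix(p, 1L), matrix(q, 1L), epsilon)[1L]
}

# ---- alignment loss over attention stacks ----------------------------------

select_blocks <- function(stack, blocks, caller) {
  if (is.null(blocks)) return(seq_along(stack))
  if (any(blocks > length(stack))) {
    stop_dim("%s: block selector %s exceeds stack depth %d", caller,
             paste(blocks[blocks > length(stack)], collapse = ","),
             length(stack))
  }
  blocks
}

check_stacks <- function(current, reference, caller) {
  if (length(current) != length(reference)) {
    stop_dim("%s: stacks have %d vs %d blocks", caller, length(current),
             length(reference))
  }
  for (l in seq_along(current)) {
    if (!identical(dim(current[[l]]), dim(reference[[l]]))) {
      stop_dim("%s: shape mismatch at block %d (%s vs %s)", caller, l,
               paste(dim(current[[l]]), collapse = "x"),
               paste(dim(reference[[l]]), collapse = "x"))
    }
  }
}

# Each (batch, head, query) slice of a (B,H,N,N) attention array is one
# distribution over the N keys; matrix(A, B*H*N, N) lays those rows out
# directly (keys are the last, slowest-varying dimension).
stack_rows <- function(A) {
  d <- dim(A)
  matrix(A, nrow = d[1] * d[2] * d[3], ncol = d[4])
}

#' Accumulated attention-alignment loss between two attention stacks
#'
#' Flattens every (batch, head, query) attention slice into a distribution
#' over keys, renormalizes both operands with [normalize_rows()], applies the
#' configured per-row distance between the current and reference rows,
#' reduces over rows (`mean` or `sum`), and sums the per-block results over
#' the selected blocks.
#'
#' @param current Attention stack of the live model (from [vit_forward()]).
#' @param reference Attention stack of the frozen previous-stage snapshot on
#'   the same batch.
#' @param config An [alignment_config()].
#' @return A single non-negative number.
#' @export
attention_alignment_loss <- function(current, reference,
                                     config = alignment_config()) {
  check_stacks(current, reference, "attention_alignment_loss")
  sel <- select_blocks(current, config$blocks, "attention_alignment_loss")
  total <- 0
  for (l in sel) {
    P <- normalize_rows(stack_rows(current[[l]]), config$epsilon)
    Q <- normalize_rows(stack_rows(reference[[l]]), config$epsilon)
    d <- row_distance(P, Q, config$distance, config$epsilon)
    total <- total + if (config$reduction == "mean") mean(d) else sum(d)
  }
  total
}

# Value plus gradient with respect to the current post-softmax attention
# entries (list of (B,H,N,N) arrays, NULL for unselected blocks). The
# gradient chains through normalize_rows; it is NOT lambda-scaled.
attention_alignment_grad <- function(current, reference, config) {
  check_stacks(current, reference, "attention_alignment_loss")
  sel <- select_blocks(current, config$blocks, "attention_alignment_loss")
  total <- 0
  dattn <- vector("list", length(current))
  for (l in sel) {
    X <- stack_rows(current[[l]])          # raw post-softmax rows (>= 0)
    s <- rowSums(abs(X))
    P <- normalize_rows(X, config$epsilon)
    Q <- normalize_rows(stack_rows(reference[[l]]), config$epsilon)
    d <- row_distance(P, Q, config$distance, config$epsilon)
    gP <- row_distance_grad(P, Q, config$distance, config$epsilon)
    if (config$reduction == "mean") {
      total <- total + mean(d)
      gP <- gP / nrow(P)
    } else {
      total <- total + sum(d)
    }
    # back through y = |x| / (sum|x| + eps)
    gX <- sign(X) * (gP - rowSums(gP * P)) / (s + config$epsilon)
    dattn[[l]] <- array(gX, dim = dim(current[[l]]))
  }
  list(value = total, dattn = dattn)
}

# ---- composite objective ---------------------------------------------------

# Softmax cross-entropy averaged over the batch, with gradient w.r.t. logits.
softmax_xent <- function(logits, labels) {
  if (any(labels < 1L) || any(labels > ncol(logits))) {
    bad <- labels[labels < 1L | labels > ncol(logits)][1L]
    stop(sprintf("invalid label %d for %d-way logits", bad, ncol(logits)),
         call. = FALSE)
  }
  B <- nrow(logits)
  sm <- softmax_rows(logits)
  picked <- sm[cbind(seq_len(B), labels)]
  loss <- -mean(log(pmax(picked, 1e-12)))
  d <- sm
  d[cbind(seq_len(B), labels)] <- d[cbind(seq_len(B), labels)] - 1
  list(loss = loss, dlogits = d / B)
}

#' Composite training objective: cross-entropy plus attention alignment
#'
#' `total = cross_entropy + lambda * attention`, where the cross-entropy is
#' the batch mean of `-log softmax(logits)[label]` and the attention term is
#' the [attention_alignment_loss()] between the current and reference
#' attention stacks. On the first stage (no reference yet) the attention term
#' is 0.
#'
#' @param logits `B x K` logit matrix from the live model.
#' @param labels Integer class labels in `1..K`.
#' @param current Attention stack of the live model (may be `NULL` when no
#'   reference exists).
#' @param reference Attention stack of the frozen snapshot, or `NULL` on the
#'   first stage.
#' @param config An [alignment_config()].
#' @return An object of class `loss_breakdown`: list with `cross_entropy`,
#'   `attention` and `total`.
#' @export
composite_loss <- function(logits, labels, current = NULL, reference = NULL,
                           config = alignment_config()) {
  ce <- softmax_xent(logits, labels)$loss
  att <- if (!is.null(reference)) {
    attention_alignment_loss(current, reference, config)
  } else {
    0
  }
  structure(list(cross_entropy = ce, attention = att,
                 total = ce + config$lambda * att),
            class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf("cross_entropy %.6f  attention %.6f  total %.6f\n",
              x$cross_entropy, x$attention, x$total))
  invisible(x)
}
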