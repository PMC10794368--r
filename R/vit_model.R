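#' Initialize a compact Vision Transformer
#'
#' Creates a ViT with a growable linear classification head. All weights are
#' drawn from a truncated normal (sd 0.02, the standard transformer init);
#' layer-norm scales start at 1, biases at 0. Training is from scratch; no
#' pretrained weights are used or downloadable.
#'
#' @param config A [vit_config()].
#' @param n_classes Initial number of output classes (the head can grow later
#'   with [expand_head()]).
#' @param seed Integer seed for the weight initialization; `NULL` uses the
#'   current RNG state.
#' @return An object of class `vit_model`: a list with `config`, `params`
#'   (nested list of weight arrays), `k_classes`, and the patch index table.
#' @export
vit_model <- function(config, n_classes, seed = NULL) {
  stopifnot(inherits(config, "vit_config"))
  if (!is_count(n_classes)) {
    stop("vit_model: n_classes must be a positive integer", call. = FALSE)
  }
  D <- config$embed_dim
  Dm <- config$mlp_dim
  pdim <- config$patch_size^2 * config$channels
  params <- with_seed(seed, {
    blocks <- lapply(seq_len(config$depth), function(l) {
      W_qkv <- matrix(trunc_normal(D * 3L * D), D, 3L * D)
      W_qkv[, seq_len(2L * D)] <- W_qkv[, seq_len(2L * D)] *
        config$qk_init_gain
      list(
        ln1_g = rep(1, D), ln1_b = rep(0, D),
        W_qkv = W_qkv,
        b_qkv = rep(0, 3L * D),
        W_o   = matrix(trunc_normal(D * D), D, D),
        b_o   = rep(0, D),
        ln2_g = rep(1, D), ln2_b = rep(0, D),
        W_fc1 = matrix(trunc_normal(D * Dm), D, Dm),
        b_fc1 = rep(0, Dm),
        W_fc2 = matrix(trunc_normal(Dm * D), Dm, D),
        b_fc2 = rep(0, D)
      )
    })
    list(
      patch_W = matrix(trunc_normal(pdim * D), pdim, D),
      patch_b = rep(0, D),
      cls     = trunc_normal(D),
      pos     = matrix(trunc_normal(config$seq_len * D), config$seq_len, D),
      blocks  = blocks,
      ln_f_g  = rep(1, D), ln_f_b = rep(0, D),
      head_W  = matrix(trunc_normal(D * n_classes), D, n_classes),
      head_b  = rep(0, n_classes)
    )
  })
  structure(list(
    config = config,
    params = params,
    k_classes = as.integer(n_classes),
    patch_idx = patch_offsets(config)
  ), class = "vit_model")
}

#' @export
print.vit_model <- function(x, ...) {
  np <- sum(vapply(flatten_params(x$params), length, 0L))
  cat(sprintf("<vit_model> %d classes, %s parameters\n", x$k_classes,
              format(np, big.mark = ",")))
  print(x$config)
  invisible(x)
}

add_bias <- function(m, b) m + rep(b, each = nrow(m))

gelu <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

ln_forward <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc * inv
  list(out = add_bias(xhat * rep(g, each = nrow(x)), b), xhat = xhat,
       inv = inv)
}

ln_backward <- function(dout, xhat, inv, g) {
  dg <- colSums(dout * xhat)
  db <- colSums(dout)
  dxhat <- dout * rep(g, each = nrow(dout))
  dx <- inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx, dg = dg, db = db)
}

#' Scaled dot-product attention
#'
#' Computes `ATTN' = softmax(Q K^T / sqrt(d))` row-wise and the weighted
#' values `Z = ATTN' V` for one head. Each query row of `ATTN'` is a
#' probability distribution over keys.
#'
#' @param Q,K,V Numeric matrices; `Q` is `n_q x d`, `K` and `V` are
#'   `n_k x d`.
#' @param d Head dimension used for the `1/sqrt(d)` scaling; defaults to
#'   `ncol(Q)`.
#' @return A list with `Z` (`n_q x d`) and `attn` (`n_q x n_k`,
#'   row-stochastic).
#' @export
scaled_dot_product_attention <- function(Q, K, V, d = ncol(Q)) {
  if (!is.numeric(d) || length(d) != 1L || d <= 0) {
    stop("scaled_dot_product_attention: head dimension d must be > 0",
         call. = FALSE)
  }
  if (ncol(Q) != ncol(K) || nrow(K) != nrow(V)) {
    stop_dim("scaled_dot_product_attention: incompatible shapes Q %dx%d, K %dx%d, V %dx%d",
             nrow(Q), ncol(Q), nrow(K), ncol(K), nrow(V), ncol(V))
  }
  A <- softmax_rows((Q %*% t(K)) / sqrt(d))
  list(Z = A %*% V, attn = A)
}

#' Forward pass of the ViT
#'
#' Runs a batch through the model and returns logits, the full stack of
#' post-softmax attention maps, and the pre-head class-token features. With
#' `train = FALSE` (or `dropout = 0` in the config) the pass is
#' deterministic.
#'
#' @param model A [vit_model()].
#' @param x Image batch, a numeric array of shape
#'   `(B, channels, image_size, image_size)` with values typically in
#'   `[0, 1]`.
#' @param train Logical; enables dropout (using the current RNG state) and,
#'   with `keep_cache = TRUE`, retains the intermediates needed for the
#'   backward pass.
#' @param keep_cache Logical; retain intermediates for [vit_backward()].
#' @return A list with `logits` (`B x k_classes`), `attn` (an
#'   `attention_stack`: one `(B, H, N, N)` array per block), `features`
#'   (`B x D`), and (if requested) `cache`.
#' @export
vit_forward <- function(model, x, train = FALSE, keep_cache = FALSE) {
  cfg <- model$config
  p <- model$params
  if (length(dim(x)) != 4L) {
    stop_dim("vit_forward: expected a 4-d (B, C, %d, %d) array, got %d dims",
             cfg$image_size, cfg$image_size, length(dim(x)))
  }
  dm <- dim(x)
  if (dm[2] != cfg$channels || dm[3] != cfg$image_size ||
      dm[4] != cfg$image_size) {
    stop_dim("vit_forward: image batch is (%d,%d,%d,%d) but config expects (B,%d,%d,%d)",
             dm[1], dm[2], dm[3], dm[4], cfg$channels, cfg$image_size,
             cfg$image_size)
  }
  B <- dm[1]
  N <- cfg$seq_len
  n <- cfg$n_patches
  D <- cfg$embed_dim
  H <- cfg$heads
  dh <- cfg$head_dim
  drop_p <- if (train) cfg$dropout else 0

  # patchify: rows are (sample-major) flattened patches
  om <- model$patch_idx[rep(seq_len(n), times = B), , drop = FALSE]
  idx <- rep(seq_len(B), each = n) + B * om
  patches <- matrix(x[idx], nrow = B * n, ncol = ncol(om))

  tok <- add_bias(patches %*% p$patch_W, p$patch_b)
  X <- matrix(0, B * N, D)
  cls_rows <- seq(1L, B * N, by = N)
  X[cls_rows, ] <- matrix(p$cls, B, D, byrow = TRUE)
  X[-cls_rows, ] <- tok
  X <- X + p$pos[rep(seq_len(N), B), , drop = FALSE]

  dropmask <- function(nr, nc) {
    if (drop_p > 0) {
      matrix(stats::rbinom(nr * nc, 1L, 1 - drop_p), nr, nc) / (1 - drop_p)
    } else {
      NULL
    }
  }
  m_emb <- dropmask(B * N, D)
  if (!is.null(m_emb)) X <- X * m_emb

  attn_stack <- vector("list", cfg$depth)
  caches <- if (keep_cache) vector("list", cfg$depth) else NULL

  for (l in seq_len(cfg$depth)) {
    bp <- p$blocks[[l]]
    ln1 <- ln_forward(X, bp$ln1_g, bp$ln1_b)
    qkv <- add_bias(ln1$out %*% bp$W_qkv, bp$b_qkv)
    A4 <- array(0, c(B, H, N, N))
    Zmat <- matrix(0, B * N, D)
    scale <- 1 / sqrt(dh)
    for (b in seq_len(B)) {
      rows <- ((b - 1L) * N + 1L):(b * N)
      for (h in seq_len(H)) {
        hc <- ((h - 1L) * dh + 1L):(h * dh)
        Qb <- qkv[rows, hc, drop = FALSE]
        Kb <- qkv[rows, D + hc, drop = FALSE]
        Vb <- qkv[rows, 2L * D + hc, drop = FALSE]
        A <- softmax_rows(tcrossprod(Qb, Kb) * scale)
        A4[b, h, , ] <- A
        Zmat[rows, hc] <- A %*% Vb
      }
    }
    proj <- add_bias(Zmat %*% bp$W_o, bp$b_o)
    m_attn <- dropmask(B * N, D)
    if (!is.null(m_attn)) proj <- proj * m_attn
    X <- X + proj

    ln2 <- ln_forward(X, bp$ln2_g, bp$ln2_b)
    h1 <- add_bias(ln2$out %*% bp$W_fc1, bp$b_fc1)
    a <- gelu(h1)
    h2 <- add_bias(a %*% bp$W_fc2, bp$b_fc2)
    m_mlp <- dropmask(B * N, D)
    if (!is.null(m_mlp)) h2 <- h2 * m_mlp
    X <- X + h2

    attn_stack[[l]] <- A4
    if (keep_cache) {
      caches[[l]] <- list(ln1 = ln1, qkv = qkv, attn = A4, Zmat = Zmat,
                          m_attn = m_attn, ln2 = ln2, h1 = h1, a = a,
                          m_mlp = m_mlp)
    }
  }

  lnf <- ln_forward(X, p$ln_f_g, p$ln_f_b)
  features <- lnf$out[cls_rows, , drop = FALSE]
  logits <- add_bias(features %*% p$head_W, p$head_b)

  out <- list(
    logits = logits,
    attn = new_attention_stack(attn_stack),
    features = features
  )
  if (keep_cache) {
    out$cache <- list(B = B, patches = patches, m_emb = m_emb,
                      blocks = caches, lnf = lnf, features = features,
                      cls_rows = cls_rows)
  }
  out
}

new_attention_stack <- function(maps) {
  structure(maps, class = "attention_stack")
}

#' @export
print.attention_stack <- function(x, ...) {
  d <- dim(x[[1]])
  cat(sprintf("<attention_stack> %d blocks, each (B=%d, H=%d, %dx%d)\n",
              length(x), d[1], d[2], d[3], d[4]))
  invisible(x)
}

# Backward pass: given upstream gradients for the logits and (optionally)
# for the post-softmax attention maps of each block, accumulate gradients
# for every parameter. `dattn` mirrors the attention stack (list of
# (B,H,N,N) arrays, or NULL entries for blocks without an alignment term).
vit_backward <- function(model, cache, dlogits, dattn = NULL) {
  cfg <- model$config
  p <- model$params
  B <- cache$B
  N <- cfg$seq_len
  D <- cfg$embed_dim
  H <- cfg$heads
  dh <- cfg$head_dim
  cls_rows <- cache$cls_rows
  g <- list()

  g$head_W <- crossprod(cache$features, dlogits)
  g$head_b <- colSums(dlogits)
  dln_out <- matrix(0, B * N, D)
  dln_out[cls_rows, ] <- dlogits %*% t(p$head_W)
  lb <- ln_backward(dln_out, cache$lnf$xhat, cache$lnf$inv, p$ln_f_g)
  g$ln_f_g <- lb$dg
  g$ln_f_b <- lb$db
  dX <- lb$dx

  g$blocks <- vector("list", cfg$depth)
  scale <- 1 / sqrt(dh)
  for (l in rev(seq_len(cfg$depth))) {
    bp <- p$blocks[[l]]
    ck <- cache$blocks[[l]]
    gb <- list()

    # MLP branch
    dh2 <- if (is.null(ck$m_mlp)) dX else dX * ck$m_mlp
    gb$W_fc2 <- crossprod(ck$a, dh2)
    gb$b_fc2 <- colSums(dh2)
    da <- dh2 %*% t(bp$W_fc2)
    dh1 <- da * gelu_grad(ck$h1)
    gb$W_fc1 <- crossprod(ck$ln2$out, dh1)
    gb$b_fc1 <- colSums(dh1)
    dln2 <- dh1 %*% t(bp$W_fc1)
    lb2 <- ln_backward(dln2, ck$ln2$xhat, ck$ln2$inv, bp$ln2_g)
    gb$ln2_g <- lb2$dg
    gb$ln2_b <- lb2$db
    dX <- dX + lb2$dx

    # attention branch
    dproj <- if (is.null(ck$m_attn)) dX else dX * ck$m_attn
    gb$W_o <- crossprod(ck$Zmat, dproj)
    gb$b_o <- colSums(dproj)
    dZmat <- dproj %*% t(bp$W_o)
    dqkv <- matrix(0, B * N, 3L * D)
    dattn_l <- if (!is.null(dattn)) dattn[[l]] else NULL
    for (b in seq_len(B)) {
      rows <- ((b - 1L) * N + 1L):(b * N)
      for (h in seq_len(H)) {
        hc <- ((h - 1L) * dh + 1L):(h * dh)
        A <- ck$attn[b, h, , ]
        Qb <- ck$qkv[rows, hc, drop = FALSE]
        Kb <- ck$qkv[rows, D + hc, drop = FALSE]
        Vb <- ck$qkv[rows, 2L * D + hc, drop = FALSE]
        dZ <- dZmat[rows, hc, drop = FALSE]
        dA <- tcrossprod(dZ, Vb)
        if (!is.null(dattn_l)) dA <- dA + dattn_l[b, h, , ]
        dS <- A * (dA - rowSums(dA * A))
        dqkv[rows, hc] <- dqkv[rows, hc] + (dS %*% Kb) * scale
        dqkv[rows, D + hc] <- dqkv[rows, D + hc] + (crossprod(dS, Qb)) * scale
        dqkv[rows, 2L * D + hc] <- dqkv[rows, 2L * D + hc] + crossprod(A, dZ)
      }
    }
    gb$W_qkv <- crossprod(ck$ln1$out, dqkv)
    gb$b_qkv <- colSums(dqkv)
    dln1 <- dqkv %*% t(bp$W_qkv)
    lb1 <- ln_backward(dln1, ck$ln1$xhat, ck$ln1$inv, bp$ln1_g)
    gb$ln1_g <- lb1$dg
    gb$ln1_b <- lb1$db
    dX <- dX + lb1$dx

    g$blocks[[l]] <- gb
  }

  if (!is.null(cache$m_emb)) dX <- dX * cache$m_emb
  token_idx <- rep(seq_len(N), B)
  g$pos <- rowsum(dX, token_idx)
  dimnames(g$pos) <- NULL
  g$cls <- colSums(dX[cls_rows, , drop = FALSE])
  dtok <- dX[-cls_rows, , drop = FALSE]
  g$patch_W <- crossprod(cache$patches, dtok)
  g$patch_b <- colSums(dtok)

  # order fields to match the params template
  g[c("patch_W", "patch_b", "cls", "pos", "blocks", "ln_f_g", "ln_f_b",
      "head_W", "head_b")]
}

#' Grow the classification head for newly arrived classes
#'
#' Appends freshly initialized output units for new classes while keeping the
#' existing units bit-identical, so logits for previously seen classes are
#' unchanged on any fixed input. Uses a single growing head (one unified
#' output space), as class-incremental evaluation scores the model over all
#' classes seen so far.
#'
#' @param model A [vit_model()].
#' @param new_class_count Total class count after growth; must exceed the
#'   current `k_classes`.
#' @param seed Seed for the new-unit initializer (truncated normal sd 0.02;
#'   biases 0).
#' @return The model with an enlarged head.
#' @export
expand_head <- function(model, new_class_count, seed = NULL) {
  stopifnot(inherits(model, "vit_model"))
  if (!is_count(new_class_count) || new_class_count <= model$k_classes) {
    stop(sprintf(
      "expand_head: new_class_count (%s) must exceed current k_classes (%d)",
      format(new_class_count), model$k_classes), call. = FALSE)
  }
  D <- model$config$embed_dim
  k_old <- model$k_classes
  k_new <- as.integer(new_class_count)
  W <- matrix(0, D, k_new)
  W[, seq_len(k_old)] <- model$params$head_W
  W[, (k_old + 1L):k_new] <- with_seed(
    seed, matrix(trunc_normal(D * (k_new - k_old)), D, k_new - k_old))
  model$params$head_W <- W
  model$params$head_b <- c(model$params$head_b, rep(0, k_new - k_old))
  model$k_classes <- k_new
  model
}

#' Freeze a copy of the model as the previous-task reference
#'
#' Returns a deep, frozen copy of the model. Forwarding data through the
#' snapshot yields the reference attention distributions used by the
#' attention-alignment regularizer; the snapshot is never updated by
#' subsequent training of the live model.
#'
#' @param model A [vit_model()].
#' @return An object of classes `model_snapshot` and `vit_model`.
#' @export
snapshot <- function(model) {
  stopifnot(inherits(model, "vit_model"))
  snap <- unclass(model)
  structure(snap, class = c("model_snapshot", "vit_model"), frozen = TRUE)
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single serialized file holding the config, all
#' parameters and the current class count; loading restores bit-identical
#' forward behaviour.
#'
#' @param model A [vit_model()].
#' @param path File path.
#' @return `load_checkpoint` returns the restored `vit_model`.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "vit_model"))
  saveRDS(unclass(model)[c("config", "params", "k_classes")], path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  structure(list(
    config = obj$config,
    params = obj$params,
    k_classes = obj$k_classes,
    patch_idx = patch_offsets(obj$config)
  ), class = "vit_model")
}

# Batched deterministic inference; returns logits, features, and predicted
# 1-based class indices. Used by evaluation and feature export.
model_predict <- function(model, x, batch_size = 64L, attn = FALSE) {
  B <- dim(x)[1]
  logits <- matrix(0, B, model$k_classes)
  features <- matrix(0, B, model$config$embed_dim)
  starts <- seq(1L, B, by = batch_size)
  for (s in starts) {
    e <- min(s + batch_size - 1L, B)
    fw <- vit_forward(model, x[s:e, , , , drop = FALSE])
    logits[s:e, ] <- fw$logits
    features[s:e, ] <- fw$features
  }
  list(logits = logits, features = features,
       pred = max.col(logits, ties.method = "first"))
}
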