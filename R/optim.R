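# First-moment / second-moment optimizers over flat named parameter lists.
# AdamW is used for joint training, AdaMax for the incremental stages.

opt_init <- function(flat) {
  zeros <- lapply(flat, function(w) array(0, dim = dim(w) %||% length(w)))
  list(t = 0L, m = zeros, v = zeros)
}

# One update. `mask`: names of parameters allowed to move (NULL = all);
# frozen parameters also keep their optimizer state untouched. Weight decay
# (AdamW only) applies to matrices, not biases or layer-norm vectors.
opt_step <- function(state, flat, grads, lr, type = c("adamw", "adamax"),
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-4,
                     weight_decay = 0.01, mask = NULL) {
  type <- match.arg(type)
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- mask %||% names(flat)
  for (nm in upd) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    if (type == "adamw") {
      state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
      step <- (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
      if (weight_decay > 0 && !is.null(dim(flat[[nm]]))) {
        step <- step + weight_decay * flat[[nm]]
      }
    } else {
      state$v[[nm]] <- pmax(beta2 * state$v[[nm]], abs(g))
      step <- (state$m[[nm]] / bc1) / (state$v[[nm]] + eps)
    }
    flat[[nm]] <- flat[[nm]] - lr * step
  }
  list(state = state, flat = flat)
}

# Linear warmup over the first `warmup_frac` of steps, then cosine decay.
# Warmup counters the noisy sign-like early steps of moment optimizers,
# which at this parameter scale (init sd 0.02) otherwise knock the model
# around before the moment estimates are informative.
cosine_lr <- function(base_lr, step, total_steps, warmup_frac = 0.1) {
  if (total_steps <= 1L) return(base_lr)
  w <- max(1, floor(warmup_frac * total_steps))
  if (step <= w) return(base_lr * step / w)
  base_lr * 0.5 * (1 + cos(pi * (step - w) / (total_steps - w)))
}
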