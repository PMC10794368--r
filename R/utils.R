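#' @keywords internal
"_PACKAGE"

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All stochastic components route through
# this so a single experiment seed fans out deterministically.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic sub-seed derivation: one user-facing seed fans out to
# per-component seeds (data generation, init, shuffling, ...). Kept below
# 2^31 - 1 so the result is always a valid R integer seed.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 7919 + h * 104729 + 12345) %% 2147483629)
}

# Truncated normal initializer (values resampled into [-2, 2] sd units),
# the standard transformer weight init at sd = 0.02.
trunc_normal <- function(n, sd = 0.02) {
  u <- stats::runif(n, stats::pnorm(-2), stats::pnorm(2))
  stats::qnorm(u) * sd
}

# Row-wise softmax of a numeric matrix, max-shifted for stability.
softmax_rows <- function(x) {
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  e / rowSums(e)
}

# Row-wise softmax backward: given y = softmax(x) and dL/dy, return dL/dx.
softmax_rows_backward <- function(y, dy) {
  y * (dy - rowSums(dy * y))
}

stop_dim <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x > 0
}

# Flatten a nested list of numeric arrays into a flat named list; used by
# the optimizers and parameter checksums so model structure stays nested.
flatten_params <- function(p, prefix = "") {
  out <- list()
  keys <- names(p) %||% as.character(seq_along(p))
  for (i in seq_along(p)) {
    key <- if (nzchar(prefix)) paste0(prefix, ".", keys[i]) else keys[i]
    if (is.list(p[[i]])) {
      out <- c(out, flatten_params(p[[i]], key))
    } else {
      out[[key]] <- p[[i]]
    }
  }
  out
}

# Inverse of flatten_params against a structural template.
unflatten_params <- function(flat, template, prefix = "") {
  keys <- names(template) %||% as.character(seq_along(template))
  for (i in seq_along(template)) {
    key <- if (nzchar(prefix)) paste0(prefix, ".", keys[i]) else keys[i]
    if (is.list(template[[i]])) {
      template[[i]] <- unflatten_params(flat, template[[i]], key)
    } else {
      template[[i]] <- flat[[key]]
    }
  }
  template
}

# Checksum over all parameters; used by the freeze/snapshot contracts.
param_checksum <- function(params) {
  sum(vapply(flatten_params(params), function(w) sum(as.numeric(w)), 0.0))
}
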