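# Shared fixtures: tiny configs and datasets built in code at test time.

tiny_config <- function(...) {
  vit_config(image_size = 16L, patch_size = 8L, channels = 3L,
             embed_dim = 24L, depth = 2L, heads = 3L, mlp_ratio = 2, ...)
}

tiny_batch <- function(B = 2L, cfg = tiny_config(), seed = 1L) {
  vitalign:::with_seed(seed, array(
    stats::runif(B * cfg$channels * cfg$image_size^2),
    c(B, cfg$channels, cfg$image_size, cfg$image_size)))
}

# random probability vectors (rows of a matrix), Dirichlet-ish via
# normalized exponentials so zeros are approached but not hit
random_prob_rows <- function(n, k, seed = 1L) {
  vitalign:::with_seed(seed, {
    m <- matrix(stats::rexp(n * k), n, k)
    m / rowSums(m)
  })
}

# small, quickly separable synthetic set for engine tests
small_dataset <- function(n_classes = 4L, train = 8L, test = 4L,
                          seed = 11L, noise_sd = 0.05) {
  spec <- synthetic_spec(n_classes = n_classes, image_size = 16L,
                         train_per_class = train, test_per_class = test,
                         seed = seed, noise_sd = noise_sd)
  generate_dataset(spec)
}

# independent loop-coded distance oracles (never vectorized, never shared
# with the implementation)
oracle_tv <- function(p, q) {
  s <- 0
  for (j in seq_along(p)) s <- s + abs(p[j] - q[j])
  s / 2
}
oracle_js <- function(p, q, eps = 1e-8) {
  s <- 0
  for (j in seq_along(p)) {
    m <- (p[j] + q[j]) / 2
    s <- s + 0.5 * p[j] * (log(p[j] + eps) - log(m + eps)) +
      0.5 * q[j] * (log(q[j] + eps) - log(m + eps))
  }
  s
}
oracle_hellinger <- function(p, q) {
  s <- 0
  for (j in seq_along(p)) s <- s + (sqrt(p[j]) - sqrt(q[j]))^2
  sqrt(s) / sqrt(2)
}
oracle_bhattacharyya <- function(p, q, eps = 1e-8) {
  s <- 0
  for (j in seq_along(p)) s <- s + sqrt(p[j] * q[j])
  -log(max(s, eps))
}

# counting oracle for classification metrics
oracle_metrics <- function(true, pred, classes) {
  k <- length(classes)
  prec <- sens <- f1 <- numeric(k)
  for (ci in seq_len(k)) {
    cl <- classes[ci]
    tp <- fp <- fn <- 0
    for (i in seq_along(true)) {
      if (pred[i] == cl && true[i] == cl) tp <- tp + 1
      if (pred[i] == cl && true[i] != cl) fp <- fp + 1
      if (pred[i] != cl && true[i] == cl) fn <- fn + 1
    }
    prec[ci] <- if (tp + fp > 0) tp / (tp + fp) else 0
    sens[ci] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[ci] <- if (prec[ci] + sens[ci] > 0) {
      2 * prec[ci] * sens[ci] / (prec[ci] + sens[ci])
    } else 0
  }
  top1 <- 0
  for (i in seq_along(true)) if (true[i] == pred[i]) top1 <- top1 + 1
  list(precision = prec, sensitivity = sens, f1 = f1,
       accuracy = top1 / length(true))
}
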