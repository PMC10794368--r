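#' Specification of the synthetic lesion-texture benchmark
#'
#' A deterministic generator of a toy multi-class image benchmark that
#' mirrors the structure of a plant-disease dataset: 13 classes organized as
#' 4 crop-like background hues, with class identity carried by local lesion
#' texture (disc count, radius and hue) rather than global layout. Classes
#' sharing a background differ only in their lesions, so raw-pixel nearest
#' neighbour is imperfect while a small trained backbone separates them.
#'
#' Each class "genotype" fixes: the background RGB hue, the lesion count
#' range, the lesion radius range (pixels), the lesion RGB hue, and the
#' Gaussian pixel-noise sd.
#'
#' @param n_classes Number of classes (default 13).
#' @param image_size Square image side in pixels.
#' @param channels Image channels (3 = RGB).
#' @param train_per_class,test_per_class Samples per class in each split.
#' @param seed Generator seed; the whole dataset is a pure function of the
#'   spec.
#' @param noise_sd Gaussian pixel-noise standard deviation.
#' @param genotypes Optional data frame overriding the default class
#'   genotypes (columns: class, bg_r, bg_g, bg_b, lesion_r, lesion_g,
#'   lesion_b, count_min, count_max, radius_min, radius_max).
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_classes = 13L, image_size = 32L, channels = 3L,
                           train_per_class = 40L, test_per_class = 20L,
                           seed = 42L, noise_sd = 0.05, genotypes = NULL) {
  for (nm in c("n_classes", "image_size", "channels", "train_per_class",
               "test_per_class")) {
    if (!is_count(get(nm))) {
      stop(sprintf("synthetic_spec: invalid field `%s` (must be a positive integer)",
                   nm), call. = FALSE)
    }
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop("synthetic_spec: invalid field `noise_sd` (must be >= 0)",
         call. = FALSE)
  }
  if (is.null(genotypes)) genotypes <- default_genotypes(n_classes)
  req <- c("class", "bg_r", "bg_g", "bg_b", "lesion_r", "lesion_g",
           "lesion_b", "count_min", "count_max", "radius_min", "radius_max")
  if (!all(req %in% names(genotypes)) || nrow(genotypes) != n_classes) {
    stop("synthetic_spec: invalid field `genotypes` (need one row per class with the documented columns)",
         call. = FALSE)
  }
  key <- apply(genotypes[, setdiff(req, "class")], 1L, paste, collapse = "|")
  if (anyDuplicated(key)) {
    stop("synthetic_spec: invalid field `genotypes` (class genotypes must be pairwise distinct)",
         call. = FALSE)
  }
  structure(list(n_classes = as.integer(n_classes),
                 image_size = as.integer(image_size),
                 channels = as.integer(channels),
                 train_per_class = as.integer(train_per_class),
                 test_per_class = as.integer(test_per_class),
                 seed = as.integer(seed), noise_sd = noise_sd,
                 genotypes = genotypes),
            class = "synthetic_spec")
}

# 13 default classes = 4 crop background hues x lesion variants. Lesion
# variants differ in hue (necrotic brown, chlorotic yellow, dark anthracnose,
# pale mildew) and in count/radius statistics; each disease additionally
# tints the whole leaf slightly (chlorosis/necrosis shift the canopy color
# in real imagery), so class identity combines a global hue component with
# local lesion texture. The per-disease tint keeps the task learnable by a
# small backbone at desk scale, while the lesion randomness and pixel noise
# keep raw-pixel nearest neighbour well below perfect.
default_genotypes <- function(n_classes = 13L) {
  crops <- matrix(c(0.20, 0.48, 0.18,
                    0.42, 0.58, 0.22,
                    0.28, 0.52, 0.34,
                    0.50, 0.52, 0.16), ncol = 3, byrow = TRUE)
  # whole-leaf tint per disease variant (RGB shift)
  tints <- matrix(c(0.00,  0.00,  0.00,
                    0.08, -0.06,  0.00,
                    -0.06,  0.00,  0.08,
                    0.06,  0.08, -0.06), ncol = 3, byrow = TRUE)
  lesions <- matrix(c(0.45, 0.22, 0.08,
                      0.82, 0.72, 0.18,
                      0.12, 0.08, 0.08,
                      0.82, 0.82, 0.74), ncol = 3, byrow = TRUE)
  counts <- matrix(c(3L, 6L,
                     7L, 12L,
                     2L, 4L,
                     9L, 14L), ncol = 2, byrow = TRUE)
  radii <- matrix(c(2.0, 3.5,
                    1.0, 2.0,
                    3.0, 5.0,
                    1.0, 1.6), ncol = 2, byrow = TRUE)
  g <- lapply(seq_len(n_classes), function(k) {
    crop <- (k - 1L) %% 4L + 1L
    var <- (k - 1L) %/% 4L + 1L
    bg <- pmin(pmax(crops[crop, ] + tints[var, ], 0), 1)
    data.frame(class = sprintf("crop%d_lesion%d", crop, var),
               bg_r = bg[1], bg_g = bg[2], bg_b = bg[3],
               lesion_r = lesions[var, 1], lesion_g = lesions[var, 2],
               lesion_b = lesions[var, 3],
               count_min = counts[var, 1], count_max = counts[var, 2],
               radius_min = radii[var, 1], radius_max = radii[var, 2])
  })
  do.call(rbind, g)
}

render_image <- function(S, C, geno) {
  img <- array(0, c(C, S, S))
  bg <- c(geno$bg_r, geno$bg_g, geno$bg_b)[seq_len(C)]
  # per-image illumination jitter so background hue is not a constant
  bg <- pmin(pmax(bg + stats::rnorm(C, 0, 0.03), 0), 1)
  for (cc in seq_len(C)) img[cc, , ] <- bg[cc]
  n_lesion <- sample(geno$count_min:geno$count_max, 1L)
  hue <- c(geno$lesion_r, geno$lesion_g, geno$lesion_b)[seq_len(C)]
  xs <- matrix(rep(seq_len(S), S), S, S)
  ys <- t(xs)
  for (i in seq_len(n_lesion)) {
    r <- stats::runif(1, geno$radius_min, geno$radius_max)
    cx <- stats::runif(1, 1 + r, S - r)
    cy <- stats::runif(1, 1 + r, S - r)
    d2 <- (xs - cx)^2 + (ys - cy)^2
    alpha <- 0.9 * pmax(0, 1 - d2 / r^2)  # soft-edged disc
    for (cc in seq_len(C)) {
      img[cc, , ] <- img[cc, , ] * (1 - alpha) + hue[cc] * alpha
    }
  }
  img
}

#' Generate the synthetic benchmark
#'
#' Fully deterministic given `spec$seed`: each image is a crop-hue
#' background plus randomly placed soft-edged lesion discs with the class
#' genotype's count/radius/hue, plus Gaussian pixel noise, clipped to
#' `[0, 1]`. Train and test samples are separate draws, so the splits are
#' disjoint by construction and exactly class-balanced.
#'
#' @param spec A [synthetic_spec()].
#' @return A dataset split: list with `train` and `test` (each `x` =
#'   `(B, C, S, S)` array, `y` = integer labels in `1..n_classes`) and
#'   `class_names`.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  S <- spec$image_size
  C <- spec$channels
  make_split <- function(per_class, tag) {
    B <- per_class * spec$n_classes
    x <- array(0, c(B, C, S, S))
    y <- integer(B)
    i <- 0L
    for (k in seq_len(spec$n_classes)) {
      geno <- spec$genotypes[k, ]
      for (s in seq_len(per_class)) {
        i <- i + 1L
        img <- render_image(S, C, geno)
        img <- img + array(stats::rnorm(length(img), 0, spec$noise_sd),
                           dim(img))
        x[i, , , ] <- pmin(pmax(img, 0), 1)
        y[i] <- k
      }
    }
    list(x = x, y = y)
  }
  with_seed(spec$seed, {
    train <- make_split(spec$train_per_class, "train")
    test <- make_split(spec$test_per_class, "test")
    list(train = train, test = test,
         class_names = spec$genotypes$class)
  })
}
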