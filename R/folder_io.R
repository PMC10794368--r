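# Plain-text raster I/O (ASCII PPM "P3" / PGM "P2"). A text format is used
# so written datasets remain portable and diffable; no binary image codec is
# required.

write_ppm <- function(img, path, maxval = 255L) {
  # img: (C, S, S) array in [0, 1]; C must be 1 or 3
  C <- dim(img)[1]
  S1 <- dim(img)[2]
  S2 <- dim(img)[3]
  v <- round(pmin(pmax(img, 0), 1) * maxval)
  magic <- if (C == 3L) "P3" else "P2"
  # pixel order: row-major, channels interleaved per pixel
  px <- integer(0)
  if (C == 3L) {
    m <- sapply(seq_len(3L), function(cc) as.vector(t(v[cc, , ])))
    px <- as.vector(t(m))
  } else {
    px <- as.vector(t(v[1L, , ]))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(magic, paste(S2, S1), as.character(maxval)), con)
  writeLines(paste(px, collapse = " "), con)
  invisible(path)
}

read_ppm <- function(path) {
  txt <- readLines(path, warn = FALSE)
  txt <- sub("#.*$", "", txt)
  toks <- unlist(strsplit(paste(txt, collapse = " "), "[[:space:]]+"))
  toks <- toks[nzchar(toks)]
  magic <- toks[1L]
  if (!magic %in% c("P2", "P3")) {
    stop(sprintf("read_ppm: '%s' is not an ASCII PGM/PPM file", path),
         call. = FALSE)
  }
  nums <- suppressWarnings(as.numeric(toks[-1L]))
  if (anyNA(nums) || length(nums) < 3L) {
    stop(sprintf("read_ppm: cannot parse '%s'", path), call. = FALSE)
  }
  w <- nums[1L]; h <- nums[2L]; maxval <- nums[3L]
  C <- if (magic == "P3") 3L else 1L
  px <- nums[-(1:3)]
  if (length(px) != w * h * C) {
    stop(sprintf("read_ppm: '%s' has %d values, expected %d", path,
                 length(px), w * h * C), call. = FALSE)
  }
  img <- array(0, c(C, h, w))
  if (C == 3L) {
    m <- matrix(px, ncol = 3L, byrow = TRUE)  # one row per pixel, row-major
    for (cc in seq_len(3L)) {
      img[cc, , ] <- matrix(m[, cc], nrow = h, byrow = TRUE)
    }
  } else {
    img[1L, , ] <- matrix(px, nrow = h, byrow = TRUE)
  }
  img / maxval
}

# Nearest-neighbour resample of a (C, h, w) image to (C, size, size).
# Aspect ratio is not preserved: non-square sources are stretched to square.
resize_image <- function(img, size) {
  d <- dim(img)
  if (d[2] == size && d[3] == size) return(img)
  ri <- pmin(d[2], floor((seq_len(size) - 0.5) * d[2] / size) + 1L)
  ci <- pmin(d[3], floor((seq_len(size) - 0.5) * d[3] / size) + 1L)
  img[, ri, ci, drop = FALSE]
}

#' Write a dataset as a directory-per-class image tree
#'
#' Emits ASCII PPM (P3) images under `dir/<split>/<class>/imgNNNN.ppm` plus a
#' `manifest.csv` (filename, class, split), so [load_folder()] can round-trip
#' the dataset.
#'
#' @param dataset A dataset split ([generate_dataset()] output).
#' @param dir Output directory.
#' @return The manifest data frame, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  rows <- list()
  for (split in c("train", "test")) {
    d <- dataset[[split]]
    for (i in seq_along(d$y)) {
      cls <- dataset$class_names[d$y[i]]
      cdir <- file.path(dir, split, cls)
      dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
      fn <- file.path(cdir, sprintf("img%04d.ppm", i))
      write_ppm(d$x[i, , , ], fn)
      rows[[length(rows) + 1L]] <- data.frame(
        filename = fn, class = cls, split = split)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Load a directory-per-class image dataset
#'
#' Reads a tree of ASCII PPM/PGM images laid out one directory per class.
#' If `path` contains `train/` and `test/` subtrees those define the split;
#' otherwise a deterministic seeded split is drawn per class. Class names are
#' sorted lexicographically and mapped to label indices `1..K`. Images are
#' resized (nearest neighbour, aspect ratio not preserved) to
#' `image_size` and scaled to `[0, 1]`.
#'
#' @param path Dataset root directory.
#' @param image_size Target square resolution.
#' @param split_fraction Fraction of each class used for training when no
#'   explicit split directories exist.
#' @param seed Seed for the implicit split.
#' @return A dataset split with `train`, `test` and `class_names`, as in
#'   [generate_dataset()].
#' @export
load_folder <- function(path, image_size = 32L, split_fraction = 0.8,
                        seed = 1L) {
  if (!dir.exists(path)) {
    stop(sprintf("load_folder: '%s' is not a directory", path),
         call. = FALSE)
  }
  has_split <- dir.exists(file.path(path, "train")) &&
    dir.exists(file.path(path, "test"))

  read_class_dir <- function(cdir, cname) {
    files <- sort(list.files(cdir, full.names = TRUE,
                             pattern = "\\.(ppm|pgm)$", ignore.case = TRUE))
    imgs <- list()
    for (f in files) {
      img <- tryCatch(read_ppm(f), error = function(e) {
        warning(sprintf("load_folder: skipping undecodable file '%s'", f),
                call. = FALSE)
        NULL
      })
      if (!is.null(img)) imgs[[length(imgs) + 1L]] <- resize_image(img,
                                                                   image_size)
    }
    if (length(imgs) == 0L) {
      stop(sprintf("load_folder: class '%s' has no decodable images", cname),
           call. = FALSE)
    }
    imgs
  }

  stack_split <- function(per_class_imgs, labels) {
    B <- length(per_class_imgs)
    if (B == 0L) {
      return(list(x = array(0, c(0L, 0L, image_size, image_size)),
                  y = integer(0)))
    }
    C <- dim(per_class_imgs[[1L]])[1L]
    x <- array(0, c(B, C, image_size, image_size))
    for (i in seq_len(B)) x[i, , , ] <- per_class_imgs[[i]]
    list(x = x, y = as.integer(labels))
  }

  if (has_split) {
    classes <- sort(list.dirs(file.path(path, "train"), recursive = FALSE,
                              full.names = FALSE))
    if (length(classes) == 0L) {
      stop("load_folder: no class directories found", call. = FALSE)
    }
    get <- function(split) {
      imgs <- list(); labels <- integer(0)
      for (k in seq_along(classes)) {
        ci <- read_class_dir(file.path(path, split, classes[k]), classes[k])
        imgs <- c(imgs, ci)
        labels <- c(labels, rep(k, length(ci)))
      }
      stack_split(imgs, labels)
    }
    return(list(train = get("train"), test = get("test"),
                class_names = classes))
  }

  classes <- sort(list.dirs(path, recursive = FALSE, full.names = FALSE))
  if (length(classes) == 0L) {
    stop("load_folder: no class directories found", call. = FALSE)
  }
  tr_imgs <- list(); tr_y <- integer(0)
  te_imgs <- list(); te_y <- integer(0)
  for (k in seq_along(classes)) {
    ci <- read_class_dir(file.path(path, classes[k]), classes[k])
    n <- length(ci)
    n_tr <- round(n * split_fraction)
    ord <- with_seed(derive_seed(seed, paste0("split-", classes[k])),
                     sample.int(n))
    tr_imgs <- c(tr_imgs, ci[ord[seq_len(n_tr)]])
    tr_y <- c(tr_y, rep(k, n_tr))
    if (n_tr < n) {
      te_imgs <- c(te_imgs, ci[ord[(n_tr + 1L):n]])
      te_y <- c(te_y, rep(k, n - n_tr))
    }
  }
  list(train = stack_split(tr_imgs, tr_y),
       test = stack_split(te_imgs, te_y),
       class_names = classes)
}
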