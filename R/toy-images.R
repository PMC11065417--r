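#' Generate a toy image dataset
#'
#' Procedurally draws small grayscale PNG images in a
#' directory-per-class layout, as a desk-scale stand-in for a real image
#' corpus when exercising the image-level classifier path. Each ID class
#' is an axis-aligned ellipse whose aspect ratio and fill intensity are
#' determined by the class index (with small per-image jitter and pixel
#' noise); the OOD generator emits bright rectangles, a shape/intensity
#' family disjoint from every ID class. A manifest table mapping file to
#' label accompanies the images.
#'
#' @param out_dir output directory; one subdirectory per class
#'   (`class_01`, ...), plus `OOD/` when `ood_count > 0`.
#' @param n_classes number of ID classes.
#' @param per_class_counts integer vector of images per class (recycled
#'   if scalar).
#' @param image_size side length in pixels (>= 16).
#' @param ood_count number of OOD images (default 0).
#' @param seed integer seed; the same seed reproduces identical pixels.
#' @return The manifest `data.frame(file, domain, label)`, invisibly;
#'   also written as `manifest.csv` in `out_dir`.
#' @export
generate_toy_images <- function(out_dir, n_classes, per_class_counts,
                                image_size = 32L, ood_count = 0L,
                                seed = 1L) {
  image_size <- as.integer(image_size)
  if (image_size < 16L) stop("image_size must be at least 16 pixels",
                             call. = FALSE)
  n_classes <- as.integer(n_classes)
  stopifnot(n_classes >= 2L)
  per_class_counts <- as.integer(rep_len(per_class_counts, n_classes))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir,
                                 call. = FALSE)

  # class-determined shape parameters: ID aspect ratios and intensities
  # stay away from the OOD rectangle family (intensity ~ 1, square-ish)
  aspect <- seq(0.25, 0.75, length.out = n_classes)
  intensity <- seq(0.35, 0.80, length.out = n_classes)
  grid_x <- matrix(seq_len(image_size), image_size, image_size)
  grid_y <- t(grid_x)
  center <- (image_size + 1) / 2

  rows <- list()
  with_seed(derive_seed(seed, 83L), {
    for (cl in seq_len(n_classes)) {
      cls_dir <- file.path(out_dir, sprintf("class_%02d", cl))
      dir.create(cls_dir, showWarnings = FALSE)
      for (i in seq_len(per_class_counts[cl])) {
        a <- image_size * 0.38 * stats::runif(1, 0.9, 1.1)
        b <- a * aspect[cl]
        cx <- center + stats::runif(1, -1.5, 1.5)
        cy <- center + stats::runif(1, -1.5, 1.5)
        img <- matrix(0.10, image_size, image_size)
        inside <- ((grid_x - cx) / a)^2 + ((grid_y - cy) / b)^2 <= 1
        img[inside] <- intensity[cl]
        img <- img + matrix(stats::rnorm(image_size^2, sd = 0.03),
                            image_size, image_size)
        img <- pmin(pmax(img, 0), 1)
        file <- file.path(cls_dir, sprintf("img_%04d.png", i))
        png::writePNG(img, file)
        rows[[length(rows) + 1L]] <- data.frame(
          file = file, domain = "ID", label = cl,
          stringsAsFactors = FALSE)
      }
    }
    if (ood_count > 0L) {
      ood_dir <- file.path(out_dir, "OOD")
      dir.create(ood_dir, showWarnings = FALSE)
      for (i in seq_len(ood_count)) {
        half_w <- image_size * stats::runif(1, 0.25, 0.40)
        half_h <- image_size * stats::runif(1, 0.25, 0.40)
        cx <- center + stats::runif(1, -1.5, 1.5)
        cy <- center + stats::runif(1, -1.5, 1.5)
        img <- matrix(0.10, image_size, image_size)
        inside <- abs(grid_x - cx) <= half_w & abs(grid_y - cy) <= half_h
        img[inside] <- stats::runif(1, 0.92, 1.0)
        img <- img + matrix(stats::rnorm(image_size^2, sd = 0.03),
                            image_size, image_size)
        img <- pmin(pmax(img, 0), 1)
        file <- file.path(ood_dir, sprintf("img_%04d.png", i))
        png::writePNG(img, file)
        rows[[length(rows) + 1L]] <- data.frame(
          file = file, domain = "OOD", label = NA_integer_,
          stringsAsFactors = FALSE)
      }
    }
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE, na = "")
  invisible(manifest)
}

#' Read a directory-per-class image dataset into feature records
#'
#' Accepts the layout written by [generate_toy_images()] (and the common
#' class-foldered layout of real image corpora): one subdirectory per
#' class of PNG images, with an optional `OOD/` subdirectory of unlabeled
#' images. Pixels are flattened (grayscale; RGB channels averaged) into
#' the feature vector, which is what the reference classifier trains on.
#'
#' @param dir dataset root directory.
#' @return A record table; the attribute `class_levels` maps label
#'   indices back to subdirectory names.
#' @export
read_image_features <- function(dir) {
  if (!dir.exists(dir)) stop("no such directory: ", dir, call. = FALSE)
  sub <- list.dirs(dir, recursive = FALSE, full.names = FALSE)
  id_classes <- sort(setdiff(sub, "OOD"))
  if (length(id_classes) == 0L) stop("no class subdirectories under ", dir,
                                     call. = FALSE)
  load_dir <- function(name) {
    files <- sort(list.files(file.path(dir, name), pattern = "\\.png$",
                             full.names = TRUE))
    feats <- lapply(files, function(f) {
      px <- png::readPNG(f)
      if (length(dim(px)) == 3L) px <- apply(px, c(1, 2), mean)
      as.numeric(px)
    })
    list(files = files, features = do.call(rbind, feats))
  }
  parts <- lapply(id_classes, load_dir)
  feats <- do.call(rbind, lapply(parts, `[[`, "features"))
  ids <- unlist(lapply(parts, `[[`, "files"))
  labels <- rep(seq_along(id_classes),
                times = vapply(parts, function(p) length(p$files),
                               integer(1)))
  domain <- rep("ID", length(ids))
  if ("OOD" %in% sub) {
    ood <- load_dir("OOD")
    if (length(ood$files)) {
      feats <- rbind(feats, ood$features)
      ids <- c(ids, ood$files)
      labels <- c(labels, rep(NA_integer_, length(ood$files)))
      domain <- c(domain, rep("OOD", length(ood$files)))
    }
  }
  out <- feature_records(id = ids, domain = domain, label = labels,
                         features = feats)
  attr(out, "class_levels") <- id_classes
  out
}
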