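# Seeded generator of 3-class H&E-like images. Classes differ along the two
# axes the feature blocks are built for: nuclear blob density and size
# (texture -> r_LBP / r_sta) and stain tint (color -> r_Lab). FL-style
# images additionally cluster nuclei into follicle-like disks.

#' Synthetic dataset configuration
#'
#' Per-class parameters of the H&E-like generator. Densities are nuclear
#' blobs per 10^4 pixels; radii are the uniform range of ellipse semi-major
#' axes in pixels; colors are 8-bit RGB. Defaults (600 x 600 images;
#' densities CLL 10, FL 6, MCL 16) make nuclear area coverage monotone in
#' density, so mean blue-ratio intensity ranks the classes by density, and
#' give each class a distinct background tint so color features are
#' independently informative.
#'
#' @param image_size integer `c(H, W)` (default 600 x 600; the source
#'   microscope format 1040 x 1388 also works).
#' @param noise_sd Gaussian pixel noise standard deviation (8-bit units).
#' @param classes named list of per-class parameter lists with fields
#'   `density`, `radius` (length-2 range), `nucleus_color`, `bg_color`,
#'   `follicles` (logical).
#' @param ... overrides for `image_size` or `noise_sd`.
#' @return a `lp_synth_config` list.
#' @export
synth_config <- function(image_size = c(600L, 600L), noise_sd = 8,
                         classes = NULL, ...) {
  defaults <- list(
    CLL = list(density = 10, radius = c(4, 6),
               nucleus_color = c(75, 55, 140), bg_color = c(232, 185, 205),
               follicles = FALSE),
    FL  = list(density = 6, radius = c(4, 7),
               nucleus_color = c(90, 60, 150), bg_color = c(240, 178, 192),
               follicles = TRUE),
    MCL = list(density = 16, radius = c(3, 6),
               nucleus_color = c(60, 50, 120), bg_color = c(224, 192, 212),
               follicles = FALSE)
  )
  if (!is.null(classes)) {
    for (cl in names(classes)) defaults[[cl]][names(classes[[cl]])] <-
        classes[[cl]]
  }
  structure(list(image_size = as.integer(image_size), noise_sd = noise_sd,
                 classes = defaults, ...),
            class = "lp_synth_config")
}

# Pixel mask of one filled rotated ellipse, clipped to the H x W canvas.
# Returns NULL or a list with row range, col range and logical mask.
ellipse_mask <- function(H, W, cy, cx, a, b, theta) {
  ext <- ceiling(max(a, b))
  ys <- max(1, floor(cy - ext)):min(H, ceiling(cy + ext))
  xs <- max(1, floor(cx - ext)):min(W, ceiling(cx + ext))
  if (!length(ys) || !length(xs)) return(NULL)
  dy <- outer(ys - cy, rep(1, length(xs)))
  dx <- outer(rep(1, length(ys)), xs - cx)
  u <- dy * cos(theta) + dx * sin(theta)
  v <- -dy * sin(theta) + dx * cos(theta)
  mask <- (u / a)^2 + (v / b)^2 <= 1
  if (!any(mask)) return(NULL)
  list(ys = ys, xs = xs, mask = mask)
}

#' Generate one synthetic H&E-like image
#'
#' Draws an eosin-pink background, places dark blue-purple elliptical
#' "nuclei" by a Poisson process at the class's density with the class's
#' radius distribution (FL-style images cluster most nuclei into
#' follicle-like disks), and adds Gaussian pixel noise. Deterministic given
#' `(class_id, cfg, seed)`.
#'
#' @param class_id one of `"CLL"`, `"FL"`, `"MCL"`.
#' @param cfg a [synth_config()] object.
#' @param seed RNG seed.
#' @return H x W x 3 numeric array with integer values in \[0, 255\].
#' @export
generate_image <- function(class_id, cfg = synth_config(), seed = 1L) {
  if (!class_id %in% lp_classes()) stop("unknown class: ", class_id)
  par <- cfg$classes[[class_id]]
  H <- cfg$image_size[1]; W <- cfg$image_size[2]
  with_local_seed(seed, {
    # one matrix per channel: in-place subassignment avoids copying the
    # full canvas for every nucleus painted
    c1 <- matrix(par$bg_color[1], H, W)
    c2 <- matrix(par$bg_color[2], H, W)
    c3 <- matrix(par$bg_color[3], H, W)
    n <- rpois(1, par$density * H * W / 1e4)
    if (n > 0) {
      if (isTRUE(par$follicles)) {
        nf <- max(3L, round(H * W / 6e4))
        fol_y <- runif(nf, H * 0.1, H * 0.9)
        fol_x <- runif(nf, W * 0.1, W * 0.9)
        fol_r <- min(H, W) / 8
        in_fol <- runif(n) < 0.8
        pick <- sample.int(nf, n, replace = TRUE)
        cy <- ifelse(in_fol,
                     pmin(pmax(fol_y[pick] + rnorm(n, 0, fol_r / 2), 1), H),
                     runif(n, 1, H))
        cx <- ifelse(in_fol,
                     pmin(pmax(fol_x[pick] + rnorm(n, 0, fol_r / 2), 1), W),
                     runif(n, 1, W))
      } else {
        cy <- runif(n, 1, H); cx <- runif(n, 1, W)
      }
      a <- runif(n, par$radius[1], par$radius[2])
      b <- a * runif(n, 0.6, 1)
      theta <- runif(n, 0, pi)
      cshift <- matrix(rnorm(3 * n, 0, 10), n, 3)
      for (i in seq_len(n)) {
        em <- ellipse_mask(H, W, cy[i], cx[i], a[i], b[i], theta[i])
        if (is.null(em)) next
        col <- pmin(pmax(par$nucleus_color + cshift[i, ], 0), 255)
        sl <- c1[em$ys, em$xs]; sl[em$mask] <- col[1]
        c1[em$ys, em$xs] <- sl
        sl <- c2[em$ys, em$xs]; sl[em$mask] <- col[2]
        c2[em$ys, em$xs] <- sl
        sl <- c3[em$ys, em$xs]; sl[em$mask] <- col[3]
        c3[em$ys, em$xs] <- sl
      }
    }
    img <- array(c(c1, c2, c3), dim = c(H, W, 3))
    img <- img + array(rnorm(length(img), 0, cfg$noise_sd), dim = dim(img))
    round(pmin(pmax(img, 0), 255))
  })
}

#' Generate a balanced labelled synthetic dataset
#'
#' `n_per_class` images per class with a manifest recording image id, class
#' and per-image seed. With `dir` set, images are written as PNG under one
#' subdirectory per class (the on-disk layout of the IICBU lymphoma
#' benchmark, so a real dataset is a drop-in replacement) along with
#' `manifest.tsv`.
#'
#' @param n_per_class images per class.
#' @param cfg a [synth_config()] object.
#' @param seed base RNG seed; image i of the dataset uses seed
#'   `(seed * 10007 + i) mod 2^31-1`, so disjoint base seeds give disjoint
#'   image sets.
#' @param dir optional output directory.
#' @return list with `images` (named list of arrays) and `manifest`
#'   (data.frame: `image_id`, `class`, `seed`).
#' @export
generate_dataset <- function(n_per_class, cfg = synth_config(), seed = 1L,
                             dir = NULL) {
  if (n_per_class < 1L) stop("n_per_class must be >= 1")
  manifest <- expand.grid(idx = seq_len(n_per_class), class = lp_classes(),
                          stringsAsFactors = FALSE)
  manifest$image_id <- sprintf("%s_%03d", manifest$class, manifest$idx)
  manifest$seed <- (seed * 10007 + seq_len(nrow(manifest))) %% 2147483647
  images <- setNames(vector("list", nrow(manifest)), manifest$image_id)
  for (i in seq_len(nrow(manifest))) {
    images[[i]] <- generate_image(manifest$class[i], cfg, manifest$seed[i])
  }
  manifest <- manifest[, c("image_id", "class", "seed")]
  if (!is.null(dir)) {
    for (cl in lp_classes())
      dir.create(file.path(dir, cl), recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(nrow(manifest))) {
      path <- file.path(dir, manifest$class[i],
                        paste0(manifest$image_id[i], ".png"))
      write_image(images[[i]], path)
    }
    write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  list(images = images, manifest = manifest)
}
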