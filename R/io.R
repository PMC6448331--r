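# Image and dataset I/O: 8-bit RGB PNG/TIFF in, feature tables and
# prediction reports out as plain delimited text.

#' Read an RGB image file
#'
#' Reads a PNG or TIFF file into the package's working representation: an
#' H x W x 3 numeric array with channel values in \[0, 255\]. Gray images
#' are replicated to 3 channels; an alpha channel, if present, is dropped.
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @return H x W x 3 numeric array.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext)
  )
  if (length(dim(px)) == 2L) px <- array(px, dim = c(dim(px), 1L))
  if (dim(px)[3] == 1L) px <- px[, , c(1L, 1L, 1L), drop = FALSE]
  if (dim(px)[3] >= 4L) px <- px[, , 1:3, drop = FALSE]
  round(px * 255)
}

#' Write an RGB image as PNG
#'
#' @param img H x W x 3 numeric array in \[0, 255\].
#' @param path output path (`.png`).
#' @export
write_image <- function(img, path) {
  assert_rgb(img)
  png::writePNG(img / 255, path)
  invisible(path)
}

#' Read a dataset directory
#'
#' Accepts either a `manifest.tsv` written by [generate_dataset()] or a
#' bare IICBU-style layout with one subdirectory per class containing
#' `.png`/`.tif` images.
#'
#' @param dir dataset root directory.
#' @return list with `images` (named list of arrays) and `manifest`
#'   (data.frame: `image_id`, `class`).
#' @export
read_dataset <- function(dir) {
  mpath <- file.path(dir, "manifest.tsv")
  if (file.exists(mpath)) {
    manifest <- read.delim(mpath, stringsAsFactors = FALSE)
    files <- file.path(dir, manifest$class,
                       paste0(manifest$image_id, ".png"))
  } else {
    cls <- intersect(lp_classes(), list.dirs(dir, recursive = FALSE,
                                             full.names = FALSE))
    if (!length(cls)) stop("no class subdirectories found under ", dir)
    files <- character(0); manifest <- NULL
    for (cl in cls) {
      f <- list.files(file.path(dir, cl), pattern = "\\.(png|tif|tiff)$",
                      ignore.case = TRUE, full.names = TRUE)
      files <- c(files, f)
      manifest <- rbind(manifest, data.frame(
        image_id = tools::file_path_sans_ext(basename(f)), class = cl,
        stringsAsFactors = FALSE))
    }
  }
  images <- setNames(lapply(files, read_image), manifest$image_id)
  list(images = images, manifest = manifest)
}

#' Write a parent-patch feature table as delimited text
#'
#' One row per parent patch: `image_id`, `label`, parent `row`/`col`/
#' `top`/`left`, then named feature columns (block name + index).
#'
#' @param features named list: per image, the output of
#'   [extract_image_features()].
#' @param labels named character vector of image labels.
#' @param path output TSV path.
#' @export
write_feature_table <- function(features, labels, path) {
  rows <- lapply(names(features), function(id) {
    fs <- features[[id]]
    blocks <- do.call(cbind, lapply(c("r_LBP", "r_sta", "r_Lab"), function(b) {
      m <- fs[[b]]
      colnames(m) <- paste0(b, "_", seq_len(ncol(m)))
      m
    }))
    cbind(data.frame(image_id = id, label = unname(labels[id]), fs$meta),
          as.data.frame(blocks))
  })
  tab <- do.call(rbind, rows)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
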