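#' Read a decoded photograph and its iris mask
#'
#' PNG is read with the \pkg{png} package; TIFF with \pkg{tiff} when
#' installed. The mask may be a single-channel image (nonzero = iris) or a
#' run-length TSV written by [write_mask_rle()]. RAW decoding is the caller's
#' responsibility; record the provenance in `encoding_tag`.
#'
#' @param image_path Path to a PNG or TIFF image.
#' @param mask_path Path to the mask (PNG/TIFF or `.tsv` run-length file).
#' @param image_id Identifier; defaults to the file name without extension.
#' @param encoding_tag Provenance tag stored on the image.
#' @return An [iris_image()].
#' @export
read_iris_image <- function(image_path, mask_path, image_id = NULL,
                            encoding_tag = "unknown") {
  px <- .read_raster(image_path)
  if (length(dim(px)) == 2L) stop("image must have RGB channels")
  if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]  # drop alpha
  px <- round(px * 255)
  mask <- if (grepl("\\.tsv$", mask_path)) {
    read_mask_rle(mask_path, dim(px)[1:2])
  } else {
    m <- .read_raster(mask_path)
    if (length(dim(m)) == 3L) m <- m[, , 1]
    m > 0
  }
  if (is.null(image_id))
    image_id <- sub("\\.[A-Za-z]+$", "", basename(image_path))
  iris_image(px, mask, image_id = image_id, encoding_tag = encoding_tag)
}

.read_raster <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) return(png::readPNG(path))
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF requires the 'tiff' package")
    return(tiff::readTIFF(path))
  }
  stop("unsupported image format: ", path)
}

#' Write an iris image (and mask) as PNG
#'
#' @param image An [iris_image()].
#' @param image_path,mask_path Output paths; the mask is written as a
#'   single-channel PNG with iris pixels white.
#' @return Invisibly, the image path.
#' @export
write_iris_image <- function(image, image_path, mask_path = NULL) {
  png::writePNG(image$pixels / 255, image_path)
  if (!is.null(mask_path))
    png::writePNG(matrix(as.numeric(image$mask), nrow = nrow(image$mask)),
                  mask_path)
  invisible(image_path)
}

#' Run-length encoded masks
#'
#' A plain-text alternative to mask images: each row gives a column-major
#' start offset (1-based) and run length of consecutive iris pixels.
#'
#' @param mask Logical matrix.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_mask_rle <- function(mask, path) {
  r <- rle(as.vector(mask))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  df <- data.frame(start = starts[r$values], length = r$lengths[r$values])
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_mask_rle
#' @param dim Dimensions `c(h, w)` of the mask to reconstruct.
#' @export
read_mask_rle <- function(path, dim) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  m <- logical(prod(dim))
  for (i in seq_len(nrow(df)))
    m[df$start[i]:(df$start[i] + df$length[i] - 1L)] <- TRUE
  matrix(m, nrow = dim[1])
}

#' Read and write tab-separated tables with a stable dialect
#'
#' Thin wrappers so every pipeline stage writes the same TSV flavour
#' (header, no quoting, `NA` for missing).
#'
#' @param x Data frame.
#' @param path File path.
#' @return `read_tsv_table` returns a data frame; the writer returns `path`
#'   invisibly.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tsv_table
#' @export
read_tsv_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}
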