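# IDX-format readers/writers (MNIST layout): big-endian magic 2051 for
# image files, 2049 for label files, unsigned-byte payload.

#' Read an IDX image/label file pair
#'
#' @param image_path path to an IDX3 image file (magic 2051).
#' @param label_path path to an IDX1 label file (magic 2049).
#' @return list with `images` (list of `gray_image`, labels attached) and
#'   `labels` (integer vector).
#' @export
load_idx <- function(image_path, label_path) {
  icon <- file(image_path, "rb"); on.exit(close(icon), add = TRUE)
  magic <- readBin(icon, "integer", 1L, size = 4L, endian = "big")
  if (!identical(magic, 2051L))
    stop("load_idx: bad image-file magic ", magic, " (expected 2051)")
  dims <- readBin(icon, "integer", 3L, size = 4L, endian = "big")
  if (length(dims) < 3L || dims[2] != P_SIDE || dims[3] != P_SIDE)
    stop("load_idx: expected ", P_SIDE, "x", P_SIDE, " images")
  n <- dims[1]
  raw <- readBin(icon, "integer", n * P_SIDE * P_SIDE, size = 1L,
                 signed = FALSE)
  if (length(raw) != n * P_SIDE * P_SIDE)
    stop("load_idx: truncated image file (", length(raw), " of ",
         n * P_SIDE * P_SIDE, " bytes)")

  lcon <- file(label_path, "rb"); on.exit(close(lcon), add = TRUE)
  lmagic <- readBin(lcon, "integer", 1L, size = 4L, endian = "big")
  if (!identical(lmagic, 2049L))
    stop("load_idx: bad label-file magic ", lmagic, " (expected 2049)")
  nl <- readBin(lcon, "integer", 1L, size = 4L, endian = "big")
  if (nl != n)
    stop("load_idx: image/label count mismatch (", n, " vs ", nl, ")")
  labels <- readBin(lcon, "integer", nl, size = 1L, signed = FALSE)
  if (length(labels) != nl) stop("load_idx: truncated label file")
  if (any(labels < 0L | labels > 9L))
    stop("load_idx: labels outside 0..9")

  images <- lapply(seq_len(n), function(i) {
    px <- matrix(raw[((i - 1L) * P_SIDE^2 + 1L):(i * P_SIDE^2)],
                 P_SIDE, P_SIDE, byrow = TRUE)   # IDX stores rows first
    gray_image(px, label = labels[i])
  })
  list(images = images, labels = labels)
}

#' Write images and labels as an IDX file pair
#'
#' Inverse of [load_idx()]; used for fixtures and round-trip checks.
#'
#' @param images list of `gray_image`.
#' @param labels integer labels in 0..9.
#' @param image_path,label_path output paths.
#' @export
write_idx <- function(images, labels, image_path, label_path) {
  stopifnot(length(images) == length(labels))
  icon <- file(image_path, "wb"); on.exit(close(icon), add = TRUE)
  writeBin(c(2051L, length(images), P_SIDE, P_SIDE), icon, size = 4L,
           endian = "big")
  for (im in images)
    writeBin(as.integer(t(unclass(im))), icon, size = 1L)
  lcon <- file(label_path, "wb"); on.exit(close(lcon), add = TRUE)
  writeBin(c(2049L, length(labels)), lcon, size = 4L, endian = "big")
  writeBin(as.integer(labels), lcon, size = 1L)
}
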