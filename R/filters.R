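# Block 1: convolutional class/feature filters producing the binary feature map.

P_SIDE <- 28L   # input image side
F_SIDE <- 20L   # filter side
R_SIDE <- P_SIDE - F_SIDE + 1L  # 9: valid-convolution response side

#' Construct a 28x28 grayscale image
#'
#' Validates and wraps a raw intensity matrix as used throughout the
#' pipeline: 28x28 integers in \[0, 255\], optionally carrying a class label
#' in 0..9.
#'
#' @param pixels 28x28 numeric matrix of integer intensities in \[0, 255\].
#' @param label optional class id in 0..9, or `NULL`.
#' @return An object of class `gray_image` (the pixel matrix with a `label`
#'   attribute).
#' @export
gray_image <- function(pixels, label = NULL) {
  pixels <- as.matrix(pixels)
  if (!all(dim(pixels) == c(P_SIDE, P_SIDE)))
    stop("gray_image: pixels must be ", P_SIDE, "x", P_SIDE,
         ", got ", nrow(pixels), "x", ncol(pixels))
  if (anyNA(pixels) || any(pixels < 0) || any(pixels > 255) ||
      any(pixels != round(pixels)))
    stop("gray_image: pixels must be integers in [0, 255]")
  if (!is.null(label)) {
    label <- as.integer(label)
    if (length(label) != 1L || is.na(label) || label < 0L || label > 9L)
      stop("gray_image: label must be a single class id in 0..9")
  }
  storage.mode(pixels) <- "double"   # exact integers; avoids 32-bit overflow
  structure(pixels, label = label, class = c("gray_image", "matrix"))
}

#' Construct a 20x20 integer convolutional filter
#'
#' @param weights 20x20 matrix of signed integers in \[-128, 127\].
#' @param kind `"class"` (fires for one trained class) or `"feature"`
#'   (generic shape detector).
#' @param target_class class id in 0..9; required for class filters,
#'   forbidden for feature filters.
#' @param threshold integer binarization threshold applied to the max-pooled
#'   response (strict `>`).
#' @return An object of class `conv_filter`.
#' @export
conv_filter <- function(weights, kind = c("class", "feature"),
                        target_class = NULL, threshold = 0L) {
  kind <- match.arg(kind)
  weights <- as.matrix(weights)
  if (!all(dim(weights) == c(F_SIDE, F_SIDE)))
    stop("conv_filter: weights must be ", F_SIDE, "x", F_SIDE)
  if (anyNA(weights) || any(weights < -128) || any(weights > 127) ||
      any(weights != round(weights)))
    stop("conv_filter: weights must be integers in [-128, 127]")
  if (kind == "class" && is.null(target_class))
    stop("conv_filter: class filters need a target_class")
  if (kind == "feature" && !is.null(target_class))
    stop("conv_filter: feature filters carry no target_class")
  storage.mode(weights) <- "double"
  structure(list(weights = weights, kind = kind,
                 target_class = if (is.null(target_class)) NULL
                                else as.integer(target_class),
                 threshold = as.numeric(threshold)),
            class = "conv_filter")
}

#' @export
print.conv_filter <- function(x, ...) {
  cat("<conv_filter> kind:", x$kind,
      if (x$kind == "class") paste0("(class ", x$target_class, ")") else "",
      " threshold:", x$threshold, "\n")
  invisible(x)
}

#' Valid convolution of an image with a filter
#'
#' Slides the 20x20 filter over the 28x28 image with no padding
#' (cross-correlation convention, no kernel flip) and returns the 9x9
#' integer response matrix: entry (r, c) is the dot product of the filter
#' with the image window anchored at (r, c).  Arithmetic is exact: the
#' largest possible magnitude, 400 * 255 * 128, is far below double
#' precision's exact-integer range.
#'
#' @param image `gray_image` or plain 28x28 matrix.
#' @param filt `conv_filter` or plain 20x20 weight matrix.
#' @return 9x9 numeric matrix of integer-valued responses.
#' @export
convolve_valid <- function(image, filt) {
  w <- if (inherits(filt, "conv_filter")) filt$weights else as.matrix(filt)
  img <- unclass(image)
  if (!all(dim(img) == c(P_SIDE, P_SIDE)))
    stop("convolve_valid: image must be ", P_SIDE, "x", P_SIDE)
  if (!all(dim(w) == c(F_SIDE, F_SIDE)))
    stop("convolve_valid: filter must be ", F_SIDE, "x", F_SIDE)
  out <- matrix(0, R_SIDE, R_SIDE)
  for (r in seq_len(R_SIDE)) for (c in seq_len(R_SIDE)) {
    out[r, c] <- sum(img[r:(r + F_SIDE - 1L), c:(c + F_SIDE - 1L)] * w)
  }
  out
}

# im2col: rows are the 81 20x20 windows of an image, flattened column-major.
# Used by the trainers so a whole response map is one matrix product.
image_patches <- function(img) {
  img <- unclass(img)
  n <- R_SIDE * R_SIDE
  P <- matrix(0, n, F_SIDE * F_SIDE)
  k <- 1L
  for (c in seq_len(R_SIDE)) for (r in seq_len(R_SIDE)) {
    P[k, ] <- as.vector(img[r:(r + F_SIDE - 1L), c:(c + F_SIDE - 1L)])
    k <- k + 1L
  }
  P
}

#' Max-pool a response matrix and binarize against a threshold
#'
#' The digital response of a filter to an image: 1 if the maximum response
#' is strictly greater than the threshold, else 0.  A maximum exactly equal
#' to the threshold gives 0.
#'
#' @param resp response matrix from [convolve_valid()].
#' @param threshold integer threshold.
#' @return 0 or 1.
#' @export
pool_and_binarize <- function(resp, threshold) {
  if (max(resp) > threshold) 1L else 0L
}

#' Compute the 16-bit binary feature map of an image
#'
#' Applies every filter in the bank (class filters first) and binarizes the
#' max-pooled responses, giving the ordered binary feature map that feeds
#' the equalization stage.
#'
#' @param image `gray_image` or 28x28 matrix.
#' @param bank a `filter_bank`.
#' @return integer vector of 0/1 bits, length `bank$n_total`.
#' @export
compute_feature_map <- function(image, bank) {
  stopifnot(inherits(bank, "filter_bank"))
  vapply(bank$filters, function(f) {
    pool_and_binarize(convolve_valid(image, f), f$threshold)
  }, integer(1))
}

# Quantize a real-valued kernel to signed 8-bit.
quantize_weights <- function(w) {
  m <- max(abs(w))
  if (m == 0) return(matrix(0, F_SIDE, F_SIDE))
  matrix(pmin(127, pmax(-128, round(w / m * 127))), F_SIDE, F_SIDE)
}

# Max-pooled responses of a quantized kernel over cached patch matrices.
max_responses <- function(patches, wvec) {
  vapply(patches, function(P) max(P %*% wvec), numeric(1))
}

# Threshold maximizing Youden's J (sensitivity + specificity - 1) for the
# strict rule resp > theta.  All cuts achieving the maximum form a margin;
# the centre of that margin is returned so the decision generalizes.
youden_threshold <- function(resp, is_target) {
  vals <- sort(unique(resp))
  cands <- unique(c(vals - 1, vals))
  npos <- sum(is_target); nneg <- sum(!is_target)
  j <- vapply(cands, function(t)
    sum(resp > t & is_target) / npos - sum(resp > t & !is_target) / nneg,
    numeric(1))
  best <- cands[j >= max(j) - 1e-12]
  list(threshold = round(mean(range(best))), j = max(j))
}

#' Train a class filter for one target class
#'
#' Trains a single 20x20 kernel by stochastic subgradient descent on the
#' max-pooled response with a logistic one-vs-rest loss, then quantizes the
#' weights to signed 8-bit and calibrates the binarization threshold on a
#' validation split by maximizing Youden's J.  The kernel is initialized
#' from the difference between mean target and mean non-target central
#' crops, so in the one-target-image limit it degenerates to a template
#' matcher.
#'
#' @param train_images list of `gray_image` (or 28x28 matrices).
#' @param labels integer class labels aligned with `train_images`.
#' @param target_class the class this filter must recognize.
#' @param epochs,lr,val_frac training hyperparameters: subgradient epochs,
#'   learning rate, and fraction held out for threshold calibration.
#' @param seed RNG seed for the split and shuffling.
#' @return a `conv_filter` of kind `"class"`.  If target and non-target
#'   responses are inseparable (Youden's J below 0.1 on the validation
#'   split) a warning is issued and the filter carries
#'   `attr(, "separable") = FALSE`.
#' @export
train_class_filter <- function(train_images, labels, target_class,
                               epochs = 12L, lr = 0.05, val_frac = 0.3,
                               seed = 1L) {
  labels <- as.integer(labels)
  if (length(train_images) == 0L)
    stop("train_class_filter: empty training set")
  if (length(train_images) != length(labels))
    stop("train_class_filter: images and labels differ in length")
  y <- labels == target_class
  if (!any(y) || all(y))
    stop("train_class_filter: training set must contain both target and ",
         "non-target images")

  rng <- make_rng(seed)
  n <- length(train_images)
  idx <- sample_int(rng, n, n)                  # seeded permutation
  n_val <- max(2L, floor(val_frac * n))
  val_i <- idx[seq_len(n_val)]
  tr_i  <- idx[-seq_len(n_val)]
  # keep both classes in each split
  if (!any(y[tr_i]) || all(y[tr_i]) || !any(y[val_i]) || all(y[val_i])) {
    tr_i <- idx; val_i <- idx
  }

  patches <- lapply(train_images, function(im) image_patches(im) / 255)
  # template init: mean target center crop minus mean non-target center crop
  ctr <- (P_SIDE - F_SIDE) %/% 2L + 1L
  crop <- function(im) unclass(im)[ctr:(ctr + F_SIDE - 1L),
                                   ctr:(ctr + F_SIDE - 1L)] / 255
  w <- Reduce(`+`, lapply(train_images[y], crop)) / sum(y) -
       Reduce(`+`, lapply(train_images[!y], crop)) / sum(!y)
  w <- as.vector(w)
  w <- w / max(1e-9, max(abs(w)))

  yy <- ifelse(y, 1, -1)
  for (ep in seq_len(epochs)) {
    for (i in tr_i[sample_int(rng, length(tr_i), length(tr_i))]) {
      s <- patches[[i]] %*% w
      p <- which.max(s)
      g <- -yy[i] / (1 + exp(yy[i] * s[p]))     # d logistic / d score
      w <- w - lr * (g * patches[[i]][p, ] + 1e-4 * w)
    }
  }

  wq <- quantize_weights(matrix(w, F_SIDE, F_SIDE))
  resp <- max_responses(lapply(train_images[val_i], image_patches),
                        as.vector(wq))
  cal <- youden_threshold(resp, y[val_i])
  filt <- conv_filter(wq, "class", target_class = target_class,
                      threshold = cal$threshold)
  attr(filt, "weights_real") <- matrix(w, F_SIDE, F_SIDE)  # pre-quantization
  if (cal$j < 0.1) {
    warning("train_class_filter: class ", target_class,
            " is not separable from the rest (Youden's J = ",
            signif(cal$j, 3), ")")
    attr(filt, "separable") <- FALSE
  } else attr(filt, "separable") <- TRUE
  filt
}

#' Train a set of generic feature filters
#'
#' Jointly trains `n_filters + extra` 20x20 kernels as the first layer of a
#' small fully-convolutional softmax classifier over the trained classes
#' (max-pooled kernel responses -> linear readout -> softmax), then keeps
#' the `n_filters` kernels with the highest activation variance across the
#' training set.  Each kept kernel is quantized to signed 8-bit and its
#' threshold set at the `threshold_quantile` of its responses, so each
#' feature bit fires on a nontrivial fraction of images.
#'
#' @param train_images list of `gray_image`.
#' @param labels integer labels (trained classes only).
#' @param n_filters number of feature filters to return.
#' @param epochs,lr training hyperparameters.
#' @param extra surplus kernels trained before variance selection.
#' @param threshold_quantile response quantile used as threshold.
#' @param seed RNG seed.
#' @return list of `conv_filter` objects of kind `"feature"`.
#' @export
train_feature_filters <- function(train_images, labels, n_filters,
                                  epochs = 10L, lr = 0.05, extra = 4L,
                                  threshold_quantile = 0.75, seed = 1L) {
  if (n_filters < 1L) stop("train_feature_filters: n_filters must be >= 1")
  if (length(train_images) == 0L)
    stop("train_feature_filters: empty training set")
  if (all(vapply(train_images, function(im) all(unclass(im) == 0),
                 logical(1))))
    stop("train_feature_filters: degenerate (all-blank) training set")

  labels <- as.integer(labels)
  classes <- sort(unique(labels))
  K <- n_filters + extra
  n <- length(train_images)
  rng <- make_rng(seed)

  patches <- lapply(train_images, function(im) image_patches(im) / 255)
  # kernels start as centered random crops of training images, so each is a
  # localized template that training then refines
  mean_px <- mean(unlist(lapply(train_images, unclass))) / 255
  W <- vapply(seq_len(K), function(k) {
    i <- sample_int(rng, n, 1L)
    p <- sample_int(rng, nrow(patches[[i]]), 1L)
    crop <- patches[[i]][p, ] - mean_px
    crop / max(1e-9, max(abs(crop))) * 0.5 +
      rng_runif(rng, F_SIDE * F_SIDE, -0.05, 0.05)
  }, numeric(F_SIDE * F_SIDE))
  V <- matrix(rng_runif(rng, length(classes) * K, -0.05, 0.05),
              length(classes), K)

  for (ep in seq_len(epochs)) {
    for (i in sample_int(rng, n, n)) {
      S <- patches[[i]] %*% W                   # 81 x K response maps
      p <- max.col(t(S))                        # argmax position per kernel
      f <- S[cbind(p, seq_len(K))]              # max-pooled features
      z <- as.vector(V %*% f)
      z <- z - max(z)
      prob <- exp(z) / sum(exp(z))
      yvec <- as.numeric(classes == labels[i])
      dz <- prob - yvec
      dF <- as.vector(crossprod(V, dz))
      V <- V - lr * (outer(dz, f) + 1e-4 * V)
      for (k in seq_len(K))
        W[, k] <- W[, k] - lr * (dF[k] * patches[[i]][p[k], ] + 1e-4 * W[, k])
    }
  }

  feats <- t(vapply(patches, function(P) {
    S <- P %*% W
    apply(S, 2, max)
  }, numeric(K)))
  keep <- order(apply(feats, 2, stats::var), decreasing = TRUE)[seq_len(n_filters)]

  lapply(keep, function(k) {
    wq <- quantize_weights(matrix(W[, k], F_SIDE, F_SIDE))
    resp <- max_responses(patches, as.vector(wq) * 255)  # undo /255 scaling
    thr <- stats::quantile(resp, threshold_quantile, names = FALSE, type = 1)
    conv_filter(wq, "feature", threshold = thr)
  })
}

#' Assemble and train the full 16-filter bank
#'
#' Trains one class filter per trained class and fills the remaining slots
#' with feature filters trained on the same (trained-class) images; class
#' filters come first, in increasing class order, matching the bus layout
#' the equalizer expects.
#'
#' @param train_images list of `gray_image` from the trained classes only.
#' @param labels integer labels aligned with `train_images`.
#' @param trained_classes sorted vector of trained class ids.
#' @param n_total total bank size (default 16).
#' @param seed RNG seed.
#' @param ... further hyperparameters passed to the two trainers.
#' @return a `filter_bank`: list with `filters`, `n_total`, `n_class`,
#'   `trained_classes`.
#' @export
fit_filter_bank <- function(train_images, labels, trained_classes,
                            n_total = 16L, seed = 1L, ...) {
  trained_classes <- sort(as.integer(trained_classes))
  n_cf <- length(trained_classes)
  if (n_cf >= n_total)
    stop("fit_filter_bank: need at least one feature-filter slot (",
         n_cf, " class filters, bank size ", n_total, ")")
  cfs <- lapply(trained_classes, function(cl)
    train_class_filter(train_images, labels, cl, seed = seed + cl, ...))
  ffs <- train_feature_filters(train_images, labels,
                               n_filters = n_total - n_cf, seed = seed, ...)
  filter_bank(c(cfs, ffs))
}

#' Build a filter bank from a list of filters
#'
#' @param filters list of `conv_filter`, class filters first.
#' @return a `filter_bank`.
#' @export
filter_bank <- function(filters) {
  kinds <- vapply(filters, function(f) f$kind, character(1))
  n_cf <- sum(kinds == "class")
  if (n_cf > 0 && any(kinds[seq_len(n_cf)] != "class"))
    stop("filter_bank: class filters must precede feature filters")
  structure(list(filters = filters,
                 n_total = length(filters),
                 n_class = n_cf,
                 trained_classes = vapply(filters[seq_len(n_cf)],
                                          function(f) f$target_class,
                                          integer(1))),
            class = "filter_bank")
}

#' @export
print.filter_bank <- function(x, ...) {
  cat("<filter_bank>", x$n_total, "filters:", x$n_class, "class (",
      paste(x$trained_classes, collapse = ","), ") +",
      x$n_total - x$n_class, "feature\n")
  invisible(x)
}

#' @describeIn fit_filter_bank feature maps for new images: returns an
#'   n x n_total 0/1 matrix (one row per image).
#' @param object a `filter_bank`.
#' @param newdata a single image or list of images.
#' @export
predict.filter_bank <- function(object, newdata, ...) {
  if (!is.list(newdata)) newdata <- list(newdata)
  t(vapply(newdata, compute_feature_map, integer(object$n_total),
           bank = object))
}
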