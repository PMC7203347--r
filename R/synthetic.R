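# Synthetic data: class-conditional Bernoulli feature-map streams (the
# feature-level shortcut into Blocks 2-3) and seven-segment-style stroke
# images (the image-level path through Block 1).  Both are fully seeded.

#' Class-conditional feature-map distribution
#'
#' Describes, per class, the probability that each of the 16 filter-response
#' bits is ON (class-filter bits first).  Emulates the averaged feature maps
#' of a trained bank: trained classes drive their own class-filter bit with
#' high rate; non-trained classes leave every class-filter bit near 0 and
#' are characterised by a small set of strongly driven feature-filter bits.
#'
#' @param rates numeric matrix, classes x bits, entries in \[0, 1\];
#'   rownames are class labels.
#' @param n_class number of leading class-filter bits.
#' @param priors class sampling probabilities (default uniform).
#' @return a `synthetic_feature_spec`.
#' @export
synthetic_feature_spec <- function(rates, n_class, priors = NULL) {
  rates <- as.matrix(rates)
  if (any(rates < 0) || any(rates > 1))
    stop("synthetic_feature_spec: rates must lie in [0, 1]")
  if (is.null(priors)) priors <- rep(1 / nrow(rates), nrow(rates))
  if (length(priors) != nrow(rates))
    stop("synthetic_feature_spec: one prior per class required")
  structure(list(rates = rates, n_class = as.integer(n_class),
                 classes = as.integer(rownames(rates)),
                 priors = priors / sum(priors)),
            class = "synthetic_feature_spec")
}

#' Default synthetic feature-map distribution
#'
#' Builds a rate matrix for a trained/non-trained split of the ten digit
#' classes over a 16-bit bank: one class-filter bit per trained class (own
#' rate 0.95, cross-talk 0.01), and for each non-trained class a distinct
#' pair of strongly driven feature bits (rate 0.88) plus one moderately
#' driven bit (rate 0.40), so each non-trained class exhibits a few probable
#' feature-map variants with distinct dominant combinations across classes.
#'
#' @param trained sorted trained class ids (default the running example
#'   0, 1, 2, 4, 7, 8, 9).
#' @param nontrained non-trained class ids (default 3, 5, 6).
#' @param n_total bank size (default 16).
#' @return a `synthetic_feature_spec`.
#' @export
default_synthetic_feature_spec <- function(trained = c(0, 1, 2, 4, 7, 8, 9),
                                           nontrained = c(3, 5, 6),
                                           n_total = 16L) {
  trained <- sort(as.integer(trained)); nontrained <- sort(as.integer(nontrained))
  if (length(intersect(trained, nontrained)))
    stop("default_synthetic_feature_spec: trained and non-trained overlap")
  n_cf <- length(trained)
  n_ff <- n_total - n_cf
  if (2L * length(nontrained) > n_ff)
    stop("default_synthetic_feature_spec: not enough feature bits for ",
         length(nontrained), " non-trained classes")
  classes <- c(trained, nontrained)
  rates <- matrix(0.01, length(classes), n_total,
                  dimnames = list(classes, NULL))
  for (i in seq_along(trained)) {
    rates[i, seq_len(n_cf)] <- 0.01
    rates[i, i] <- 0.95
    # trained classes also excite some generic features
    ffb <- n_cf + ((2L * i) %% n_ff) + 1L
    rates[i, ffb] <- 0.55
  }
  for (k in seq_along(nontrained)) {
    r <- n_cf + k
    strong <- n_cf + c(2L * k - 1L, 2L * k)
    medium <- n_cf + 2L * length(nontrained) + (k - 1L) %%
              max(1L, n_ff - 2L * length(nontrained)) + 1L
    rates[r, seq_len(n_cf)] <- 0.01
    rates[r, (n_cf + 1L):n_total] <- 0.03
    rates[r, strong] <- 0.88
    if (medium <= n_total) rates[r, medium] <- 0.40
  }
  synthetic_feature_spec(rates, n_class = n_cf)
}

#' Sample a labelled stream of synthetic feature maps
#'
#' Per item, a class is drawn from the spec's priors and each bit sampled
#' independently from that class's Bernoulli rate.
#'
#' @param spec a `synthetic_feature_spec`.
#' @param n stream length.
#' @param seed RNG seed.
#' @return list with `maps` (n x 16 0/1 matrix) and `labels` (integer
#'   vector).
#' @export
make_synthetic_feature_stream <- function(spec, n, seed = 1L) {
  if (n < 1L) stop("make_synthetic_feature_stream: n must be >= 1")
  rng <- make_rng(seed)
  cls_idx <- sample_int(rng, nrow(spec$rates), n, replace = TRUE,
                        prob = spec$priors)
  u <- matrix(rng_runif(rng, n * ncol(spec$rates)), n, ncol(spec$rates))
  maps <- (u < spec$rates[cls_idx, , drop = FALSE]) + 0L
  list(maps = maps, labels = spec$classes[cls_idx])
}

# Seven-segment geometry: each stroke class is a set of line segments
# (r1, c1, r2, c2) on the 28x28 grid.  Distinct, stroke-like, separable.
seg_coords <- list(
  A = c(5, 8, 5, 20),    B = c(5, 20, 14, 20),  C = c(14, 20, 23, 20),
  D = c(23, 8, 23, 20),  E = c(14, 8, 23, 8),   F = c(5, 8, 14, 8),
  G = c(14, 8, 14, 20))
digit_segments <- list(
  `0` = c("A","B","C","D","E","F"), `1` = c("B","C"),
  `2` = c("A","B","G","E","D"),     `3` = c("A","B","G","C","D"),
  `4` = c("F","G","B","C"),         `5` = c("A","F","G","C","D"),
  `6` = c("A","F","G","E","C","D"), `7` = c("A","B","C"),
  `8` = c("A","B","C","D","E","F","G"), `9` = c("A","B","C","D","F","G"))

#' Stroke-image generator settings
#'
#' @param classes class ids the generator can draw (default 0..9).
#' @param geometries named list (by class id) of segment matrices (rows
#'   r1, c1, r2, c2); defaults to seven-segment digit shapes.  An empty
#'   matrix gives a blank (zero-stroke) class.
#' @param thickness stroke half-width in pixels.
#' @param jitter max absolute random translation in pixels.
#' @param intensity mean stroke intensity (0-255).
#' @param intensity_sd per-image intensity spread.
#' @return a `synthetic_image_spec`.
#' @export
synthetic_image_spec <- function(classes = 0:9, geometries = NULL,
                                 thickness = 1.6, jitter = 2L,
                                 intensity = 210, intensity_sd = 15) {
  if (is.null(geometries))
    geometries <- lapply(as.character(classes), function(cl) {
      segs <- digit_segments[[cl]]
      if (is.null(segs)) matrix(numeric(0), 0, 4)
      else do.call(rbind, lapply(segs, function(s) seg_coords[[s]]))
    })
  names(geometries) <- as.character(classes)
  structure(list(classes = as.integer(classes), geometries = geometries,
                 thickness = thickness, jitter = as.integer(jitter),
                 intensity = intensity, intensity_sd = intensity_sd),
            class = "synthetic_image_spec")
}

# Render one image: intensity falls off with distance from the nearest
# segment; strokes beyond `thickness` are background.
render_strokes <- function(segs, thickness, intensity) {
  img <- matrix(0, P_SIDE, P_SIDE)
  if (nrow(segs) == 0L) return(img)
  rr <- matrix(rep(seq_len(P_SIDE), P_SIDE), P_SIDE, P_SIDE)
  cc <- t(rr)
  d <- matrix(Inf, P_SIDE, P_SIDE)
  for (i in seq_len(nrow(segs))) {
    p1 <- segs[i, 1:2]; p2 <- segs[i, 3:4]
    v <- p2 - p1
    len2 <- sum(v^2)
    t_ <- if (len2 == 0) matrix(0, P_SIDE, P_SIDE)
          else pmin(1, pmax(0, ((rr - p1[1]) * v[1] + (cc - p1[2]) * v[2]) / len2))
    di <- sqrt((rr - (p1[1] + t_ * v[1]))^2 + (cc - (p1[2] + t_ * v[2]))^2)
    d <- pmin(d, di)
  }
  on <- d <= thickness
  img[on] <- pmax(0, pmin(255, round(intensity * (1 - 0.4 * d[on] / thickness))))
  img
}

#' Generate labelled synthetic stroke images
#'
#' Draws class-conditional seven-segment-style stroke images with seeded
#' random translation and intensity; pixel values are integers in
#' \[0, 255\].
#'
#' @param spec a `synthetic_image_spec`.
#' @param n number of images.
#' @param seed RNG seed.
#' @param labels optional explicit label sequence (recycled); by default
#'   classes are drawn uniformly.
#' @return list with `images` (list of `gray_image`) and `labels`.
#' @export
make_synthetic_images <- function(spec, n, seed = 1L, labels = NULL) {
  if (n < 1L) stop("make_synthetic_images: n must be >= 1")
  rng <- make_rng(seed)
  if (is.null(labels)) {
    labels <- spec$classes[sample_int(rng, length(spec$classes), n,
                                      replace = TRUE)]
  } else labels <- rep_len(as.integer(labels), n)
  images <- vector("list", n)
  for (i in seq_len(n)) {
    segs <- spec$geometries[[as.character(labels[i])]]
    if (nrow(segs) > 0L && spec$jitter > 0L) {
      dr <- sample_int(rng, 2L * spec$jitter + 1L, 1L) - spec$jitter - 1L
      dc <- sample_int(rng, 2L * spec$jitter + 1L, 1L) - spec$jitter - 1L
      segs <- segs + matrix(c(dr, dc, dr, dc), nrow(segs), 4L, byrow = TRUE)
    }
    inten <- min(255, max(60, spec$intensity +
                            round(rng_rnorm(rng, 1L, 0, spec$intensity_sd))))
    images[[i]] <- gray_image(render_strokes(segs, spec$thickness, inten),
                              label = labels[i])
  }
  list(images = images, labels = labels)
}
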