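test_that("valid convolution has 9x9 geometry and exact closed-form values", {
  zeros <- gray_image(matrix(0, 28, 28))
  w <- matrix(1, 20, 20)
  r <- convolve_valid(zeros, w)
  expect_identical(dim(r), c(9L, 9L))
  expect_true(all(r == 0))

  full <- gray_image(matrix(255, 28, 28))
  r2 <- convolve_valid(full, w)
  expect_true(all(r2 == 20 * 20 * 255))   # 102000 at every position

  expect_error(convolve_valid(matrix(0, 27, 28), w), "28x28")
  expect_error(convolve_valid(zeros, matrix(0, 19, 20)), "20x20")
})

test_that("convolution agrees with a naive quadruple-loop oracle", {
  for (s in 1:20) {
    img <- random_image(s)
    w <- random_filter_weights(1000 + s)
    expect_equal(convolve_valid(img, w), naive_convolve(img, w))
  }
})

test_that("max-pool binarization uses a strict threshold", {
  resp <- matrix(0, 9, 9); resp[4, 7] <- 500
  expect_identical(pool_and_binarize(resp, 500), 0L)  # tie -> 0
  expect_identical(pool_and_binarize(resp, 499), 1L)
  expect_identical(pool_and_binarize(resp - 1000, -2000), 1L)
  for (s in 1:10) {
    set.seed(s)
    resp <- matrix(sample(-5000:5000, 81), 9, 9)
    thr <- sample(-5000:5000, 1)
    brute <- as.integer(max(as.vector(resp)) > thr)
    expect_identical(pool_and_binarize(resp, thr), brute)
  }
})

test_that("feature maps follow bank order, have length 16 and are deterministic", {
  filters <- c(
    lapply(0:6, function(cl)
      conv_filter(random_filter_weights(cl + 1), "class", target_class = cl,
                  threshold = 1e6)),
    lapply(1:9, function(k)
      conv_filter(random_filter_weights(100 + k), "feature",
                  threshold = 1e6)))
  bank <- filter_bank(filters)
  expect_identical(bank$n_total, 16L)
  expect_identical(bank$n_class, 7L)

  zeros <- gray_image(matrix(0, 28, 28))
  expect_identical(compute_feature_map(zeros, bank), rep(0L, 16))

  img <- random_image(77)
  expect_identical(compute_feature_map(img, bank),
                   compute_feature_map(img, bank))
  expect_length(compute_feature_map(img, bank), 16L)
})

test_that("embedding a filter's own template in an image fires its bit", {
  w <- random_filter_weights(5)
  pos <- pmax(w, 0)
  crop <- round(pos / max(pos) * 255)
  img <- matrix(0, 28, 28)
  img[3:22, 6:25] <- crop
  filt <- conv_filter(w, "feature", threshold = 0)
  resp <- convolve_valid(gray_image(img), filt)
  self_resp <- resp[3, 6]
  expect_gt(self_resp, 0)
  calibrated <- conv_filter(w, "feature", threshold = self_resp - 1)
  bank <- filter_bank(list(calibrated))
  expect_identical(compute_feature_map(gray_image(img), bank), 1L)
})

test_that("class-filter training separates well-separated stroke classes", {
  spec <- synthetic_image_spec(c(0, 1))
  gen <- make_synthetic_images(spec, 60, seed = 4)
  cf <- train_class_filter(gen$images, gen$labels, 0, seed = 5)
  expect_s3_class(cf, "conv_filter")
  expect_true(all(cf$weights >= -128 & cf$weights <= 127))
  expect_true(all(cf$weights == round(cf$weights)))

  held <- make_synthetic_images(spec, 40, seed = 90)
  pred <- vapply(held$images, function(im)
    pool_and_binarize(convolve_valid(im, cf), cf$threshold), integer(1))
  expect_gte(mean(pred == (held$labels == 0)), 0.95)
})

test_that("one-target training degenerates to template matching", {
  spec <- synthetic_image_spec(c(7, 1))
  one <- make_synthetic_images(spec, 1, seed = 2, labels = 7)
  blanks <- make_synthetic_images(synthetic_image_spec(1), 5, seed = 3)
  cf <- train_class_filter(c(one$images, blanks$images),
                           c(7, blanks$labels), 7, seed = 6)
  # best 20x20 crop of the single target image
  best <- -Inf; crop <- NULL
  px <- unclass(one$images[[1]])
  for (r in 1:9) for (c in 1:9) {
    cand <- px[r:(r + 19), c:(c + 19)]
    sc <- sum(cand * cf$weights)
    if (sc > best) { best <- sc; crop <- cand }
  }
  cosine <- sum(crop * cf$weights) /
    sqrt(sum(crop^2) * sum(cf$weights^2))
  expect_gt(cosine, 0)
})

test_that("degenerate training sets are rejected or reported", {
  spec <- synthetic_image_spec(c(0, 1))
  gen <- make_synthetic_images(spec, 10, seed = 1, labels = rep(0, 10))
  expect_error(train_class_filter(gen$images, gen$labels, 0),
               "target and non-target")
  expect_error(train_class_filter(list(), integer(0), 0), "empty")

  # identical images under both labels cannot be separated
  one <- make_synthetic_images(spec, 1, seed = 2, labels = 1)$images[[1]]
  same <- rep(list(one), 8)
  expect_warning(
    cf <- train_class_filter(same, rep(c(0, 1), 4), 0, seed = 3),
    "not separable")
  expect_false(attr(cf, "separable"))

  blank <- lapply(1:6, function(i) gray_image(matrix(0, 28, 28)))
  expect_error(train_feature_filters(blank, rep(0:1, 3), 3), "blank")
  expect_error(train_feature_filters(list(), integer(0), 3), "empty")
  expect_error(train_feature_filters(blank, rep(0:1, 3), 0), ">= 1")
})

test_that("feature filters fire at intermediate rates and differ pairwise", {
  spec <- synthetic_image_spec(c(0, 1, 2, 4))
  gen <- make_synthetic_images(spec, 80, seed = 8)
  ffs <- train_feature_filters(gen$images, gen$labels, n_filters = 5,
                               seed = 9)
  expect_length(ffs, 5L)
  held <- make_synthetic_images(spec, 60, seed = 91)
  resp <- t(vapply(held$images, function(im)
    vapply(ffs, function(f)
      pool_and_binarize(convolve_valid(im, f), f$threshold), integer(1)),
    integer(5)))
  rates <- colMeans(resp)
  expect_true(all(rates > 0.02 & rates < 0.98))
  for (i in 1:4) for (j in (i + 1):5)
    expect_false(all(ffs[[i]]$weights == ffs[[j]]$weights))
  # at least two classes get distinct feature response vectors
  profiles <- apply(resp, 1, paste, collapse = "")
  cls_prof <- tapply(profiles, held$labels, function(p)
    names(sort(table(p), decreasing = TRUE))[1])
  expect_gte(length(unique(cls_prof)), 2L)
})

test_that("a full bank trains with class filters first and 16 slots", {
  spec <- synthetic_image_spec(c(0, 1, 2))
  gen <- make_synthetic_images(spec, 75, seed = 12)
  bank <- fit_filter_bank(gen$images, gen$labels, c(0, 1, 2),
                          n_total = 8L, seed = 13)
  expect_identical(bank$n_total, 8L)
  expect_identical(bank$n_class, 3L)
  expect_identical(bank$trained_classes, c(0L, 1L, 2L))
  kinds <- vapply(bank$filters, function(f) f$kind, character(1))
  expect_identical(kinds, c(rep("class", 3), rep("feature", 5)))
  fm <- predict(bank, gen$images[1:3])
  expect_identical(dim(fm), c(3L, 8L))
})

test_that("8-bit quantization rarely flips held-out filter decisions", {
  spec <- synthetic_image_spec(c(0, 2))
  gen <- make_synthetic_images(spec, 60, seed = 21)
  cf <- train_class_filter(gen$images, gen$labels, 0, seed = 22)
  w_real <- attr(cf, "weights_real")
  m <- max(abs(w_real))
  held <- make_synthetic_images(spec, 100, seed = 95)
  flips <- vapply(held$images, function(im) {
    bit_q <- pool_and_binarize(convolve_valid(im, cf), cf$threshold)
    # real-valued responses compared on the quantized scale
    resp_r <- convolve_valid(im, w_real / m * 127)
    bit_r <- as.integer(max(resp_r) > cf$threshold)
    bit_q != bit_r
  }, logical(1))
  expect_lte(mean(flips), 0.05)
})
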