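test_that("candidate enumeration is the complete 25%-density set", {
  cand <- enumerate_candidates()
  expect_identical(nrow(cand), 1820L)   # choose(16, 4)
  expect_true(all(rowSums(cand) == 4L))
  keys <- apply(cand, 1, paste, collapse = "")
  expect_identical(length(unique(keys)), nrow(cand))
})

test_that("pattern banks keep density 4/16 and pairwise overlap <= 2", {
  for (s in 1:20) {
    bank <- build_pattern_bank(16, seed = s)
    expect_true(all(rowSums(bank$patterns) == 4L))
    ov <- pattern_overlap(bank)
    expect_lte(max(ov[upper.tri(ov)]), 2L)
  }
  # typical run size: 16 LUT lines plus spares
  bank20 <- build_pattern_bank(20, seed = 1)
  expect_identical(nrow(bank20$patterns), 20L)
  ov <- pattern_overlap(bank20)
  expect_lte(max(ov[upper.tri(ov)]), 2L)
  # a pair trivially satisfies the constraint
  expect_lte(max(pattern_overlap(build_pattern_bank(2, seed = 9))[1, 2]), 2L)
})

test_that("pattern-bank construction is deterministic and fails loudly", {
  b1 <- build_pattern_bank(12, seed = 42)
  b2 <- build_pattern_bank(12, seed = 42)
  expect_identical(b1$patterns, b2$patterns)
  expect_error(build_pattern_bank(500, seed = 1), "capacity|only")
  expect_error(build_pattern_bank(0), ">= 1")
})

test_that("LUT building gives each class filter a line and ranks FF combos by frequency", {
  pbank <- build_pattern_bank(16, seed = 2)
  # calibration stream: 7 CF classes + 3 non-trained classes
  spec <- default_synthetic_feature_spec()
  stream <- make_synthetic_feature_stream(spec, 2000, seed = 3)
  lut <- build_lut(stream$maps, n_class = 7, n_nontrained = 3,
                   redundancy = 3, pattern_bank = pbank)
  expect_identical(length(lut$cf_entries) + length(lut$ff_entries), 16L)

  # frequency ranking equals a brute-force count over the calibration maps
  cf0 <- rowSums(stream$maps[, 1:7, drop = FALSE]) == 0
  keys <- apply(stream$maps[cf0, -(1:7), drop = FALSE], 1, paste,
                collapse = "")
  keys <- keys[keys != paste(rep(0, 9), collapse = "")]  # no active line
  tab <- sort(table(keys), decreasing = TRUE)
  expect_identical(names(lut$ff_entries), names(tab)[1:9])
  expect_equal(unname(lut$ff_rates),
               as.numeric(tab[1:9]) / sum(cf0))

  # LUT injectivity: all lines map to distinct patterns
  ids <- c(lut$cf_entries, unname(lut$ff_entries))
  expect_identical(length(unique(ids)), length(ids))
})

test_that("a single repeated FF combination yields exactly one FF line", {
  pbank <- build_pattern_bank(10, seed = 4)
  maps <- matrix(rep(c(0, 0, 1, 1, 0, 0, 0, 0), 50), ncol = 8,
                 byrow = TRUE)
  lut <- build_lut(maps, n_class = 2, n_nontrained = 2, redundancy = 3,
                   pattern_bank = pbank)
  expect_identical(length(lut$ff_entries), 1L)
  expect_equal(unname(lut$ff_rates), 1)
})

test_that("LUT capacity errors are explicit", {
  pbank <- build_pattern_bank(4, seed = 5)
  maps <- matrix(0L, 10, 16)
  expect_error(build_lut(maps, n_class = 7, n_nontrained = 3,
                         redundancy = 3, pattern_bank = pbank),
               "LUT lines")
})

test_that("equalization gives class filters priority and is pure", {
  pbank <- build_pattern_bank(16, seed = 6)
  spec <- default_synthetic_feature_spec()
  stream <- make_synthetic_feature_stream(spec, 1500, seed = 7)
  lut <- build_lut(stream$maps, 7, 3, 3, pbank)

  fm <- rep(0L, 16)
  fm[3] <- 1L                      # CF bit 2 (0-based) fires
  fm[c(9, 12, 15)] <- 1L          # FF bits set but must be ignored
  out <- equalize(fm, lut)
  expect_identical(out$via, "cf")
  expect_identical(out$pattern_id, lut$cf_entries[3])
  expect_identical(out, equalize(fm, lut))   # pure

  # lowest-index CF wins when several fire
  fm2 <- fm; fm2[1] <- 1L
  expect_identical(equalize(fm2, lut)$pattern_id, lut$cf_entries[1])

  # all-zero map -> none under the default fallback
  expect_null(equalize(rep(0L, 16), lut))

  # a stored FF combination routes to its own pattern
  key <- names(lut$ff_entries)[1]
  fm3 <- c(rep(0L, 7), as.integer(strsplit(key, "")[[1]]))
  out3 <- equalize(fm3, lut)
  expect_identical(out3$via, "ff")
  expect_identical(out3$pattern_id, unname(lut$ff_entries[1]))

  expect_error(equalize(rep(0L, 5), lut), "bits")
})

test_that("nearest-key fallback maps unknown combinations by Hamming distance", {
  pbank <- build_pattern_bank(6, seed = 8)
  maps <- rbind(matrix(rep(c(1, 1, 0, 0), 30), ncol = 4, byrow = TRUE),
                matrix(rep(c(0, 0, 1, 1), 20), ncol = 4, byrow = TRUE))
  lut <- build_lut(maps, n_class = 0, n_nontrained = 1, redundancy = 2,
                   pattern_bank = pbank, fallback = "nearest")
  out <- equalize(c(1L, 1L, 0L, 1L), lut)       # distance 1 from "1100"
  expect_identical(out$pattern_id, unname(lut$ff_entries["1100"]))
})
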