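# Block 2: density-equalized 4x4 patterns and the combinational lookup from
# feature maps to patterns.  Equalization makes every frame presented to the
# WTA layer carry the same drive (4 ON cells of 16, P = 25%), so neurons
# compete fairly regardless of how many filters a class happens to excite.

#' Enumerate all 4x4 patterns with exactly 4 ON cells
#'
#' The complete candidate pool for the equalized-pattern bank:
#' choose(16, 4) = 1820 binary grids at 25% density.
#'
#' @return 1820 x 16 0/1 matrix, one row-major flattened pattern per row.
#' @export
enumerate_candidates <- function() {
  combs <- utils::combn(16L, 4L)
  out <- matrix(0L, ncol(combs), 16L)
  for (i in seq_len(ncol(combs))) out[i, combs[, i]] <- 1L
  out
}

#' Build a bank of mutually near-orthogonal equalized patterns
#'
#' Scans the 1820 candidates in a seeded-shuffled order and greedily accepts
#' a pattern iff it shares at most `max_overlap` ON cells with every pattern
#' already accepted.  Deterministic given the seed.
#'
#' @param n number of patterns required.
#' @param seed shuffle seed.
#' @param max_overlap maximum pairwise ON-cell overlap (default 2).
#' @return a `pattern_bank`: list with `patterns` (n x 16 0/1 matrix; row i
#'   is pattern id i) and `max_overlap`.
#' @export
build_pattern_bank <- function(n, seed = 1L, max_overlap = 2L) {
  if (n < 1L) stop("build_pattern_bank: n must be >= 1")
  cand <- enumerate_candidates()
  rng <- make_rng(seed)
  ord <- sample_int(rng, nrow(cand), nrow(cand))
  acc <- matrix(0L, 0L, 16L)
  for (i in ord) {
    p <- cand[i, ]
    if (nrow(acc) == 0L || all(acc %*% p <= max_overlap)) {
      acc <- rbind(acc, p, deparse.level = 0)
      if (nrow(acc) == n) break
    }
  }
  if (nrow(acc) < n)
    stop("build_pattern_bank: only ", nrow(acc), " patterns with pairwise ",
         "overlap <= ", max_overlap, " found; ", n, " requested")
  structure(list(patterns = acc, max_overlap = max_overlap),
            class = "pattern_bank")
}

#' @export
print.pattern_bank <- function(x, ...) {
  ov <- pattern_overlap(x)
  cat("<pattern_bank>", nrow(x$patterns), "patterns, density",
      sum(x$patterns[1, ]), "/16, max pairwise overlap",
      if (nrow(x$patterns) > 1) max(ov[upper.tri(ov)]) else 0, "\n")
  invisible(x)
}

#' Pairwise ON-cell overlap matrix of a pattern bank
#'
#' @param bank a `pattern_bank`.
#' @return integer matrix of shared ON-cell counts.
#' @export
pattern_overlap <- function(bank) {
  tcrossprod(bank$patterns)
}

# Canonical string key for an FF-bit combination.
ff_key <- function(bits) paste(bits, collapse = "")

#' Build the feature-map -> equalized-pattern lookup table
#'
#' Each class filter gets one dedicated pattern.  Among calibration feature
#' maps whose class-filter bits are all 0, the most frequent feature-filter
#' bit combinations — `redundancy` per expected non-trained class — each get
#' a dedicated pattern, mirroring the storage of the most probable feature
#' maps per new class.  The empirical frequency of a combination in the
#' calibration stream is its appearance rate R_P.
#'
#' @param calibration_maps matrix of 0/1 feature maps (rows) or list of
#'   bit vectors, from an unlabeled calibration stream.
#' @param n_class number of class filters (leading bits of each map).
#' @param n_nontrained expected number of non-trained classes.
#' @param redundancy dedicated patterns (and hence output neurons) per
#'   non-trained class (default 3).
#' @param pattern_bank a `pattern_bank` with at least
#'   `n_class + redundancy * n_nontrained` patterns.
#' @return a `wta_lut`: list with `cf_entries` (pattern id per class-filter
#'   index), `ff_entries` (named vector: FF-bit-combination key -> pattern
#'   id), `ff_rates` (appearance rate R_P per stored combination),
#'   `n_class`, `n_bits`, `fallback`.
#' @export
build_lut <- function(calibration_maps, n_class, n_nontrained,
                      redundancy = 3L, pattern_bank,
                      fallback = c("none", "nearest")) {
  fallback <- match.arg(fallback)
  if (is.list(calibration_maps))
    calibration_maps <- do.call(rbind, calibration_maps)
  n_bits <- ncol(calibration_maps)
  n_ff_entries <- redundancy * n_nontrained
  need <- n_class + n_ff_entries
  if (nrow(pattern_bank$patterns) < need)
    stop("build_lut: pattern bank has ", nrow(pattern_bank$patterns),
         " patterns but ", need, " LUT lines are required")

  cf_entries <- seq_len(n_class)

  ff_entries <- integer(0)
  ff_rates <- numeric(0)
  if (n_ff_entries > 0L) {
    cf_part <- if (n_class > 0L) calibration_maps[, seq_len(n_class), drop = FALSE]
               else matrix(0L, nrow(calibration_maps), 0L)
    unknown <- rowSums(cf_part) == 0L
    ffs <- if (n_class > 0L)
             calibration_maps[unknown, -seq_len(n_class), drop = FALSE]
           else calibration_maps[unknown, , drop = FALSE]
    if (nrow(ffs) > 0L) {
      keys <- apply(ffs, 1L, ff_key)
      # an all-zero combination activates no bus line, so it never selects
      # a pattern and is excluded from the stored entries
      keys <- keys[grepl("1", keys)]
      tab <- sort(table(keys), decreasing = TRUE)
      take <- min(n_ff_entries, length(tab))
      # stable rank: frequency desc, then key asc (table sorts ties by name)
      ff_entries <- n_class + seq_len(take)
      names(ff_entries) <- names(tab)[seq_len(take)]
      ff_rates <- as.numeric(tab[seq_len(take)]) / nrow(ffs)
      names(ff_rates) <- names(ff_entries)
    }
  }
  structure(list(cf_entries = cf_entries, ff_entries = ff_entries,
                 ff_rates = ff_rates, n_class = n_class, n_bits = n_bits,
                 fallback = fallback, pattern_bank = pattern_bank),
            class = "wta_lut")
}

#' @export
print.wta_lut <- function(x, ...) {
  cat("<wta_lut>", x$n_class, "class-filter lines +", length(x$ff_entries),
      "feature-combination lines; fallback:", x$fallback, "\n")
  if (length(x$ff_rates))
    cat("  R_P:", paste(sprintf("%s=%.1f%%", names(x$ff_rates),
                                100 * x$ff_rates), collapse = " "), "\n")
  invisible(x)
}

#' Map a feature map to its equalized pattern
#'
#' Class filters have priority: if any CF bit is 1 the pattern of the
#' lowest-index firing CF is returned and the feature bits are ignored.
#' Otherwise the FF-bit combination is looked up; an unknown combination
#' follows the LUT's fallback policy: `"none"` returns `NULL` (no frame is
#' presented downstream), `"nearest"` maps to the stored key at minimum
#' Hamming distance (ties to the lexicographically lowest key).
#'
#' @param fm 0/1 feature-map vector of length `lut$n_bits`.
#' @param lut a `wta_lut`.
#' @return list with `pattern` (length-16 0/1 vector), `pattern_id` and
#'   `via` (`"cf"` or `"ff"`), or `NULL` if no LUT line matches.
#' @export
equalize <- function(fm, lut) {
  if (length(fm) != lut$n_bits)
    stop("equalize: feature map has ", length(fm), " bits, LUT expects ",
         lut$n_bits)
  if (lut$n_class > 0L) {
    cf <- which(fm[seq_len(lut$n_class)] == 1L)
    if (length(cf) > 0L) {
      id <- lut$cf_entries[cf[1]]
      return(list(pattern = lut$pattern_bank$patterns[id, ],
                  pattern_id = id, via = "cf"))
    }
  }
  key <- if (lut$n_class > 0L) ff_key(fm[-seq_len(lut$n_class)])
         else ff_key(fm)
  hit <- match(key, names(lut$ff_entries))
  if (is.na(hit)) {
    if (lut$fallback == "none" || length(lut$ff_entries) == 0L) return(NULL)
    stored <- names(lut$ff_entries)
    hd <- vapply(stored, function(s)
      sum(strsplit(s, "")[[1]] != strsplit(key, "")[[1]]), numeric(1))
    hit <- order(hd, stored)[1]
  }
  id <- unname(lut$ff_entries[hit])
  list(pattern = lut$pattern_bank$patterns[id, ], pattern_id = id,
       via = "ff")
}
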