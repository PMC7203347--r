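# Flat-text serialization of filter banks, pattern banks and LUTs, so a
# trained configuration can be replayed exactly.

#' Write a filter bank as flat text
#'
#' One block per filter: a header line `kind target_class threshold`
#' (target_class `NA` for feature filters) followed by 20 lines of 20
#' integer weights.
#'
#' @param bank a `filter_bank`.
#' @param file output path.
#' @export
write_filter_bank <- function(bank, file) {
  con <- file(file, "w"); on.exit(close(con))
  writeLines(paste("filters", bank$n_total, bank$n_class), con)
  for (f in bank$filters) {
    writeLines(paste(f$kind,
                     if (is.null(f$target_class)) "NA" else f$target_class,
                     f$threshold), con)
    utils::write.table(f$weights, con, row.names = FALSE,
                       col.names = FALSE)
  }
}

#' Read a filter bank written by [write_filter_bank()]
#'
#' @param file path.
#' @return a `filter_bank`.
#' @export
read_filter_bank <- function(file) {
  lines <- readLines(file)
  hdr <- strsplit(lines[1], " ")[[1]]
  n_total <- as.integer(hdr[2])
  pos <- 2L
  filters <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    h <- strsplit(lines[pos], " ")[[1]]
    w <- do.call(rbind, lapply(lines[(pos + 1L):(pos + F_SIDE)],
                               function(l) as.numeric(strsplit(trimws(l), " +")[[1]])))
    filters[[i]] <- conv_filter(w, h[1],
                                target_class = if (h[2] == "NA") NULL
                                               else as.integer(h[2]),
                                threshold = as.numeric(h[3]))
    pos <- pos + F_SIDE + 1L
  }
  filter_bank(filters)
}

#' Write a pattern bank as flat text (`id bit1 ... bit16` per line)
#'
#' @param bank a `pattern_bank`.
#' @param file output path.
#' @export
write_pattern_bank <- function(bank, file) {
  df <- cbind(id = seq_len(nrow(bank$patterns)), bank$patterns)
  utils::write.table(df, file, row.names = FALSE, col.names = FALSE)
}

#' Read a pattern bank written by [write_pattern_bank()]
#'
#' @param file path.
#' @param max_overlap overlap bound recorded on the bank.
#' @return a `pattern_bank`.
#' @export
read_pattern_bank <- function(file, max_overlap = 2L) {
  m <- as.matrix(utils::read.table(file))
  structure(list(patterns = unname(m[, -1, drop = FALSE]),
                 max_overlap = max_overlap),
            class = "pattern_bank")
}

#' Write a LUT as flat text
#'
#' Lines `cf <index> <pattern id>` for class-filter entries and
#' `ff <key> <pattern id> <rate>` for feature-combination entries.
#'
#' @param lut a `wta_lut`.
#' @param file output path.
#' @export
write_lut <- function(lut, file) {
  con <- file(file, "w"); on.exit(close(con))
  writeLines(paste("lut", lut$n_class, lut$n_bits, lut$fallback), con)
  for (i in seq_along(lut$cf_entries))
    writeLines(paste("cf", i, lut$cf_entries[i]), con)
  for (i in seq_along(lut$ff_entries))
    writeLines(paste("ff", names(lut$ff_entries)[i], lut$ff_entries[i],
                     lut$ff_rates[i]), con)
}
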