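# End-to-end experiment driver: configuration, the non-trained-set
# enumerator, and the full pipeline (filters -> equalizer -> STDP session ->
# assignment -> confusion matrix), fully seeded and replayable.

#' Enumerate non-trained-class configurations
#'
#' All subsets of 1..`max_nontrained` classes out of `n_classes` that can be
#' withheld from filter training: with ten classes and up to five withheld
#' there are 637 configurations, one trained filter set each.
#'
#' @param n_classes total number of classes (default 10).
#' @param max_nontrained largest withheld-subset size (default 5).
#' @return list of integer vectors (class ids 0-based).
#' @export
enumerate_nontrained_configs <- function(n_classes = 10L,
                                         max_nontrained = 5L) {
  out <- list()
  for (k in seq_len(max_nontrained)) {
    combs <- utils::combn(n_classes, k) - 1L
    out <- c(out, lapply(seq_len(ncol(combs)), function(j) combs[, j]))
  }
  out
}

#' Build and validate an experiment configuration
#'
#' @param trained trained class ids.
#' @param nontrained non-trained class ids (0 to 5 of them).
#' @param source `"feature"` (synthetic feature maps feed Block 2
#'   directly), `"images"` (synthetic stroke images through the full
#'   chain) or `"idx"` (IDX files via `idx_dir`).
#' @param redundancy output neurons / LUT lines per non-trained class.
#' @param bank_size total filters (default 16).
#' @param calibration_n unlabeled calibration maps used to build the LUT.
#' @param train_items labelled items in the learning/assignment stream.
#' @param test_items labelled items in the scoring stream.
#' @param test_phase_fires per-neuron fire budget for assignment.
#' @param spare_neurons extra output neurons beyond the LUT lines
#'   (default 0: one neuron per line, as in the hardware).
#' @param seed master seed; all stage seeds derive from it.
#' @param n_train_images,idx_dir image-source settings.
#' @param fallback unknown-combination policy for the LUT.
#' @param wta list of overrides passed to [wta_network()].
#' @return an `experiment_config`.
#' @export
experiment_config <- function(trained, nontrained, source = "feature",
                              redundancy = 3L, bank_size = 16L,
                              calibration_n = 2000L, train_items = 2000L,
                              test_items = 500L, test_phase_fires = 100L,
                              seed = 1L, n_train_images = 40L,
                              idx_dir = NULL, fallback = "none",
                              spare_neurons = 0L, wta = list()) {
  trained <- sort(as.integer(trained)); nontrained <- sort(as.integer(nontrained))
  if (length(intersect(trained, nontrained)))
    stop("experiment_config: trained and non-trained sets must be disjoint")
  if (!all(c(trained, nontrained) %in% 0:9))
    stop("experiment_config: class ids must lie in 0..9")
  if (length(nontrained) > 5L)
    stop("experiment_config: at most 5 non-trained classes")
  structure(list(trained = trained, nontrained = nontrained,
                 source = match.arg(source, c("feature", "images", "idx")),
                 redundancy = as.integer(redundancy),
                 bank_size = as.integer(bank_size),
                 calibration_n = as.integer(calibration_n),
                 train_items = as.integer(train_items),
                 test_items = as.integer(test_items),
                 test_phase_fires = as.integer(test_phase_fires),
                 seed = as.integer(seed),
                 n_train_images = as.integer(n_train_images),
                 idx_dir = idx_dir, fallback = fallback,
                 spare_neurons = as.integer(spare_neurons), wta = wta),
            class = "experiment_config")
}

# Stream of labelled feature maps for one stage, by source.
stage_maps <- function(config, n, seed, bank = NULL, image_spec = NULL) {
  if (config$source == "feature") {
    spec <- default_synthetic_feature_spec(config$trained, config$nontrained,
                                           config$bank_size)
    make_synthetic_feature_stream(spec, n, seed)
  } else {
    gen <- make_synthetic_images(image_spec, n, seed)
    list(maps = predict(bank, gen$images), labels = gen$labels)
  }
}

# Accumulate per-neuron label counts from a session trace, respecting the
# per-neuron test-phase fire budget.
stats_from_trace <- function(trace, n_neurons, classes, budget) {
  stats <- neuron_stats(n_neurons, classes)
  rows <- which(trace$kind == "pattern" & !is.na(trace$fired) &
                !is.na(trace$label))
  for (i in rows) {
    nrn <- trace$fired[i]
    if (sum(stats[nrn, ]) < budget)
      stats <- update_neuron_accuracy(stats, nrn, trace$label[i])
  }
  stats
}

#' Run a full continual-learning experiment
#'
#' Executes the pipeline: (train or load filters for the image sources;)
#' calibrate the LUT on an unlabeled stream; run the STDP learning stream
#' and assign neurons to classes from their fire/label statistics; then run
#' a scoring stream against the frozen assignment.  Deterministic given the
#' config.
#'
#' @param config an `experiment_config`.
#' @return a `cl_experiment` report: the LUT, network, neuron statistics,
#'   assignment, confusion matrix and summary accuracies.  `accuracy_fires`
#'   scores correct fires against labelled fires only; `accuracy_items`
#'   counts test items that elicited no fire as errors; both are reported
#'   overall and restricted to the non-trained classes.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  sd <- config$seed
  classes <- c(config$trained, config$nontrained)
  n_cf <- length(config$trained)

  bank <- NULL; image_spec <- NULL
  if (config$source %in% c("images", "idx")) {
    if (config$source == "idx") {
      dat <- load_idx(file.path(config$idx_dir, "train-images-idx3-ubyte"),
                      file.path(config$idx_dir, "train-labels-idx1-ubyte"))
      keep <- dat$labels %in% config$trained
      tr_imgs <- dat$images[keep]; tr_labs <- dat$labels[keep]
      image_spec <- synthetic_image_spec(classes)
    } else {
      image_spec <- synthetic_image_spec(classes)
      tr_spec <- synthetic_image_spec(config$trained)
      gen <- make_synthetic_images(tr_spec,
                                   config$n_train_images * n_cf,
                                   seed = sd + 11L)
      tr_imgs <- gen$images; tr_labs <- gen$labels
    }
    bank <- fit_filter_bank(tr_imgs, tr_labs, config$trained,
                            n_total = config$bank_size, seed = sd + 13L)
  }

  # --- LUT calibration on an unlabeled stream -----------------------------
  calib <- stage_maps(config, config$calibration_n, sd + 17L, bank,
                      image_spec)
  n_lut <- n_cf + config$redundancy * length(config$nontrained)
  pbank <- build_pattern_bank(n_lut, seed = sd + 19L)
  lut <- build_lut(calib$maps, n_class = n_cf,
                   n_nontrained = length(config$nontrained),
                   redundancy = config$redundancy, pattern_bank = pbank,
                   fallback = config$fallback)
  n_neurons <- n_cf + length(lut$ff_entries) + config$spare_neurons

  # --- learning / assignment stream ---------------------------------------
  net <- do.call(wta_network, c(list(n_neurons = n_neurons,
                                     seed = sd + 23L), config$wta))
  lfsr <- lfsr_new(seed = sd + 29L)
  tr_stream <- stage_maps(config, config$train_items, sd + 31L, bank,
                          image_spec)
  tr_pats <- lapply(seq_len(nrow(tr_stream$maps)), function(i) {
    eq <- equalize(tr_stream$maps[i, ], lut)
    if (is.null(eq)) NULL else eq$pattern
  })
  ses1 <- run_session(net, tr_pats, lfsr, n_frames = 2L * config$train_items,
                      labels = tr_stream$labels)
  stats <- stats_from_trace(ses1$trace, n_neurons, classes,
                            config$test_phase_fires)
  assignment <- assign_neurons(stats)

  # --- scoring stream -----------------------------------------------------
  te_stream <- stage_maps(config, config$test_items, sd + 37L, bank,
                          image_spec)
  te_pats <- lapply(seq_len(nrow(te_stream$maps)), function(i) {
    eq <- equalize(te_stream$maps[i, ], lut)
    if (is.null(eq)) NULL else eq$pattern
  })
  ses2 <- run_session(ses1$net, te_pats, ses1$lfsr,
                      n_frames = 2L * config$test_items,
                      labels = te_stream$labels)
  tr2 <- ses2$trace
  fired_rows <- which(tr2$kind == "pattern" & !is.na(tr2$fired) &
                      !is.na(tr2$label))
  fire_log <- data.frame(neuron = tr2$fired[fired_rows],
                         label = tr2$label[fired_rows])
  cm <- score(assignment, fire_log)

  correct <- sum(unclass(assignment)[fire_log$neuron] == fire_log$label,
                 na.rm = TRUE)
  nt <- te_stream$labels %in% config$nontrained
  nt_rows <- fire_log$label %in% config$nontrained
  nt_correct <- sum(unclass(assignment)[fire_log$neuron[nt_rows]] ==
                    fire_log$label[nt_rows], na.rm = TRUE)

  acc <- list(
    accuracy_fires = if (nrow(fire_log)) 100 * correct / nrow(fire_log)
                     else NA_real_,
    accuracy_items = 100 * correct / config$test_items,
    nontrained_accuracy_fires = if (sum(nt_rows)) 100 * nt_correct /
                                  sum(nt_rows) else NA_real_,
    nontrained_accuracy_items = if (sum(nt)) 100 * nt_correct / sum(nt)
                                else NA_real_,
    no_response_items = config$test_items - nrow(fire_log),
    noise_fires = sum(tr2$kind == "noise" & !is.na(tr2$fired)))

  structure(c(list(config = config, bank = bank, lut = lut,
                   net = ses2$net, stats = stats, assignment = assignment,
                   confusion = cm), acc),
            class = "cl_experiment")
}

#' @export
print.cl_experiment <- function(x, ...) {
  cat("<cl_experiment> trained {",
      paste(x$config$trained, collapse = ","), "} non-trained {",
      paste(x$config$nontrained, collapse = ","), "} redundancy",
      x$config$redundancy, "\n")
  cat(sprintf("  accuracy (fires): %.1f%%   accuracy (items): %.1f%%\n",
              x$accuracy_fires, x$accuracy_items))
  if (!is.na(x$nontrained_accuracy_items))
    cat(sprintf("  non-trained accuracy (fires/items): %.1f%% / %.1f%%\n",
                x$nontrained_accuracy_fires, x$nontrained_accuracy_items))
  cat("  no-response items:", x$no_response_items,
      "  noise-frame fires:", x$noise_fires, "\n")
  invisible(x)
}

#' @export
summary.cl_experiment <- function(object, ...) {
  print(object)
  cat("\n")
  print(object$assignment)
  cat("\n")
  print(object$confusion)
  invisible(object)
}

#' Write a run report as a flat key-value file plus confusion CSV
#'
#' @param report a `cl_experiment`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  kv <- c(trained = paste(report$config$trained, collapse = ","),
          nontrained = paste(report$config$nontrained, collapse = ","),
          redundancy = report$config$redundancy,
          seed = report$config$seed,
          accuracy_fires = report$accuracy_fires,
          accuracy_items = report$accuracy_items,
          nontrained_accuracy_fires = report$nontrained_accuracy_fires,
          nontrained_accuracy_items = report$nontrained_accuracy_items,
          no_response_items = report$no_response_items,
          noise_fires = report$noise_fires)
  writeLines(paste(names(kv), kv, sep = "="),
             file.path(dir, "report.txt"))
  write_confusion(report$confusion, file.path(dir, "confusion.csv"))
  invisible(dir)
}
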