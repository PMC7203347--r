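# Incremental per-neuron accuracy bookkeeping, neuron -> class assignment
# after the test phase, and the confusion matrix with global accuracy.
# Percentages are displayed truncated toward zero (a 1/3 - 2/3 split reads
# 33% / 66%); internal arithmetic keeps exact counts.

#' Create an empty per-neuron fire-count table
#'
#' @param n_neurons number of output neurons.
#' @param classes vector of class labels that can appear.
#' @return a `neuron_stats`: integer matrix neurons x classes of fire
#'   counts.
#' @export
neuron_stats <- function(n_neurons, classes) {
  m <- matrix(0L, n_neurons, length(classes),
              dimnames = list(paste0("n", seq_len(n_neurons) - 1L),
                              as.character(classes)))
  structure(m, classes = as.integer(classes), class = c("neuron_stats", "matrix"))
}

#' Record one fire event against the input label
#'
#' @param stats a `neuron_stats`.
#' @param neuron 1-based neuron index.
#' @param label class label of the input that elicited the fire.
#' @return updated `neuron_stats`.
#' @export
update_neuron_accuracy <- function(stats, neuron, label) {
  j <- match(as.character(label), colnames(stats))
  if (is.na(j)) stop("update_neuron_accuracy: unknown label ", label)
  stats[neuron, j] <- stats[neuron, j] + 1L
  stats
}

#' Per-neuron class accuracies in display form
#'
#' Accuracy of neuron i for class c is 100 * count(i, c) / total fires of
#' i, truncated toward zero for display.
#'
#' @param stats a `neuron_stats`.
#' @param truncate if `TRUE` (default), integer-truncate the percentages.
#' @return numeric matrix of percentages (rows with zero fires are all 0).
#' @export
neuron_accuracy <- function(stats, truncate = TRUE) {
  tot <- rowSums(stats)
  acc <- 100 * sweep(unclass(stats), 1L, pmax(tot, 1L), "/")
  acc[tot == 0L, ] <- 0
  if (truncate) trunc(acc) else acc
}

#' Link each neuron to its best class after the test phase
#'
#' Each neuron that fired is assigned to the class with its maximum
#' accuracy (equivalently, maximum fire count); ties go to the lowest class
#' label.  Neurons that never fired are left unassigned (`NA`) and flagged.
#'
#' @param stats a `neuron_stats` accumulated over the test phase.
#' @return an `assignment`: integer vector of class labels (NA for silent
#'   neurons) with attribute `unassigned` listing silent neuron indices.
#' @export
assign_neurons <- function(stats) {
  classes <- attr(stats, "classes")
  tot <- rowSums(stats)
  lab <- apply(unclass(stats), 1L, function(cnt) {
    classes[which.max(cnt)]          # which.max: ties -> lowest class label
  })
  lab[tot == 0L] <- NA_integer_
  structure(as.integer(lab), unassigned = unname(which(tot == 0L)),
            class = "assignment")
}

#' @export
print.assignment <- function(x, ...) {
  cat("<assignment> neuron -> class:",
      paste(seq_along(x) - 1L, unclass(x), sep = ":", collapse = " "), "\n")
  if (length(attr(x, "unassigned")))
    cat("  unassigned neurons:",
        paste(attr(x, "unassigned") - 1L, collapse = " "), "\n")
  invisible(x)
}

#' Score a fire log against a neuron assignment
#'
#' Each fire event predicts the class assigned to the firing neuron;
#' redundant neurons assigned to the same class fold into one prediction
#' column.  Fires from unassigned neurons are counted in an `"unassigned"`
#' column.
#'
#' @param assignment an `assignment` from [assign_neurons()].
#' @param fire_log data.frame with columns `neuron` (1-based index) and
#'   `label` (true class).
#' @return a `confusion_matrix`: counts true label x predicted class, with
#'   attributes `global_accuracy` (percent, `NA` for an empty log) and
#'   `per_class_accuracy`.
#' @export
score <- function(assignment, fire_log) {
  true_classes <- sort(unique(fire_log$label))
  pred_classes <- sort(unique(stats::na.omit(unclass(assignment))))
  cols <- c(as.character(pred_classes), "unassigned")
  cm <- matrix(0L, length(true_classes), length(cols),
               dimnames = list(as.character(true_classes), cols))
  if (nrow(fire_log) > 0L) {
    pred <- unclass(assignment)[fire_log$neuron]
    pc <- ifelse(is.na(pred), "unassigned", as.character(pred))
    for (i in seq_len(nrow(fire_log)))
      cm[as.character(fire_log$label[i]), pc[i]] <-
        cm[as.character(fire_log$label[i]), pc[i]] + 1L
  }
  total <- sum(cm)
  correct <- sum(vapply(rownames(cm), function(cl)
    if (cl %in% colnames(cm)) cm[cl, cl] else 0L, numeric(1)))
  per_class <- vapply(rownames(cm), function(cl) {
    n <- sum(cm[cl, ])
    if (n == 0L) NA_real_
    else 100 * (if (cl %in% colnames(cm)) cm[cl, cl] else 0L) / n
  }, numeric(1))
  structure(cm,
            global_accuracy = if (total == 0L) NA_real_
                              else 100 * correct / total,
            per_class_accuracy = per_class,
            class = c("confusion_matrix", "matrix"))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion matrix (rows: true label, cols: predicted class)\n")
  print(unclass(x))
  ga <- attr(x, "global_accuracy")
  cat("Global accuracy:",
      if (is.na(ga)) "undefined (no fire events)"
      else paste0(trunc(ga), "%"), "\n")
  invisible(x)
}

#' Write a confusion matrix to CSV
#'
#' @param cm a `confusion_matrix`.
#' @param file output path.
#' @export
write_confusion <- function(cm, file) {
  utils::write.csv(as.data.frame(unclass(cm)), file, row.names = TRUE)
}
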