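# Block 3: digital winner-take-all spiking layer.  Synapses are 8-bit
# counters (0-255); each neuron integrates the weighted input frame into an
# adder that persists across frames until a fire resets every integrator
# (lateral inhibition).  The winner's synapses are updated at the frame's
# falling edge (+dLTP on ON synapses, -dLTD on OFF synapses, clipped), and
# its fire threshold grows by dTheta (spike-frequency adaptation).

#' Construct a digital STDP winner-take-all network
#'
#' Synaptic counters start uniform-random in `w_init` (seeded); every
#' neuron's fire threshold starts at `theta0`, by default just below the
#' expected drive of one 4-ON frame at the mean initial weight (so a single
#' pattern presentation can recruit an untrained neuron), and grows by
#' `d_theta` (default 5% of `theta0`) on each of its fires up to
#' `theta_max`.
#'
#' @param n_neurons number of output neurons (one per LUT line in the full
#'   pipeline).
#' @param n_inputs number of input lines (16: the flattened 4x4 frame).
#' @param d_ltp,d_ltd potentiation / depression counter steps.
#' @param w_init two-element range for the uniform initial weights.
#' @param theta0 initial fire threshold (integrator must exceed it
#'   strictly).
#' @param d_theta threshold increment per fire.
#' @param theta_max threshold ceiling: like the hardware's threshold
#'   counters, adaptation saturates.  The default (1000) sits just below
#'   the drive of a fully potentiated 4-ON pattern (4 x 255 = 1020), so a
#'   specialized neuron keeps answering its own pattern at a reduced,
#'   stable rate instead of falling silent in long runs.
#' @param seed RNG seed for the initial weights.
#' @return an object of class `wta_network`.
#' @export
wta_network <- function(n_neurons, n_inputs = 16L, d_ltp = 16L, d_ltd = 4L,
                        w_init = c(96L, 160L),
                        theta0 = NULL, d_theta = NULL, theta_max = NULL,
                        seed = 1L) {
  if (n_neurons < 1L) stop("wta_network: need at least one neuron")
  rng <- make_rng(seed)
  W <- matrix(floor(rng_runif(rng, n_neurons * n_inputs,
                              w_init[1], w_init[2] + 1)),
              n_neurons, n_inputs)
  # one full pattern presentation at mean initial weight must be able to
  # trigger an untrained neuron, so capture bootstraps on single frames
  if (is.null(theta0)) theta0 <- round(0.95 * 4 * mean(w_init))
  if (is.null(d_theta)) d_theta <- max(1, round(0.05 * theta0))
  # threshold counters saturate just below the drive of a fully potentiated
  # 4-ON pattern (4 x 255), so a specialized neuron always answers its own
  # pattern even after heavy adaptation
  if (is.null(theta_max)) theta_max <- 1000
  structure(list(
    weights = W,
    integrator = numeric(n_neurons),
    fire_threshold = rep(as.numeric(theta0), n_neurons),
    fires_count = integer(n_neurons),
    n_neurons = n_neurons, n_inputs = as.integer(n_inputs),
    d_ltp = as.numeric(d_ltp), d_ltd = as.numeric(d_ltd),
    theta0 = as.numeric(theta0), d_theta = as.numeric(d_theta),
    theta_max = as.numeric(theta_max)),
    class = "wta_network")
}

#' @export
print.wta_network <- function(x, ...) {
  cat("<wta_network>", x$n_neurons, "neurons x", x$n_inputs,
      "counter synapses [0,255]\n")
  cat("  dLTP:", x$d_ltp, " dLTD:", x$d_ltd, " theta0:", x$theta0,
      " dTheta:", x$d_theta, "\n")
  cat("  fires:", paste(x$fires_count, collapse = " "), "\n")
  invisible(x)
}

#' @export
coef.wta_network <- function(object, ...) object$weights

#' @export
summary.wta_network <- function(object, ...) {
  s <- list(n_neurons = object$n_neurons,
            fires = object$fires_count,
            thresholds = object$fire_threshold,
            weight_range = range(object$weights),
            mean_weight = rowMeans(object$weights))
  class(s) <- "summary.wta_network"
  s
}

#' @export
print.summary.wta_network <- function(x, ...) {
  cat("Digital STDP WTA network:", x$n_neurons, "neurons\n")
  print(data.frame(neuron = seq_len(x$n_neurons) - 1L, fires = x$fires,
                   threshold = x$thresholds,
                   mean_weight = round(x$mean_weight, 1)))
  invisible(x)
}

#' Apply falling-edge STDP to one synapse row
#'
#' The digitized plasticity rule applied to the firing neuron: every ON
#' input synapse is potentiated by `d_ltp`, every OFF synapse depressed by
#' `d_ltd`, and the counters are clipped to \[0, 255\].
#'
#' @param weights_row numeric vector of synaptic counters.
#' @param frame 0/1 input frame of the same length.
#' @param d_ltp,d_ltd counter steps.
#' @return updated counter vector.
#' @export
apply_plasticity <- function(weights_row, frame, d_ltp = 16, d_ltd = 4) {
  upd <- weights_row + ifelse(frame == 1, d_ltp, -d_ltd)
  pmin(255, pmax(0, upd))
}

#' Present one frame to the network
#'
#' Every neuron adds its weighted input to its integrator.  If any
#' integrator strictly exceeds its threshold, the winner (largest
#' integrator; ties to the lowest index) fires: all integrators reset to
#' zero (lateral inhibition), the winner's threshold grows by `d_theta`
#' (adaptation) and its synapses are updated by [apply_plasticity()] at the
#' falling edge.  At most one neuron fires per frame.
#'
#' @param net a `wta_network`.
#' @param frame 0/1 vector of length `net$n_inputs`.
#' @param kind `"pattern"` or `"noise"`, recorded in the result.
#' @return list with `net` (updated network) and `result` (list with
#'   `fired_neuron` — 1-based index or `NA` — `frame_kind`, `presented`).
#' @export
run_frame <- function(net, frame, kind = c("pattern", "noise")) {
  kind <- match.arg(kind)
  if (net$n_neurons < 1L) stop("run_frame: empty network")
  if (length(frame) != net$n_inputs)
    stop("run_frame: frame length ", length(frame), ", expected ",
         net$n_inputs)
  net$integrator <- net$integrator + as.vector(net$weights %*% frame)
  fired <- NA_integer_
  over <- net$integrator > net$fire_threshold
  if (any(over)) {
    cand <- which(over)                  # neurons past their own threshold
    fired <- cand[which.max(net$integrator[cand])]  # ties -> lowest index
    net$integrator[] <- 0                # inhibition resets every adder
    net$fire_threshold[fired] <- min(net$theta_max,
                                     net$fire_threshold[fired] + net$d_theta)
    net$fires_count[fired] <- net$fires_count[fired] + 1L
    net$weights[fired, ] <- apply_plasticity(net$weights[fired, ], frame,
                                             net$d_ltp, net$d_ltd)
  }
  list(net = net,
       result = list(fired_neuron = fired, frame_kind = kind,
                     presented = frame))
}

#' Run a pattern/noise STDP session
#'
#' Presents `n_frames` frames under the hardware schedule: pattern and
#' noise frames at equal 50% rates.  The default `"alternate"` policy is a
#' strict pattern/noise alternation starting with a pattern slot; the
#' `"bernoulli"` policy draws each slot as pattern with probability `r_i`.
#' Pattern slots consume the next element of `pattern_stream` (an `NA`/NULL
#' element presents nothing that slot); noise slots draw a 1-pixel frame
#' from the LFSR.
#'
#' @param net a `wta_network`.
#' @param pattern_stream list of length-16 0/1 vectors (or `NULL` entries),
#'   recycled if shorter than the number of pattern slots.
#' @param lfsr an `lfsr_state` noise source.
#' @param n_frames total frames to present.
#' @param policy `"alternate"` (default) or `"bernoulli"`.
#' @param r_i pattern-slot probability for the Bernoulli policy.
#' @param seed RNG seed (Bernoulli policy only).
#' @param labels optional vector of labels aligned with `pattern_stream`,
#'   carried into the trace for evaluation.
#' @param record_weights if `TRUE`, snapshot the weight matrix every
#'   `snapshot_every` frames.
#' @param snapshot_every snapshot period in frames.
#' @return an object of class `wta_session`: list with the final `net`,
#'   `trace` (data.frame: frame, kind, fired, label, pattern_id) and
#'   `snapshots` (list of weight matrices, named by frame index).
#' @export
run_session <- function(net, pattern_stream, lfsr, n_frames,
                        policy = c("alternate", "bernoulli"), r_i = 0.5,
                        seed = 1L, labels = NULL,
                        record_weights = FALSE, snapshot_every = 100L) {
  policy <- match.arg(policy)
  if (n_frames < 1L) stop("run_session: n_frames must be >= 1")
  rng <- if (policy == "bernoulli") make_rng(seed) else NULL
  n_pat <- length(pattern_stream)
  trace <- data.frame(frame = seq_len(n_frames),
                      kind = character(n_frames),
                      fired = NA_integer_,
                      label = NA_integer_,
                      stream_idx = NA_integer_,
                      stringsAsFactors = FALSE)
  snapshots <- list()
  pat_i <- 0L
  for (t in seq_len(n_frames)) {
    is_pattern <- if (policy == "alternate") (t %% 2L == 1L)
                  else rng_runif(rng, 1L) < r_i
    if (is_pattern) {
      pat_i <- pat_i + 1L
      idx <- if (n_pat > 0L) (pat_i - 1L) %% n_pat + 1L else 0L
      pat <- if (idx > 0L) pattern_stream[[idx]] else NULL
      trace$kind[t] <- "pattern"
      if (!is.null(pat) && !anyNA(pat) && length(pat) == net$n_inputs) {
        step <- run_frame(net, pat, "pattern")
        net <- step$net
        trace$fired[t] <- step$result$fired_neuron
        trace$stream_idx[t] <- idx
        if (!is.null(labels)) trace$label[t] <- labels[idx]
      }
    } else {
      nf <- noise_frame(lfsr)
      lfsr <- nf$state
      step <- run_frame(net, nf$frame, "noise")
      net <- step$net
      trace$kind[t] <- "noise"
      trace$fired[t] <- step$result$fired_neuron
    }
    if (record_weights && (t %% snapshot_every == 0L || t == n_frames))
      snapshots[[as.character(t)]] <- net$weights
  }
  structure(list(net = net, trace = trace, snapshots = snapshots,
                 lfsr = lfsr),
            class = "wta_session")
}

#' @export
print.wta_session <- function(x, ...) {
  tr <- x$trace
  cat("<wta_session>", nrow(tr), "frames (",
      sum(tr$kind == "pattern"), "pattern /", sum(tr$kind == "noise"),
      "noise ),", sum(!is.na(tr$fired)), "fires\n")
  invisible(x)
}

#' Synaptic window of a neuron for a pattern
#'
#' The learning-quality measure: mean counter over the pattern's ON cells
#' minus mean counter over its OFF cells.  A fully specialized neuron
#' approaches 255 (ON saturated, background depressed to 0).
#'
#' @param weights_row synaptic counter vector of one neuron.
#' @param pattern 0/1 vector with at least one ON and one OFF cell.
#' @return the window width (numeric).
#' @export
synaptic_window <- function(weights_row, pattern) {
  on <- pattern == 1
  if (all(on) || !any(on))
    stop("synaptic_window: pattern must have both ON and OFF cells")
  mean(weights_row[on]) - mean(weights_row[!on])
}

#' Plot the synaptic-window evolution of a session
#'
#' Draws, for each supplied pattern, the window of its best-matching neuron
#' across the recorded weight snapshots — the digital analogue of watching
#' pattern vs background conductances separate during learning.
#'
#' @param x a `wta_session` recorded with `record_weights = TRUE`.
#' @param patterns list of 0/1 pattern vectors to track.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.wta_session <- function(x, patterns, ...) {
  if (length(x$snapshots) == 0L)
    stop("plot.wta_session: session was run without weight snapshots")
  frames <- as.integer(names(x$snapshots))
  win <- sapply(patterns, function(p) {
    vapply(x$snapshots, function(W)
      max(apply(W, 1L, synaptic_window, pattern = p)), numeric(1))
  })
  graphics::matplot(frames, win, type = "l", lty = 1,
                    xlab = "frame", ylab = "synaptic window (counts)", ...)
  graphics::legend("bottomright",
                   legend = paste("pattern", seq_along(patterns)),
                   col = seq_along(patterns), lty = 1, bty = "n")
  invisible(win)
}

#' Export a session's weight snapshots as a flat trace table
#'
#' @param session a `wta_session` recorded with `record_weights = TRUE`.
#' @param file optional path; if given, written as CSV.
#' @return data.frame with columns frame, neuron and w1..w16.
#' @export
weight_trace <- function(session, file = NULL) {
  rows <- do.call(rbind, lapply(names(session$snapshots), function(fr) {
    W <- session$snapshots[[fr]]
    data.frame(frame = as.integer(fr), neuron = seq_len(nrow(W)) - 1L, W)
  }))
  names(rows) <- c("frame", "neuron", paste0("w", seq_len(ncol(rows) - 2L)))
  if (!is.null(file)) utils::write.csv(rows, file, row.names = FALSE)
  rows
}

#' Multi-pattern STDP learning study
#'
#' Presents several equalized patterns at given appearance rates (the
#' remaining pattern slots stay empty), interleaved 50/50 with LFSR noise,
#' and summarises how the network divides them up: which neuron captures
#' which pattern, the final synaptic windows, and whether any pattern's
#' best window collapses during the final third of the session.
#'
#' @param patterns list of 0/1 pattern vectors (e.g. rows of a
#'   [build_pattern_bank()] bank).
#' @param rates appearance rate of each pattern among pattern slots; the
#'   remainder to 1 presents nothing.
#' @param n_neurons output neurons (default 8, leaving redundant spares so
#'   frequent patterns can recruit several neurons while rare ones still
#'   find a free specialist).
#' @param n_frames session length (default 4000).
#' @param seed seed for the slot sequence, initial weights and LFSR.
#' @param ... overrides passed to [wta_network()].
#' @return list with `windows` (neurons x patterns final synaptic
#'   windows), `winner` (best neuron per pattern), `captured` (all
#'   patterns on distinct neurons with positive windows), `stable` (no
#'   best-window collapse below half its final-third peak),
#'   `fires_by_third` and the `session`.
#' @export
run_pattern_study <- function(patterns, rates, n_neurons = 8L,
                              n_frames = 4000L, seed = 1L, ...) {
  stopifnot(length(rates) == length(patterns), sum(rates) <= 1 + 1e-9)
  rng <- make_rng(seed)
  n_slots <- ceiling(n_frames / 2)
  idx <- sample_int(rng, length(patterns) + 1L, n_slots, replace = TRUE,
                    prob = c(rates, max(0, 1 - sum(rates))))
  stream <- lapply(idx, function(i)
    if (i > length(patterns)) NULL else patterns[[i]])
  net <- wta_network(n_neurons, seed = seed, ...)
  ses <- run_session(net, stream, lfsr_new(seed), n_frames = n_frames,
                     record_weights = TRUE, snapshot_every = 100L)
  W <- coef(ses$net)
  windows <- sapply(patterns, function(p)
    apply(W, 1L, synaptic_window, pattern = p))
  winner <- apply(windows, 2L, which.max)
  wmax <- windows[cbind(winner, seq_along(patterns))]
  snaps <- ses$snapshots[as.integer(names(ses$snapshots)) >= 2 * n_frames / 3]
  traj <- sapply(snaps, function(Ws) sapply(patterns, function(p)
    max(apply(Ws, 1L, synaptic_window, pattern = p))))
  if (is.null(dim(traj))) traj <- matrix(traj, nrow = length(patterns))
  stable <- all(traj / apply(traj, 1L, max) > 0.5)
  tr <- ses$trace
  fires_by_third <- vapply(1:3, function(th)
    sum(!is.na(tr$fired[tr$frame > (th - 1) * n_frames / 3 &
                        tr$frame <= th * n_frames / 3])), numeric(1))
  list(windows = windows, winner = winner, best_windows = wmax,
       captured = length(unique(winner)) == length(patterns) &&
                  all(wmax > 0),
       stable = stable, fires_by_third = fires_by_third, session = ses)
}
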