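# 4-bit linear feedback shift register: the pseudo-random noise source that
# drives background depression in the STDP layer.  Fibonacci XOR feedback;
# with the default taps (4,3) the orbit over the 15 nonzero states is
# maximal.  The all-zero register is a fixed point of XOR feedback and is
# therefore forbidden.

#' Create a 4-bit LFSR state
#'
#' @param seed initial register value in 1..15 (any integer is folded into
#'   that range deterministically).
#' @param taps two distinct bit positions in 1..4 (1 = LSB) XORed to form
#'   the feedback bit.  The default `c(4, 3)` is maximal (period 15).
#' @return an object of class `lfsr_state`.
#' @export
lfsr_new <- function(seed = 1L, taps = c(4L, 3L)) {
  reg <- (as.integer(seed) - 1L) %% 15L + 1L   # folds any seed into 1..15
  taps <- as.integer(taps)
  if (length(taps) != 2L || any(taps < 1L) || any(taps > 4L) ||
      taps[1] == taps[2])
    stop("lfsr_new: taps must be two distinct bit positions in 1..4")
  structure(list(register = reg, taps = taps), class = "lfsr_state")
}

#' Advance the LFSR by one step
#'
#' Shifts the register left by one and feeds back the XOR of the tap bits
#' into the LSB.
#'
#' @param state an `lfsr_state`.
#' @return the successor `lfsr_state`.
#' @export
lfsr_step <- function(state) {
  reg <- state$register
  if (is.null(reg) || reg < 1L || reg > 15L)
    stop("lfsr_step: invalid register state (must be in 1..15)")
  bit <- function(pos) bitwAnd(bitwShiftR(reg, pos - 1L), 1L)
  fb <- bitwXor(bit(state$taps[1]), bit(state$taps[2]))
  state$register <- bitwAnd(bitwOr(bitwShiftL(reg, 1L), fb), 15L)
  state
}

#' Generate one 1-pixel noise frame and advance the LFSR
#'
#' Produces a 4x4 binary frame with exactly one ON cell (the hardware's 5%
#' noise density, rounded to one pixel of 16) at row-major linear index
#' `(register - 1) mod 16`, then steps the register so successive frames
#' are uncorrelated.
#'
#' @param state an `lfsr_state`.
#' @return list with `frame` (length-16 0/1 vector, row-major 4x4) and
#'   `state` (advanced `lfsr_state`).
#' @export
noise_frame <- function(state) {
  if (state$register < 1L || state$register > 15L)
    stop("noise_frame: invalid register state")
  frame <- integer(16)
  frame[(state$register - 1L) %% 16L + 1L] <- 1L
  list(frame = frame, state = lfsr_step(state))
}

#' @export
print.lfsr_state <- function(x, ...) {
  cat("<lfsr_state> register:", x$register,
      " taps:", paste(x$taps, collapse = ","), "\n")
  invisible(x)
}
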