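#' Two-state strand-break dynamics
#'
#' Every strand section is an independent two-state Markov chain updated once
#' per second: an intact section breaks with probability
#' `p_break * length` and a broken section reseals with probability
#' `p_seal`. `p_break` is therefore a probability per strand length per
#' update, so longer sections break more often.
#'
#' @param p_break Break-forming probability per strand length per update,
#'   in 1/(m s). Must satisfy `p_break * length <= 1` for every section of
#'   the network it is used with (checked at simulation time).
#' @param p_seal Break-sealing probability per update, 1/s. The default
#'   0.033 corresponds to breaks staying open for about 30 s on average.
#' @param dt State-update interval in seconds. The models are formulated at
#'   a fixed 1-s cadence; other values are rejected.
#' @return An object of class `tj_dynamics`.
#' @export
#' @examples
#' dyn <- tj_dynamics(p_break = 0.047e6)  # 0.047 um^-1 s^-1 in SI units
#' tj_stationary_broken(dyn, length = 50e-9)
tj_dynamics <- function(p_break, p_seal = 0.033, dt = 1) {
  if (!is.numeric(p_break) || length(p_break) != 1L || p_break < 0 ||
      !is.finite(p_break)) {
    stop("'p_break' must be a non-negative number (units 1/(m s))")
  }
  if (!is.numeric(p_seal) || length(p_seal) != 1L || p_seal <= 0 ||
      p_seal > 1) {
    stop("'p_seal' must be a probability in (0, 1]")
  }
  if (!identical(as.numeric(dt), 1)) {
    stop("the state-update interval is fixed at 1 s")
  }
  structure(list(p_break = p_break, p_seal = p_seal, dt = 1),
            class = "tj_dynamics")
}

#' @export
print.tj_dynamics <- function(x, ...) {
  cat(sprintf(
    "Strand dynamics: p_break = %.4g um^-1 s^-1, p_seal = %.3g s^-1 (1-s updates)\n",
    x$p_break / 1e6, x$p_seal))
  invisible(x)
}

#' Stationary probability that a strand section is broken
#'
#' The limit distribution of the two-state chain with per-update break
#' probability `p_break * length` and seal probability `p_seal`:
#' `p_break * length / (p_break * length + p_seal)`.
#'
#' @param dyn A [tj_dynamics()] object.
#' @param length Section length(s) in metres.
#' @return Stationary broken probability, vectorized over `length`.
#' @export
tj_stationary_broken <- function(dyn, length) {
  stopifnot(inherits(dyn, "tj_dynamics"))
  if (any(length < 0)) stop("section lengths must be non-negative")
  pb <- dyn$p_break * length
  if (any(pb > 1)) stop("'p_break' * length exceeds 1 for some section")
  ifelse(pb == 0, 0, pb / (pb + dyn$p_seal))
}

#' Sample initial section states from the stationary distribution
#'
#' @param network A [tj_network()].
#' @param dyn A [tj_dynamics()] object.
#' @return Integer vector of section states (0 intact, 1 broken), drawn
#'   independently with each section's stationary broken probability. Uses
#'   the R random number generator, so results are reproducible under
#'   [set.seed()].
#' @export
tj_sample_states <- function(network, dyn) {
  stopifnot(inherits(network, "tj_network"))
  p <- tj_stationary_broken(dyn, network$sections$length)
  as.integer(stats::runif(length(p)) < p)
}

#' Advance all section states by one update interval
#'
#' Synchronous update: independently for each section, intact sections break
#' with probability `p_break * length` and broken sections reseal with
#' probability `p_seal`.
#'
#' @param states Integer vector of current states (0 intact, 1 broken).
#' @param network A [tj_network()].
#' @param dyn A [tj_dynamics()] object.
#' @return The state vector after one update.
#' @export
tj_step_states <- function(states, network, dyn) {
  stopifnot(inherits(network, "tj_network"),
            length(states) == nrow(network$sections))
  pb <- dyn$p_break * network$sections$length
  if (any(pb > 1)) stop("'p_break' * length exceeds 1 for some section")
  u <- stats::runif(length(states))
  ifelse(states == 1L,
         ifelse(u < dyn$p_seal, 0L, 1L),
         ifelse(u < pb, 1L, 0L))
}
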