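#' Resistance of a single strand break (geometric estimate)
#'
#' Evaluates `R_break = rho_em * h_strand / A_break` with the break
#' cross-section `A_break = 2 * w_TJ * l_break`. With the default geometry
#' this gives about 0.02 GOhm; all calibrated strand resistances are
#' however consistent with a break resistance of 0.2 GOhm, which is what
#' [tj_electrical()] ships as its default. Pass this function's value as
#' `R_break` to use the geometric estimate instead.
#'
#' @param geom A [tj_geometry()].
#' @param elec A [tj_electrical()] (supplies `rho_em`).
#' @return Break resistance in Ohm.
#' @export
tj_break_resistance <- function(geom, elec) {
  stopifnot(inherits(geom, "tj_geometry"), inherits(elec, "tj_electrical"))
  A_break <- 2 * geom$w_TJ * geom$l_break
  elec$rho_em * geom$h_strand / A_break
}

#' Resistance of a strand section
#'
#' An intact section of length `l` conducts only through the strand itself:
#' `R = R_strand / l`. A broken section conducts through the remaining
#' strand in parallel with the break:
#' `R = ((l - l_break) / R_strand + 1 / R_break)^-1`, which is always below
#' the intact value.
#'
#' @param state Section state(s), 0 intact or 1 broken.
#' @param length Section length(s), m.
#' @param elec A [tj_electrical()].
#' @param l_break Break size, m.
#' @return Section resistance(s) in Ohm (per unit depth of the 2D model).
#' @export
tj_section_resistance <- function(state, length, elec, l_break = 20e-9) {
  stopifnot(inherits(elec, "tj_electrical"))
  n <- max(base::length(state), base::length(length))
  state <- rep_len(state, n)
  length <- rep_len(length, n)
  if (any(length <= l_break & state == 1)) {
    stop("section length must exceed 'l_break'")
  }
  ifelse(state == 1,
         1 / ((length - l_break) / elec$R_strand + 1 / elec$R_break),
         elec$R_strand / length)
}

#' Solve the strand resistor network by loop (mesh) analysis
#'
#' Assembles the loop-resistance system over the network's current loops
#' (triangular inner faces plus the outer source loop) and solves for the
#' loop currents. The two-dimensional network resistance is
#' `R_2D = V_s / I_outer`.
#'
#' @param network A [tj_network()].
#' @param R_sections Section resistances, Ohm, in section-id order.
#' @param V_s Source voltage, V.
#' @return A list with the loop currents `I`, the outer-loop current
#'   `I_outer` and the network resistance `R_2D` (Ohm per unit depth).
#' @export
tj_solve_network <- function(network, R_sections, V_s = 1) {
  stopifnot(inherits(network, "tj_network"),
            length(R_sections) == nrow(network$sections))
  if (any(!is.finite(R_sections)) || any(R_sections <= 0)) {
    stop("all section resistances must be positive and finite")
  }
  n <- length(network$loops)
  B <- matrix(0, n, nrow(network$sections))
  for (i in seq_len(n)) {
    B[i, network$loops[[i]]] <- network$loop_signs[[i]]
  }
  M <- B %*% (R_sections * t(B))
  rhs <- numeric(n)
  rhs[n] <- V_s  # the outer source loop is built last
  I <- solve(M, rhs)
  list(I = I, I_outer = abs(I[n]), R_2D = V_s / abs(I[n]))
}

#' Area-specific resistance of the tricellular pore pathway
#'
#' `R_tTJ = rho_em * h_tTJ / (pi * r_tTJ^2 * rho_tTJ)`.
#'
#' @param ttj A [tj_tricellular()].
#' @param elec A [tj_electrical()].
#' @return Resistance in Ohm m^2 (multiply by 1e4 for Ohm cm^2).
#' @export
tj_ttj_resistance <- function(ttj, elec) {
  stopifnot(inherits(ttj, "tj_tricellular"), inherits(elec, "tj_electrical"))
  elec$rho_em * ttj$h_tTJ / (pi * ttj$r_tTJ^2 * ttj$rho_tTJ)
}

#' Simulate transepithelial electrical resistance (TER)
#'
#' Runs the dynamic resistor-network model: section states follow the same
#' two-state break/seal process as the permeability model, and at every 1-s
#' snapshot the loop equations are solved for the outer-loop current. The
#' bicellular resistance is scaled to the epithelium as
#' `R_bTJ(t) = (V_s / I_outer) * w_model / l_cb` and combined in parallel
#' with the static tricellular resistance; the time average of the TER
#' trace is reported. Snapshots whose break pattern is unchanged reuse the
#' previous solution.
#'
#' @param epi A [tj_epithelium()] or preset name (supplies `l_cb`,
#'   `rho_tTJ`, `p_break`, `R_strand`).
#' @param geom A [tj_geometry()].
#' @param elec Optional [tj_electrical()] override (default uses
#'   `epi$R_strand` with the 0.2 GOhm break resistance).
#' @param ttj Optional [tj_tricellular()] override.
#' @param dyn Optional [tj_dynamics()] override.
#' @param horizon Simulated time in seconds (reference runs use 1e6; 1e5
#'   changes the time average by less than the replicate spread).
#' @return An object of class `tj_ter` with the TER trace (Ohm m^2), its
#'   time average, the bicellular and tricellular components and the
#'   conductance shares.
#' @export
#' @examples
#' set.seed(1)
#' sim <- tj_ter("Caco-2", geom = tj_geometry(width = 10), horizon = 500)
#' sim
tj_ter <- function(epi, geom = tj_geometry(), elec = NULL, ttj = NULL,
                   dyn = NULL, horizon = 1e5) {
  if (is.character(epi)) epi <- tj_preset(epi)
  stopifnot(inherits(epi, "tj_epithelium"), inherits(geom, "tj_geometry"))
  if (is.null(elec)) {
    if (is.na(epi$R_strand)) stop("no 'R_strand' available: supply 'elec'")
    elec <- tj_electrical(epi$R_strand)
  }
  if (is.null(ttj)) ttj <- tj_tricellular(epi$rho_tTJ)
  if (is.null(dyn)) {
    if (is.na(epi$p_break)) stop("no 'p_break' available: supply 'dyn'")
    dyn <- tj_dynamics(epi$p_break)
  }

  network <- tj_network(geom)
  n_loops <- length(network$loops)
  n_sec <- nrow(network$sections)
  sec_loops <- matrix(-1L, n_sec, 2)
  sec_signs <- matrix(0, n_sec, 2)
  for (i in seq_len(n_loops)) {
    ids <- network$loops[[i]]
    sg <- network$loop_signs[[i]]
    for (k in seq_along(ids)) {
      s <- ids[k]
      col <- if (sec_loops[s, 1] < 0) 1L else 2L
      sec_loops[s, col] <- i - 1L
      sec_signs[s, col] <- sg[k]
    }
  }

  r2d <- cpp_sim_ter(n_loops, n_loops - 1L, sec_loops, sec_signs,
                     network$sections$length, elec$R_strand, elec$R_break,
                     geom$l_break, dyn$p_break, dyn$p_seal, elec$V_s,
                     as.integer(horizon))
  R_bTJ <- r2d * network$w_model / epi$l_cb       # Ohm m^2
  R_tTJ <- tj_ttj_resistance(ttj, elec)
  TER <- 1 / (1 / R_bTJ + 1 / R_tTJ)
  TER_mean <- mean(TER)

  structure(
    list(TER_mean = TER_mean, TER = TER, R_bTJ = R_bTJ, R_tTJ = R_tTJ,
         R_bTJ_mean = mean(R_bTJ),
         share_tTJ = TER_mean / R_tTJ,
         share_bTJ = 1 - TER_mean / R_tTJ,
         time = seq_along(TER) - 1,
         epithelium = epi$name, n_strand = geom$n_strand,
         horizon = horizon, network = network, elec = elec),
    class = "tj_ter")
}

#' @export
print.tj_ter <- function(x, ...) {
  cat(sprintf("Dynamic TJ resistance: %s (n_strand = %d, %g s)\n",
              x$epithelium, x$n_strand, x$horizon))
  cat(sprintf("  time-averaged TER = %.1f Ohm cm^2\n", x$TER_mean * 1e4))
  cat(sprintf("  bTJ component = %.1f Ohm cm^2, tTJ = %.1f Ohm cm^2\n",
              x$R_bTJ_mean * 1e4, x$R_tTJ * 1e4))
  cat(sprintf("  tTJ conductance share = %.1f%%\n", x$share_tTJ * 100))
  invisible(x)
}

#' @export
summary.tj_ter <- function(object, ...) {
  out <- c(TER_ohm_cm2 = object$TER_mean * 1e4,
           R_bTJ_ohm_cm2 = object$R_bTJ_mean * 1e4,
           R_tTJ_ohm_cm2 = object$R_tTJ * 1e4,
           share_tTJ = object$share_tTJ)
  print(object)
  invisible(out)
}

#' @export
plot.tj_ter <- function(x, n = 7200, ...) {
  idx <- seq_len(min(n, length(x$TER)))
  graphics::plot(x$time[idx] / 60, x$TER[idx] * 1e4, type = "l",
                 xlab = "time (min)", ylab = "TER (Ohm cm^2)",
                 main = sprintf("%s: TER trace", x$epithelium), ...)
  graphics::abline(h = x$TER_mean * 1e4, lty = 2)
  invisible(x)
}
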