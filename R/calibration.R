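#' Calibrate the break-forming probability to a measured permeability
#'
#' Finds the `p_break` for which the simulated total leak-pathway
#' permeability `P_bTJ(p_break) + P_tTJ` matches the measured `P_exp`.
#' Because the simulated permeability is monotone in `p_break`, the search
#' is a bisection on the calibration grid (resolution 0.001 um^-1 s^-1 by
#' default) using common random numbers: every candidate is simulated from
#' the same seed, which makes the empirical objective monotone and lets the
#' bisection reach grid resolution reliably at moderate replicate counts.
#'
#' The bicellular target `P_exp - P_tTJ` must be positive; for epithelia
#' whose tricellular pores alone meet or exceed the measured permeability
#' (the MDCK C7 case) calibration is impossible and an error is raised.
#'
#' The search runs in two stages: a coarse bisection (`coarse_reps`
#' replicates, `coarse_horizon` seconds) narrows the bracket to
#' `coarse_width` grid steps, and the final steps down to one grid step are
#' simulated at full precision (`reps`, `horizon`). Most of the simulation
#' effort is thereby spent on the candidates that decide the last grid
#' digits, where the leak-pathway response is steep in `p_break` and the
#' replicate noise matters most.
#'
#' @param epi A [tj_epithelium()] or preset name with a finite `P_exp`.
#' @param geom A [tj_geometry()].
#' @param mol A [tj_molecule()].
#' @param reps Replicates per candidate simulation in the final stage.
#' @param horizon Simulated seconds per candidate in the final stage.
#' @param coarse_reps,coarse_horizon Scale of the coarse stage.
#' @param coarse_width Bracket width (in grid steps) at which the search
#'   switches to the final stage.
#' @param resolution Calibration grid step for `p_break`, 1/(m s)
#'   (default 0.001 um^-1 s^-1).
#' @param p_max Upper bound for the bracket search, 1/(m s).
#' @param crn_seed Seed reused for every candidate (common random numbers).
#'   Defaults to a draw from the current RNG stream, so results are
#'   reproducible under [set.seed()].
#' @param ... Further arguments to [tj_permeability()].
#' @return An object of class `tj_fit` with the calibrated value (`value`,
#'   also via [coef()]), the candidate trace, and the achieved relative
#'   deviation from the target.
#' @export
tj_fit_p_break <- function(epi, geom = tj_geometry(), mol = tj_molecule(547),
                           reps = 128, horizon = 5400,
                           coarse_reps = 32, coarse_horizon = 3000,
                           coarse_width = 4L,
                           resolution = 0.001e6, p_max = 0.5e6,
                           crn_seed = NULL, ...) {
  if (is.character(epi)) epi <- tj_preset(epi)
  stopifnot(inherits(epi, "tj_epithelium"))
  if (!is.finite(epi$P_exp)) stop("'epi' has no measured permeability")
  P_tTJ <- tj_ttj_permeability(tj_tricellular(epi$rho_tTJ), mol)
  target <- epi$P_exp - P_tTJ
  if (target <= 0) {
    stop("infeasible target: the tricellular pores alone give P_tTJ = ",
         signif(P_tTJ * 1e9, 3), " nm/s >= P_exp = ",
         signif(epi$P_exp * 1e9, 3),
         " nm/s, so 'p_break' cannot be calibrated")
  }
  if (is.null(crn_seed)) crn_seed <- sample.int(2^30, 1)

  cache <- new.env(parent = emptyenv())
  sim_P <- function(k, fine) {  # candidate = k * resolution
    key <- paste0(k, if (fine) "f" else "c")
    hit <- get0(key, envir = cache)
    if (!is.null(hit)) return(hit)
    set.seed(crn_seed)
    v <- if (k == 0) 0 else tj_permeability(
      epi, geom = geom, mol = mol, dyn = tj_dynamics(k * resolution),
      reps = if (fine) reps else coarse_reps,
      horizon = if (fine) horizon else coarse_horizon, ...)$P_bTJ
    assign(key, v, envir = cache)
    v
  }

  trace <- list()
  note <- function(k, v, fine) trace[[length(trace) + 1L]] <<-
    data.frame(p_break = k * resolution, P_bTJ = v,
               stage = if (fine) "fine" else "coarse")

  lo <- 0L; v_lo <- 0
  hi <- max(2L, as.integer(round(min(p_max, 0.064e6) / resolution)))
  repeat {
    v_hi <- sim_P(hi, FALSE); note(hi, v_hi, FALSE)
    if (v_hi >= target) break
    if (hi * resolution >= p_max) {
      stop("'p_break' bracket exceeded 'p_max' without reaching the target")
    }
    lo <- hi; v_lo <- v_hi
    hi <- min(hi * 2L, as.integer(ceiling(p_max / resolution)))
  }
  while (hi - lo > 1L) {
    fine <- (hi - lo) <= coarse_width
    mid <- (lo + hi) %/% 2L
    v <- sim_P(mid, fine); note(mid, v, fine)
    if (v < target) { lo <- mid; v_lo <- v } else { hi <- mid; v_hi <- v }
  }
  # decide between the final bracket ends at full precision; if the coarse
  # stage mis-bracketed (both full-precision values on the same side of the
  # target), walk the bracket outward at full precision until the target is
  # straddled again
  v_lo <- sim_P(lo, TRUE)
  v_hi <- sim_P(hi, TRUE)
  while (v_hi < target && hi * resolution < p_max) {
    lo <- hi; v_lo <- v_hi
    hi <- hi + 1L
    v_hi <- sim_P(hi, TRUE); note(hi, v_hi, TRUE)
  }
  while (v_lo > target && lo > 0L) {
    hi <- lo; v_hi <- v_lo
    lo <- lo - 1L
    v_lo <- sim_P(lo, TRUE); note(lo, v_lo, TRUE)
  }
  k_best <- if (abs(v_lo - target) <= abs(v_hi - target)) lo else hi
  P_best <- sim_P(k_best, TRUE)

  structure(
    list(parameter = "p_break", value = k_best * resolution,
         target = epi$P_exp, achieved = abs(P_best + P_tTJ - epi$P_exp) /
           epi$P_exp,
         P_bTJ = P_best, P_tTJ = P_tTJ,
         trace = do.call(rbind, trace), resolution = resolution,
         reps = reps, horizon = horizon, epithelium = epi$name,
         crn_seed = crn_seed),
    class = "tj_fit")
}

#' Calibrate the strand resistance to a measured TER
#'
#' With `p_break` fixed (typically from [tj_fit_p_break()]), finds the
#' `R_strand` for which the time-averaged simulated TER matches the
#' measured `TER_exp`, by common-random-number bisection on the 0.01
#' GOhm um grid. The target must lie below the static tricellular
#' resistance, which caps the achievable TER.
#'
#' @param epi A [tj_epithelium()] or preset name with a finite `TER_exp`.
#' @param p_break Break-forming probability, 1/(m s); defaults to the
#'   epithelium's calibrated value.
#' @param geom A [tj_geometry()].
#' @param horizon Simulated seconds per candidate.
#' @param resolution Grid step for `R_strand`, Ohm m (default 0.01
#'   GOhm um).
#' @param R_max Upper bound for the bracket search, Ohm m.
#' @param R_break Break resistance, Ohm.
#' @param crn_seed Seed reused for every candidate.
#' @return An object of class `tj_fit`.
#' @export
tj_fit_r_strand <- function(epi, p_break = NULL, geom = tj_geometry(),
                            horizon = 2e4, resolution = 10,
                            R_max = 20e3, R_break = 0.2e9,
                            crn_seed = NULL) {
  if (is.character(epi)) epi <- tj_preset(epi)
  stopifnot(inherits(epi, "tj_epithelium"))
  if (!is.finite(epi$TER_exp)) stop("'epi' has no measured TER")
  if (is.null(p_break)) p_break <- epi$p_break
  dyn <- tj_dynamics(p_break)
  R_tTJ <- tj_ttj_resistance(tj_tricellular(epi$rho_tTJ),
                             tj_electrical(1, R_break = R_break))
  if (R_tTJ <= epi$TER_exp) {
    stop("infeasible target: the tricellular resistance alone (",
         signif(R_tTJ * 1e4, 3), " Ohm cm^2) is at or below TER_exp")
  }
  if (is.null(crn_seed)) crn_seed <- sample.int(2^30, 1)

  cache <- new.env(parent = emptyenv())
  sim_TER <- function(k) {
    key <- as.character(k)
    hit <- get0(key, envir = cache)
    if (!is.null(hit)) return(hit)
    set.seed(crn_seed)
    v <- tj_ter(epi, geom = geom,
                elec = tj_electrical(k * resolution, R_break = R_break),
                dyn = dyn, horizon = horizon)$TER_mean
    assign(key, v, envir = cache)
    v
  }

  trace <- list()
  note <- function(k, v) trace[[length(trace) + 1L]] <<-
    data.frame(R_strand = k * resolution, TER = v)

  lo <- 1L; v_lo <- sim_TER(lo); note(lo, v_lo)
  if (v_lo >= epi$TER_exp) {
    k_best <- lo
  } else {
    hi <- max(2L, as.integer(round(
      min(R_max, if (is.finite(epi$R_strand)) 2 * epi$R_strand else 1e3) /
        resolution)))
    repeat {
      v_hi <- sim_TER(hi); note(hi, v_hi)
      if (v_hi >= epi$TER_exp) break
      if (hi * resolution >= R_max) {
        stop("'R_strand' bracket exceeded 'R_max' without reaching the target")
      }
      lo <- hi; v_lo <- v_hi
      hi <- min(hi * 2L, as.integer(ceiling(R_max / resolution)))
    }
    while (hi - lo > 1L) {
      mid <- (lo + hi) %/% 2L
      v <- sim_TER(mid); note(mid, v)
      if (v < epi$TER_exp) { lo <- mid; v_lo <- v } else { hi <- mid; v_hi <- v }
    }
    k_best <- if (abs(v_lo - epi$TER_exp) <= abs(v_hi - epi$TER_exp)) lo
      else hi
  }
  TER_best <- sim_TER(k_best)

  structure(
    list(parameter = "R_strand", value = k_best * resolution,
         target = epi$TER_exp,
         achieved = abs(TER_best - epi$TER_exp) / epi$TER_exp,
         TER = TER_best, trace = do.call(rbind, trace),
         resolution = resolution, horizon = horizon,
         epithelium = epi$name, crn_seed = crn_seed),
    class = "tj_fit")
}

#' @export
print.tj_fit <- function(x, ...) {
  unit <- if (x$parameter == "p_break") {
    sprintf("%.3f um^-1 s^-1", x$value / 1e6)
  } else {
    sprintf("%.2f GOhm um", x$value / 1e3)
  }
  cat(sprintf("Calibrated %s for %s: %s\n", x$parameter, x$epithelium, unit))
  cat(sprintf("  achieved |simulated - target| / target = %.1f%% (%d candidates)\n",
              x$achieved * 100, nrow(x$trace)))
  invisible(x)
}

#' @export
coef.tj_fit <- function(object, ...) {
  stats::setNames(object$value, object$parameter)
}

#' Relative roles of the bicellular and tricellular pathways
#'
#' Decomposes the total leak-pathway permeability and the TER conductance
#' into bicellular and tricellular shares. With `method = "measured"` the
#' decomposition uses the measured totals and the analytic tricellular
#' components (`P_tTJ / P_exp` and `TER_exp / R_tTJ`); with
#' `method = "simulated"` supply `perm` ([tj_permeability()]) and/or `ter`
#' ([tj_ter()]) results.
#'
#' @param epi A [tj_epithelium()] or preset name.
#' @param mol A [tj_molecule()].
#' @param method `"measured"` or `"simulated"`.
#' @param perm,ter Simulation results for `method = "simulated"`.
#' @return A list with `perm_bTJ`, `perm_tTJ`, `ter_bTJ`, `ter_tTJ`
#'   (fractions; each pair sums to 1; `NA` where no input is available).
#' @export
tj_pathway_shares <- function(epi, mol = tj_molecule(547),
                              method = c("measured", "simulated"),
                              perm = NULL, ter = NULL) {
  if (is.character(epi)) epi <- tj_preset(epi)
  method <- match.arg(method)
  if (method == "measured") {
    P_tTJ <- tj_ttj_permeability(tj_tricellular(epi$rho_tTJ), mol)
    R_tTJ <- tj_ttj_resistance(tj_tricellular(epi$rho_tTJ),
                               tj_electrical(1))
    pt <- min(1, P_tTJ / epi$P_exp)
    st <- epi$TER_exp / R_tTJ
  } else {
    pt <- if (is.null(perm)) NA_real_ else perm$P_tTJ / perm$P_TJ
    st <- if (is.null(ter)) NA_real_ else ter$share_tTJ
  }
  list(perm_bTJ = 1 - pt, perm_tTJ = pt, ter_bTJ = 1 - st, ter_tTJ = st)
}

#' Strand-number sweep of permeability and TER
#'
#' Re-simulates an epithelium with `n_strand` varying (2-6 by default),
#' holding the junction densities at the across-MDCK averages unless the
#' supplied epithelium says otherwise, and reports absolute and
#' 4-strand-normalized permeability and TER with their pathway shares.
#'
#' @param epi A [tj_epithelium()] or preset name (typically
#'   `"MDCK II mean"` or `"MDCK C7 mean-geometry"`).
#' @param n_strand Integer vector of strand numbers.
#' @param width Compartments across the model strip.
#' @param reps,horizon_perm Permeability replicates and horizon (s).
#' @param horizon_ter TER horizon (s).
#' @param mol A [tj_molecule()].
#' @return A data frame, one row per strand number, with `P_bTJ`, `P_tTJ`,
#'   `P_TJ` (m/s), `TER` (Ohm m^2), pathway shares, and `P_rel`/`TER_rel`
#'   normalized to the 4-strand row (or the first row if 4 is absent).
#' @export
tj_strand_sweep <- function(epi, n_strand = 2:6, width = 50, reps = 128,
                            horizon_perm = 7200, horizon_ter = 1e5,
                            mol = tj_molecule(547)) {
  if (is.character(epi)) epi <- tj_preset(epi)
  rows <- lapply(n_strand, function(n) {
    geom <- tj_geometry(n_strand = n, width = width)
    perm <- tj_permeability(epi, geom = geom, mol = mol, reps = reps,
                            horizon = horizon_perm)
    ter <- tj_ter(epi, geom = geom, horizon = horizon_ter)
    data.frame(n_strand = n, P_bTJ = perm$P_bTJ, P_tTJ = perm$P_tTJ,
               P_TJ = perm$P_TJ, TER = ter$TER_mean,
               perm_share_tTJ = perm$P_tTJ / perm$P_TJ,
               ter_share_tTJ = ter$share_tTJ)
  })
  out <- do.call(rbind, rows)
  ref <- match(4L, out$n_strand)
  if (is.na(ref)) ref <- 1L
  out$P_rel <- out$P_TJ / out$P_TJ[ref]
  out$TER_rel <- out$TER / out$TER[ref]
  out
}

#' Parameter sensitivity analysis
#'
#' Re-simulates permeability and TER with each parameter individually
#' altered by `+/- delta` (25% by default) and reports the outputs relative
#' to the unperturbed baseline. Common random numbers are used across all
#' runs so the ratios isolate the parameter effect.
#'
#' @param epi A [tj_epithelium()] or preset name.
#' @param params Parameters to perturb, from `p_break`, `p_seal`,
#'   `l_break`, `l_cb`, `rho_tTJ`, `R_strand`.
#' @param delta Relative perturbation.
#' @param geom A [tj_geometry()].
#' @param reps,horizon_perm,horizon_ter Simulation scale.
#' @param mol A [tj_molecule()].
#' @param crn_seed Seed reused for every run.
#' @return A data frame with one row per (parameter, direction): relative
#'   permeability `P_rel` and TER `TER_rel` versus baseline.
#' @export
tj_sensitivity <- function(epi,
                           params = c("p_break", "p_seal", "l_break",
                                      "l_cb", "rho_tTJ", "R_strand"),
                           delta = 0.25, geom = tj_geometry(), reps = 128,
                           horizon_perm = 7200, horizon_ter = 1e5,
                           mol = tj_molecule(547), crn_seed = NULL) {
  if (is.character(epi)) epi <- tj_preset(epi)
  params <- match.arg(params, several.ok = TRUE)
  if (is.null(crn_seed)) crn_seed <- sample.int(2^30, 1)

  run <- function(p_break = epi$p_break, p_seal = 0.033,
                  l_break = geom$l_break, l_cb = epi$l_cb,
                  rho_tTJ = epi$rho_tTJ, R_strand = epi$R_strand) {
    e <- tj_epithelium(epi$name, l_cb = l_cb, rho_tTJ = rho_tTJ,
                       P_exp = epi$P_exp, TER_exp = epi$TER_exp,
                       p_break = p_break, R_strand = R_strand)
    g <- geom; g$l_break <- l_break
    dyn <- tj_dynamics(p_break, p_seal)
    set.seed(crn_seed)
    perm <- tj_permeability(e, geom = g, mol = mol, dyn = dyn, reps = reps,
                            horizon = horizon_perm)
    set.seed(crn_seed + 1L)
    ter <- tj_ter(e, geom = g, dyn = dyn,
                  elec = tj_electrical(R_strand), horizon = horizon_ter)
    c(P = perm$P_TJ, TER = ter$TER_mean)
  }

  base <- run()
  rows <- list()
  for (p in params) {
    for (s in c(1 - delta, 1 + delta)) {
      args <- list(); args[[p]] <- switch(
        p, p_break = epi$p_break, p_seal = 0.033, l_break = geom$l_break,
        l_cb = epi$l_cb, rho_tTJ = epi$rho_tTJ, R_strand = epi$R_strand) * s
      v <- do.call(run, args)
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = p, change = s - 1,
        P_rel = v["P"] / base["P"], TER_rel = v["TER"] / base["TER"],
        row.names = NULL)
    }
  }
  do.call(rbind, rows)
}

#' Junction densities of a regular hexagonal cell array
#'
#' For a perfect hexagonal tiling with cell apothem `a` (the
#' centre-to-edge distance, i.e. half the cell "diameter" across flats):
#' each cell of area `2 sqrt(3) a^2` owns half of its perimeter `6 *
#' (2a / sqrt(3))`, giving a boundary length per area `l_cb = 1 / a`; each
#' cell owns `6 / 3 = 2` tricellular vertices, giving
#' `rho_tTJ = 1 / (sqrt(3) a^2)`.
#'
#' @param apothem Cell apothem in metres.
#' @return A list with `l_cb` (1/m) and `rho_tTJ` (1/m^2).
#' @export
#' @examples
#' tj_hexagonal_geometry(20e-6)  # l_cb = 0.05 um^-1
tj_hexagonal_geometry <- function(apothem) {
  if (!is.numeric(apothem) || any(apothem <= 0)) {
    stop("'apothem' must be positive")
  }
  list(l_cb = 1 / apothem, rho_tTJ = 1 / (sqrt(3) * apothem^2))
}
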