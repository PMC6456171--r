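#' Epithelium parameter sets
#'
#' An epithelium is described by its junction geometry densities (cell
#' boundary length per area `l_cb`, tricellular pore density `rho_tTJ`), the
#' measured barrier properties the models are calibrated against (`P_exp`,
#' `TER_exp`), and the calibrated dynamic parameters (`p_break`,
#' `R_strand`). All values are stored in SI units.
#'
#' @param name Epithelium label.
#' @param l_cb Cell boundary (bicellular TJ) length per epithelial area,
#'   1/m.
#' @param rho_tTJ Tricellular junction density, 1/m^2.
#' @param P_exp Measured 547-Da PEG permeability, m/s (may be `NA`).
#' @param TER_exp Measured TER, Ohm m^2 (may be `NA`).
#' @param p_break Break-forming probability, 1/(m s) (may be `NA` before
#'   calibration).
#' @param R_strand Strand resistance per length, Ohm m (may be `NA`).
#' @return An object of class `tj_epithelium`.
#' @seealso [tj_presets()], [tj_preset()]
#' @export
tj_epithelium <- function(name, l_cb, rho_tTJ, P_exp = NA_real_,
                          TER_exp = NA_real_, p_break = NA_real_,
                          R_strand = NA_real_) {
  num <- c(l_cb = l_cb, rho_tTJ = rho_tTJ)
  if (any(!is.finite(num)) || any(num <= 0)) {
    stop("'l_cb' and 'rho_tTJ' must be positive")
  }
  structure(list(name = name, l_cb = l_cb, rho_tTJ = rho_tTJ,
                 P_exp = P_exp, TER_exp = TER_exp, p_break = p_break,
                 R_strand = R_strand),
            class = "tj_epithelium")
}

#' @export
print.tj_epithelium <- function(x, ...) {
  cat(sprintf("Epithelium: %s\n", x$name))
  cat(sprintf("  l_cb = %.3f um^-1, rho_tTJ = %.3f um^-2\n",
              x$l_cb / 1e6, x$rho_tTJ / 1e12))
  cat(sprintf("  P_exp = %s nm/s, TER_exp = %s Ohm cm^2\n",
              format(x$P_exp * 1e9), format(x$TER_exp * 1e4)))
  cat(sprintf("  p_break = %s um^-1 s^-1, R_strand = %s GOhm um\n",
              format(x$p_break / 1e6), format(x$R_strand / 1e3)))
  invisible(x)
}

# Preset table in reporting units: P_exp nm/s, TER Ohm cm^2, l_cb um^-1,
# rho_tTJ um^-2, p_break um^-1 s^-1, R_strand GOhm um. Converted to SI on
# load. The MDCK C7 p_break was derived from break-density counts rather
# than calibrated (the tricellular pores alone account for its measured
# permeability). The two "mean" entries carry the across-dataset averages
# used for the strand-number sweep and the sensitivity analysis.
tj_preset_table <- data.frame(
  name = c("Caco-2", "MDCK C7", "MDCK IIa", "MDCK IIb", "MDCK IIc",
           "MDCK IId", "MDCK IIb ZO-1 KD", "MDCK IId ZO-1/2 dKD",
           "MDCK II mean", "MDCK C7 mean-geometry"),
  P_exp = c(10.0, 1.0, 4.3, 0.8, 2.9, 2.3, 3.1, 26.0, NA, NA),
  TER_exp = c(220, 460, 28, 54, 41, 30, 62, 26, NA, NA),
  l_cb = c(0.525, 0.424, 0.484, 0.185, 0.311, 0.179, 0.189, 0.200,
           0.282, 0.282),
  rho_tTJ = c(0.130, 0.078, 0.106, 0.014, 0.035, 0.014, 0.015, 0.019,
              0.049, 0.049),
  p_break = c(0.047, 0.005, 0.032, 0.029, 0.038, 0.044, 0.047, 0.084,
              0.036, 0.005),
  R_strand = c(7.65, 10.62, 0.46, 0.32, 0.45, 0.20, 0.45, 0.34,
               0.36, 10.62),
  stringsAsFactors = FALSE)

#' Registry of calibrated epithelium presets
#'
#' Eight calibrated epithelia (Caco-2, MDCK C7, four MDCK II datasets and
#' the two ZO knockdowns) plus two averaged parameter sets used by the
#' strand-number sweep and the sensitivity analysis ("MDCK II mean",
#' "MDCK C7 mean-geometry", both with the across-MDCK average junction
#' densities l_cb = 0.282 um^-1 and rho_tTJ = 0.049 um^-2).
#'
#' @param si Return values in SI units (default) or in the reporting units
#'   of the preset table (nm/s, Ohm cm^2, um^-1, um^-2, um^-1 s^-1,
#'   GOhm um).
#' @return `tj_presets()`: a data frame of all presets. `tj_preset()`: a
#'   single [tj_epithelium()] object.
#' @export
#' @examples
#' tj_presets(si = FALSE)
#' tj_preset("Caco-2")
tj_presets <- function(si = TRUE) {
  tab <- tj_preset_table
  if (si) {
    tab$P_exp <- tab$P_exp * 1e-9        # nm/s -> m/s
    tab$TER_exp <- tab$TER_exp * 1e-4    # Ohm cm^2 -> Ohm m^2
    tab$l_cb <- tab$l_cb * 1e6           # um^-1 -> m^-1
    tab$rho_tTJ <- tab$rho_tTJ * 1e12    # um^-2 -> m^-2
    tab$p_break <- tab$p_break * 1e6     # um^-1 s^-1 -> m^-1 s^-1
    tab$R_strand <- tab$R_strand * 1e3   # GOhm um -> Ohm m
  }
  tab
}

#' @rdname tj_presets
#' @param name Preset name, matched exactly against `tj_presets()$name`.
#' @export
tj_preset <- function(name) {
  tab <- tj_presets(si = TRUE)
  i <- match(name, tab$name)
  if (is.na(i)) {
    stop("unknown preset '", name, "'; available: ",
         paste(tab$name, collapse = ", "))
  }
  tj_epithelium(tab$name[i], l_cb = tab$l_cb[i], rho_tTJ = tab$rho_tTJ[i],
                P_exp = tab$P_exp[i], TER_exp = tab$TER_exp[i],
                p_break = tab$p_break[i], R_strand = tab$R_strand[i])
}

#' Tricellular pore parameters
#'
#' The tricellular central tube is modelled as a static cylindrical pore of
#' radius `r_tTJ` and height `h_tTJ`, at density `rho_tTJ` per epithelial
#' area.
#'
#' @param rho_tTJ Pore density, 1/m^2.
#' @param r_tTJ Pore radius, m (default 5 nm).
#' @param h_tTJ Pore height, m (default 1 um).
#' @return An object of class `tj_tricellular`.
#' @export
tj_tricellular <- function(rho_tTJ, r_tTJ = 5e-9, h_tTJ = 1e-6) {
  v <- c(rho_tTJ = rho_tTJ, r_tTJ = r_tTJ, h_tTJ = h_tTJ)
  if (any(!is.finite(v)) || any(v <= 0)) {
    stop("tricellular parameters must be positive")
  }
  structure(list(rho_tTJ = rho_tTJ, r_tTJ = r_tTJ, h_tTJ = h_tTJ),
            class = "tj_tricellular")
}

#' Electrical parameters of the resistor-network model
#'
#' @param R_strand Intact strand resistance per length, Ohm m.
#' @param rho_em Extracellular medium resistivity, Ohm m (default 0.537).
#' @param V_s Source voltage in the outer loop, V. A pure scaling
#'   parameter: the computed resistances do not depend on it.
#' @param R_break Resistance of a single strand break, Ohm. The default
#'   0.2 GOhm is the value all calibrated strand resistances are consistent
#'   with; [tj_break_resistance()] evaluates the geometric estimate
#'   `rho_em * h_strand / (2 w_TJ l_break)` instead, which is about an
#'   order of magnitude smaller, and can be passed here explicitly.
#' @return An object of class `tj_electrical`.
#' @export
tj_electrical <- function(R_strand, rho_em = 0.537, V_s = 1,
                          R_break = 0.2e9) {
  v <- c(R_strand = R_strand, rho_em = rho_em, V_s = V_s, R_break = R_break)
  if (any(!is.finite(v)) || any(v <= 0)) {
    stop("electrical parameters must be positive")
  }
  structure(list(R_strand = R_strand, rho_em = rho_em, V_s = V_s,
                 R_break = R_break),
            class = "tj_electrical")
}
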