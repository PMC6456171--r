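#' Permeant molecule: PEG size and diffusivity from molecular mass
#'
#' Polyethylene-glycol oligomers are the standard probes of the
#' size-selective leak pathway. Their hydrodynamic radius follows the
#' empirical power law `r_m = 0.29 * M^0.454` Angstrom and their aqueous
#' diffusion coefficient `D0 = 9.9e-9 * M^-0.453` m^2/s, with `M` in Da.
#'
#' @param mass Molecular mass in Da. The default 547 Da is the PEG oligomer
#'   used for fitting (radius about 0.51 nm), too large for claudin pores.
#' @return An object of class `tj_molecule` with elements `mass`, `radius`
#'   (m) and `D0` (m^2/s).
#' @export
#' @examples
#' m <- tj_molecule(547)
#' m$radius * 1e9  # ~0.51 nm
tj_molecule <- function(mass = 547) {
  if (!is.numeric(mass) || length(mass) != 1L || mass <= 0) {
    stop("'mass' must be a positive number (Da)")
  }
  structure(list(mass = mass, radius = peg_radius(mass),
                 D0 = peg_diffusivity(mass)),
            class = "tj_molecule")
}

#' @export
print.tj_molecule <- function(x, ...) {
  cat(sprintf("PEG-like molecule: %.0f Da, r = %.3f nm, D0 = %.3g m^2/s\n",
              x$mass, x$radius * 1e9, x$D0))
  invisible(x)
}

#' @rdname tj_molecule
#' @return `peg_radius()`: molecular radius in metres.
#' @export
peg_radius <- function(mass) {
  if (any(mass <= 0)) stop("'mass' must be positive")
  0.29 * mass^0.454 * 1e-10
}

#' @rdname tj_molecule
#' @return `peg_diffusivity()`: aqueous diffusion coefficient in m^2/s.
#' @export
peg_diffusivity <- function(mass) {
  if (any(mass <= 0)) stop("'mass' must be positive")
  9.9e-9 * mass^-0.453
}

#' Hindrance factors for diffusion in a slit or a cylindrical pore
#'
#' Dechadilok-Deen polynomial fits for the reduction of diffusivity of a
#' sphere of radius `r_m` in a confined geometry, as a function of
#' `lambda`, the ratio of solute radius to aperture half-width (slit) or
#' radius (pore). `hindrance_slit()` applies to the strand-break slit of
#' half-width `w_TJ`; `hindrance_pore()` to the tricellular central tube.
#' Both equal 1 at `lambda = 0` (free diffusion); the pore factor vanishes
#' at `lambda = 1` (steric exclusion).
#'
#' @param lambda Solute-to-aperture size ratio. The slit factor requires
#'   `0 <= lambda < 1`; the pore factor `0 <= lambda <= 1`.
#' @return Dimensionless hindrance factor, vectorized over `lambda`.
#' @export
#' @examples
#' hindrance_slit(0)           # 1
#' hindrance_pore(1)           # 0
#' hindrance_slit(0.51 / 4)    # 547-Da PEG in a 4-nm half-width slit
hindrance_slit <- function(lambda) {
  if (any(lambda < 0 | lambda >= 1)) {
    stop("slit hindrance requires 0 <= lambda < 1")
  }
  llog <- ifelse(lambda == 0, 0, lambda * log(lambda))
  1 + 9 / 16 * llog - 1.19358 * lambda + 0.4285 * lambda^3 -
    0.3192 * lambda^4 + 0.08428 * lambda^5
}

#' @rdname hindrance_slit
#' @export
hindrance_pore <- function(lambda) {
  if (any(lambda < 0 | lambda > 1)) {
    stop("pore hindrance requires 0 <= lambda <= 1")
  }
  llog <- ifelse(lambda == 0, 0, lambda * log(lambda))
  1 + 9 / 8 * llog - 1.56034 * lambda + 0.528155 * lambda^2 +
    1.91521 * lambda^3 - 2.81903 * lambda^4 + 0.270788 * lambda^5 +
    1.10115 * lambda^6 - 0.435933 * lambda^7
}
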