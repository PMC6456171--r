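#' Steady-state (mean-field) comparator models
#'
#' Static simplifications of the dynamic barrier models that replace the
#' stochastic break process by its expectation. Each strand carries its
#' stationary expected number of open breaks (summing the stationary broken
#' probability over its sections; fractional counts are used directly), and
#' the compartment rows are assumed internally well mixed, reducing the
#' system to a series of `n_strand` static layers.
#'
#' `tj_ss_permeability()` gives the series combination of the per-strand
#' break conductances `E_s * l_break * P_break / w_model`;
#' `tj_ss_resistance()` the series combination of per-strand resistances,
#' each an intact strand of the full model width in parallel with `E_s`
#' breaks of resistance `R_break`, scaled to the epithelium by
#' `w_model / l_cb`. Both coincide with the dynamic model at
#' `p_break = 0`; with dynamics present the steady-state permeability lies
#' far above and the steady-state resistance far below the dynamic values,
#' because the dynamic barrier is rate-limited by how often breaks line up
#' across strands rather than by the mean break density.
#'
#' @param epi A [tj_epithelium()] or preset name.
#' @param geom A [tj_geometry()].
#' @param mol A [tj_molecule()].
#' @param dyn Optional [tj_dynamics()] override.
#' @return Permeability in m/s, or bicellular resistance in Ohm m^2.
#' @export
tj_ss_permeability <- function(epi, geom = tj_geometry(),
                               mol = tj_molecule(547), dyn = NULL) {
  if (is.character(epi)) epi <- tj_preset(epi)
  stopifnot(inherits(epi, "tj_epithelium"))
  if (is.null(dyn)) dyn <- tj_dynamics(epi$p_break)
  if (dyn$p_break == 0) return(0)
  net <- tj_network(geom)
  E_s <- expected_breaks_per_strand(net, dyn)
  P_break <- tj_break_permeability(geom, mol, epi$l_cb)
  G_s <- E_s * geom$l_break * P_break / net$w_model
  1 / sum(1 / G_s)
}

#' @rdname tj_ss_permeability
#' @param elec Optional [tj_electrical()] override.
#' @export
tj_ss_resistance <- function(epi, geom = tj_geometry(), elec = NULL,
                             dyn = NULL) {
  if (is.character(epi)) epi <- tj_preset(epi)
  stopifnot(inherits(epi, "tj_epithelium"))
  if (is.null(elec)) elec <- tj_electrical(epi$R_strand)
  if (is.null(dyn)) dyn <- tj_dynamics(epi$p_break)
  net <- tj_network(geom)
  E_s <- expected_breaks_per_strand(net, dyn)
  g_s <- net$w_model / elec$R_strand + E_s / elec$R_break
  R_2D <- sum(1 / g_s)
  R_2D * net$w_model / epi$l_cb
}

# Stationary expected number of open breaks on each horizontal strand.
expected_breaks_per_strand <- function(net, dyn) {
  sec <- net$sections[net$sections$strand > 0, ]
  p <- tj_stationary_broken(dyn, sec$length)
  as.numeric(tapply(p, sec$strand, sum))
}
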