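# Assembly energetics.
#
# A partial capsid is a spanning tree plus a set of occupied faces
# (pentamers).  Its assembly energy, relative to the bare RNA molecule and
# in units of the pentamer-pentamer binding scale E0, is
#
#   dE(n) = n1*eps1 + n2*eps2 - n3 - mu0*n
#
# where n1 counts tree links under exactly one pentamer edge, n2 tree links
# shared by two pentamer edges, n3 shared pentamer-pentamer edges not on the
# tree, and mu0 is the reference chemical potential of a free pentamer
# (which absorbs the non-specific electrostatic RNA affinity).  eps1 < 0 is
# the specific link-edge affinity per contact; additivity over the two edges
# meeting a link fixes eps2 = -1 + 2*eps1.

#' Energy parameters of the assembly model
#'
#' @param eps1 Dimensionless specific affinity of a tree link for a single
#'   pentamer edge, in units of E0 (typically negative; -0.5 in the
#'   reference calculations).
#' @param mu0 Reference chemical potential in E0 units, or
#'   \code{"equilibrium"} to choose the value at which a complete capsid has
#'   zero assembly energy (see \code{\link{equilibrium_mu0}}).
#' @param e0 Overall energy scale in units of kT: the binding energy of two
#'   pentamer edges with no specific RNA affinity.  Boltzmann factors use
#'   \code{exp(-e0 * dE)} with dE in E0 units.
#' @param poly Polyhedron used when \code{mu0 = "equilibrium"} (defaults to
#'   dodecahedral counts).
#' @return List with class \code{energy_params}: \code{e0}, \code{eps1},
#'   \code{eps2 = -1 + 2*eps1}, \code{mu0}.
#' @examples
#' energy_params(eps1 = -0.5, mu0 = -4)
#' @export
energy_params <- function(eps1, mu0 = "equilibrium", e0 = 4, poly = NULL) {
  stopifnot(e0 > 0)
  if (identical(mu0, "equilibrium")) mu0 <- equilibrium_mu0(eps1, poly)
  structure(
    list(e0 = e0, eps1 = eps1, eps2 = -1 + 2 * eps1, mu0 = mu0),
    class = "energy_params"
  )
}

#' @export
print.energy_params <- function(x, ...) {
  cat(sprintf(
    "energy_params: E0=%g kT, eps1=%g, eps2=%g, mu0=%g (E0 units)\n",
    x$e0, x$eps1, x$eps2, x$mu0
  ))
  invisible(x)
}

#' Chemical potential at assembly equilibrium
#'
#' The reference chemical potential for which the complete capsid has zero
#' assembly energy, dE(F) = (V-1)*eps2 - (E-V+1) - F*mu0 = 0.  On the
#' dodecahedron this is (19*(-1+2*eps1) - 11)/12; for eps1 = -0.5 it equals
#' -49/12, about -4.083.
#'
#' @param eps1 Specific link-edge affinity (E0 units).
#' @param poly Optional \code{capsid_polyhedron}; dodecahedron counts are
#'   used when omitted.
#' @return mu0 in E0 units.
#' @export
equilibrium_mu0 <- function(eps1, poly = NULL) {
  V <- if (is.null(poly)) 20L else poly$V
  E <- if (is.null(poly)) 30L else poly$E
  Fn <- if (is.null(poly)) 12L else poly$F
  ((V - 1) * (-1 + 2 * eps1) - (E - V + 1)) / Fn
}

#' Edge-contact counts of an assembly configuration
#'
#' For each graph edge let t indicate a tree link and k the number of its two
#' bordering faces that carry a pentamer.  Then \code{n1} counts edges with
#' (t, k) = (1, 1), \code{n2} edges with (1, 2), and \code{n3} edges with
#' (0, 2).
#'
#' @param tree Integer vector of tree edge indices.
#' @param faces Integer vector of occupied face ids.
#' @param poly A \code{capsid_polyhedron}.
#' @return Named integer vector \code{c(n1, n2, n3)}.
#' @export
edge_counts <- function(tree, faces, poly) {
  occ <- logical(poly$F)
  occ[faces] <- TRUE
  k <- occ[poly$edge_faces[, 1]] + occ[poly$edge_faces[, 2]]
  t <- logical(poly$E)
  t[tree] <- TRUE
  c(
    n1 = sum(t & k == 1L),
    n2 = sum(t & k == 2L),
    n3 = sum(!t & k == 2L)
  )
}

#' Assembly energy of a configuration
#'
#' dE = n1*eps1 + n2*eps2 - n3 - mu0*n in E0 units (multiply by
#' \code{params$e0} for kT).  The empty configuration has energy zero, and
#' the complete capsid energy (V-1)*eps2 - (E-V+1) - F*mu0 is the same for
#' every spanning tree.
#'
#' @inheritParams edge_counts
#' @param params An \code{\link{energy_params}} object.
#' @return Energy in E0 units.
#' @export
assembly_energy <- function(tree, faces, poly, params) {
  nc <- edge_counts(tree, faces, poly)
  unname(nc[1] * params$eps1 + nc[2] * params$eps2 - nc[3] -
           params$mu0 * length(faces))
}

#' Calibrate eps1 from assembly-onset concentrations
#'
#' The specific-affinity parameter can be estimated from the ratio of capsid
#' protein concentrations at assembly onset without RNA versus with viral
#' RNA.  At the virion reference state the full-capsid energy
#' E0*(-30 + 38*eps1 - 12*mu0) is zero by construction, so the empty-capsid
#' assembly energy is -38*eps1 (in E0 units, dodecahedral counts): raising
#' the chemical potential by log(conc_ratio) kT, i.e. log(conc_ratio)/e0 in
#' E0 units per pentamer, must close that gap:
#' -2*(V-1)*eps1 = F*log(conc_ratio)/e0.
#'
#' For MS2-like onset concentrations (2.0 vs 0.05 mg/ml, ratio 40) and
#' e0 = 4 this gives -eps1 of about 0.29.
#'
#' @param conc_ratio Ratio of empty-capsid to virion assembly-onset protein
#'   concentrations.
#' @param e0 Energy scale in kT.
#' @param poly Optional polyhedron (dodecahedral counts by default).
#' @return eps1 (negative).
#' @export
calibrate_eps1 <- function(conc_ratio = 40, e0 = 4, poly = NULL) {
  V <- if (is.null(poly)) 20L else poly$V
  Fn <- if (is.null(poly)) 12L else poly$F
  -Fn * (log(conc_ratio) / e0) / (2 * (V - 1))
}
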