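# Derived observables: assembly delay time, kinetic selectivity, and
# selectivity scans over the energy scale E0.

#' Assembly delay time
#'
#' The lag between establishing assembly conditions and the first appearance
#' of complete capsids, read off the packaged-fraction curve P_12(t) as the
#' intercept of the maximum-slope tangent with the time axis:
#' t_d = t* - P(t*)/P'(t*), with t* the time of maximum slope.  The series
#' is resampled with a monotone cubic spline before differencing, so the
#' estimate is stable against the logarithmic spacing of the solver output.
#'
#' @param traj A \code{capsid_trajectory}, or a numeric vector of times when
#'   \code{p12} is given separately.
#' @param p12 Packaged-fraction series matching \code{traj} as a time
#'   vector; omit when \code{traj} is a trajectory object.
#' @param species Species index used when \code{traj} is a trajectory.
#' @param n_grid Size of the dense evaluation grid.
#' @return List with class \code{delay_time}: \code{t_d}, \code{t_star}
#'   (time of maximum slope), \code{slope}.
#' @export
delay_time <- function(traj, p12 = NULL, species = 1L, n_grid = 20000L) {
  if (inherits(traj, "capsid_trajectory")) {
    times <- traj$times
    p12 <- traj$species[[species]]$p12
  } else {
    times <- traj
  }
  stopifnot(length(times) == length(p12))
  rise <- diff(range(p12))
  if (rise < 1e-10) stop("packaged fraction is flat; delay time undefined")
  if (min(diff(p12)) < -0.2 * rise && which.max(p12) < length(p12) / 2)
    warning("packaged fraction is strongly non-monotone; tangent construction may be unreliable")
  f <- stats::splinefun(times, p12, method = "monoH.FC")
  # dense grid, logarithmic over the simulated window
  pos <- times[times > 0]
  grid <- 10^seq(log10(min(pos)), log10(max(pos)), length.out = n_grid)
  slope <- f(grid, deriv = 1)
  i <- which.max(slope)
  t_star <- grid[i]
  td <- t_star - f(t_star) / slope[i]
  structure(list(t_d = td, t_star = t_star, slope = slope[i]),
            class = "delay_time")
}

#' @export
print.delay_time <- function(x, ...) {
  cat(sprintf("delay time t_d = %.4g (max slope %.3g at t* = %.4g)\n",
              x$t_d, x$slope, x$t_star))
  invisible(x)
}

#' Kinetic selectivity of a packaging competition
#'
#' S = (P_12^(1)(t_max) - P_12^(2)(t_max)) / P_12^(1)(t_max), where t_max is
#' the time at which the encoded species (species 1, low MLD / high wrapping
#' number) reaches its maximum packaged fraction.  If species 2 outcompetes
#' species 1 at that time, S is set to 0.  S lies in [0, 1] by construction.
#'
#' @param traj A two-species \code{capsid_trajectory}.
#' @return List with class \code{selectivity}: \code{S}, \code{t_max},
#'   \code{p1}, \code{p2} (the two packaged fractions at \code{t_max}).
#' @export
selectivity <- function(traj) {
  stopifnot(inherits(traj, "capsid_trajectory"), length(traj$species) == 2L)
  p1 <- traj$species[[1]]$p12
  p2 <- traj$species[[2]]$p12
  i <- which.max(p1)
  if (i == length(p1) && p1[i] > p1[1] + 1e-9 &&
      (p1[i] - p1[i - 1]) > 1e-6 * p1[i])
    warning("species-1 yield still rising at t_end; using the final time as t_max")
  if (p1[i] <= 0) {
    warning("species-1 yield is identically zero; selectivity reported as 0")
    return(structure(list(S = 0, t_max = traj$times[i], p1 = 0, p2 = p2[i]),
                     class = "selectivity"))
  }
  S <- (p1[i] - p2[i]) / p1[i]
  if (p2[i] > p1[i]) S <- 0
  S <- min(max(S, 0), 1)
  structure(list(S = S, t_max = traj$times[i], p1 = p1[i], p2 = p2[i]),
            class = "selectivity")
}

#' @export
print.selectivity <- function(x, ...) {
  cat(sprintf("kinetic selectivity S = %.4f at t_max = %.4g (p1 = %.4f, p2 = %.4f)\n",
              x$S, x$t_max, x$p1, x$p2))
  invisible(x)
}

#' Selectivity as a function of the energy scale E0
#'
#' Runs one packaging competition per E0 grid value (rebuilding the assembly
#' networks, whose minimum-energy structure does not depend on E0, and
#' re-integrating the kinetics, which does) and evaluates the kinetic
#' selectivity for each.  Across the physically interesting range the curve
#' behaves like the order parameter of an order-disorder transition: S is
#' erased by assembly-pathway entropy below E0 of roughly 1.2 kT and
#' approaches 1 near 4 kT.
#'
#' @param e0_grid Energy scales in kT.
#' @param tree1,tree2 Edge-index vectors of the two competing spanning
#'   trees (species 1 = encoded class).
#' @param poly A \code{capsid_polyhedron}.
#' @param eps1 Specific affinity parameter.
#' @param mu0 Reference chemical potential (E0 units) or
#'   \code{"equilibrium"}.
#' @param c0,D,t_end,... Passed to \code{\link{compete_packaging}}.
#' @return data.frame with columns \code{e0}, \code{S}, \code{t_max},
#'   \code{p1}, \code{p2}.
#' @export
selectivity_scan <- function(e0_grid, tree1, tree2, poly,
                             eps1 = -0.5, mu0 = -4, c0 = 1, D = 0.5,
                             t_end = 1e6, ...) {
  rows <- lapply(e0_grid, function(e0) {
    par <- energy_params(eps1 = eps1, mu0 = mu0, e0 = e0, poly = poly)
    net1 <- build_network(tree1, poly, par)
    net2 <- build_network(tree2, poly, par)
    traj <- compete_packaging(net1, net2, c0 = c0, D = D, t_end = t_end, ...)
    s <- selectivity(traj)
    data.frame(e0 = e0, S = s$S, t_max = s$t_max, p1 = s$p1, p2 = s$p2)
  })
  do.call(rbind, rows)
}
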