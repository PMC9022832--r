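# Master-equation kinetics.
#
# Assembly proceeds node-to-node on the assembly network by single-pentamer
# addition and removal.  On-rates follow a kinetic Monte-Carlo (Metropolis)
# prescription: lambda*c_f, suppressed by an Arrhenius factor
# exp(-e0*ddE) when the step is uphill (ddE > 0, in E0 units).  Off-rates
# are fixed by detailed balance against the Boltzmann distribution,
# W_on/W_off = c_f * exp(-e0*ddE), and never depend on c_f: disassembly is
# concentration-independent.  The free pentamer concentration c_f is slaved
# to the occupation probabilities by mass conservation, which couples the
# otherwise linear master equations into a nonlinear system, and couples the
# two RNA species of a packaging competition to each other.

#' Kinetic Monte-Carlo on/off rates
#'
#' \code{on_rate}: rate of adding a pentamer across an energy step of
#' \code{delta} E0 units: \code{lambda*c_f} when the step is downhill or
#' level, \code{lambda*c_f*exp(-e0*delta)} when uphill.  \code{off_rate}:
#' the detailed-balance partner, \code{lambda} for an uphill addition and
#' \code{lambda*exp(e0*delta)} for a downhill one, independent of
#' \code{c_f}.  Their ratio is always \code{c_f*exp(-e0*delta)}, the
#' Boltzmann factor of the step, so clamped-concentration dynamics
#' thermalises to the equilibrium distribution.
#'
#' @param delta Energy step dE(n+1) - dE(n) in E0 units (vectorised).
#' @param c_f Free pentamer concentration (reference units).
#' @param e0 Energy scale in kT.
#' @param lambda Base rate; its inverse is the unit of time.
#' @return Rate(s) in units of lambda.
#' @export
on_rate <- function(delta, c_f, e0, lambda = 1) {
  stopifnot(all(c_f >= 0))
  lambda * c_f * ifelse(delta > 0, exp(-e0 * delta), 1)
}

#' @rdname on_rate
#' @export
off_rate <- function(delta, e0, lambda = 1) {
  lambda * ifelse(delta > 0, 1, exp(e0 * delta))
}

#' Free pentamer concentration from mass conservation
#'
#' c_f/c0 = 1 - (D / (s*F)) * sum over species of the mean pentamer number,
#' where s is the number of species and F the number of faces (pentamers per
#' capsid).  With two dodecahedral species this is the D/24 rule; a single
#' species uses D/12.  D = F*r_t/c0 is the RNA-to-protein mixing ratio:
#' D = 1 is stoichiometric for one species.
#'
#' @param occupations List with one numeric vector per species: level
#'   occupation probabilities Q_n for n = 0..F.
#' @param D Mixing ratio.
#' @param c0 Total pentamer concentration (reference units).
#' @param n_faces Number of faces per capsid.
#' @return c_f in reference units; an error is raised if mass conservation
#'   would require a negative concentration.
#' @export
free_pentamer_fraction <- function(occupations, D, c0 = 1, n_faces = 12L) {
  s <- length(occupations)
  nbar <- sum(vapply(occupations, function(q) sum((seq_along(q) - 1) * q),
                     numeric(1)))
  cf <- c0 * (1 - (D / (s * n_faces)) * nbar)
  if (cf < -1e-9) stop("mass conservation violated: computed c_f < 0")
  max(cf, 0)
}

# Per-species rate tables given instantaneous c_f.
.species_rates <- function(net, c_f, lambda) {
  dd <- diff(net$e_min)
  list(
    on = on_rate(dd, c_f, net$params$e0, lambda),
    off = off_rate(dd, net$params$e0, lambda)
  )
}

#' Integrate the packaging master equation
#'
#' Solves the coupled nonlinear master equations for one or two RNA species
#' competing for a shared pool of free pentamers, starting from fully
#' unassembled RNA (all probability in the n=0 state, c_f = c0), with a
#' stiff solver on a logarithmic output grid.
#'
#' Two granularities are available.  \code{"node"} integrates the
#' node-resolved master equation on the assembly network, one probability
#' per physically distinct intermediate, with uniform per-link rates.
#' \code{"level"} integrates the per-level reduction obtained by assuming
#' equal occupation of the equal-energy nodes within a level, in which the
#' network enters through the multiplicities m_n and inter-level link counts
#' L_n; this is the default and reduces a species to F+1 equations.  Both
#' granularities share the same equilibrium distribution; they are compared
#' directly in the test suite.
#'
#' @param networks An \code{\link{assembly_network}} or a list of one or two
#'   (two for a packaging competition; equal RNA concentrations).
#' @param c0 Total pentamer concentration in reference units.
#' @param D RNA-to-protein mixing ratio.
#' @param lambda Base rate (sets the unit of time).
#' @param t_end Final time in units of 1/lambda.
#' @param granularity \code{"level"} or \code{"node"}.
#' @param clamp_cf If non-NULL, hold c_f fixed at this value (grand-canonical
#'   dynamics; used for thermalisation checks).
#' @param n_out Number of logarithmically spaced output times.
#' @param t_first First positive output time.
#' @param rtol,atol Solver tolerances.
#' @param method \code{deSolve} integration method.
#' @return Object of class \code{capsid_trajectory}: \code{times}, per
#'   species the level-occupation matrix \code{Q} (rows = times, columns =
#'   n = 0..F), the packaged fraction \code{p12 = Q[, F+1]}, node-resolved
#'   occupations when requested, the \code{c_f} series, and the maximum
#'   probability-conservation error \code{max_mass_err}.
#' @export
integrate_master <- function(networks, c0 = 1, D = 0.5, lambda = 1,
                             t_end = 1e4,
                             granularity = c("level", "node"),
                             clamp_cf = NULL, n_out = 400, t_first = 1e-2,
                             rtol = 1e-8, atol = 1e-12, method = "lsoda") {
  granularity <- match.arg(granularity)
  if (inherits(networks, "assembly_network")) networks <- list(networks)
  s <- length(networks)
  stopifnot(s %in% c(1L, 2L), c0 > 0, D > 0, lambda > 0, t_end > 0)
  nF <- networks[[1]]$poly$F
  for (net in networks) stopifnot(net$poly$F == nF)

  times <- c(0, 10^seq(log10(t_first), log10(t_end), length.out = n_out))

  if (granularity == "level") {
    nl <- nF + 1L
    y0 <- rep(0, s * nl)
    for (k in seq_len(s)) y0[(k - 1) * nl + 1] <- 1
    deriv <- function(t, y, parms) {
      qs <- lapply(seq_len(s), function(k) y[(k - 1) * nl + seq_len(nl)])
      cf <- if (!is.null(clamp_cf)) clamp_cf else {
        nbar <- sum(vapply(qs, function(q) sum((0:nF) * q), numeric(1)))
        max(c0 * (1 - (D / (s * nF)) * nbar), 0)
      }
      dy <- numeric(s * nl)
      for (k in seq_len(s)) {
        net <- networks[[k]]
        r <- .species_rates(net, cf, lambda)
        q <- qs[[k]]
        flux <- r$on * (net$L / net$m[seq_len(nF)]) * q[seq_len(nF)] -
          r$off * (net$L / net$m[-1]) * q[-1]
        dy[(k - 1) * nl + seq_len(nl)] <- c(0, flux) - c(flux, 0)
      }
      list(dy)
    }
    sol <- deSolve::ode(y0, times, deriv, parms = NULL, method = method,
                        rtol = rtol, atol = atol, maxsteps = 50000)
    Qs <- lapply(seq_len(s), function(k) {
      sol[, 1 + (k - 1) * nl + seq_len(nl), drop = FALSE]
    })
    nodes <- NULL
  } else {
    layout <- lapply(networks, function(net) {
      sizes <- net$m
      offs <- cumsum(c(0, sizes))
      indeg <- lapply(0:nF, function(n) {
        if (n == 0) rep(0, sizes[1]) else colSums(net$A[[n]])
      })
      outdeg <- lapply(0:nF, function(n) {
        if (n == nF) rep(0, sizes[nF + 1]) else rowSums(net$A[[n + 1]])
      })
      list(sizes = sizes, offs = offs, total = sum(sizes),
           indeg = indeg, outdeg = outdeg)
    })
    sp_off <- cumsum(c(0, vapply(layout, `[[`, numeric(1), "total")))
    y0 <- rep(0, sp_off[s + 1])
    for (k in seq_len(s)) y0[sp_off[k] + 1] <- 1
    deriv <- function(t, y, parms) {
      dy <- numeric(length(y))
      # level occupations for mass conservation
      nbar <- 0
      Pk <- vector("list", s)
      for (k in seq_len(s)) {
        lay <- layout[[k]]
        yk <- y[sp_off[k] + seq_len(lay$total)]
        P <- lapply(0:nF, function(n) yk[lay$offs[n + 1] + seq_len(lay$sizes[n + 1])])
        Pk[[k]] <- P
        nbar <- nbar + sum(vapply(0:nF, function(n) n * sum(P[[n + 1]]), numeric(1)))
      }
      cf <- if (!is.null(clamp_cf)) clamp_cf
        else max(c0 * (1 - (D / (s * nF)) * nbar), 0)
      for (k in seq_len(s)) {
        net <- networks[[k]]
        lay <- layout[[k]]
        r <- .species_rates(net, cf, lambda)
        P <- Pk[[k]]
        for (n in 0:nF) {
          gain <- numeric(lay$sizes[n + 1])
          loss <- numeric(lay$sizes[n + 1])
          if (n > 0) {
            gain <- gain + r$on[n] * as.vector(t(net$A[[n]]) %*% P[[n]])
            loss <- loss + r$off[n] * lay$indeg[[n + 1]]
          }
          if (n < nF) {
            gain <- gain + r$off[n + 1] * as.vector(net$A[[n + 1]] %*% P[[n + 2]])
            loss <- loss + r$on[n + 1] * lay$outdeg[[n + 1]]
          }
          dy[sp_off[k] + lay$offs[n + 1] + seq_len(lay$sizes[n + 1])] <-
            gain - P[[n + 1]] * loss
        }
      }
      list(dy)
    }
    sol <- deSolve::ode(y0, times, deriv, parms = NULL, method = method,
                        rtol = rtol, atol = atol, maxsteps = 50000)
    nodes <- lapply(seq_len(s), function(k) {
      lay <- layout[[k]]
      sol[, 1 + sp_off[k] + seq_len(lay$total), drop = FALSE]
    })
    Qs <- lapply(seq_len(s), function(k) {
      lay <- layout[[k]]
      q <- sapply(0:nF, function(n) {
        rowSums(nodes[[k]][, lay$offs[n + 1] + seq_len(lay$sizes[n + 1]),
                           drop = FALSE])
      })
      q
    })
  }

  if (attr(sol, "istate")[1] < 0)
    stop("master-equation integration failed; solver diagnostics: ",
         paste(attr(sol, "istate"), collapse = " "))

  mass_err <- max(vapply(Qs, function(q) max(abs(rowSums(q) - 1)), numeric(1)))
  cf_series <- if (!is.null(clamp_cf)) rep(clamp_cf, length(times)) else {
    nbar <- Reduce(`+`, lapply(Qs, function(q) q %*% (0:nF)))
    pmax(c0 * (1 - (D / (s * nF)) * nbar), 0)[, 1]
  }

  structure(
    list(
      times = times,
      species = lapply(seq_len(s), function(k) {
        list(
          Q = Qs[[k]],
          p12 = Qs[[k]][, nF + 1],
          nodes = if (is.null(nodes)) NULL else nodes[[k]],
          mld = if (length(networks[[k]]$tree))
            mld(networks[[k]]$tree, networks[[k]]$poly) else NA_integer_,
          np = if (length(networks[[k]]$tree))
            wrapping_number(networks[[k]]$tree, networks[[k]]$poly)
          else NA_integer_
        )
      }),
      c_f = cf_series, c0 = c0, D = D, lambda = lambda,
      granularity = granularity, clamp_cf = clamp_cf,
      networks = networks, max_mass_err = mass_err
    ),
    class = "capsid_trajectory"
  )
}

#' @export
print.capsid_trajectory <- function(x, ...) {
  cat(sprintf(
    "capsid_trajectory: %d species, t in [0, %.3g], %s granularity\n",
    length(x$species), max(x$times), x$granularity
  ))
  for (k in seq_along(x$species)) {
    sp <- x$species[[k]]
    cat(sprintf("  species %d (MLD=%d, Np=%d): final packaged fraction %.4f\n",
                k, sp$mld, sp$np, sp$p12[length(sp$p12)]))
  }
  invisible(x)
}

#' Packaged fraction series
#'
#' @param traj A \code{capsid_trajectory}.
#' @param species Species index.
#' @return Numeric vector P_F(t) (probability of the complete capsid).
#' @export
packaged_fraction <- function(traj, species = 1L) {
  traj$species[[species]]$p12
}

#' Single-species packaging run
#'
#' Convenience wrapper: build nothing, just integrate one species'
#' master equation with mass conservation (D/F rule).
#'
#' @inheritParams integrate_master
#' @param network An \code{\link{assembly_network}}.
#' @param ... Passed to \code{\link{integrate_master}}.
#' @export
simulate_packaging <- function(network, c0 = 1, D = 0.5, t_end = 1e4, ...) {
  integrate_master(list(network), c0 = c0, D = D, t_end = t_end, ...)
}

#' Two-species packaging competition
#'
#' Both RNA species are present at equal concentrations and compete for the
#' same free-pentamer pool (D/(2F) rule in the mass-conservation relation).
#'
#' @inheritParams simulate_packaging
#' @param network1,network2 Assembly networks of the two competing species;
#'   species 1 is conventionally the low-MLD/high-Np (encoded) class.
#' @export
compete_packaging <- function(network1, network2, c0 = 1, D = 0.5,
                              t_end = 1e7, ...) {
  integrate_master(list(network1, network2), c0 = c0, D = D, t_end = t_end, ...)
}

#' Stochastic (Gillespie) simulation of a single RNA molecule
#'
#' Continuous-time Markov chain on the assembly network at clamped free
#' pentamer concentration, using exactly the on/off rates of the master
#' equation.  Averaged over replicates this provides an independent
#' stochastic cross-check of the node-resolved ODE solution.
#'
#' @param network An \code{\link{assembly_network}}.
#' @param c_f Clamped free pentamer concentration.
#' @param times Output times at which occupancy is recorded.
#' @param n_rep Number of independent replicate molecules.
#' @param lambda Base rate.
#' @return Matrix (length(times) x total nodes) of occupation frequencies.
#' @export
gillespie_packaging <- function(network, c_f, times, n_rep = 500, lambda = 1) {
  nF <- network$poly$F
  r <- .species_rates(network, c_f, lambda)
  sizes <- network$m
  offs <- cumsum(c(0, sizes))
  total <- sum(sizes)
  # flat transition table: for node id, lists of target ids and rates
  targets <- vector("list", total)
  rates <- vector("list", total)
  for (n in 0:nF) {
    for (i in seq_len(sizes[n + 1])) {
      id <- offs[n + 1] + i
      tg <- integer(0); rt <- numeric(0)
      if (n < nF) {
        js <- which(network$A[[n + 1]][i, ] == 1L)
        tg <- c(tg, offs[n + 2] + js)
        rt <- c(rt, rep(r$on[n + 1], length(js)))
      }
      if (n > 0) {
        js <- which(network$A[[n]][, i] == 1L)
        tg <- c(tg, offs[n] + js)
        rt <- c(rt, rep(r$off[n], length(js)))
      }
      targets[[id]] <- tg
      rates[[id]] <- rt
    }
  }
  counts <- matrix(0, length(times), total)
  t_max <- max(times)
  for (rep in seq_len(n_rep)) {
    state <- 1L
    t_now <- 0
    ptr <- 1L
    while (t_now <= t_max) {
      tot <- sum(rates[[state]])
      t_next <- if (tot > 0) t_now + stats::rexp(1, tot) else Inf
      while (ptr <= length(times) && times[ptr] < t_next) {
        counts[ptr, state] <- counts[ptr, state] + 1
        ptr <- ptr + 1L
      }
      if (ptr > length(times) || !is.finite(t_next)) break
      state <- targets[[state]][
        sample.int(length(rates[[state]]), 1, prob = rates[[state]])]
      t_now <- t_next
    }
  }
  counts / n_rep
}
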