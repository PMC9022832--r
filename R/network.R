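# Minimum-energy assembly networks.
#
# For a given spanning tree the assembly intermediates considered by the
# kinetics are, per pentamer number n, the face occupations that achieve the
# minimum assembly energy dE_min(n) (exhaustively over all C(F,n) subsets).
# Physically identical intermediates -- related by a symmetry of the
# dodecahedron that maps the tree onto itself -- are merged into one node.
# Nodes at consecutive levels are adjacent when a single pentamer
# addition/removal interconverts them.

# Energies of all 2^F face subsets, vectorised over subset bitmasks.
.subset_energies <- function(tree, poly, params) {
  nF <- poly$F
  masks <- 0:(2^nF - 1)
  M <- matrix(FALSE, length(masks), nF)
  for (f in seq_len(nF)) M[, f] <- bitwAnd(masks, bitwShiftL(1L, f - 1L)) != 0L
  K <- M[, poly$edge_faces[, 1], drop = FALSE] +
    M[, poly$edge_faces[, 2], drop = FALSE] # subsets x edges
  t <- seq_len(poly$E) %in% tree
  n1 <- rowSums(K[, t, drop = FALSE] == 1L)
  n2 <- rowSums(K[, t, drop = FALSE] == 2L)
  n3 <- rowSums(K[, !t, drop = FALSE] == 2L)
  n <- rowSums(M)
  list(
    masks = masks,
    n = n,
    energy = n1 * params$eps1 + n2 * params$eps2 - n3 - params$mu0 * n
  )
}

#' Minimum-energy assembly profile
#'
#' For each pentamer number n = 0..F, the minimum assembly energy over all
#' n-face occupations (exact, by exhaustive search), together with the
#' activation barrier (the maximum of the profile) and the location of the
#' profile minimum.  Near assembly equilibrium the profile has the classic
#' nucleation-and-growth shape: uphill to a critical nucleus, then downhill
#' to the complete capsid.
#'
#' @param tree Integer vector of tree edge indices.
#' @param poly A \code{capsid_polyhedron}.
#' @param params An \code{\link{energy_params}} object.
#' @return List with class \code{energy_profile}: \code{e_min} (numeric,
#'   length F+1, E0 units, indexed by n = 0..F), \code{barrier},
#'   \code{barrier_n}, \code{argmin_n}.
#' @export
min_energy_profile <- function(tree, poly, params) {
  se <- .subset_energies(tree, poly, params)
  e_min <- vapply(0:poly$F, function(n) min(se$energy[se$n == n]), numeric(1))
  structure(
    list(
      e_min = e_min,
      barrier = max(e_min),
      barrier_n = which.max(e_min) - 1L,
      argmin_n = which.min(e_min) - 1L
    ),
    class = "energy_profile"
  )
}

#' @export
print.energy_profile <- function(x, ...) {
  cat("minimum-energy assembly profile (E0 units):\n")
  print(round(stats::setNames(x$e_min, 0:(length(x$e_min) - 1L)), 4))
  cat(sprintf(
    "barrier %.4g E0 at n=%d; minimum at n=%d\n",
    x$barrier, x$barrier_n, x$argmin_n
  ))
  invisible(x)
}

# Symmetry operations of the polyhedron that map the tree onto itself,
# returned as rows of poly$face_perm.
.tree_stabilizer <- function(tree, poly) {
  tree <- sort(as.integer(tree))
  keep <- vapply(seq_len(nrow(poly$edge_perm)), function(g) {
    identical(sort(poly$edge_perm[g, tree]), tree)
  }, logical(1))
  poly$face_perm[keep, , drop = FALSE]
}

.face_mask_apply <- function(mask, fperm) {
  img <- 0L
  m <- mask
  f <- 1L
  while (m != 0L) {
    if (bitwAnd(m, 1L) != 0L) img <- bitwOr(img, bitwShiftL(1L, fperm[f] - 1L))
    m <- bitwShiftR(m, 1L)
    f <- f + 1L
  }
  img
}

#' Build the assembly-intermediate network
#'
#' Determines, for every pentamer number n, all face occupations achieving
#' the level-minimum assembly energy; merges occupations related by a
#' tree-preserving symmetry of the polyhedron into single nodes (the
#' stabiliser of the tree, not the full group, since the tree breaks the
#' symmetry); and links nodes at consecutive levels that differ by one
#' pentamer.  The node counts m_n are the level multiplicities.  Nodes that
#' are dead ends (for example a nucleation site that no minimum-energy
#' two-pentamer state contains) are kept: they are physically meaningful
#' parking states that exchange with the level below.  The construction
#' fails with a diagnostic naming the level only if some level has no node
#' at all on a single-pentamer path from the empty state to the complete
#' capsid, since then assembly cannot proceed through minimum-energy
#' intermediates.
#'
#' @inheritParams min_energy_profile
#' @return Object of class \code{assembly_network}: per-level canonical
#'   config masks, orbits, multiplicities \code{m}, level energies
#'   \code{e_min}, adjacency matrices \code{A} (one per consecutive level
#'   pair) and link counts \code{L}.
#' @export
build_network <- function(tree, poly, params) {
  se <- .subset_energies(tree, poly, params)
  fperms <- .tree_stabilizer(tree, poly)
  nF <- poly$F
  tol <- 1e-9

  levels <- vector("list", nF + 1)
  e_min <- numeric(nF + 1)
  for (n in 0:nF) {
    sel <- se$n == n
    emin <- min(se$energy[sel])
    e_min[n + 1] <- emin
    cand <- se$masks[sel & abs(se$energy - emin) < tol]
    seen <- integer(0)
    configs <- integer(0)
    orbits <- list()
    for (mk in cand) {
      if (mk %in% seen) next
      orb <- unique(vapply(seq_len(nrow(fperms)), function(g) {
        .face_mask_apply(mk, fperms[g, ])
      }, integer(1)))
      seen <- c(seen, orb)
      configs <- c(configs, min(orb))
      orbits <- c(orbits, list(orb))
    }
    ord <- order(configs)
    levels[[n + 1]] <- list(
      n = n, configs = configs[ord], orbits = orbits[ord],
      m = length(configs), energy = emin
    )
  }

  A <- vector("list", nF)
  L <- integer(nF)
  for (n in 0:(nF - 1)) {
    lo <- levels[[n + 1]]; hi <- levels[[n + 2]]
    mat <- matrix(0L, lo$m, hi$m)
    for (i in seq_len(lo$m)) {
      rep_i <- lo$configs[i]
      for (j in seq_len(hi$m)) {
        if (any(bitwAnd(rep_i, hi$orbits[[j]]) == rep_i)) mat[i, j] <- 1L
      }
    }
    A[[n + 1]] <- mat
    L[n + 1] <- sum(mat)
  }

  net <- structure(
    list(
      poly = poly, tree = sort(as.integer(tree)), params = params,
      levels = levels, m = vapply(levels, `[[`, integer(1), "m"),
      e_min = e_min, A = A, L = L,
      barrier = max(e_min)
    ),
    class = "assembly_network"
  )
  net$on_path <- .check_network_connected(net)
  net
}

#' Number of distinct assembly pathways
#'
#' Counts the monotone (no back-step) paths from the empty state to the
#' complete capsid through the network adjacency.  The linear-chain class
#' has vastly more assembly pathways than the compact class, which is the
#' entropic origin of the loss of kinetic selectivity at small E0.
#'
#' @param network An \code{\link{assembly_network}}.
#' @return Path count (numeric; counts grow combinatorially).
#' @export
count_assembly_paths <- function(network) {
  v <- rep(1, network$m[1])
  for (A in network$A) v <- as.vector(t(A) %*% v)
  sum(v)
}

#' Reference competition classes
#'
#' Selects the benchmark pair of spanning-tree classes used throughout the
#' packaging-competition analyses: the encoded species is the compact
#' (MLD=9, Np=8) class, the competitor the linear-chain (MLD=19, Np=2)
#' class.  Buckets can hold several symmetry classes whose minimum-energy
#' profiles differ slightly, so the pair is pinned down by the physics of
#' the contest: the encoded class is the bucket member with the most
#' distinct five-pentamer nucleation intermediates (m_5 = 4), i.e. the
#' geometry best adapted to multi-route nucleation, and the competitor is
#' the bucket member with the highest activation barrier (5.0 E0 at
#' eps1 = -0.5, mu0 = -4), i.e. the least nucleation-adapted linear chain.
#' Both criteria select a unique class.
#'
#' @param lib A dodecahedral \code{tree_library}.
#' @param params Energy parameters used to rank the bucket members
#'   (defaults to eps1 = -0.5, mu0 = -4).
#' @return List with edge-index vectors \code{tree1} (encoded) and
#'   \code{tree2} (competitor).
#' @export
reference_competition_classes <- function(lib,
                                          params = energy_params(
                                            eps1 = -0.5, mu0 = -4)) {
  poly <- lib$poly
  b1 <- library_lookup(lib, 9, 8)
  if (nrow(b1) == 0) stop("library lacks an (MLD=9, Np=8) class")
  nets1 <- lapply(b1$mask, function(m)
    build_network(tree_edges(m, poly), poly, params))
  m5 <- vapply(nets1, function(nn) nn$m[6], integer(1))
  tree1 <- nets1[[which.max(m5)]]$tree
  b2 <- library_lookup(lib, 19, 2)
  if (nrow(b2) == 0) stop("library lacks an (MLD=19, Np=2) class")
  prof2 <- vapply(b2$mask, function(m)
    min_energy_profile(tree_edges(m, poly), poly, params)$barrier, numeric(1))
  tree2 <- tree_edges(b2$mask[which.max(prof2)], poly)
  list(tree1 = tree1, tree2 = tree2)
}

# Forward/backward reachability over the layered adjacency.  Errors only
# when an entire level is unreachable on the way from n=0 to n=F; otherwise
# returns the per-node on-path indicator for diagnostics.
.check_network_connected <- function(net) {
  nF <- net$poly$F
  fwd <- vector("list", nF + 1)
  fwd[[1]] <- rep(TRUE, net$m[1])
  for (n in seq_len(nF)) {
    fwd[[n + 1]] <- as.vector(t(net$A[[n]]) %*% fwd[[n]]) > 0
    if (!any(fwd[[n + 1]]))
      stop(sprintf("assembly network disconnected: no path into level n=%d", n))
  }
  bwd <- vector("list", nF + 1)
  bwd[[nF + 1]] <- rep(TRUE, net$m[nF + 1])
  for (n in rev(seq_len(nF))) {
    bwd[[n]] <- as.vector(net$A[[n]] %*% bwd[[n + 1]]) > 0
  }
  lapply(seq_len(nF + 1), function(l) fwd[[l]] & bwd[[l]])
}

#' @export
print.assembly_network <- function(x, ...) {
  cat(sprintf(
    "assembly_network on %s: tree MLD=%d Np=%d, %d nodes, barrier %.3g E0\n",
    x$poly$name, mld(x$tree, x$poly), wrapping_number(x$tree, x$poly),
    sum(x$m), x$barrier
  ))
  cat("multiplicities m_n:", x$m, "\n")
  invisible(x)
}

#' Boltzmann equilibrium distribution over network nodes
#'
#' Per-node equilibrium probability at free-pentamer concentration
#' \code{c_f}: P_eq(n) proportional to exp(-e0*dE(n) + n*log(c_f)),
#' normalised so that sum_n m_n P_eq(n) = 1 over n = 0..F (all nodes of a
#' level share one energy, hence one probability).  This is the stationary
#' distribution of the master-equation kinetics at clamped c_f.
#'
#' @param network An \code{\link{assembly_network}}.
#' @param c_f Free pentamer concentration (reference-concentration units).
#' @return List: \code{p_node} (per-node probability by level, length F+1),
#'   \code{p_level} = m_n * p_node.
#' @export
equilibrium_distribution <- function(network, c_f) {
  stopifnot(c_f > 0)
  n <- 0:network$poly$F
  logw <- -network$params$e0 * network$e_min + n * log(c_f)
  w <- exp(logw - max(logw))
  p <- w / sum(network$m * w)
  list(p_node = p, p_level = network$m * p)
}

#' Serialize / read an assembly network as JSON
#'
#' @param network An \code{\link{assembly_network}}.
#' @param path File path.
#' @export
write_network_json <- function(network, path) {
  obj <- list(
    polyhedron = network$poly$name,
    tree_edges = lapply(network$tree, function(e) network$poly$edges[e, ]),
    params = unclass(network$params),
    levels = lapply(network$levels, function(lv) {
      list(n = lv$n, m = lv$m, energy = lv$energy, configs = lv$configs)
    }),
    adjacency = network$A
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
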