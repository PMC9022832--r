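#' @useDynLib capsidselect, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Rotation matrix about the unit vector `axis` by `theta` radians (Rodrigues).
.rotation_matrix <- function(axis, theta) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# Map an orthogonal matrix to a vertex permutation of `coords` (rows).
.matrix_to_perm <- function(mat, coords, tol = 1e-6) {
  img <- coords %*% t(mat)
  perm <- integer(nrow(coords))
  for (i in seq_len(nrow(coords))) {
    d <- colSums((t(coords) - img[i, ])^2)
    j <- which.min(d)
    if (d[j] > tol) stop("matrix is not a symmetry of the vertex set")
    perm[i] <- j
  }
  if (anyDuplicated(perm)) stop("matrix does not permute the vertices")
  perm
}

# Close a set of vertex permutations under composition.
.close_group <- function(generators, nv) {
  id <- seq_len(nv)
  elems <- list(id)
  keys <- new.env(parent = emptyenv())
  assign(paste(id, collapse = ","), TRUE, envir = keys)
  frontier <- generators
  for (g in generators) {
    k <- paste(g, collapse = ",")
    if (!exists(k, envir = keys)) {
      assign(k, TRUE, envir = keys)
      elems <- c(elems, list(g))
    }
  }
  frontier <- elems
  while (length(frontier) > 0) {
    new_front <- list()
    for (f in frontier) {
      for (g in generators) {
        h <- g[f] # apply f, then g
        k <- paste(h, collapse = ",")
        if (!exists(k, envir = keys)) {
          assign(k, TRUE, envir = keys)
          elems <- c(elems, list(h))
          new_front <- c(new_front, list(h))
        }
      }
    }
    frontier <- new_front
  }
  elems
}

# Order face vertices as a cycle around the face normal, then put the cycle
# into minimal-rotation form (smallest vertex first, smaller neighbour second).
.order_face <- function(vids, coords, normal) {
  n <- normal / sqrt(sum(normal^2))
  centre <- colMeans(coords[vids, , drop = FALSE])
  a <- coords[vids[1], ] - centre
  a <- a - sum(a * n) * n
  a <- a / sqrt(sum(a^2))
  b <- c(
    n[2] * a[3] - n[3] * a[2],
    n[3] * a[1] - n[1] * a[3],
    n[1] * a[2] - n[2] * a[1]
  )
  rel <- sweep(coords[vids, , drop = FALSE], 2, centre)
  ang <- atan2(rel %*% b, rel %*% a)
  cyc <- vids[order(ang)]
  .canonical_cycle(cyc)
}

.canonical_cycle <- function(cyc) {
  k <- length(cyc)
  i <- which.min(cyc)
  fwd <- cyc[((seq_len(k) + i - 2) %% k) + 1]
  rev_cyc <- rev(cyc)
  i <- which.min(rev_cyc)
  bwd <- rev_cyc[((seq_len(k) + i - 2) %% k) + 1]
  if (fwd[2] <= bwd[2]) fwd else bwd
}

# Assemble a polyhedron object from vertex coordinates, symmetry generator
# matrices, and outward face normals.
.make_polyhedron <- function(name, coords, gen_mats, face_normals, face_size) {
  V <- nrow(coords)
  d2 <- as.matrix(dist(coords))^2
  emin <- min(d2[d2 > 1e-9])
  pairs <- which(abs(d2 - emin) < 1e-6 & upper.tri(d2), arr.ind = TRUE)
  edges <- cbind(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  dimnames(edges) <- NULL
  E <- nrow(edges)

  faces <- lapply(seq_len(nrow(face_normals)), function(f) {
    nrm <- face_normals[f, ]
    dots <- coords %*% nrm
    vids <- order(dots, decreasing = TRUE)[seq_len(face_size)]
    .order_face(sort(vids), coords, nrm)
  })
  Fn <- length(faces)

  edge_index <- matrix(0L, V, V)
  for (e in seq_len(E)) {
    edge_index[edges[e, 1], edges[e, 2]] <- e
    edge_index[edges[e, 2], edges[e, 1]] <- e
  }
  face_edges <- lapply(faces, function(cyc) {
    k <- length(cyc)
    idx <- integer(k)
    for (j in seq_len(k)) {
      u <- cyc[j]; v <- cyc[if (j == k) 1 else j + 1]
      e <- edge_index[u, v]
      if (e == 0L) stop("face cycle uses a non-edge; face construction failed")
      idx[j] <- e
    }
    sort(idx)
  })
  edge_faces <- matrix(0L, E, 2)
  for (f in seq_len(Fn)) {
    for (e in face_edges[[f]]) {
      slot <- if (edge_faces[e, 1] == 0L) 1L else 2L
      if (slot == 2L && edge_faces[e, 2] != 0L)
        stop("edge borders more than two faces")
      edge_faces[e, slot] <- f
    }
  }
  if (any(edge_faces == 0L)) stop("some edge does not border two faces")

  gens <- lapply(gen_mats, .matrix_to_perm, coords = coords)
  group <- .close_group(gens, V)
  G <- length(group)

  edge_perm <- matrix(0L, G, E)
  face_perm <- matrix(0L, G, Fn)
  face_key <- vapply(faces, function(f) paste(sort(f), collapse = ","), "")
  for (g in seq_len(G)) {
    p <- group[[g]]
    for (e in seq_len(E)) {
      ie <- edge_index[p[edges[e, 1]], p[edges[e, 2]]]
      if (ie == 0L) stop("group element does not map edges to edges")
      edge_perm[g, e] <- ie
    }
    for (f in seq_len(Fn)) {
      key <- paste(sort(p[faces[[f]]]), collapse = ",")
      jf <- match(key, face_key)
      if (is.na(jf)) stop("group element does not map faces to faces")
      face_perm[g, f] <- jf
    }
  }

  structure(
    list(
      name = name, V = V, E = E, F = Fn,
      coords = coords, edges = edges, faces = faces,
      face_edges = face_edges, edge_faces = edge_faces,
      group = group, edge_perm = edge_perm, face_perm = face_perm
    ),
    class = "capsid_polyhedron"
  )
}

#' Dodecahedral capsid scaffold
#'
#' Builds the pentagonal dodecahedron on which the assembly model lives: 20
#' vertices, 30 edges, 12 pentagonal faces, each face the site of one capsid
#' pentamer.  The folded psi sequence of packaging signals is modelled as a
#' spanning tree of this graph, its 19 links lying along dodecahedron edges.
#' The full symmetry group (120 rotations and reflections) is generated from
#' two five-fold face rotations and the central inversion and closed under
#' composition.
#'
#' Vertices are labelled 1..20 in the order of the standard golden-ratio
#' coordinates: the eight cube points (+-1, +-1, +-1) followed by the three
#' rectangle families (0, +-1/phi, +-phi), (+-1/phi, +-phi, 0),
#' (+-phi, 0, +-1/phi), each family ordered lexicographically.  All canonical
#' forms produced by the package refer to this labelling.
#'
#' @return An object of class \code{capsid_polyhedron}: a list with vertex
#'   count \code{V}, edge matrix \code{edges} (rows are sorted vertex pairs in
#'   lexicographic order), face vertex cycles \code{faces}, per-face edge
#'   indices \code{face_edges}, the edge-to-face incidence \code{edge_faces},
#'   the symmetry group as vertex permutations \code{group}, and the induced
#'   edge and face permutation tables \code{edge_perm}, \code{face_perm}.
#' @examples
#' dod <- build_dodecahedron()
#' dod$V; dod$E; dod$F; length(dod$group)
#' @export
build_dodecahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  s <- c(-1, 1)
  cube <- as.matrix(expand.grid(x = s, y = s, z = s))[, 3:1]
  cube <- cube[order(cube[, 1], cube[, 2], cube[, 3]), ]
  fam1 <- as.matrix(expand.grid(a = s / phi, b = s * phi))
  fam1 <- cbind(0, fam1)[order(fam1[, 1], fam1[, 2]), ]
  fam2 <- cbind(s[c(1, 1, 2, 2)] / phi,
                c(-phi, phi, -phi, phi), 0)
  fam2 <- fam2[order(fam2[, 1], fam2[, 2]), ]
  fam3 <- cbind(c(-phi, -phi, phi, phi), 0, c(-1, 1, -1, 1) / phi)
  coords <- rbind(cube, fam1, fam2, fam3)
  dimnames(coords) <- NULL

  # face normals point at the vertices of the dual icosahedron
  fn <- rbind(
    cbind(0, c(-phi, -phi, phi, phi), c(-1, 1, -1, 1)),
    cbind(c(-1, -1, 1, 1), 0, c(-phi, phi, -phi, phi)),
    cbind(c(-phi, -phi, phi, phi), c(-1, 1, -1, 1), 0)
  )
  gens <- list(
    .rotation_matrix(c(0, phi, 1), 2 * pi / 5),
    .rotation_matrix(c(1, 0, phi), 2 * pi / 5),
    -diag(3)
  )
  poly <- .make_polyhedron("dodecahedron", coords, gens, fn, 5L)
  stopifnot(poly$V == 20L, poly$E == 30L, poly$F == 12L,
            length(poly$group) == 120L)
  poly
}

#' Small polyhedral fixtures
#'
#' Builds a tetrahedron or cube scaffold with the same structure as
#' \code{\link{build_dodecahedron}}.  These small graphs admit exhaustive
#' cross-checks (full spanning-tree and orbit enumeration by brute force) and
#' are used throughout the test suite as oracles for the dodecahedral
#' machinery.
#'
#' @param name \code{"tetrahedron"} (V=4, E=6, F=4, group order 24) or
#'   \code{"cube"} (V=8, E=12, F=6, group order 48).
#' @return A \code{capsid_polyhedron} object.
#' @examples
#' cube <- build_fixture("cube")
#' cube$E # 12
#' @export
build_fixture <- function(name = c("tetrahedron", "cube")) {
  name <- match.arg(name)
  if (name == "tetrahedron") {
    coords <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
    fn <- -coords # face opposite each vertex
    mirror <- matrix(c(0, 1, 0, 1, 0, 0, 0, 0, 1), 3, 3)
    gens <- list(
      .rotation_matrix(c(1, 1, 1), 2 * pi / 3),
      .rotation_matrix(c(1, -1, -1), 2 * pi / 3),
      mirror
    )
    poly <- .make_polyhedron(name, coords, gens, fn, 3L)
    stopifnot(poly$V == 4L, poly$E == 6L, poly$F == 4L,
              length(poly$group) == 24L)
  } else {
    s <- c(-1, 1)
    coords <- as.matrix(expand.grid(x = s, y = s, z = s))[, 3:1]
    coords <- coords[order(coords[, 1], coords[, 2], coords[, 3]), ]
    dimnames(coords) <- NULL
    fn <- rbind(diag(3), -diag(3))
    gens <- list(
      .rotation_matrix(c(0, 0, 1), pi / 2),
      .rotation_matrix(c(1, 0, 0), pi / 2),
      -diag(3)
    )
    poly <- .make_polyhedron(name, coords, gens, fn, 4L)
    stopifnot(poly$V == 8L, poly$E == 12L, poly$F == 6L,
              length(poly$group) == 48L)
  }
  poly
}

#' @export
print.capsid_polyhedron <- function(x, ...) {
  cat(sprintf(
    "capsid_polyhedron: %s (V=%d, E=%d, F=%d, |G|=%d)\n",
    x$name, x$V, x$E, x$F, length(x$group)
  ))
  invisible(x)
}

#' Edge indices of vertex pairs (and back)
#'
#' Edge subsets are handled internally as sorted vectors of edge indices into
#' \code{poly$edges}; these helpers convert between that representation and
#' explicit vertex-pair matrices.
#'
#' @param poly A \code{capsid_polyhedron}.
#' @param pairs Two-column matrix of vertex pairs.
#' @param idx Integer vector of edge indices.
#' @return \code{edge_indices}: sorted integer vector; \code{edge_pairs}: a
#'   two-column matrix of sorted vertex pairs.
#' @export
edge_indices <- function(poly, pairs) {
  pairs <- cbind(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
  key <- paste(poly$edges[, 1], poly$edges[, 2])
  idx <- match(paste(pairs[, 1], pairs[, 2]), key)
  if (anyNA(idx)) stop("some pairs are not edges of the polyhedron")
  sort(idx)
}

#' @rdname edge_indices
#' @export
edge_pairs <- function(poly, idx) {
  if (any(idx < 1L | idx > poly$E)) stop("edge index out of range")
  poly$edges[idx, , drop = FALSE]
}

#' Canonical form of an edge subset under the symmetry group
#'
#' Returns the lexicographically minimal image of the subset over all
#' symmetry-group elements, the comparison being over the sorted edge-index
#' list (equivalently, the sorted list of sorted vertex pairs, since edges are
#' indexed lexicographically).  Two subsets have the same canonical form
#' exactly when one can be rotated/reflected into the other, so canonical
#' forms serve as orbit labels when winnowing spanning trees and assembly
#' configurations.
#'
#' @param edge_subset Integer vector of edge indices.
#' @param poly A \code{capsid_polyhedron}.
#' @return Sorted integer vector of edge indices; idempotent under repetition.
#' @export
canonical_form <- function(edge_subset, poly) {
  edge_subset <- as.integer(edge_subset)
  if (any(edge_subset < 1L | edge_subset > poly$E))
    stop("edge index out of range for this polyhedron")
  best <- NULL
  for (g in seq_len(nrow(poly$edge_perm))) {
    img <- sort(poly$edge_perm[g, edge_subset])
    if (is.null(best) || .lex_less(img, best)) best <- img
  }
  best
}

# strict lexicographic comparison of equal-length sorted integer vectors
.lex_less <- function(a, b) {
  d <- which(a != b)
  length(d) > 0 && a[d[1]] < b[d[1]]
}

#' Orbit of an edge subset
#'
#' All distinct images of an edge subset under the symmetry group.  Orbit
#' sizes always divide the group order (orbit-stabiliser theorem), which the
#' test suite uses as a structural check.
#'
#' @inheritParams canonical_form
#' @return List of sorted integer vectors, one per distinct image.
#' @export
edge_orbit <- function(edge_subset, poly) {
  imgs <- lapply(seq_len(nrow(poly$edge_perm)), function(g) {
    sort(poly$edge_perm[g, as.integer(edge_subset)])
  })
  unique(imgs)
}

#' Serialize a polyhedron to JSON
#'
#' Writes \code{\{"vertices": [...], "edges": [[u,v],...], "faces":
#' [[...],...]\}} with 1-based vertex labels.
#'
#' @param poly A \code{capsid_polyhedron}.
#' @param path Output file path.
#' @export
write_polyhedron_json <- function(poly, path) {
  obj <- list(
    name = poly$name,
    vertices = seq_len(poly$V),
    edges = lapply(seq_len(poly$E), function(e) poly$edges[e, ]),
    faces = poly$faces
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  invisible(path)
}
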