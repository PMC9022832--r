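# Spanning-tree enumeration and classification.
#
# A folded psi sequence is modelled as a spanning tree of the capsid
# scaffold: V-1 links joining all V vertices.  Trees are stored compactly as
# edge bitmasks (bit e-1 set when edge e of poly$edges is a link), and
# symmetry-inequivalent classes carry the two indices used to organise the
# library: the maximum ladder distance (MLD, the tree diameter in links) and
# the wrapping number (number of faces whose boundary holds the maximum
# possible number of tree links, one less than the face size).

.capsid_cache <- new.env(parent = emptyenv())

.tree_mask <- function(idx) {
  m <- 0L
  for (e in idx) m <- bitwOr(m, bitwShiftL(1L, e - 1L))
  m
}

.mask_edges <- function(mask, E) {
  which(bitwAnd(mask, bitwShiftL(1L, seq_len(E) - 1L)) != 0L)
}

#' Enumerate all labelled spanning trees
#'
#' Exhaustively enumerates every spanning tree of the polyhedron graph by a
#' branch-and-bound over edges (include an edge unless it closes a cycle;
#' exclude it only when the remaining graph still connects all vertices), so
#' each tree is produced exactly once.  The total is checked against the
#' matrix-tree determinant in the test suite.
#'
#' @param poly A \code{capsid_polyhedron}.
#' @return Integer vector of edge bitmasks, one per labelled spanning tree.
#'   Use \code{\link{tree_edges}} to recover edge indices.
#' @examples
#' length(enumerate_spanning_trees(build_fixture("tetrahedron"))) # 16
#' @export
enumerate_spanning_trees <- function(poly) {
  cpp_enumerate_spanning_trees(poly$edges - 1L, poly$V)
}

#' @rdname enumerate_spanning_trees
#' @param mask Edge bitmask of a tree (element of the enumeration output).
#' @export
tree_edges <- function(mask, poly) {
  .mask_edges(mask, poly$E)
}

#' Spanning-tree count by the matrix-tree theorem
#'
#' Kirchhoff determinant of a cofactor of the graph Laplacian; the
#' independent closed-form count against which exhaustive enumeration is
#' validated.
#'
#' @param poly A \code{capsid_polyhedron}.
#' @return Number of labelled spanning trees.
#' @export
count_spanning_trees <- function(poly) {
  L <- matrix(0, poly$V, poly$V)
  for (e in seq_len(poly$E)) {
    u <- poly$edges[e, 1]; v <- poly$edges[e, 2]
    L[u, v] <- L[u, v] - 1
    L[v, u] <- L[v, u] - 1
    L[u, u] <- L[u, u] + 1
    L[v, v] <- L[v, v] + 1
  }
  round(det(L[-1, -1, drop = FALSE]))
}

#' Maximum ladder distance (MLD) of a tree
#'
#' The tree diameter in links: the largest ladder distance between any two
#' nodes of the secondary-structure tree.  A Hamiltonian path attains the
#' maximum, V-1 (19 on the dodecahedron); compact branched psi structures
#' reach values as low as 9.
#'
#' @param tree Integer vector of edge indices (use \code{\link{tree_edges}}
#'   to convert an enumeration bitmask).
#' @param poly A \code{capsid_polyhedron}.
#' @return Integer diameter in links.
#' @export
mld <- function(tree, poly) {
  idx <- as.integer(tree)
  adj <- vector("list", poly$V)
  for (e in idx) {
    u <- poly$edges[e, 1]; v <- poly$edges[e, 2]
    adj[[u]] <- c(adj[[u]], v)
    adj[[v]] <- c(adj[[v]], u)
  }
  verts <- sort(unique(as.vector(poly$edges[idx, , drop = FALSE])))
  diam <- 0L
  for (s in verts) {
    dist <- rep(-1L, poly$V)
    dist[s] <- 0L
    queue <- s
    while (length(queue) > 0) {
      u <- queue[1]; queue <- queue[-1]
      for (w in adj[[u]]) if (dist[w] < 0L) {
        dist[w] <- dist[u] + 1L
        queue <- c(queue, w)
      }
    }
    diam <- max(diam, max(dist))
  }
  diam
}

#' Wrapping number of a tree
#'
#' Number of faces whose boundary carries the maximum possible number of tree
#' links (one less than the face size; four on a pentagonal face, since all
#' five would close a cycle).  Each such face is a maximum-wrapping pentamer
#' site where a pentamer gains the full specific packaging-signal affinity.
#'
#' @inheritParams mld
#' @return Integer wrapping number.
#' @export
wrapping_number <- function(tree, poly) {
  idx <- as.integer(tree)
  sum(vapply(poly$face_edges, function(fe) {
    sum(fe %in% idx) == length(fe) - 1L
  }, logical(1)))
}

#' Winnow labelled trees into symmetry classes
#'
#' Partitions labelled spanning trees into orbits of the polyhedron's
#' symmetry group: each tree is mapped to the lexicographically minimal image
#' of its edge set over the group, and one representative is kept per orbit.
#' Orbit sizes sum back to the labelled count, and MLD and wrapping number
#' are orbit invariants.
#'
#' @param trees Integer vector of tree edge bitmasks
#'   (from \code{\link{enumerate_spanning_trees}}).
#' @param poly A \code{capsid_polyhedron}.
#' @return A data.frame with one row per class: \code{mask} (canonical
#'   representative), \code{orbit_size}, \code{mld}, \code{np},
#'   \code{hamiltonian} (\code{mld == V-1}), sorted by (mld, np, mask).
#' @export
dedupe_by_symmetry <- function(trees, poly) {
  df <- cpp_classify_trees(
    trees, poly$edge_perm - 1L, poly$edges - 1L, poly$V,
    lapply(poly$face_edges, function(x) x - 1L)
  )
  df$hamiltonian <- df$mld == poly$V - 1L
  df <- df[order(df$mld, df$np, df$mask), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Count Hamiltonian paths
#'
#' Number of distinct edge subsets forming a simple path through all
#' vertices, by exhaustive depth-first search (each undirected path is found
#' from both ends and counted once).  These are the linear-chain psi
#' configurations; the dodecahedron has 1620 of them.
#'
#' @param poly A \code{capsid_polyhedron}.
#' @return Integer count.
#' @export
count_hamiltonian_paths <- function(poly) {
  cpp_count_hamiltonian_paths(poly$edges - 1L, poly$V)
}

#' Symmetry-class count by Burnside's lemma
#'
#' Independent recount of the number of spanning-tree classes:
#' (1/|G|) times the sum over group elements of the number of labelled trees
#' fixed by that element.  The identity contribution is the matrix-tree
#' count; for every other element the fixed trees are found by exhaustive
#' search over unions of that element's edge orbits.
#'
#' @param poly A \code{capsid_polyhedron}.
#' @return Number of symmetry-inequivalent spanning trees.
#' @export
count_tree_classes_burnside <- function(poly) {
  total <- count_spanning_trees(poly)
  id <- seq_len(poly$E)
  fixed <- vapply(seq_len(nrow(poly$edge_perm)), function(g) {
    ep <- poly$edge_perm[g, ]
    if (all(ep == id)) return(total)
    cpp_count_fixed_trees(ep - 1L, poly$edges - 1L, poly$V)
  }, numeric(1))
  s <- sum(fixed)
  stopifnot(s %% nrow(poly$edge_perm) == 0)
  s / nrow(poly$edge_perm)
}

#' Build the spanning-tree class library
#'
#' Enumerates all labelled spanning trees, winnows them into symmetry
#' classes, and indexes the classes by (MLD, wrapping number).  For the
#' dodecahedron this is the library of all distinct psi-sequence folding
#' geometries (tens of thousands of classes); the two classes driving the
#' packaging-competition analyses are (MLD=9, Np=8), the maximally compact
#' branched structure, and (MLD=19, Np=2), the least adapted linear chain.
#'
#' Results are cached per polyhedron name within the session.
#'
#' @param poly A \code{capsid_polyhedron}.
#' @param cache Reuse a previously built library for the same polyhedron.
#' @return An object of class \code{tree_library}: the class data.frame plus
#'   the polyhedron and labelled-tree total.
#' @export
build_library <- function(poly, cache = TRUE) {
  key <- paste0("library_", poly$name)
  if (cache && !is.null(.capsid_cache[[key]])) return(.capsid_cache[[key]])
  trees <- enumerate_spanning_trees(poly)
  classes <- dedupe_by_symmetry(trees, poly)
  lib <- structure(
    list(classes = classes, poly = poly, n_labelled = length(trees)),
    class = "tree_library"
  )
  if (cache) .capsid_cache[[key]] <- lib
  lib
}

#' @export
print.tree_library <- function(x, ...) {
  cat(sprintf(
    "tree_library: %s, %d labelled trees, %d symmetry classes\n",
    x$poly$name, x$n_labelled, nrow(x$classes)
  ))
  invisible(x)
}

#' Look up tree classes by (MLD, wrapping number)
#'
#' @param lib A \code{tree_library}.
#' @param mld,np The requested class indices.
#' @return The matching rows of the class table (zero rows if the bucket is
#'   empty; absence is reported, not an error).
#' @export
library_lookup <- function(lib, mld, np) {
  lib$classes[lib$classes$mld == mld & lib$classes$np == np, , drop = FALSE]
}

#' Representative tree of a class
#'
#' Selects the canonical-form-minimal representative of an (MLD, Np) bucket
#' (or the class with an explicit \code{mask}) and returns its edge indices.
#'
#' @inheritParams library_lookup
#' @param mask Optional explicit class representative bitmask.
#' @return Integer vector of edge indices of the representative tree.
#' @export
select_tree_class <- function(lib, mld, np, mask = NULL) {
  rows <- library_lookup(lib, mld, np)
  if (nrow(rows) == 0)
    stop(sprintf("no spanning-tree class with MLD=%d, Np=%d", mld, np))
  if (!is.null(mask)) {
    rows <- rows[rows$mask == mask, , drop = FALSE]
    if (nrow(rows) == 0) stop("requested class mask not found in bucket")
  }
  m <- rows$mask[1]
  for (k in seq_len(nrow(rows))[-1]) {
    a <- .mask_edges(rows$mask[k], lib$poly$E)
    if (.lex_less(a, .mask_edges(m, lib$poly$E))) m <- rows$mask[k]
  }
  .mask_edges(m, lib$poly$E)
}

#' Write / read a tree-class library as JSON lines
#'
#' One record per class: \code{\{"edges": [[u,v],...], "mld":, "np":,
#' "orbit_size":, "hamiltonian":\}}.
#'
#' @param lib A \code{tree_library}.
#' @param path File path.
#' @export
write_tree_library <- function(lib, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(lib$classes))) {
    idx <- .mask_edges(lib$classes$mask[i], lib$poly$E)
    rec <- list(
      edges = lapply(idx, function(e) lib$poly$edges[e, ]),
      mld = lib$classes$mld[i],
      np = lib$classes$np[i],
      orbit_size = lib$classes$orbit_size[i],
      hamiltonian = lib$classes$hamiltonian[i]
    )
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' @rdname write_tree_library
#' @param poly The polyhedron the library refers to.
#' @export
read_tree_library <- function(path, poly) {
  lines <- readLines(path)
  recs <- lapply(lines, jsonlite::fromJSON)
  classes <- data.frame(
    mask = vapply(recs, function(r) {
      m <- if (is.matrix(r$edges)) r$edges else
        matrix(unlist(r$edges), ncol = 2, byrow = TRUE)
      .tree_mask(edge_indices(poly, m))
    }, integer(1)),
    orbit_size = vapply(recs, function(r) as.integer(r$orbit_size), integer(1)),
    mld = vapply(recs, function(r) as.integer(r$mld), integer(1)),
    np = vapply(recs, function(r) as.integer(r$np), integer(1)),
    hamiltonian = vapply(recs, function(r) isTRUE(r$hamiltonian), logical(1))
  )
  structure(
    list(classes = classes, poly = poly,
         n_labelled = sum(classes$orbit_size)),
    class = "tree_library"
  )
}
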