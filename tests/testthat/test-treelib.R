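test_that("exhaustive enumeration matches the matrix-tree determinant", {
  expect_identical(length(enumerate_spanning_trees(tet)), 16L) # Cayley 4^2
  expect_identical(length(enumerate_spanning_trees(tet)),
                   as.integer(count_spanning_trees(tet)))
  expect_identical(length(enumerate_spanning_trees(cube)),
                   as.integer(count_spanning_trees(cube)))
  lib <- dod_lib()
  expect_identical(lib$n_labelled, as.integer(count_spanning_trees(dod)))
  # every enumerated edge set is a spanning tree: acyclic, spanning, V-1 edges
  set.seed(3)
  trees <- enumerate_spanning_trees(cube)
  for (m in sample(trees, 25)) {
    idx <- tree_edges(m, cube)
    expect_length(idx, cube$V - 1L)
    expect_identical(mld(idx, cube) >= 1L, TRUE)
    verts <- unique(as.vector(cube$edges[idx, ]))
    expect_length(verts, cube$V)
  }
})

test_that("symmetry winnowing produces one class per orbit", {
  trees <- enumerate_spanning_trees(tet)
  cl <- dedupe_by_symmetry(trees, tet)
  # K4: independent brute-force orbit partition via the stored vertex perms
  canon <- vapply(trees, function(m) {
    idx <- tree_edges(m, tet)
    pairs <- tet$edges[idx, , drop = FALSE]
    imgs <- vapply(tet$group, function(g) {
      mapped <- cbind(g[pairs[, 1]], g[pairs[, 2]])
      mapped <- cbind(pmin(mapped[, 1], mapped[, 2]),
                      pmax(mapped[, 1], mapped[, 2]))
      paste(sort(paste(mapped[, 1], mapped[, 2])), collapse = ";")
    }, "")
    min(imgs)
  }, "")
  expect_identical(nrow(cl), length(unique(canon))) # 2: paths and stars
  expect_identical(nrow(cl), 2L)
  expect_identical(sum(cl$orbit_size), length(trees))
  # applying a group element to a representative does not change its class
  for (i in seq_len(nrow(cl))) {
    idx <- tree_edges(cl$mask[i], tet)
    img <- sort(tet$edge_perm[5, idx])
    expect_identical(canonical_form(img, tet), canonical_form(idx, tet))
  }
  # cube: orbit sizes partition the labelled count
  ccl <- dedupe_by_symmetry(enumerate_spanning_trees(cube), cube)
  expect_identical(sum(ccl$orbit_size), as.integer(count_spanning_trees(cube)))
})

test_that("class counts match an independent Burnside recount", {
  for (p in list(tet, cube)) {
    cl <- dedupe_by_symmetry(enumerate_spanning_trees(p), p)
    expect_equal(count_tree_classes_burnside(p), nrow(cl))
  }
})

test_that("MLD is the tree diameter and an orbit invariant", {
  # single link
  expect_identical(mld(1L, dod), 1L)
  lib <- dod_lib()
  ham <- lib$classes[lib$classes$hamiltonian, ]
  expect_identical(mld(tree_edges(ham$mask[1], dod), dod), 19L)
  # independent diameter oracle via igraph on sampled classes
  skip_if_not_installed("igraph")
  set.seed(11)
  for (m in sample(lib$classes$mask, 20)) {
    idx <- tree_edges(m, dod)
    g <- igraph::graph_from_edgelist(dod$edges[idx, , drop = FALSE],
                                     directed = FALSE)
    expect_identical(mld(idx, dod), as.integer(igraph::diameter(g)))
  }
  # invariance along orbits
  for (m in sample(lib$classes$mask, 5)) {
    idx <- tree_edges(m, dod)
    ref_mld <- mld(idx, dod); ref_np <- wrapping_number(idx, dod)
    for (g in sample(120, 6)) {
      img <- sort(dod$edge_perm[g, idx])
      expect_identical(mld(img, dod), ref_mld)
      expect_identical(wrapping_number(img, dod), ref_np)
    }
  }
})

test_that("wrapping numbers: Hamiltonian paths carry 2-4 wrapped faces, never five links on one face", {
  lib <- dod_lib()
  ham <- lib$classes[lib$classes$hamiltonian, ]
  expect_true(all(ham$np %in% 2:4))
  expect_setequal(unique(ham$np), 2:4)
  set.seed(5)
  for (m in sample(lib$classes$mask, 30)) {
    idx <- tree_edges(m, dod)
    per_face <- vapply(dod$face_edges, function(fe) sum(fe %in% idx),
                       integer(1))
    expect_true(all(per_face <= 4L)) # 5 would close a pentagon, impossible in a tree
  }
})

test_that("Hamiltonian path counts agree with independent oracles", {
  # K4: adjacency-consistent vertex orderings, each undirected path twice
  perms <- as.matrix(expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4))
  perms <- perms[apply(perms, 1, function(x) length(unique(x)) == 4L), ]
  ekey <- paste(tet$edges[, 1], tet$edges[, 2])
  ok <- apply(perms, 1, function(x) {
    all(paste(pmin(x[-4], x[-1]), pmax(x[-4], x[-1])) %in% ekey)
  })
  expect_identical(count_hamiltonian_paths(tet), sum(ok) / 2)
  # C4 cycle (degenerate fixture): dropping any one edge leaves one path
  c4 <- list(edges = cbind(c(1, 2, 3, 1), c(2, 3, 4, 4)), V = 4L)
  expect_identical(count_hamiltonian_paths(c4), 4)
})

test_that("the class library is a complete (MLD, Np) index", {
  lib <- dod_lib()
  cl <- lib$classes
  # union of all buckets is the whole class set
  buckets <- unique(cl[, c("mld", "np")])
  tot <- sum(vapply(seq_len(nrow(buckets)), function(i) {
    nrow(library_lookup(lib, buckets$mld[i], buckets$np[i]))
  }, integer(1)))
  expect_identical(tot, nrow(cl))
  # the two benchmark buckets exist
  expect_gt(nrow(library_lookup(lib, 9, 8)), 0)
  expect_gt(nrow(library_lookup(lib, 19, 2)), 0)
  # MLD=19 buckets occur only with Np in {2,3,4}; empty buckets are absent, not errors
  expect_identical(nrow(library_lookup(lib, 19, 5)), 0L)
  expect_identical(nrow(library_lookup(lib, 19, 1)), 0L)
  # minimum MLD in the library is nine
  expect_identical(min(cl$mld), 9L)
})

test_that("library serialization round-trips", {
  lib <- build_library(cube, cache = FALSE)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_tree_library(lib, path)
  lib2 <- read_tree_library(path, cube)
  expect_identical(lib2$classes$mld, lib$classes$mld)
  expect_identical(lib2$classes$np, lib$classes$np)
  expect_identical(sort(lib2$classes$mask), sort(lib$classes$mask))
  expect_identical(lib2$n_labelled, lib$n_labelled)
})
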