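# Shared fixtures: built once per test run; the dodecahedral tree library is
# cached inside the package so repeated build_library() calls are free.

tet <- build_fixture("tetrahedron")
cube <- build_fixture("cube")
dod <- build_dodecahedron()

dod_lib <- function() build_library(dod)

ref_pair <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- reference_competition_classes(dod_lib())
    val
  }
})

par_ref <- energy_params(eps1 = -0.5, mu0 = -4, e0 = 4)

# Independent assembly-energy computation used as an oracle: works directly
# from face vertex cycles, never through edge_counts()/assembly_energy().
oracle_energy <- function(tree_idx, face_ids, poly, eps1, mu0) {
  eps2 <- -1 + 2 * eps1
  e <- 0
  for (ei in seq_len(poly$E)) {
    fs <- poly$edge_faces[ei, ]
    k <- sum(fs %in% face_ids)
    is_link <- ei %in% tree_idx
    if (is_link && k == 1) e <- e + eps1
    if (is_link && k == 2) e <- e + eps2
    if (!is_link && k == 2) e <- e - 1
  }
  e - mu0 * length(face_ids)
}
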