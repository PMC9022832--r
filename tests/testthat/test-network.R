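test_that("minimum-energy profiles agree with naive full enumeration on the cube", {
  clib <- build_library(cube, cache = FALSE)
  pc <- energy_params(eps1 = -0.5, mu0 = -1, e0 = 2, poly = cube)
  for (m in clib$classes$mask[c(1, 4, 9)]) {
    tree <- tree_edges(m, cube)
    prof <- min_energy_profile(tree, cube, pc)
    # independent oracle: combn over faces + per-edge energy recomputation
    for (n in 0:6) {
      subs <- if (n == 0) list(integer(0)) else
        asplit(utils::combn(6, n), 2)
      emin <- min(vapply(subs, function(fs)
        oracle_energy(tree, as.integer(fs), cube, pc$eps1, pc$mu0),
        numeric(1)))
      expect_equal(prof$e_min[n + 1], emin)
    }
  }
})

test_that("benchmark activation barriers and their ordering are reproduced", {
  ref <- ref_pair()
  p1 <- min_energy_profile(ref$tree1, dod, par_ref)
  p2 <- min_energy_profile(ref$tree2, dod, par_ref)
  expect_equal(p1$barrier, 3.0)
  expect_equal(p2$barrier, 5.0)
  expect_equal(p2$barrier - p1$barrier, 2.0)
  expect_lt(p1$barrier, p2$barrier)
  expect_equal(p1$e_min[1], 0)
  expect_gte(p1$barrier, 0)
})

test_that("network nodes are deduplicated minimum-energy intermediates with m_0 = m_F = 1", {
  ref <- ref_pair()
  net1 <- build_network(ref$tree1, dod, par_ref)
  net2 <- build_network(ref$tree2, dod, par_ref)
  expect_identical(net1$m[1], 1L)
  expect_identical(net1$m[13], 1L)
  expect_identical(net2$m[1], 1L)
  expect_identical(net2$m[13], 1L)
  # the compact class has four distinct five-pentamer intermediates
  expect_identical(net1$m[6], 4L)
  # level energies equal the profile minima
  expect_equal(net1$e_min, min_energy_profile(ref$tree1, dod, par_ref)$e_min)
  # the linear chain offers more intermediates and more assembly routes
  expect_gt(sum(net2$m), sum(net1$m))
  expect_gt(count_assembly_paths(net2), count_assembly_paths(net1))
  # adjacency links configs differing by one face: check against orbits
  lv <- net1$levels
  for (n in 1:11) {
    A <- net1$A[[n]]
    for (i in seq_len(nrow(A))) for (j in seq_len(ncol(A))) {
      rep_i <- lv[[n]]$configs[i]
      hit <- any(bitwAnd(rep_i, lv[[n + 1]]$orbits[[j]]) == rep_i)
      expect_identical(A[i, j] == 1L, hit)
    }
  }
})

test_that("network construction on the cube agrees with brute-force stabilizer dedupe", {
  clib <- build_library(cube, cache = FALSE)
  pc <- energy_params(eps1 = -0.5, mu0 = -1, e0 = 2, poly = cube)
  tree <- tree_edges(clib$classes$mask[2], cube)
  net <- build_network(tree, cube, pc)
  # brute force: group elements fixing the tree, applied to face subsets
  stab <- Filter(function(g) {
    identical(sort(cube$edge_perm[g, tree]), sort(tree))
  }, seq_len(48))
  for (n in 0:6) {
    subs <- if (n == 0) list(integer(0)) else asplit(utils::combn(6, n), 2)
    en <- vapply(subs, function(fs)
      oracle_energy(tree, as.integer(fs), cube, pc$eps1, pc$mu0), numeric(1))
    mins <- subs[abs(en - min(en)) < 1e-9]
    canon <- unique(vapply(mins, function(fs) {
      imgs <- vapply(stab, function(g)
        paste(sort(cube$face_perm[g, as.integer(fs)]), collapse = ","), "")
      min(imgs)
    }, ""))
    expect_identical(net$m[n + 1], length(canon))
  }
})

test_that("at strong RNA affinity the compact bucket develops incomplete-particle minima", {
  p11 <- energy_params(eps1 = -1.1, mu0 = "equilibrium")
  lib <- dod_lib()
  rows <- library_lookup(lib, 9, 8)
  argmins <- vapply(rows$mask, function(m) {
    min_energy_profile(tree_edges(m, dod), dod, p11)$argmin_n
  }, integer(1))
  # the bucket contains a class whose minimum-energy state has ten pentamers
  expect_true(10L %in% argmins)
  # all compact classes prefer incomplete particles at this affinity
  expect_true(all(argmins < 12L))
  # whereas the linear chain keeps the complete capsid as a ground state
  ref <- ref_pair()
  prof2 <- min_energy_profile(ref$tree2, dod, p11)
  expect_equal(min(prof2$e_min), prof2$e_min[13])
})

test_that("equilibrium distribution is normalized, uniform for flat energies, and reached by clamped dynamics", {
  toy_flat <- toy_network(e_min = c(0, 0, 0), e0 = 3)
  eq <- equilibrium_distribution(toy_flat, c_f = 1)
  expect_equal(eq$p_node, rep(0.25, 3)) # 4 nodes, all equally likely
  expect_equal(sum(eq$p_level), 1)
  set.seed(21)
  for (rep in 1:5) {
    toy <- toy_network(e_min = c(0, runif(1, -2, 2), runif(1, -2, 2)),
                       e0 = runif(1, 0.5, 4))
    cf <- runif(1, 0.2, 2)
    eq <- equilibrium_distribution(toy, cf)
    expect_equal(sum(toy$m * eq$p_node), 1)
    tr <- integrate_master(toy, clamp_cf = cf, t_end = 1e5, n_out = 60)
    expect_equal(unname(tail(tr$species[[1]]$Q, 1)[1, ]),
                 eq$p_level, tolerance = 1e-6)
  }
})
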