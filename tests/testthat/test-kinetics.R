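test_that("on/off rates follow the Metropolis form and detailed balance", {
  # downhill or level additions proceed at the base rate
  expect_equal(on_rate(-1, c_f = 0.5, e0 = 4), 0.5)
  expect_equal(on_rate(0, c_f = 0.5, e0 = 4), 0.5)
  # uphill additions carry the Arrhenius factor
  expect_equal(on_rate(1, c_f = 1, e0 = 4), exp(-4))
  # off-rates never depend on c_f and mirror the on-rates
  expect_equal(off_rate(1, e0 = 4), 1)
  expect_equal(off_rate(0, e0 = 4), 1)
  expect_equal(off_rate(-1, e0 = 4), exp(-4))
  # ratio equals the Boltzmann factor of the step for either sign
  set.seed(8)
  for (d in runif(20, -3, 3)) {
    cf <- runif(1, 0.1, 4)
    e0 <- runif(1, 0.5, 5)
    expect_equal(on_rate(d, cf, e0) / off_rate(d, e0), cf * exp(-e0 * d))
  }
})

test_that("mass conservation fixes the free pentamer concentration", {
  # all RNA pentamer-free
  q0 <- c(1, rep(0, 12))
  expect_equal(free_pentamer_fraction(list(q0), D = 0.5, c0 = 2), 2)
  # two species fully packaged at stoichiometric ratio exhaust the pool
  q12 <- c(rep(0, 12), 1)
  expect_equal(free_pentamer_fraction(list(q12, q12), D = 1), 0)
  # single species fully packaged at D = 0.5 leaves half the pentamers
  expect_equal(free_pentamer_fraction(list(q12), D = 0.5, c0 = 1), 0.5)
  expect_error(free_pentamer_fraction(list(3 * q12), D = 1), "c_f < 0")
})

test_that("probability is conserved per species along trajectories", {
  ref <- ref_pair()
  net1 <- build_network(ref$tree1, dod, par_ref)
  net2 <- build_network(ref$tree2, dod, par_ref)
  tr <- integrate_master(list(net1, net2), c0 = 1, D = 0.5, t_end = 1e5)
  expect_lt(tr$max_mass_err, 1e-6)
  trn <- integrate_master(net1, c0 = 1, D = 0.5, t_end = 1e4,
                          granularity = "node")
  expect_lt(trn$max_mass_err, 1e-6)
  expect_true(all(tr$c_f >= 0 & tr$c_f <= 1))
})

test_that("clamped-concentration dynamics thermalizes to the Boltzmann distribution with decreasing relative entropy", {
  ref <- ref_pair()
  net <- build_network(ref$tree1, dod, par_ref)
  cf <- 0.8
  tr <- integrate_master(net, clamp_cf = cf, t_end = 1e8, n_out = 200,
                         granularity = "node")
  eq <- equilibrium_distribution(net, cf)
  lastQ <- unname(tail(tr$species[[1]]$Q, 1)[1, ])
  expect_equal(lastQ, eq$p_level, tolerance = 1e-5)
  # Kullback-Leibler divergence of the node-resolved distribution to
  # equilibrium decreases monotonically (H-theorem)
  peq_node <- rep(eq$p_node, net$m)
  kl <- apply(tr$species[[1]]$nodes, 1, function(p) {
    sel <- p > 1e-300
    sum(p[sel] * log(p[sel] / peq_node[sel]))
  })
  expect_true(all(diff(kl) < 1e-8))
})

test_that("stochastic simulation agrees with the node-resolved master equation on the cube", {
  clib <- build_library(cube, cache = FALSE)
  pc <- energy_params(eps1 = -0.5, mu0 = -1.2, e0 = 2, poly = cube)
  net <- build_network(tree_edges(clib$classes$mask[1], cube), cube, pc)
  cf <- 0.8
  times <- c(0.5, 2, 10, 50)
  n_rep <- 600
  set.seed(101)
  ssa <- gillespie_packaging(net, cf, times, n_rep = n_rep)
  ode <- integrate_master(net, clamp_cf = cf, t_end = 50,
                          granularity = "node", n_out = 300)
  for (k in seq_along(times)) {
    i <- which.min(abs(ode$times - times[k]))
    p <- ode$species[[1]]$nodes[i, ]
    # binomial Monte-Carlo error, three sigma plus a small floor
    tol <- 3 * sqrt(pmax(p * (1 - p), 1e-4) / n_rep) + 0.01
    expect_true(all(abs(ssa[k, ] - p) < tol))
  }
})

test_that("the linear chain thermalizes far more slowly than the compact class", {
  ref <- ref_pair()
  net1 <- build_network(ref$tree1, dod, par_ref)
  net2 <- build_network(ref$tree2, dod, par_ref)
  t1 <- simulate_packaging(net1, c0 = 1, D = 0.5, t_end = 1e6)
  t2 <- simulate_packaging(net2, c0 = 1, D = 0.5, t_end = 1e6)
  p1 <- packaged_fraction(t1); p2 <- packaged_fraction(t2)
  # the compact class is essentially equilibrated by 1e6; the chain is not
  expect_gt(p1[length(p1)], 0.5)
  expect_lt(p2[length(p2)], 0.1)
  # half-rise times differ by orders of magnitude
  half1 <- t1$times[which(p1 > 0.5 * max(p1))[1]]
  half2sofar <- max(t2$times) # still below half its plateau at t_end
  expect_gt(half2sofar / half1, 10)
})

test_that("level-resolved and node-resolved dynamics agree closely for the compact class", {
  ref <- ref_pair()
  net <- build_network(ref$tree1, dod, par_ref)
  tl <- simulate_packaging(net, c0 = 1, D = 0.5, t_end = 1e5)
  tn <- simulate_packaging(net, c0 = 1, D = 0.5, t_end = 1e5,
                           granularity = "node")
  pl <- packaged_fraction(tl); pn <- packaged_fraction(tn)
  expect_lt(max(abs(pl - pn)), 0.05)
  # the long-time limit is the self-consistent equilibrium
  tl2 <- simulate_packaging(net, c0 = 1, D = 0.5, t_end = 1e7)
  pl2 <- packaged_fraction(tl2)
  eq <- equilibrium_distribution(net, tl2$c_f[length(tl2$c_f)])
  expect_equal(pl2[length(pl2)], eq$p_level[13], tolerance = 1e-3)
})
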