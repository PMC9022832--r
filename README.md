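# capsidselect

How does a virus pick its own genome out of a sea of similar host RNA?
For many small ssRNA viruses the answer is kinetic: clustered *packaging
signals* (the psi sequence) on the folded genome act as a template that
lowers the activation barrier for nucleating capsid assembly, so viral RNA
is packaged fast while competing RNA is still waiting to nucleate — even
though both end up with the same assembly energy at equilibrium.

`capsidselect` is an R package for quantitative study of this mechanism on
the dodecahedral (pentamer-only) capsid model.  It is aimed at researchers
in virus assembly biophysics and statistical mechanics who want a complete,
testable implementation of the spanning-tree / master-equation model of
packaging competition.

## The model in brief

* The capsid is 12 pentamers on the faces of a dodecahedron; the psi
  section of the condensed RNA is a **spanning tree** of the dodecahedral
  graph (19 links, 20 vertices, 11 bare edges).  Folding geometries are the
  spanning trees modulo the 120 symmetries: 43,380 classes out of 5,184,000
  labelled trees, indexed by the **wrapping number** Np (faces with the
  maximal four tree links) and the **maximum ladder distance** MLD (tree
  diameter; 19 for the 1620 Hamiltonian-path linear chains, 9 at most
  compact).

* A partial capsid with `n` pentamers has assembly energy (in units of the
  pentamer contact energy E0)

  ```
  dE(n) = n1*eps1 + n2*eps2 - n3 - mu0*n ,   eps2 = -1 + 2*eps1
  ```

  from which the package builds, per tree class, the exact minimum-energy
  assembly profile, its activation barrier, and the network of distinct
  minimum-energy intermediates (multiplicities `m_n`, single-pentamer
  adjacency).

* Packaging kinetics is a master equation on that network with Metropolis
  on-rates `lambda*c_f*min(1, exp(-e0*ddE))`, detailed-balance off-rates,
  and a shared free-pentamer pool `c_f` slaved to the occupations by mass
  conservation — the nonlinearity that makes two RNA species compete.
  Derived observables: assembly delay time (maximum-slope tangent), packaged
  fractions, and the kinetic selectivity `S(E0)`.

## Worked example

```r
library(capsidselect)

dod <- build_dodecahedron()
lib <- build_library(dod)          # exhaustive enumeration + winnowing, ~2 s
lib
#> tree_library: dodecahedron, 5184000 labelled trees, 43380 symmetry classes

ref <- reference_competition_classes(lib)   # encoded (9,8) vs linear (19,2)
par <- energy_params(eps1 = -0.5, mu0 = -4, e0 = 4)

net1 <- build_network(ref$tree1, dod, par)
net1
#> assembly_network on dodecahedron: tree MLD=9 Np=8, 57 nodes, barrier 3 E0
#> multiplicities m_n: 1 8 13 6 5 4 5 7 1 1 3 2 1
net2 <- build_network(ref$tree2, dod, par)
net2
#> assembly_network on dodecahedron: tree MLD=19 Np=2, 86 nodes, barrier 5 E0
#> multiplicities m_n: 1 1 5 5 10 25 6 5 6 5 11 5 1

# supersaturated, stoichiometric packaging competition
traj <- compete_packaging(net1, net2, c0 = 4, D = 2, t_end = 1e6)
selectivity(traj)
#> kinetic selectivity S = 0.9900 at t_max = 2.282e+05 (p1 = 0.7872, p2 = 0.0079)

delay_time(simulate_packaging(net1, c0 = 1, D = 0.5, t_end = 1e4, n_out = 600))
#> delay time t_d = 9.537 (max slope 8.03e-06 at t* = 35.59)
```

Reading the numbers: the compact, maximally wrapped psi geometry (MLD=9,
Np=8) has a 3 E0 nucleation barrier against 5 E0 for the linear chain, so at
E0 = 4 kT it assembles orders of magnitude sooner.  Run at four-fold
supersaturation with the mixing ratio at the stoichiometric point (D = 2),
it packages ~79% of its molecules and monopolises the pentamer pool: the
competitor reaches under 1%, a kinetic selectivity of 0.99 sustained beyond
2×10^5 time units (units of 1/lambda).

A pipeline wrapper (`run_pipeline()`) executes
enumerate → select classes → energies → networks → master equation from a
flat key-value config and writes JSONL/JSON/CSV artifacts, and
`inst/cli/capsidselect.R` exposes the same steps as shell subcommands
(`enumerate`, `network`, `simulate`, `compete`, `scan`, `fixtures`).

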