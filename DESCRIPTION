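Package: capsidselect
Title: Kinetic Selection of Viral RNA by Packaging Signals During Capsid
    Assembly
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Statistical-mechanics model of how packaging-signal geometry
    controls the kinetics of small RNA virus assembly. The psi sequence of
    packaging signals is represented as a spanning tree of the dodecahedral
    capsid scaffold; the package enumerates and classifies all
    symmetry-inequivalent spanning trees by wrapping number and maximum
    ladder distance, computes minimum-energy assembly profiles and
    activation barriers for pentamer-by-pentamer growth, builds the network
    of minimum-energy assembly intermediates, and integrates coupled master
    equations for packaging competition between RNA species, yielding delay
    times, packaged fractions, and kinetic selectivity as a function of the
    pentamer binding energy scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
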