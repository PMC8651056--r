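Package: boolctmc
Title: Stochastic Simulation of Boolean Networks as Continuous-Time Markov Chains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates logical (Boolean) models of biological networks as
    continuous-time Markov chains with separate per-node activation and
    inactivation rates, using the Gillespie algorithm over an ensemble of
    trajectories. Produces windowed state- and node-probability trajectories,
    last-state distributions and fixed-point tables; supports automatic
    single/double mutant screening with phenotype filtering; reads and writes
    BoolNet text models and MaBoSS-style model/settings files, imports
    SBML-qual documents, and converts multi-valued logical models to purely
    Boolean ones via level-component duplication. Includes an exact
    matrix-exponential transient solver for small networks, exhaustive
    fixed-point enumeration, built-in toy models and a random N-K network
    generator, and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, tools, Rcpp, Matrix, xml2, jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'expr.R'
    'model.R'
    'multivalued.R'
    'booleanize.R'
    'engine.R'
    'fixtures.R'
    'io_bnet.R'
    'io_maboss.R'
    'io_sbmlqual.R'
    'io_results.R'
    'screening.R'
    'cli.R'
    'boolctmc-package.R'
    'RcppExports.R'
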