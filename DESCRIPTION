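Package: drugsel
Title: Hybrid Particle Swarm and African Vulture Optimization for Multi-Criteria Drug Prioritization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Constrained combinatorial selection of drug subsets from patient
    review tables by a hybrid of particle swarm optimization (PSO) and the
    enhanced African vulture optimization algorithm (EAVOA), with Levy-flight
    mutation, opposition-based initialization, stagnation restarts and elite
    preservation. Candidate subsets are scored by a penalized weighted-sum
    fitness over min-max normalized user ratings, lexicon-weighted side-effect
    severity and review counts. Includes the standalone PSO and EAVOA
    baselines, a brute-force enumeration oracle, a multi-run benchmark
    harness, weight-sensitivity tools (one-way sweeps, simplex grids, Sobol
    variance decomposition, Kruskal-Wallis comparison) and a synthetic
    drug-table generator with planted optima for verifiable testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
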