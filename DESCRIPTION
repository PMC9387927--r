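Package: ktwsim
Title: Assembly Dynamics of Open Phage-Bacteria Ecosystems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the assembly of well-mixed phage-bacteria communities
    under sequential stochastic invasions, using generalized Lotka-Volterra
    dynamics with a shared bacterial resource. New bacterial and phage strains
    invade one at a time; after each attempt the community is resolved to a
    feasible (strictly positive, non-degenerate) steady state by combining a
    linear steady-state solver with fourth-order Runge-Kutta integration down
    to an extinction threshold. Two wiring rules for invaders are provided: a
    nested model (N) in which invading bacteria are resistant to all resident
    phages, and a random model (R) in which resident phages attack invaders
    with a cross-link probability p. Includes analysis tools for the resulting
    ecosystems: classification of the two-bacteria/one-shared-phage triplet
    motif (coexistence, exclusion of either competitor, phage loss), detection
    of eliminate-the-winner events in assembly histories, kill-the-winner
    pairing of strongest predator-prey links, growth-rate occupancy and entry
    profiles, and the elimination factor summarizing fast-grower advantage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
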