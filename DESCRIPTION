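Package: pestgame
Title: Differential-Game Analysis of Cooperative Forest Pest Management
Version: 1.0.0
Authors@R: person("pestgame", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Solves the infinite-horizon government-enterprise differential
    game for forest pest-and-disease management under carbon offsets, in
    three cooperation modes, individual action, scarce-resource sharing and
    information sharing. Each (mode, player) pair reduces to a linear-state,
    concave-effort optimal-control problem with Nerlove-Arrow reputation
    dynamics; the package returns closed-form HJB feedback equilibria
    (constant optimal effort, linear value function), verifies them against
    an independent numerical quadrature and grid-search oracle, and provides
    mode-comparison analytics, value tables over gain grids, crossover
    roots, dominance-region maps and comparative statics. Includes a seeded
    scenario generator, JSON configuration, batch reporting and a small
    command-line interface.
License: MIT
Encoding: UTF-8
Imports: jsonlite, stats, utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
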