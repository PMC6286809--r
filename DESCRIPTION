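Package: lyapnet
Title: Inference of Directed Metabolic Networks from Steady-State
    Metabolome Covariance via the Lyapunov Equation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers the sparse sign structure of the Jacobian matrix of a
    metabolic reaction network from the covariance of replicate steady-state
    metabolome measurements. The stationary fluctuation-dissipation relation
    (Lyapunov equation) J C + C J' = -2 D links the Jacobian J to the sample
    covariance C and a diagonal fluctuation matrix D estimated from replicate
    standard deviations; the underdetermined vectorized system is solved by a
    sparsity-constrained genetic algorithm with a scan over the sparsity
    scaling factor, and the final directed network is the consensus of a
    community of best-found candidate structures. Includes a Langevin-type
    stochastic simulator of kinetic models for generating synthetic replicate
    data, a Gaussian graphical model baseline based on full-order partial
    correlations, and network-reconstruction evaluation metrics (TPR, FPR,
    g-score, sparsity, reproducibility).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
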