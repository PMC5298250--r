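Package: amasgd
Title: Accuracy Maximization Analysis with Stochastic Gradient Descent
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns small sets of unit-norm linear encoding filters
    (receptive fields) that maximize accuracy in a latent-variable
    estimation task, using a Bayesian ideal-observer decoder with a
    Gaussian response model and scaled additive (Poisson-like) encoding
    noise. Provides closed-form posteriors over discrete latent-variable
    levels, analytic gradients of the KL-divergence (0-1) and squared-error
    costs, constrained stochastic gradient descent on the unit hypersphere,
    a synthetic "energy-task" stimulus generator, prior manipulation by
    stimulus culling, PCA baseline filters, and subspace-rotation analyses
    of encoding fidelity under scaled versus constant additive noise.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
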