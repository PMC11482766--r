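Package: taskdyn
Title: Latent Task Dynamics with Over-Parameterized Linear-Gaussian State-Space Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits linear-Gaussian state-space models to epoched multi-trial
    neural recordings by maximum a posteriori expectation-maximization with
    subspace-identification (canonical variate analysis) initialization,
    supporting the over-parameterized regime in which the number of latent
    factors exceeds the number of observed dimensions. Provides
    control-theoretic "dynamic signatures" of task switching computed from a
    fitted model (additive state decomposition into task subsystems,
    cross-lagged switch similarity, initial-centrality midpoint scores, and
    recursive-Lyapunov task energy), model comparison and group inference
    (Cox-Snell generalized R-squared, sensor-level null models, protected
    exceedance probabilities, threshold-free cluster enhancement, bootstrap
    cross-modality similarity), and synthetic generators: planted ground-truth
    state-space models and a gated-recurrent-unit task-switching simulator
    trained by backpropagation through time.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    splines,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
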