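Package: erflnp
Title: Linear-Nonlinear-Poisson Models for Electrically Evoked Retinal Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for probing retinal ganglion cell responses to smooth electrical
    Gaussian white-noise stimulation and for fitting linear-nonlinear-Poisson (LNP)
    encoding models to the evoked spike trains. Provides a reflected-random-walk
    stimulus generator with Butterworth band limiting, stimulation-artefact removal
    by scaled stimulus subtraction after Bessel band-pass filtering, response
    reliability and light-response indices, LNP filter estimation by whitened
    spike-triggered averaging with histogram-ratio nonlinearities and by
    elastic-net-penalized Bernoulli regression, blockwise cross-validated firing-rate
    prediction, and PCA-based hierarchical clustering of the fitted temporal filters.
    A synthetic-data generator with known ground truth supports recovery testing of
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    signal,
    glmnet,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
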