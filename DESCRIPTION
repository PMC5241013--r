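Package: coversad
Title: Point-Intercept Cover, Species Abundance Distributions and
    Rainfall Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing point-intercept vegetation surveys on
    gridded transects: per-species percent cover (Foliage Projective
    Cover and Opaque Canopy Cover), fractional cover, species
    accumulation and cumulative-cover sampling diagnostics, Shannon and
    Simpson diversity, maximum-likelihood fitting of Pareto and
    lognormal species abundance distributions with AIC comparison and
    rank-abundance prediction, and robust (Huber M-estimation)
    regression of SAD shape on mean annual precipitation with
    bootstrap confidence intervals. Includes a synthetic survey
    generator that reproduces the survey geometry (10 transects of 101
    points in a 1 ha plot) and a known abundance-rainfall link, so the
    whole pipeline can be exercised with ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    jsonlite,
    stats,
    utils,
    vegan
Suggests:
    fitdistrplus,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
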