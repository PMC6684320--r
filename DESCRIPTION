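Package: ecpolarity
Title: Quantification of Endothelial Collective Cell Behavior
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for collective cell behavior in endothelial
    monolayers and sprouting vessels. Extracts Golgi-nucleus axial polarity
    from centroid tables or labeled images, computes the polarity index
    (mean resultant vector length) with its 50 um distance-binned profile,
    leader/follower classification and a randomization threshold; performs
    object-based two-channel co-localization; computes acceptor-photobleaching
    FRET efficiency and counts ratiometric biosensor activation peaks;
    analyses single-cell force-spectroscopy curves (detachment work, maximum
    detachment force, cadherin-dependent fraction); and estimates
    velocity-correlation lengths from gridded velocity fields. A synthetic
    data generator with known ground truth makes every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    clue,
    deldir,
    EBImage,
    jsonlite,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
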