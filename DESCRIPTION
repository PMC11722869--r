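Package: edgethresh
Title: Ground-Truth-Driven Threshold Selection for Classical Edge Detectors
    on Noisy Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how noise and image complexity affect classical
    edge detection, and for choosing detector thresholds against a ground-truth
    edge map. Implements the five classical detectors (Sobel, Prewitt, Roberts,
    Laplacian-of-Gaussian, Canny), simulators for Gaussian, salt-and-pepper,
    speckle and Rician noise, spatial-information image-complexity statistics,
    objective edge-quality measures (F-measure, Pratt's figure of merit,
    performance ratio), grid and random search over a candidate-threshold
    dataset, seeded synthetic phantoms with exact one-pixel ground-truth
    boundaries, and an experiment pipeline that crosses corpus, noise model,
    detector and selection method.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    png,
    tiff,
    yaml,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
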