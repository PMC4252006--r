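Package: ihcscore
Title: Quantification and Categorical Scoring of DAB Immunohistochemistry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies 3,3'-diaminobenzidine (DAB) immunohistochemistry in
    brightfield RGB images. Separates hematoxylin and DAB stains by optical
    density color deconvolution, sets a background cutoff by global histogram
    thresholding, fits a three-component Gaussian mixture to positive DAB
    white-pixel intensities by expectation-maximization with k-means
    initialization, and places category thresholds at the intersections of the
    fitted components to convert continuous staining intensity into the
    weak/moderate/strong categories used in pathology scoring. Also provides
    nuclear positivity counting, fraction-weighted 0-3 scores, the statistical
    battery used in decalcification time-course studies, scanner histogram
    comparison utilities, and a fully ground-truthed synthetic H-DAB image and
    time-course generator so the whole pipeline is testable without slides.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    png,
    tiff,
    EBImage,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
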