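Package: conegain
Title: Information Available to Normal and Color-Deficient Observers in
    Natural Scenes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates the information, in bits, that noisy cone
    photoreceptor excitations carry about the spectral radiances of
    colored surfaces in hyperspectral scenes, and the information lost
    under red-green color vision deficiency and cone monochromacy.
    Implements a cone excitation model with normal, hybrid (spectrally
    shifted), and absent photopigments; Weber-scaled Gaussian cone noise;
    an offset Kozachenko-Leonenko k-nearest-neighbor mutual-information
    estimator; sup-metric thinning toward uniform surface frequencies;
    CAM02-UCS scene color descriptors and dichromatic confusion-axis
    directions; percentile-bootstrap and linear-circular regression
    analyses; and a calibrated generator of synthetic hyperspectral
    scenes with natural-scene-like color statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
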