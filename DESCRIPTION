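Package: ddmix
Title: Diffusion and Fast-Guess Mixture Modeling of Choice Response Times
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for modeling two-choice response-time data as a
    probabilistic mixture of a Wiener diffusion decision process and a
    chance-accuracy "fast guess" process with normally distributed latencies.
    Provides first-passage-time densities and defective distribution
    functions for the diffusion process with across-trial variability in
    drift rate, starting point, and nondecision time; quantile-based
    G-square (multinomial likelihood-ratio) fitting of a constrained 5 x 5
    speed-accuracy by stimulus-contrast experimental design; synthetic-data
    generation emulating heavily speed-stressed experiments; and benchmark
    diagnostics for contaminated RT distributions (error minus correct RT,
    coefficient of variation, moment, quartile and Pearson skewness,
    sub-300-ms chance-accuracy tests, and quantile-probability-plot tables).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    pracma,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
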