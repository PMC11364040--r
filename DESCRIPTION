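Package: crefdenoise
Title: Self-Supervised Denoising of Cryo-EM Density Maps with a Cref
    Fourier-Shell Loss
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for denoising three-dimensional cryo-EM density maps
    using only the pair of half-maps deposited alongside an entry. A 3D
    U-Net denoiser is trained self-supervised against the Rosenthal-
    Henderson Cref curve: the Fourier shell correlation (FSC) between the
    half-map average and the denoised map is driven toward the Cref curve
    predicted from the half-map FSC, so no noise-free reference is ever
    needed. Includes the full Fourier-shell toolbox (FSC, Cref, shell
    partitions, the Cref training loss and its analytic gradient), a
    per-shell covariance decomposition of denoised maps into signal,
    noise, bias and leftover-noise variances, a patch-extraction and
    standardization pipeline, a synthetic half-map generator with
    controlled spectral signal-to-noise ratio, FSC-threshold resolution
    estimation, native MRC volume input/output, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
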