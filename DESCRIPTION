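Package: furrowvm
Title: Vertex-Model Simulation of Drosophila Ventral Furrow Formation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Energy-based two-dimensional vertex model of the apical surface of
    the Drosophila ventral epithelium during ventral furrow formation. A sheet
    of hexagonal cells evolves by overdamped gradient descent on a potential
    combining area elasticity, anisotropic line tension and area-based
    contractility. Contractility programs include a sharp cutoff band, a
    Gaussian latero-ventral gradient, linear temporal ramps, per-cell Wiener
    noise, a centroid-distance (non-cell-autonomous) gradient and a
    twist-mutant attenuation variant. Supports T1 neighbour exchanges,
    bit-exact archiving and replay with declarative modifications, a reduced
    seven-cell model, and trace analytics: moment-ellipse eccentricity,
    smoothed rates, stagnation-period detection and lagged rate correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    grDevices,
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
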