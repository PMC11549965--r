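Package: tmbarrel
Title: De Novo Design and Analysis of Transmembrane Beta-Barrel Nanopores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parametric generation of idealized transmembrane beta-barrel
    (TMB) backbones from blueprint parameters (strand count, shear number,
    canonical beta-sheet spacings), with glycine-kink sculpting of the
    barrel cross-section into square, rectangular, triangular or oval
    shapes, and short beta-hairpin loop closure.  Companion analysis tools
    cover rule-based membrane-protein sequence patterning (polar lumen
    networks around Tyr-Gly-Asp/Glu folding motifs, secondary-structure
    frustration patches, hydrophobic exterior with Ser/Thr near kinks),
    inscribed-sphere pore-radius profiling of channel structures, a
    cylindrical-pore plus access-resistance conductance model linking pore
    diameter to single-channel conductance, and simulation and analysis of
    single-channel planar-bilayer recordings (insertion step detection,
    current-jump histograms with Gaussian fits, I/V monotonicity checks).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    optparse,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
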