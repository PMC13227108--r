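Package: dnaforge
Title: Generation and Rigid-Base Analysis of Double-Stranded DNA Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds atomic-resolution double-stranded DNA models in arbitrary
    shapes by fitting an interpolating spline through control points, placing
    base-pair reference frames at 0.34 nm spacing with a 10.5 bp/turn helical
    twist, and imposing a linking-number difference on closed topologies via
    the White-Fuller relation Lk = Tw + Wr.  Structures can be relaxed by
    Metropolis Monte Carlo sampling under a quadratic rigid-base-step elastic
    energy with hard-sphere excluded volume that conserves the linking number
    of closed chains.  Editing operations cover mutation over an extended
    nucleobase alphabet, Watson-Crick-Franklin to Hoogsteen flips about the
    glycosidic bond, CpG-aware cytosine methylation, and extension or
    connection of duplexes.  Analysis routines fit base reference frames from
    atomic coordinates and compute the twelve rigid base-pair parameters,
    twist, writhe and linking number, total curvature, and persistence length.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    bio3d,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
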