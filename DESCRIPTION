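Package: eftfm
Title: Three-Dimensional Traction Force Microscopy from Epifluorescence
    Bead-Layer Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reconstructs fully three-dimensional substrate displacement and
    surface traction fields from paired epifluorescence z-stacks of a single
    layer of fluorescent microbeads embedded at the surface of a soft
    hydrogel.  The workflow deconvolves the volumetric images with an
    empirically extracted point spread function (Richardson-Lucy), localizes
    beads at subvoxel precision by the radial-symmetry method, links them
    between reference and deformed stacks with a topology-based single
    particle tracker, resamples the scattered near-planar displacements onto
    the best-fit bead plane by curvature-regularized least squares, and
    solves the resulting Dirichlet boundary-value problem for a compressible
    neo-Hookean substrate on a graded hexahedral mesh to obtain full-field
    stress and in-plane plus out-of-plane Cauchy surface tractions.  A
    synthetic-data generator (analytic Boussinesq/bonded-layer indentation
    fields, bead-layer rendering with realistic noise) provides ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    methods,
    pracma,
    Rcpp,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
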