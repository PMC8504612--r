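Package: lungwarp
Title: Unsupervised Deformable Registration of 3D Chest CT Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for unsupervised learning of deformable registration of
    intrapatient 3D chest CT volumes. Provides 3D thin-plate-spline (TPS)
    data augmentation, a fully convolutional encoder-decoder with
    multi-kernel inception modules on the skip connections that predicts a
    dense displacement field, a differentiable trilinear warping layer, a
    composite training objective (windowed squared normalized
    cross-correlation, a Jacobian-determinant folding penalty and a
    first-derivative smoothness penalty), and an evaluation suite (landmark
    target registration error, lung-mask Dice overlap, folding-voxel
    counts). Includes a synthetic phantom generator with known ground-truth
    deformations so the whole pipeline runs at desk scale, plus NIfTI and
    MetaImage volume input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
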