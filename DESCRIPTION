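Package: aneuseg
Title: Detection and Voxel-Wise Segmentation of Intracranial Aneurysms on CTA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for automatic detection and voxel-wise
    segmentation of intracranial aneurysms on computed tomography angiography
    (CTA), exercised on synthetic vascular phantoms. Provides a phantom
    generator with ground-truth aneurysm and vessel masks; preprocessing with
    brain masking, two-scale Hessian vesselness channels, isotropic resampling
    and intensity normalization; a dual-pathway patch-based 3D convolutional
    segmentation network trained with a soft Dice loss; STAPLE
    (simultaneous truth and performance level estimation) label fusion of
    cross-validation folds and ensembling of input-configuration variants; and
    a volume-binned detection/segmentation evaluation harness (sensitivity,
    precision, F1, false positives per scan, Dice coefficient, Pearson volume
    correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
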