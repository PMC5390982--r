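Package: endocast
Title: Automatic Extraction of Endocranial Surfaces from Cranial CT Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for virtual anthropology: segments the endocranial
    (braincase) cavity of a cranium CT volume and polygonizes it into a
    closed two-manifold triangle mesh. The pipeline binarizes the volume at
    an isovalue, fills small bone voids (diploic space, cracks) by
    morphological closing with a ball structuring element, seeds a
    marker-controlled watershed on the exact Euclidean distance field of the
    filled bone mask, and polygonizes only the endocast region. Includes
    readers and writers for common CT containers (DICOM series, NIfTI-1,
    NRRD, raw with sidecar), mesh export (PLY, STL, OBJ), mesh validity and
    surface-distance measures, and a synthetic cranium-phantom generator
    with analytic ground truth so the whole pipeline can be exercised
    without real CT data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
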