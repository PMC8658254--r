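Package: osteoplan
Title: CT-to-Print Modelling of Mandibular Anatomical Models and Surgical Templates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Digital chain for patient-specific mandibular reconstruction
    planning: reads CT volumes (DICOM series) in Hounsfield units, reduces
    post-operative metal noise with a per-slice minimum filter, resamples to
    isotropic voxels with a Lanczos windowed-sinc kernel, segments bone by
    dual Hounsfield thresholds with resection curves and seeded region
    growing, extracts sub-voxel triangle surfaces by marching-cubes style
    isosurfacing, estimates resected bone volume, designs mirror-based
    reconstruction templates with marked resection sites, and verifies model
    accuracy by best-fit rigid alignment (ICP) with signed deviation maps
    against a stated tolerance. A synthetic mandible-like CT phantom with
    analytic ground truth makes every stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, tools, Rcpp, jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), RNifti, yaml, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
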