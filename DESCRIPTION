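Package: bhqpipe
Title: Brain Healthcare Quotient Scoring and Intervention-Study Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Voxelwise quotient scoring of spatially normalized brain maps
    (gray-matter volume and diffusion fractional anisotropy), atlas-based
    regional aggregation into participant-level Brain Healthcare Quotients
    (GM-BHQ, FA-BHQ), and the complete inferential battery of a two-group
    pre/post intervention design: Time-by-Group mixed ANOVA interactions,
    paired and pooled t-tests, change-score correlations, Fisher r-to-z
    comparison of correlations between groups, Benjamini-Hochberg multiple
    comparison control, and noncentral-t power analysis. Includes a synthetic
    longitudinal neuroimaging cohort generator so that every pipeline stage is
    testable without scanner data, and an end-to-end simulate-score-analyze
    runner with reproducible seeded output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
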