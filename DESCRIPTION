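Package: gastamponade
Title: MRI-Based Quantification of Intraocular Gas Tamponade
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify an intraocular gas tamponade bubble on
    sagittal MRI-like image stacks of a post-vitrectomy eye. Provides a
    synthetic eye-phantom generator with closed-form spherical-cap ground
    truth, Otsu-threshold segmentation of the vitreous cavity and the gas
    bubble with slice-wise integration to a gas-volume percentage, a
    four-part retinal-arc partition (superior/inferior x anterior/posterior,
    split at the ora serrata and the equator) with gas contact rates and
    supraduction-angle measurement in prone and supine postures, and exact
    small-sample rank tests (Wilcoxon signed-rank, Mann-Whitney U) with
    mean-and-standard-error cohort summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
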