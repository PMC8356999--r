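Package: dntopo
Title: Connectivity- and Microstructure-Based Topography of the Dentate Nuclei
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping the internal topography of the cerebellar
    dentate nuclei (DN) from diffusion MRI derivatives on a common voxel
    grid. Builds per-voxel membership vectors from streamline-count
    (track-density) maps and assigns each DN voxel to its most-connected
    target with a winner-takes-all rule; clusters DN voxels by their
    seven-metric diffusion profile (FA, MD, AD, RD, MK, AK, RK) with fuzzy
    c-means and reduces the result to a medial/lateral parcellation;
    combines per-subject parcellations into modal group atlases with
    per-label probability maps; compares atlases with the Dice similarity
    coefficient; and summarises cohorts with nonparametric tests (Wilcoxon
    signed-rank, Friedman, Mann-Whitney). Includes a synthetic-cohort
    generator with planted connectivity bands and microstructural clusters
    so the whole pipeline can be exercised end to end without patient data.
License: MIT
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    stats
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
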