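Package: fusiwall
Title: Wall Enhancement, Hemodynamics and Morphology of Fusiform Aneurysms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Co-analysis of aneurysm wall enhancement, wall hemodynamics and
    centerline morphology for intracranial fusiform aneurysms. Provides mesh,
    centerline, NIfTI volume and pulsatile wall-shear-stress containers with
    readers and writers (STL, PLY, legacy VTK polydata, NIfTI-1); per-vertex
    hemodynamic indices (TAWSS, OSI, GON, RRT) with parent-vessel
    normalization; centerline curvature and torsion morphometrics with
    aneurysm-segment delimitation (D_max, L_max); threshold-based wall
    enhancement segmentation, surface projection and enhancement-ratio maps;
    cohort statistics (one-way ANOVA, Mann-Whitney U, node-wise Spearman
    correlation); and a seeded synthetic cohort generator producing fusiform,
    dolichoectatic and transitional vessel geometries with pulsatile
    wall-shear fields and surrogate post-contrast volumes so the whole
    pipeline runs without clinical inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
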