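Package: migrastat
Title: Quantitative Statistics for Cell Migration, Adhesion Profiling and
    Expression Set Logic
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements the quantitative layer of a combined in vitro / in
    vivo cell-migration study of E-cadherin missense variants: single-cell
    trajectory statistics (travelled distance, instantaneous speed,
    time-averaged mean-squared displacement, diffusion-coefficient
    estimation via MSD = 4Dt, straightness), collective wound-front
    statistics from binary mask stacks (gap area, closure rate, time to
    fractional closure, front velocity, leading-edge extraction and
    edge-regularity variance), border-cell cluster morphometrics (migration
    index, principal-axis extents, isosurface surface area, volume, Wadell
    sphericity), ECM adhesion-array profiling (replicate means,
    reference-normalised effects, Pearson-correlation similarity and
    distance, per-composition Welch tests), and differential-expression set
    logic (TPM, signed fold change, Welch t with Benjamini-Hochberg FDR,
    annotation filtering, Venn partition). Every input class has a seeded
    synthetic generator with known ground truth, so all statistics are
    testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
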