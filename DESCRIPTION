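Package: eggnir
Title: Egg Composition Characterization and VIS-NIR Calibration for Local
    Chicken Breeds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Characterizes albumen and yolk composition of local chicken
    breeds (one-way ANOVA, Tukey multiple comparisons with compact letter
    displays, white- versus tinted-eggshell contrasts) and develops
    VIS-NIR (400-2500 nm, log(1/R)) calibration models for composition
    traits. Implements the scatter corrections (SNV, SNV-detrend, MSC)
    and gap-segment derivative math treatments of the WinISI tradition,
    standard and modified (Shenk-Westerhaus residual-scaled) partial
    least-squares regression, segmented cross-validation with iterative
    2.5-SD outlier elimination, pretreatment grid search, and the
    SEC/SECV/R2/RPD model statistics used in NIRS calibration reports.
    A synthetic-data module emulates the breed-level study design (8
    breeds, 25 pooled samples of 2 eggs each) and Beer-Lambert style
    reflectance spectra so the whole pipeline is reproducible without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    multcomp,
    ggplot2,
    optparse
Config/testthat/edition: 3
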