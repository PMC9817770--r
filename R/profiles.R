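#' Built-in breed composition profiles
#'
#' Breed-level composition summaries (mean and SD per trait, at the pooled
#' two-egg sample level) for the eight local Veneto chicken breeds covered by
#' this package: Padovana Camosciata (PA-C), Padovana Dorata (PA-G),
#' Polverara Bianca (PO-W), Polverara Nera (PO-B), Pepoi (PP), Ermellinata di
#' Rovigo (ER), Robusta Maculata (RM) and Robusta Lionata (RL). The first
#' four breeds lay white-shell eggs, the last four tinted-shell eggs. Values
#' cover albumen (moisture, protein, ash; wet and dry basis) and yolk
#' (moisture, protein, lipid, ash, cholesterol; wet and dry basis); units are
#' percent except cholesterol (mg/100 g).
#'
#' These profiles parameterize the synthetic-data generator
#' ([generate_composition()]). Two quirks of the source summaries are kept
#' verbatim rather than corrected: the RL albumen protein on dry basis
#' (88.91 +/- 0.37) is out of line with the other breeds (~84--85) and with
#' its own ash column, and the PP yolk protein (dry basis) SD is read as
#' 0.77. Note the generator *derives* dry-basis values from the wet-basis
#' draws (see [generate_composition()]), so these dry-basis entries serve as
#' reference metadata, not as sampling parameters.
#'
#' @return A list of 8 `breed_profile` objects, each a list with elements
#'   `breed_code`, `shell_group` (`"white"` or `"tinted"`), and `traits`
#'   (data frame with columns `part`, `trait`, `mean`, `sd`).
#' @examples
#' p <- default_profiles()
#' length(p)                       # 8
#' p[["PP"]]$shell_group           # "tinted"
#' @export
default_profiles <- function() {
  tab <- breed_reference_table()
  breeds <- unique(tab$breed)
  out <- lapply(breeds, function(b) {
    rows <- tab[tab$breed == b, c("part", "trait", "mean", "sd")]
    rownames(rows) <- NULL
    structure(list(breed_code = b,
                   shell_group = unique(tab$shell_group[tab$breed == b]),
                   traits = rows),
              class = "breed_profile")
  })
  names(out) <- breeds
  out
}

#' Breed-level reference composition table
#'
#' The long-format table behind [default_profiles()]: one row per
#' breed x part x trait with the pooled-sample mean and SD.
#'
#' @return Data frame with columns `breed`, `shell_group`, `part`, `trait`,
#'   `mean`, `sd`.
#' @export
breed_reference_table <- function() {
  breeds <- c("PA-C", "PA-G", "PO-W", "PO-B", "PP", "ER", "RM", "RL")
  shell <- c(rep("white", 4L), rep("tinted", 4L))
  row <- function(part, trait, means, sds)
    data.frame(breed = breeds, shell_group = shell, part = part, trait = trait,
               mean = means, sd = sds, stringsAsFactors = FALSE)
  rbind(
    # albumen
    row("albumen", "moisture_pct_wb",
        c(89.48, 88.92, 89.57, 90.06, 88.63, 89.08, 88.90, 88.60),
        c(0.97, 0.68, 1.31, 1.23, 0.88, 1.06, 1.12, 0.78)),
    row("albumen", "protein_pct_wb",
        c(8.81, 9.33, 8.81, 8.34, 9.73, 9.25, 9.44, 9.72),
        c(0.71, 0.48, 1.27, 1.27, 0.71, 0.98, 0.91, 0.61)),
    row("albumen", "ash_pct_wb",
        c(0.69, 0.71, 0.69, 0.67, 0.68, 0.72, 0.69, 0.69),
        c(0.07, 0.04, 0.06, 0.06, 0.06, 0.06, 0.07, 0.05)),
    row("albumen", "protein_pct_dm",
        c(83.88, 84.24, 84.39, 83.94, 85.61, 84.72, 85.09, 88.91),
        c(1.99, 1.73, 1.45, 1.46, 1.29, 2.02, 1.45, 0.37)),
    row("albumen", "ash_pct_dm",
        c(6.57, 6.33, 6.68, 6.75, 6.00, 6.70, 6.24, 6.03),
        c(0.37, 0.32, 0.49, 0.38, 0.39, 0.49, 0.32, 0.36)),
    # yolk
    row("yolk", "moisture_pct_wb",
        c(50.11, 49.40, 48.98, 48.86, 50.08, 48.64, 49.14, 48.55),
        c(0.83, 0.83, 0.72, 0.74, 1.04, 0.85, 0.84, 0.58)),
    row("yolk", "protein_pct_wb",
        c(16.55, 16.35, 16.57, 16.18, 16.08, 16.16, 15.62, 15.21),
        c(0.34, 0.35, 0.31, 0.37, 0.41, 0.35, 1.13, 0.63)),
    row("yolk", "lipid_pct_wb",
        c(32.14, 33.02, 32.83, 33.64, 32.73, 33.54, 34.11, 35.30),
        c(0.93, 0.66, 0.66, 0.79, 1.11, 0.85, 1.12, 0.98)),
    row("yolk", "ash_pct_wb",
        c(1.77, 1.89, 1.71, 1.67, 1.84, 1.74, 1.78, 1.71),
        c(0.12, 0.21, 0.21, 0.24, 0.22, 0.21, 0.09, 0.15)),
    row("yolk", "cholesterol_mg100g_wb",
        c(1243.81, 1284.00, 1227.08, 1317.71, 1406.39, 1319.77, 1262.27, 1308.72),
        c(134.13, 105.79, 71.14, 89.89, 82.34, 143.37, 84.12, 57.24)),
    row("yolk", "protein_pct_dm",
        c(33.17, 32.30, 32.48, 31.65, 32.23, 31.47, 30.70, 29.56),
        c(0.45, 0.68, 0.50, 0.63, 0.77, 0.60, 0.68, 0.77)),
    row("yolk", "lipid_pct_dm",
        c(64.41, 65.23, 64.36, 65.77, 65.66, 65.30, 67.05, 68.60),
        c(1.00, 0.95, 1.03, 1.17, 1.68, 0.89, 1.34, 1.34)),
    row("yolk", "ash_pct_dm",
        c(3.54, 3.73, 3.35, 3.27, 3.69, 3.39, 3.51, 3.33),
        c(0.24, 0.42, 0.38, 0.47, 0.41, 0.38, 0.16, 0.29)),
    row("yolk", "cholesterol_mg100g_dm",
        c(2486.82, 2545.29, 2410.80, 2577.53, 2807.85, 2562.90, 2478.30, 2546.45),
        c(243.33, 200.97, 156.93, 177.32, 124.47, 277.19, 170.47, 95.38))
  )
}

#' Published benchmark calibration statistics
#'
#' The best-model calibration and cross-validation statistics reported for
#' the study system this package models: one row per trait x part x matrix
#' cell with the winning scatter correction and math treatment, number of
#' PLS terms (`t`), retained samples (`n`), reference mean and SD, SEC,
#' R2C, SECV, R2CV and RPDCV. These numbers are used as a benchmark surface
#' (e.g. auditing the RPD = SD/SECV identity) and to document the expected
#' performance ordering; they are not training data.
#'
#' @return Data frame with columns `part`, `matrix`, `trait`, `scatter`,
#'   `math`, `t`, `n`, `mean`, `sd`, `sec`, `r2c`, `secv`, `r2cv`, `rpdcv`.
#' @export
reference_calibration_stats <- function() {
  df <- rbind(
    data.frame(part = "albumen", matrix = "fresh",
               trait = c("dry_matter_pct_wb", "protein_pct_wb", "ash_pct_wb"),
               scatter = c("SNV_D", "NONE", "NONE"),
               math = c("1,4,4,1", "2,5,5,1", "1,4,4,1"),
               t = c(9, 5, 6), n = c(168, 167, 170),
               mean = c(11.07, 9.32, 0.70), sd = c(1.08, 0.87, 0.06),
               sec = c(0.48, 0.43, 0.04), r2c = c(0.81, 0.75, 0.40),
               secv = c(0.57, 0.51, 0.05), r2cv = c(0.73, 0.66, 0.26),
               rpdcv = c(1.91, 1.70, 1.16)),
    data.frame(part = "albumen", matrix = "freeze-dried",
               trait = c("dry_matter_pct", "protein_pct_dm", "ash_pct_dm"),
               scatter = c("MSC", "NONE", "MSC"),
               math = c("1,4,4,1", "1,4,4,1", "0,0,1,1"),
               t = c(5, 6, 9), n = c(176, 170, 176),
               mean = c(89.11, 84.65, 6.33), sd = c(1.58, 1.71, 0.48),
               sec = c(0.33, 1.10, 0.28), r2c = c(0.96, 0.58, 0.66),
               secv = c(0.35, 1.18, 0.30), r2cv = c(0.95, 0.52, 0.60),
               rpdcv = c(4.47, 1.45, 1.58)),
    data.frame(part = "yolk", matrix = "fresh",
               trait = c("dry_matter_pct_wb", "protein_pct_wb", "lipid_pct_wb",
                         "ash_pct_wb", "cholesterol_mg100g_wb"),
               scatter = c("NONE", "NONE", "SNV_D", "NONE", "MSC"),
               math = c("2,5,5,1", "1,4,4,1", "2,5,5,1", "0,0,1,1", "2,5,5,1"),
               t = c(3, 9, 5, 2, 1), n = c(186, 190, 190, 176, 100),
               mean = c(50.93, 16.22, 33.22, 1.73, 1256.77),
               sd = c(0.81, 0.55, 1.14, 0.14, 92.56),
               sec = c(0.60, 0.29, 0.62, 0.13, 81.37),
               r2c = c(0.44, 0.72, 0.70, 0.14, 0.23),
               secv = c(0.65, 0.31, 0.73, 0.13, 84.47),
               r2cv = c(0.36, 0.68, 0.59, 0.13, 0.16),
               rpdcv = c(1.25, 1.75, 1.56, 1.07, 1.10)),
    data.frame(part = "yolk", matrix = "freeze-dried",
               trait = c("dry_matter_pct", "protein_pct_dm", "lipid_pct_dm",
                         "ash_pct_dm", "cholesterol_mg100g_dm"),
               scatter = c("NONE", "NONE", "SNV_D", "SNV_D", "SNV_D"),
               math = c("2,5,5,1", "1,4,4,1", "1,4,4,1", "0,0,1,1", "1,4,4,1"),
               t = c(8, 7, 9, 1, 4), n = c(186, 190, 194, 182, 127),
               mean = c(99.06, 31.92, 65.29, 3.38, 2477.37),
               sd = c(0.80, 1.10, 1.75, 0.28, 177.45),
               sec = c(0.24, 0.30, 0.83, 0.26, 101.29),
               r2c = c(0.91, 0.93, 0.78, 0.14, 0.67),
               secv = c(0.30, 0.32, 0.89, 0.27, 129.14),
               r2cv = c(0.86, 0.92, 0.74, 0.12, 0.48),
               rpdcv = c(2.68, 3.48, 1.98, 1.06, 1.37))
  )
  rownames(df) <- NULL
  df
}
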