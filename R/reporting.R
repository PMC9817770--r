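#' Configuration for a full simulated study run
#'
#' Bundles every knob of the simulate -> calibrate -> stats pipeline into a
#' serializable list. Defaults reproduce the emulated study design: 8
#' breeds x 50 eggs pooled in twos (200 samples), the full 400--2500 nm /
#' 0.5 nm grid, the four scatter corrections crossed with the three math
#' treatments, five CV segments, a maximum of ten PLS terms and the 2.5-SD
#' outlier rule.
#'
#' @param seed Master seed; all stage seeds derive from it.
#' @param eggs_per_breed,pool_size Sampling design (see [study_design()]).
#' @param grid_start,grid_stop,grid_step Wavelength grid (nm).
#' @param scatter_options,math_options Pretreatment grid.
#' @param max_terms,n_segments,outlier_sd,max_passes,variant Calibration
#'   engine settings (see [calibrate_trait()]).
#' @param traits Named list `part -> matrix -> character vector` of trait
#'   columns to calibrate. Defaults to a compact representative set.
#' @param figures Emit boxplot/violin figures when ggplot2 is available.
#' @return List of class `run_config`.
#' @export
study_config <- function(seed = 1L, eggs_per_breed = 50L, pool_size = 2L,
                         grid_start = 400, grid_stop = 2500, grid_step = 0.5,
                         scatter_options = c("NONE", "SNV", "SNV_D", "MSC"),
                         math_options = c("0,0,1,1", "1,4,4,1", "2,5,5,1"),
                         max_terms = 10L, n_segments = 5L, outlier_sd = 2.5,
                         max_passes = 2L, variant = "modified",
                         traits = list(
                           albumen = list(
                             fresh = c("dry_matter_pct_wb", "protein_pct_wb"),
                             "freeze-dried" = c("protein_pct_dm")),
                           yolk = list(
                             fresh = c("protein_pct_wb", "lipid_pct_wb"),
                             "freeze-dried" = c("protein_pct_dm", "lipid_pct_dm"))),
                         figures = FALSE) {
  cfg <- list(seed = as.integer(seed), eggs_per_breed = eggs_per_breed,
              pool_size = pool_size, grid_start = grid_start,
              grid_stop = grid_stop, grid_step = grid_step,
              scatter_options = scatter_options, math_options = math_options,
              max_terms = max_terms, n_segments = n_segments,
              outlier_sd = outlier_sd, max_passes = max_passes,
              variant = variant, traits = traits, figures = figures)
  class(cfg) <- "run_config"
  validate_config(cfg)
  cfg
}

#' @rdname study_config
#' @param config A `run_config` to validate; errors carry a `stage:` tag.
#' @export
validate_config <- function(config) {
  bad <- setdiff(config$scatter_options, c("NONE", "SNV", "SNV_D", "MSC"))
  if (length(bad))
    stop(sprintf("config: unknown scatter correction(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  for (m in config$math_options) parse_math_treatment(m)
  if (!config$variant %in% c("modified", "standard"))
    stop("config: variant must be 'modified' or 'standard'", call. = FALSE)
  if (config$eggs_per_breed %% config$pool_size != 0)
    stop("config: eggs_per_breed must be divisible by pool_size", call. = FALSE)
  for (part in names(config$traits))
    if (!part %in% c("albumen", "yolk"))
      stop(sprintf("config: unknown part '%s'", part), call. = FALSE)
  invisible(config)
}

#' Render a calibration result table
#'
#' Formats a [grid_search()]/[calibrate_trait()] result in the layout of
#' classic NIRS calibration reports: Math (serialized pretreatment), T, n,
#' Mean, SD, SE_C, R2_C, SE_cv, R2_cv, RPD_cv; ratios to 2 decimals,
#' errors to 4 significant digits.
#'
#' @param results A `calibration_grid` data frame (non-empty).
#' @param path Optional CSV output path.
#' @return The formatted data frame, invisibly if `path` is given.
#' @export
render_calibration_table <- function(results, path = NULL) {
  if (!NROW(results))
    stop("no calibration results to render", call. = FALSE)
  out <- data.frame(
    trait = if ("trait" %in% names(results)) results$trait else NA_character_,
    Math = paste0(results$scatter, "/", vapply(results$math, function(m)
      parse_math_treatment(m)$code, character(1L))),
    T = results$n_terms, n = results$n,
    Mean = signif(results$mean, 6L), SD = signif(results$sd, 4L),
    SE_C = signif(results$sec, 4L), R2_C = round(results$r2c, 2L),
    SE_cv = signif(results$secv, 4L), R2_cv = round(results$r2cv, 2L),
    RPD_cv = round(results$rpdcv, 2L),
    stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    return(invisible(out))
  }
  out
}

#' Run the full simulated study
#'
#' End-to-end orchestration: generate composition tables for both egg parts,
#' simulate spectra for both matrices, compute breed-level ANOVA/Tukey
#' summary tables and the white-versus-tinted contrasts, and develop
#' calibration models for the configured traits. All outputs are plain CSV
#' (plus the archived config as JSON); the run is deterministic given
#' `config$seed`.
#'
#' @param config A [study_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the generated objects and file paths.
#' @export
run_full_study <- function(config = study_config(), out_dir) {
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(...) file.path(out_dir, paste0(...))
  jsonlite::write_json(unclass(config), pth("config.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  grid <- make_grid(config$grid_start, config$grid_stop, config$grid_step)
  libs <- list(
    albumen = default_component_library(grid, analytes = c("protein", "ash")),
    yolk = default_component_library(grid))
  design <- study_design(eggs_per_breed = config$eggs_per_breed,
                         pool_size = config$pool_size, seed = config$seed)
  files <- character(0)
  out <- list(composition = list(), spectra = list(), calibration = list(),
              stats = list(), contrasts = list())

  for (part in c("albumen", "yolk")) {
    message(sprintf("stage simulate: generating %s composition", part))
    comp <- generate_composition(design, part = part)
    out$composition[[part]] <- comp
    f <- pth("composition_", part, ".csv")
    write_composition_csv(comp, f); files <- c(files, f)

    message(sprintf("stage stats: ANOVA/Tukey summary for %s (%d samples)",
                    part, nrow(comp)))
    traits_all <- grep("_(wb|dm)$", names(comp), value = TRUE)
    summ <- composition_summary_table(comp, traits_all)
    f <- pth("summary_", part, ".csv")
    utils::write.csv(summ, f); files <- c(files, f)
    out$stats[[part]] <- summ

    contr <- do.call(rbind, lapply(traits_all, function(tr) {
      cc <- shell_group_contrast(comp, tr)
      data.frame(part = part, trait = tr,
                 mean_white = cc$group_stats$mean[cc$group_stats$group == "white"],
                 mean_tinted = cc$group_stats$mean[cc$group_stats$group == "tinted"],
                 f = cc$f_statistic, p = cc$p_value, stars = cc$stars,
                 stringsAsFactors = FALSE)
    }))
    f <- pth("contrast_", part, ".csv")
    utils::write.csv(contr, f, row.names = FALSE); files <- c(files, f)
    out$contrasts[[part]] <- contr
    if (isTRUE(config$figures) && requireNamespace("ggplot2", quietly = TRUE))
      .contrast_figure(comp, part, pth("contrast_", part, ".pdf"))

    for (mt in c("fresh", "freeze-dried")) {
      message(sprintf("stage simulate: %s %s spectra", mt, part))
      sp <- generate_spectra(comp, libs[[part]], matrix_type = mt,
                             seed = config$seed + 17L * (part == "yolk"))
      out$spectra[[paste(part, mt, sep = "_")]] <- sp
      f <- pth("spectra_", part, "_", sub("-", "_", mt), ".csv")
      write_spectra_csv(sp, f); files <- c(files, f)

      traits_cal <- config$traits[[part]][[mt]]
      if (length(traits_cal)) {
        res <- do.call(rbind, lapply(traits_cal, function(tr) {
          message(sprintf("stage calibrate: %s %s %s (%d grid cells)",
                          mt, part, tr,
                          length(config$scatter_options) *
                            length(config$math_options)))
          calibrate_trait(sp, comp, tr,
                          scatter_options = config$scatter_options,
                          math_options = config$math_options,
                          max_terms = config$max_terms,
                          n_segments = config$n_segments,
                          outlier_sd = config$outlier_sd,
                          max_passes = config$max_passes,
                          seed = config$seed, variant = config$variant)
        }))
        key <- paste(part, mt, sep = "_")
        out$calibration[[key]] <- res
        f <- pth("calibration_", part, "_", sub("-", "_", mt), ".csv")
        render_calibration_table(res, f); files <- c(files, f)
      }
    }
  }
  out$files <- files
  invisible(out)
}

# Boxplot + violin + mean dash of the wet-basis traits by shell group,
# in the style of the classic two-group composition figures.
.contrast_figure <- function(comp, part, path) {
  traits <- grep("_wb$", names(comp), value = TRUE)
  long <- do.call(rbind, lapply(traits, function(tr)
    data.frame(trait = tr, shell_group = comp$shell_group,
               value = comp[[tr]], stringsAsFactors = FALSE)))
  gg <- ggplot2::ggplot(long, ggplot2::aes(x = .data$shell_group,
                                           y = .data$value,
                                           fill = .data$shell_group)) +
    ggplot2::geom_violin(alpha = 0.4, color = NA) +
    ggplot2::geom_boxplot(width = 0.25, outlier.size = 0.5) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 95, size = 6,
                          color = "red") +
    ggplot2::facet_wrap(~trait, scales = "free_y") +
    ggplot2::labs(title = sprintf("%s composition by eggshell color", part),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
  ggplot2::ggsave(path, gg, width = 8, height = 6)
  invisible(path)
}
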