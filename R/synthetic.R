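#' Define the sampling design of a simulated egg-composition study
#'
#' The design mirrors the field protocol this package emulates: a fixed set
#' of breeds, `eggs_per_breed` eggs collected per breed, and pooling of
#' `pool_size` eggs into one laboratory sample, so each breed contributes
#' `eggs_per_breed / pool_size` pooled samples. Defaults (8 breeds, 50 eggs,
#' pools of 2) yield 200 pooled samples from 400 eggs.
#'
#' @param breeds List of breed profiles, as returned by [default_profiles()].
#' @param eggs_per_breed Eggs collected per breed; must be divisible by
#'   `pool_size`.
#' @param pool_size Eggs pooled into one sample.
#' @param seed Integer seed for all composition draws.
#'
#' @return An object of class `study_design`.
#' @export
study_design <- function(breeds = default_profiles(), eggs_per_breed = 50L,
                         pool_size = 2L, seed = 1L) {
  if (eggs_per_breed < 1L || pool_size < 1L)
    stop("eggs_per_breed and pool_size must be positive", call. = FALSE)
  if (eggs_per_breed %% pool_size != 0L)
    stop(sprintf("eggs_per_breed (%d) is not divisible by pool_size (%d)",
                 eggs_per_breed, pool_size), call. = FALSE)
  for (b in breeds) {
    if (!all(is.finite(b$traits$sd)) || any(b$traits$sd < 0))
      stop(sprintf("breed profile %s has a negative or non-finite SD",
                   b$breed_code), call. = FALSE)
  }
  structure(list(breeds = breeds, eggs_per_breed = as.integer(eggs_per_breed),
                 pool_size = as.integer(pool_size), seed = as.integer(seed)),
            class = "study_design")
}

#' Simulate a pooled-sample composition table
#'
#' Draws egg-level trait values and pools them into laboratory samples. For
#' each breed, the *solute* wet-basis traits (protein, ash, and for yolk
#' lipid and cholesterol) are independent normal draws with the profile mean
#' and an egg-level SD of `profile SD * sqrt(pool_size)`, so that pooled
#' samples (means of `pool_size` eggs) reproduce the profile SDs, which
#' describe the pooled-sample level. Moisture is then derived by mass
#' closure, `moisture = 100 - (protein + ash [+ lipid]) - r_b`, where `r_b`
#' is the breed's constant inert remainder implied by the profile means
#' (cholesterol is a lipid subfraction and is excluded from the closure).
#' This keeps moisture anti-correlated with the solutes, as it is in real
#' compositional data, so both wet- and dry-basis traits have realistic
#' dispersion. Dry-basis values are derived, not drawn:
#' `dry_matter_pct_wb = 100 - moisture_pct_wb` and
#' `x_dm = 100 * x_wb / dry_matter_pct_wb` (cholesterol analogously, in
#' mg/100 g). Negative egg-level draws are clipped at a small positive floor
#' with a warning.
#'
#' @param design A [study_design()].
#' @param part `"albumen"` or `"yolk"`; trait sets differ between parts.
#'
#' @return Data frame with one row per pooled sample: `sample_id`, `breed`,
#'   `shell_group`, `matrix` (`"reference"`; chemistry is measured once),
#'   `part`, then the trait columns (`*_pct_wb`, `dry_matter_pct_wb`,
#'   `*_pct_dm`, cholesterol in `mg100g`).
#' @examples
#' comp <- generate_composition(study_design(seed = 7), part = "albumen")
#' nrow(comp)  # 200
#' @export
generate_composition <- function(design, part = c("albumen", "yolk")) {
  part <- match.arg(part)
  stopifnot(inherits(design, "study_design"))
  n_pool <- design$eggs_per_breed %/% design$pool_size
  # independent stream per part so albumen and yolk tables are uncorrelated
  set.seed(design$seed + 131L * (part == "yolk"))
  clipped <- 0L
  per_breed <- lapply(design$breeds, function(prof) {
    tr <- prof$traits[prof$traits$part == part, ]
    wb <- tr[grepl("_wb$", tr$trait), ]
    if (!nrow(wb))
      stop(sprintf("profile %s has no wet-basis traits for part '%s'",
                   prof$breed_code, part), call. = FALSE)
    solutes <- wb[wb$trait != "moisture_pct_wb", ]
    pooled <- sapply(seq_len(nrow(solutes)), function(i) {
      eggs <- stats::rnorm(design$eggs_per_breed, solutes$mean[i],
                           solutes$sd[i] * sqrt(design$pool_size))
      neg <- eggs < 1e-6
      if (any(neg)) {
        clipped <<- clipped + sum(neg)
        eggs[neg] <- 1e-6
      }
      colMeans(matrix(eggs, nrow = design$pool_size))
    })
    pooled <- matrix(pooled, nrow = n_pool,
                     dimnames = list(NULL, solutes$trait))
    # moisture by mass closure; cholesterol (mg/100 g) is a lipid
    # subfraction, not an extra solute
    closure <- grep("_pct_wb$", colnames(pooled), value = TRUE)
    m_mean <- wb$mean[wb$trait == "moisture_pct_wb"]
    remainder <- 100 - m_mean - sum(solutes$mean[solutes$trait %in% closure])
    moisture <- 100 - rowSums(pooled[, closure, drop = FALSE]) - remainder
    pooled <- cbind(moisture_pct_wb = moisture, pooled)
    df <- data.frame(
      sample_id = sprintf("%s_%s%02d", prof$breed_code,
                          toupper(substr(part, 1L, 1L)), seq_len(n_pool)),
      breed = prof$breed_code, shell_group = prof$shell_group,
      matrix = "reference", part = part, stringsAsFactors = FALSE)
    cbind(df, as.data.frame(pooled))
  })
  out <- do.call(rbind, per_breed)
  rownames(out) <- NULL
  if (clipped > 0L)
    warning(sprintf("%d negative egg-level draw(s) clipped at the positive floor",
                    clipped), call. = FALSE)
  out$dry_matter_pct_wb <- 100 - out$moisture_pct_wb
  for (wbcol in setdiff(grep("_wb$", names(out), value = TRUE),
                        c("moisture_pct_wb", "dry_matter_pct_wb"))) {
    dmcol <- sub("_wb$", "_dm", wbcol)
    out[[dmcol]] <- 100 * out[[wbcol]] / out$dry_matter_pct_wb
  }
  attr(out, "design_seed") <- design$seed
  out
}

#' Pure-component band library for spectra simulation
#'
#' Describes how composition maps to absorbance: each analyte contributes a
#' non-negative pure-component curve (a sum of Gaussian bands) scaled by its
#' concentration, water contributes a dominant band scaled by moisture and a
#' matrix-dependent weight, and every spectrum receives a fixed baseline
#' continuum plus random multiplicative/additive scatter, a random quadratic
#' baseline, and i.i.d. channel noise.
#'
#' @param grid Wavelength grid ([make_grid()]).
#' @param components Named list mapping trait analyte (`"protein"`,
#'   `"lipid"`, `"ash"`, `"cholesterol"`, ...) to a numeric absorbance curve
#'   on `grid` (AU per unit mass fraction).
#' @param water_band Absorbance curve of water on `grid`.
#' @param baseline Fixed continuum absorbance curve added to every spectrum
#'   (default: zero).
#' @param water_weight Named numeric, weight of the water term in each
#'   matrix: `c(fresh = ..., "freeze-dried" = ...)`. A large fresh weight
#'   makes the water band dominate the spectrum, emulating the masking of
#'   solute bands in high-moisture matrices.
#' @param scatter List with elements `mult_sd` (SD of the multiplicative
#'   slope), `add_sd` (SD of the additive offset, AU) and `curve_sd` (SD of
#'   the quadratic baseline amplitude, AU).
#' @param noise_sd SD of the i.i.d. channel noise (AU).
#' @param water_jitter_sd SD (mass-fraction units) of a per-sample random
#'   perturbation of the water term, scaled by the matrix water weight. It
#'   emulates the instability of moisture in samples exposed to ambient air
#'   during acquisition (evaporation, surface drying): large in practice for
#'   fresh matrices, negligible for freeze-dried ones because the water
#'   weight is small.
#'
#' @return An object of class `component_library`.
#' @seealso [default_component_library()] for ready-made curves.
#' @export
component_library <- function(grid, components, water_band,
                              baseline = numeric(length(grid)),
                              water_weight = c(fresh = 1, "freeze-dried" = 0.05),
                              scatter = list(mult_sd = 0.03, add_sd = 0.02,
                                             curve_sd = 0.01),
                              noise_sd = 0.002, water_jitter_sd = 0.01) {
  p <- length(grid)
  curves <- c(components, list(.water = water_band, .baseline = baseline))
  for (nm in names(curves)) {
    cv <- curves[[nm]]
    if (length(cv) != p)
      stop(sprintf("curve '%s' is not defined on the shared grid", nm),
           call. = FALSE)
    if (any(!is.finite(cv)) || any(cv < 0))
      stop(sprintf("curve '%s' must be finite and non-negative", nm),
           call. = FALSE)
  }
  if (!all(c("fresh", "freeze-dried") %in% names(water_weight)))
    stop("water_weight must name both 'fresh' and 'freeze-dried'", call. = FALSE)
  structure(list(grid = as.numeric(grid), components = components,
                 water_band = water_band, baseline = baseline,
                 water_weight = water_weight, scatter = scatter,
                 noise_sd = noise_sd, water_jitter_sd = water_jitter_sd),
            class = "component_library")
}

#' Sum-of-Gaussians absorbance curve
#'
#' @param grid Wavelength grid (nm).
#' @param centers,widths,heights Equal-length vectors of band center (nm),
#'   Gaussian SD (nm) and peak height (AU).
#' @return Numeric absorbance curve on `grid`.
#' @export
gaussian_bands <- function(grid, centers, widths, heights) {
  stopifnot(length(centers) == length(widths),
            length(centers) == length(heights))
  g <- as.numeric(grid)
  out <- numeric(length(g))
  for (i in seq_along(centers))
    out <- out + heights[i] * exp(-(g - centers[i])^2 / (2 * widths[i]^2))
  out
}

#' Default component library with canonical NIR band assignments
#'
#' Band positions follow the standard NIR assignments: water O-H at ~1450
#' and ~1940 nm (plus weak visible-region overtones), protein amide/N-H
#' combination bands at ~1510 and 2050--2180 nm, lipid C-H at ~1730/1765 and
#' 2310/2350 nm, and a weak sterol C-H band near 1700 nm for cholesterol.
#' Ash has no VIS-NIR signature (inorganic material does not absorb in this
#' range) and is deliberately given a zero curve, so its unpredictability
#' emerges naturally. A gently sloping baseline continuum emulates the
#' scattering background of reflectance measurements.
#'
#' @param grid Wavelength grid ([make_grid()]).
#' @param analytes Which analyte curves to include; the library must match
#'   the trait set of the composition table it will be paired with
#'   (albumen: protein + ash, yolk: all four).
#' @inheritParams component_library
#' @return A [component_library()].
#' @export
default_component_library <- function(grid = make_grid(),
                                      analytes = c("protein", "lipid", "ash",
                                                   "cholesterol"),
                                      water_weight = c(fresh = 1,
                                                       "freeze-dried" = 0.05),
                                      scatter = list(mult_sd = 0.03,
                                                     add_sd = 0.02,
                                                     curve_sd = 0.01),
                                      noise_sd = 0.002,
                                      water_jitter_sd = 0.01) {
  g <- as.numeric(grid)
  all_components <- list(
    protein = gaussian_bands(g, c(1510, 1680, 2055, 2180),
                             c(40, 40, 30, 35), c(0.20, 0.15, 0.55, 0.45)),
    lipid = gaussian_bands(g, c(1210, 1730, 1765, 2310, 2350),
                           c(30, 25, 25, 25, 25),
                           c(0.15, 0.50, 0.30, 0.55, 0.35)),
    ash = numeric(length(g)),
    cholesterol = gaussian_bands(g, 1700, 20, 0.40))
  analytes <- match.arg(analytes, names(all_components), several.ok = TRUE)
  component_library(
    grid = g,
    components = all_components[analytes],
    water_band = gaussian_bands(g, c(970, 1190, 1450, 1940),
                                c(35, 40, 45, 50), c(0.15, 0.08, 1.0, 1.6)),
    baseline = 0.35 + 0.10 * (g - min(g)) / diff(range(g)),
    water_weight = water_weight, scatter = scatter, noise_sd = noise_sd,
    water_jitter_sd = water_jitter_sd)
}

#' Simulate VIS-NIR spectra paired to a composition table
#'
#' Builds one log(1/R)-style spectrum per pooled sample as a Beer-Lambert
#' mixture: the sum over analytes of concentration times pure-component
#' curve, plus a water term `water_weight[matrix] * moisture/100 *
#' water_band`, plus the fixed baseline continuum. Each spectrum is then
#' multiplied by `(1 + m_i)` (random scatter slope), shifted by a random
#' offset and a random quadratic baseline, and perturbed by i.i.d. channel
#' noise. Concentrations come from the wet-basis trait columns for the
#' `"fresh"` matrix and the dry-basis columns for `"freeze-dried"`
#' (cholesterol mg/100 g is converted to a mass fraction).
#'
#' @param comp Composition table from [generate_composition()].
#' @param lib A [component_library()].
#' @param matrix_type `"fresh"` or `"freeze-dried"`.
#' @param seed Integer seed for scatter and noise draws.
#'
#' @return A [spectra_set] with one spectrum per row of `comp`, ids matching
#'   `comp$sample_id`.
#' @export
generate_spectra <- function(comp, lib, matrix_type = c("fresh", "freeze-dried"),
                             seed = 1L) {
  matrix_type <- match.arg(matrix_type)
  stopifnot(inherits(lib, "component_library"))
  suffix <- if (matrix_type == "fresh") "wb" else "dm"
  n <- nrow(comp)
  p <- length(lib$grid)
  conc <- matrix(0, n, length(lib$components),
                 dimnames = list(NULL, names(lib$components)))
  for (nm in names(lib$components)) {
    col <- paste0(nm, "_pct_", suffix)
    col_mg <- paste0(nm, "_mg100g_", suffix)
    if (col %in% names(comp)) {
      conc[, nm] <- comp[[col]] / 100
    } else if (col_mg %in% names(comp)) {
      conc[, nm] <- comp[[col_mg]] / 1e5  # mg/100 g -> mass fraction
    } else {
      stop(sprintf("trait '%s' of the component library is missing from the composition table",
                   nm), call. = FALSE)
    }
  }
  if (!"moisture_pct_wb" %in% names(comp))
    stop("composition table lacks 'moisture_pct_wb' needed for the water term",
         call. = FALSE)
  comp_mat <- do.call(cbind, lapply(names(lib$components),
                                    function(nm) lib$components[[nm]]))
  base <- conc %*% t(comp_mat)  # n x p analyte mixture
  ww <- lib$water_weight[[matrix_type]]
  set.seed(seed + 977L * (matrix_type == "freeze-dried"))
  # moisture instability at scan time (ambient evaporation); scales with
  # the water weight, so it is negligible in the freeze-dried matrix
  jitter <- stats::rnorm(n, 0, lib$water_jitter_sd %||% 0)
  base <- base + (ww * (comp$moisture_pct_wb / 100 + jitter)) %o% lib$water_band
  base <- base + matrix(lib$baseline, n, p, byrow = TRUE)
  m_i <- stats::rnorm(n, 0, lib$scatter$mult_sd)
  a_i <- stats::rnorm(n, 0, lib$scatter$add_sd)
  c_i <- stats::rnorm(n, 0, lib$scatter$curve_sd)
  gmid <- (lib$grid - mean(range(lib$grid))) / (diff(range(lib$grid)) / 2)
  vals <- base * (1 + m_i) + a_i + c_i %o% (gmid^2)
  if (lib$noise_sd > 0)
    vals <- vals + matrix(stats::rnorm(n * p, 0, lib$noise_sd), n, p)
  spectra_set(vals, lib$grid, sample_id = comp$sample_id)
}
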