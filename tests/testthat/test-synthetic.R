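test_that("built-in breed profiles carry the reference values", {
  p <- default_profiles()
  expect_length(p, 8L)
  shells <- vapply(p, `[[`, character(1L), "shell_group")
  expect_identical(sum(shells == "white"), 4L)
  expect_identical(sum(shells == "tinted"), 4L)
  expect_identical(names(which(shells == "white")),
                   c("PA-C", "PA-G", "PO-W", "PO-B"))

  tr <- p[["PP"]]$traits
  chol <- tr[tr$part == "yolk" & tr$trait == "cholesterol_mg100g_wb", ]
  expect_equal(chol$mean, 1406.39)
  expect_equal(chol$sd, 82.34)
  tr2 <- p[["PO-B"]]$traits
  mo <- tr2[tr2$part == "albumen" & tr2$trait == "moisture_pct_wb", ]
  expect_equal(mo$mean, 90.06)
  expect_equal(mo$sd, 1.23)
})

test_that("study design validates pooling and SDs", {
  expect_error(study_design(eggs_per_breed = 51, pool_size = 2),
               "not divisible")
  prof <- default_profiles()[["PA-C"]]
  prof$traits$sd[1] <- -0.1
  expect_error(study_design(breeds = list(prof)), "negative")
})

test_that("composition has the design cardinality and is reproducible", {
  comp <- generate_composition(study_design(seed = 5))
  expect_identical(nrow(comp), 200L)            # 400 eggs pooled in twos
  expect_identical(as.integer(table(comp$breed)[["PP"]]), 25L)
  comp2 <- generate_composition(study_design(seed = 5))
  expect_identical(comp, comp2)
  comp3 <- generate_composition(study_design(seed = 6))
  expect_false(identical(comp, comp3))

  # other designs follow sum(eggs/pool)
  d <- study_design(breeds = default_profiles()[1:4], eggs_per_breed = 20,
                    pool_size = 4, seed = 1)
  expect_identical(nrow(generate_composition(d)), 20L)
})

test_that("zero SDs give samples exactly at the profile means", {
  comp <- generate_composition(one_breed_design(sd_scale = 0))
  prof <- default_profiles()[["PA-C"]]$traits
  pm <- function(tr) prof$mean[prof$part == "albumen" & prof$trait == tr]
  expect_equal(unique(comp$protein_pct_wb), pm("protein_pct_wb"))
  expect_equal(unique(comp$ash_pct_wb), pm("ash_pct_wb"))
  expect_equal(unique(comp$moisture_pct_wb), pm("moisture_pct_wb"))
})

test_that("wet and dry basis are coherent and pooled SDs match profiles", {
  comp <- generate_composition(study_design(seed = 9), part = "yolk")
  expect_equal(comp$moisture_pct_wb + comp$dry_matter_pct_wb,
               rep(100, nrow(comp)))
  expect_equal(comp$protein_pct_dm,
               100 * comp$protein_pct_wb / comp$dry_matter_pct_wb)

  # Monte-Carlo: pooled-sample SD ~ profile SD (egg SD = profile SD * sqrt(2))
  d <- one_breed_design(eggs = 4000, pool = 2, seed = 3)
  comp1 <- generate_composition(d)
  expect_equal(sd(comp1$protein_pct_wb), 0.71, tolerance = 0.05)
  expect_equal(sd(comp1$ash_pct_wb), 0.07, tolerance = 0.06)
})

test_that("spectra generation is Beer-Lambert linear and grid-aligned", {
  g <- make_grid(1400, 1800, 2)
  band <- gaussian_bands(g, 1600, 30, 1)
  lib <- component_library(g,
    components = list(protein = band, ash = numeric(length(g))),
    water_band = numeric(length(g)),
    scatter = list(mult_sd = 0, add_sd = 0, curve_sd = 0), noise_sd = 0,
    water_jitter_sd = 0)
  comp <- generate_composition(one_breed_design(eggs = 10, seed = 4))
  sp <- generate_spectra(comp, lib, "fresh", seed = 4)
  expect_identical(n_spectra(sp), nrow(comp))
  expect_length(sp$wavelength, length(g))
  # pure proportionality to the single active analyte
  ratio <- sp$values %*% band / sum(band^2)  # projection coefficient
  expect_equal(as.numeric(ratio), comp$protein_pct_wb / 100, tolerance = 1e-10)

  # linearity in composition: spectrum(a*c1 + b*c2) = a*s1 + b*s2
  c1 <- comp; c2 <- comp
  c2$protein_pct_wb <- rev(comp$protein_pct_wb)
  mix <- comp
  mix$protein_pct_wb <- 0.3 * c1$protein_pct_wb + 0.7 * c2$protein_pct_wb
  mix$moisture_pct_wb <- 0.3 * c1$moisture_pct_wb + 0.7 * c2$moisture_pct_wb
  s_mix <- generate_spectra(mix, lib, "fresh", seed = 4)
  s1 <- generate_spectra(c1, lib, "fresh", seed = 4)
  s2 <- generate_spectra(c2, lib, "fresh", seed = 4)
  expect_equal(s_mix$values, 0.3 * s1$values + 0.7 * s2$values,
               tolerance = 1e-12)
})

test_that("fresh matrix has the larger water band; runs are seeded", {
  d <- yolk_dataset(seed = 8, eggs = 10)
  w <- which(d$lib$grid > 1900 & d$lib$grid < 1980)
  expect_gt(mean(d$fresh$values[, w]), mean(d$fd$values[, w]))
  # determinism
  again <- generate_spectra(d$comp, d$lib, "fresh", seed = 8)
  expect_identical(again$values, d$fresh$values)

  # library trait missing from the table is an explicit error
  comp_al <- generate_composition(study_design(eggs_per_breed = 10, seed = 1))
  expect_error(generate_spectra(comp_al, d$lib, "fresh", seed = 1),
               "missing from the composition table")
})
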