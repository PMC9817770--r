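test_that("cross-validation plans are balanced and seeded", {
  p <- make_cv_plan(sprintf("s%02d", 1:10), 5, seed = 3)
  expect_identical(sort(as.integer(table(p$assignment))), rep(2L, 5))
  p200 <- make_cv_plan(sprintf("s%03d", 1:200), 5, seed = 3)
  expect_identical(as.integer(table(p200$assignment)), rep(40L, 5))
  p200b <- make_cv_plan(sprintf("s%03d", 1:200), 5, seed = 3)
  expect_identical(p200$assignment, p200b$assignment)
  # sizes differ by at most one when unbalanced
  p7 <- make_cv_plan(sprintf("s%d", 1:17), 5, seed = 1)
  expect_lte(diff(range(table(p7$assignment))), 1)
  expect_error(make_cv_plan(c("a", "b"), 5), "fewer samples")
})

test_that("a noise-free linear trait cross-validates perfectly", {
  d <- yolk_dataset(seed = 21, eggs = 20)
  g <- coarse_grid()
  band <- gaussian_bands(g, 1700, 50, 1)
  lib0 <- component_library(g,
    components = list(protein = band, lipid = numeric(length(g)),
                      ash = numeric(length(g)),
                      cholesterol = numeric(length(g))),
    water_band = numeric(length(g)),
    scatter = list(mult_sd = 0, add_sd = 0, curve_sd = 0),
    noise_sd = 0, water_jitter_sd = 0)
  sp <- generate_spectra(d$comp, lib0, "fresh", seed = 21)
  plan <- make_cv_plan(d$comp$sample_id, 5, seed = 1)
  cv <- cross_validate(sp, d$comp$protein_pct_wb,
                       pretreatment_spec("NONE", "0,0,1,1"), plan,
                       n_terms = 1, variant = "standard")
  expect_gt(cv$statistics$r2cv, 0.999)
  expect_lt(cv$statistics$secv, 1e-3)
})

test_that("pure-noise responses give R2CV near zero and RPD near one", {
  set.seed(22)
  s <- random_set(1000, grid = make_grid(400, 500, 5), seed = 22)
  y <- rnorm(1000)
  plan <- make_cv_plan(sample_ids(s), 5, seed = 2)
  cv <- cross_validate(s, y, pretreatment_spec("NONE", "0,0,1,1"), plan,
                       n_terms = 3)
  expect_lt(cv$statistics$r2cv, 0.05)
  expect_equal(cv$statistics$rpdcv, 1, tolerance = 0.1)
})

test_that("shifting the reference shifts the mean but not SECV", {
  d <- yolk_dataset(seed = 23, eggs = 20)
  plan <- make_cv_plan(d$comp$sample_id, 5, seed = 1)
  spec <- pretreatment_spec("SNV", "1,4,4,1")
  cv1 <- cross_validate(d$fd, d$comp$protein_pct_dm, spec, plan, 4)
  cv2 <- cross_validate(d$fd, d$comp$protein_pct_dm + 5, spec, plan, 4)
  expect_equal(cv2$statistics$mean, cv1$statistics$mean + 5, tolerance = 1e-9)
  expect_equal(cv2$statistics$secv, cv1$statistics$secv, tolerance = 1e-9)
  expect_equal(cv2$statistics$r2cv, cv1$statistics$r2cv, tolerance = 1e-9)
})

test_that("outlier elimination removes injected gross errors only", {
  d <- yolk_dataset(seed = 24, eggs = 20)
  plan <- make_cv_plan(d$comp$sample_id, 5, seed = 1)
  spec <- pretreatment_spec("SNV", "1,4,4,1")
  y <- d$comp$protein_pct_dm

  # clean data + huge threshold: nothing happens
  res <- remove_outliers(d$fd, y, spec, plan, n_terms = 5, threshold_sd = 50)
  expect_identical(nrow(res$removed), 0L)
  expect_identical(res$retained_ids, d$comp$sample_id)

  # max_passes = 0 is the identity
  res0 <- remove_outliers(d$fd, y, spec, plan, n_terms = 5, max_passes = 0)
  expect_identical(nrow(res0$removed), 0L)

  # inject one sample shifted by 10 reference SDs
  y_bad <- y
  y_bad[37] <- y[37] + 10 * sd(y)
  res1 <- remove_outliers(d$fd, y_bad, spec, plan, n_terms = 5,
                          threshold_sd = 2.5, max_passes = 1)
  expect_identical(res1$removed$sample_id, d$comp$sample_id[37])
  expect_identical(res1$removed$pass, 1L)
  expect_error(remove_outliers(d$fd, y, spec, plan, 5, threshold_sd = -1),
               "positive")
})

test_that("grid search covers all cells and ranks by SECV", {
  d <- yolk_dataset(seed = 25, eggs = 20)
  plan <- make_cv_plan(d$comp$sample_id, 5, seed = 1)
  res <- grid_search(d$fd, d$comp$protein_pct_dm,
                     scatter_options = c("NONE", "SNV"),
                     math_options = c("0,0,1,1", "1,4,4,1"),
                     max_terms = 4, plan = plan)
  expect_identical(nrow(res), 4L)
  expect_true(all(diff(res$secv) >= -1e-12))
  expect_true(all(res$rpdcv == res$sd / res$secv))

  # single option in each list
  res1 <- grid_search(d$fd, d$comp$protein_pct_dm, "SNV", "1,4,4,1",
                      max_terms = 3, plan = plan)
  expect_identical(nrow(res1), 1L)
  expect_error(grid_search(d$fd, d$comp$protein_pct_dm, "BAD", "0,0,1,1",
                           plan = plan), "unknown scatter")
})

test_that("a derivative treatment wins when a random baseline masks the raw signal", {
  # analyte encoded in a narrow band, plus large random offset/slope/curve
  # baselines per sample: raw-spectrum correlation is destroyed and a
  # 2-term linear model cannot project out the rank-3 nuisance, while the
  # smoothed first derivative removes it almost entirely
  g <- make_grid(1500, 1900, 2)
  band <- gaussian_bands(g, 1700, 15, 1)
  set.seed(26)
  n <- 60
  conc <- runif(n, 0.2, 0.8)
  x01 <- (as.numeric(g) - 1500) / 400
  nuisance <- outer(rnorm(n, 0, 5), rep(1, length(g))) +
    outer(rnorm(n, 0, 5), x01) + outer(rnorm(n, 0, 5), x01^2)
  vals <- outer(conc, band) + nuisance +
    matrix(rnorm(n * length(g), 0, 0.001), n)
  s <- spectra_set(vals, g, sprintf("s%02d", 1:n))
  plan <- make_cv_plan(sample_ids(s), 5, seed = 1)
  res <- grid_search(s, conc, scatter_options = "NONE",
                     math_options = c("0,0,1,1", "1,4,4,1"),
                     max_terms = 2, plan = plan)
  winner <- parse_math_treatment(res$math[1])
  expect_gte(winner$derivative_order, 1L)
})

test_that("rpd reproduces reported table ratios", {
  expect_equal(round(rpd(1.14, 0.73), 2), 1.56)
  expect_equal(round(rpd(177.45, 129.14), 2), 1.37)
  expect_equal(rpd(2.2, 2.2), 1)
  expect_error(rpd(1, 0), "positive")
})

test_that("calibrate_trait is deterministic end to end", {
  d <- yolk_dataset(seed = 27, eggs = 20)
  r1 <- calibrate_trait(d$fd, d$comp, "protein_pct_dm",
                        scatter_options = "SNV_D", math_options = "1,4,4,1",
                        max_terms = 4, seed = 5)
  r2 <- calibrate_trait(d$fd, d$comp, "protein_pct_dm",
                        scatter_options = "SNV_D", math_options = "1,4,4,1",
                        max_terms = 4, seed = 5)
  expect_identical(r1, r2)
  expect_identical(r1$trait[1], "protein_pct_dm")
})
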