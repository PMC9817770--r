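test_that("normality screen behaves as a calibrated test", {
  set.seed(31)
  # type-I error near alpha for normal samples
  rejections <- mean(replicate(400, {
    normality_check(rnorm(200))$p_value < 0.05
  }))
  expect_lt(abs(rejections - 0.05), 0.035)
  # near-certain rejection of a strongly lognormal sample
  power <- mean(replicate(50, {
    normality_check(rlnorm(200, sdlog = 1))$p_value < 0.05
  }))
  expect_gte(power, 0.99)
  expect_error(normality_check(c(1, 2)), "at least 3")
  expect_error(normality_check(rep(1, 10)), "constant")
  qq <- normality_check(rnorm(50))$qq
  expect_identical(nrow(qq), 50L)
  expect_false(is.unsorted(qq$sample))
})

test_that("letters exactly encode the Tukey pairwise matrix", {
  comp <- generate_composition(study_design(seed = 32), "yolk")
  for (trait in c("lipid_pct_wb", "ash_pct_wb")) {
    res <- anova_tukey(comp, trait)
    lv <- rownames(res$tukey_p)
    for (i in seq_along(lv)) for (j in seq_along(lv)) {
      if (i >= j) next
      share <- length(intersect(strsplit(res$letters[lv[i]], "")[[1]],
                                strsplit(res$letters[lv[j]], "")[[1]])) > 0
      expect_identical(share, res$tukey_p[lv[i], lv[j]] >= res$alpha,
                       info = sprintf("%s: %s vs %s", trait, lv[i], lv[j]))
    }
  }
})

test_that("letter display matches multcomp's insert-and-absorb", {
  skip_if_not_installed("multcomp")
  comp <- generate_composition(study_design(seed = 33))
  res <- anova_tukey(comp, "protein_pct_wb")
  d <- data.frame(y = comp$protein_pct_wb, g = factor(comp$breed))
  # suppress multcomp's multivariate-t integration precision warning
  cld_ref <- suppressWarnings({
    glht_fit <- multcomp::glht(stats::aov(y ~ g, data = d),
                               linfct = multcomp::mcp(g = "Tukey"))
    multcomp::cld(glht_fit, level = 0.05)$mcletters$Letters
  })
  # same sharing structure (letter labels themselves may differ)
  lv <- names(cld_ref)
  for (i in seq_along(lv)) for (j in seq_along(lv)) {
    if (i >= j) next
    share_ref <- length(intersect(strsplit(cld_ref[[i]], "")[[1]],
                                  strsplit(cld_ref[[j]], "")[[1]])) > 0
    share_own <- length(intersect(strsplit(res$letters[lv[i]], "")[[1]],
                                  strsplit(res$letters[lv[j]], "")[[1]])) > 0
    expect_identical(share_own, share_ref)
  }
})

test_that("identical populations usually share a single letter", {
  prof <- default_profiles()[["PA-C"]]
  breeds <- lapply(c("B1", "B2", "B3", "B4"), function(b) {
    p <- prof; p$breed_code <- b; p
  })
  names(breeds) <- c("B1", "B2", "B3", "B4")
  single <- replicate(60, {
    comp <- generate_composition(
      study_design(breeds = breeds, eggs_per_breed = 50,
                   seed = sample.int(1e6, 1)))
    res <- anova_tukey(comp, "protein_pct_wb")
    all(res$letters == "a")
  })
  expect_gte(mean(single), 0.9)
})

test_that("two-group Tukey equals the pooled two-sample comparison", {
  comp <- generate_composition(study_design(
    breeds = default_profiles()[c("PP", "PO-B")], seed = 35))
  res <- anova_tukey(comp, "protein_pct_wb")
  tt <- t.test(protein_pct_wb ~ breed, data = comp, var.equal = TRUE)
  # with k = 2, Tukey p equals the pooled t-test p and F = t^2
  expect_equal(res$tukey_p["PP", "PO-B"], tt$p.value, tolerance = 1e-8)
  expect_equal(res$f_statistic, unname(tt$statistic)^2, tolerance = 1e-8)
})

test_that("ANOVA results are invariant to row order", {
  comp <- generate_composition(study_design(seed = 36))
  res1 <- anova_tukey(comp, "protein_pct_wb")
  set.seed(1)
  res2 <- anova_tukey(comp[sample(nrow(comp)), ], "protein_pct_wb")
  expect_equal(res1$f_statistic, res2$f_statistic)
  expect_identical(res1$letters, res2$letters)
  expect_error(anova_tukey(comp[comp$breed == "PP", ], "protein_pct_wb"),
               "two groups")
})

test_that("shell contrast matches a two-group ANOVA with monotone stars", {
  comp <- generate_composition(study_design(seed = 37))
  cc <- shell_group_contrast(comp, "protein_pct_wb")
  expect_identical(sort(cc$group_stats$group), c("tinted", "white"))
  expect_identical(cc$stars, significance_stars(cc$p_value))

  # identical groups: no stars expected almost surely
  comp_null <- comp
  set.seed(2)
  comp_null$shell_group <- sample(comp$shell_group)
  many <- replicate(20, {
    comp_null$shell_group <- sample(comp$shell_group)
    shell_group_contrast(comp_null, "ash_pct_wb")$p_value
  })
  expect_gt(mean(many > 0.05), 0.7)

  expect_identical(significance_stars(c(0.0001, 0.005, 0.03, 0.3)),
                   c("***", "**", "*", ""))
  one_per_group <- comp[c(1, 101), ]
  expect_error(shell_group_contrast(one_per_group, "protein_pct_wb"),
               "at least 2")
})

test_that("summary table renders mean +/- sd with letters", {
  comp <- generate_composition(study_design(eggs_per_breed = 10, seed = 38))
  tab <- composition_summary_table(comp, c("protein_pct_wb", "ash_pct_wb"))
  expect_identical(dim(tab), c(2L, 8L))
  expect_match(tab["protein_pct_wb", "PP"], "^[0-9.]+ . [0-9.]+ \\^[a-z]+\\^$")
})
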