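test_that("math treatment codes parse positionally with normalization", {
  t1 <- parse_math_treatment("2,5,5,1")
  expect_identical(t1$derivative_order, 2L)
  expect_identical(t1$gap, 5L)
  expect_identical(t1$smooth1, 5L)
  expect_identical(t1$smooth2, 1L)

  t0 <- parse_math_treatment("0,0,1,1")
  expect_identical(t0$derivative_order, 0L)
  expect_identical(t0$gap, 0L)

  # compact digit form; even smoothing normalized to the next odd size
  t2 <- parse_math_treatment("1441")
  expect_identical(t2$gap, 4L)
  expect_identical(t2$smooth1, 5L)

  expect_error(parse_math_treatment("1,4,4"), "4 fields")
  expect_error(parse_math_treatment("1,4,x,1"), "non-integer")
  expect_error(parse_math_treatment("3,1,1,1"), "not supported")
  expect_error(parse_math_treatment("0,2,1,1"), "gap 0")
  expect_error(parse_math_treatment("1,0,1,1"), "gap of at least 1")
})

test_that("snv standardizes every spectrum and is affine-invariant", {
  expect_equal(snv(c(1, 2, 3)), c(-1, 0, 1))
  s <- random_set(8, seed = 1)
  out <- snv(s)
  expect_equal(rowMeans(out$values), rep(0, 8), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(apply(out$values, 1, sd), rep(1, 8), tolerance = 1e-12,
               ignore_attr = TRUE)
  # affine invariance
  distorted <- spectra_set(2.5 + 1.7 * s$values, s$wavelength, sample_ids(s))
  expect_equal(snv(distorted)$values, out$values, tolerance = 1e-10)
  expect_error(snv(rep(1, 10)), "constant")
})

test_that("detrend annihilates polynomials and composes into SNV_D", {
  wl <- as.numeric(make_grid(400, 500, 1))
  quad <- 2 + 0.01 * wl - 1e-5 * wl^2
  expect_equal(detrend(quad, wl), rep(0, length(wl)), tolerance = 1e-9)

  s <- random_set(4, seed = 2)
  out <- detrend(s)
  basis <- cbind(1, poly(s$wavelength, 2))
  coefs <- qr.coef(qr(basis), t(out$values))
  expect_equal(max(abs(coefs)), 0, tolerance = 1e-9)

  # SNV_D == detrend(snv(.)) against an independently coded composition
  spec <- pretreatment_spec("SNV_D", "0,0,1,1")
  via_pipeline <- apply_pretreatment(s, spec)
  manual <- detrend(snv(s))
  expect_equal(via_pipeline$values, manual$values, tolerance = 1e-12)
})

test_that("msc inverts affine distortions of the reference", {
  s <- random_set(5, seed = 3)
  ref <- colMeans(s$values)
  self <- msc(spectra_set(matrix(ref, 1), s$wavelength, "r"), ref)
  expect_equal(as.numeric(self$values), as.numeric(ref), tolerance = 1e-10)

  distorted <- spectra_set(2 + 3 * matrix(ref, 1), s$wavelength, "d")
  expect_equal(as.numeric(msc(distorted, ref)$values), as.numeric(ref),
               tolerance = 1e-10)

  # toy 4-point case vs hand least squares (2x2 normal equations)
  refv <- c(1, 2, 3, 5)
  sv <- c(2.1, 3.9, 6.2, 9.8)
  n <- 4
  b <- (n * sum(sv * refv) - sum(sv) * sum(refv)) /
    (n * sum(refv^2) - sum(refv)^2)
  a <- mean(sv) - b * mean(refv)
  expect_equal(msc(sv, refv), (sv - a) / b, tolerance = 1e-12)

  expect_error(msc(sv, rep(1, 4)), "constant")
  expect_error(msc(rnorm(4, 0, 1e-14), refv), "degenerate")
})

test_that("gap-segment derivative follows finite-difference algebra", {
  g <- make_grid(400, 600, 1)
  m <- 0.01
  line <- 1 + m * seq_along(g)
  # first derivative of a line with gap gp -> constant 2*gp*m
  for (gp in c(1L, 4L)) {
    out <- gap_segment_derivative(line, math_treatment(1, gp, 1, 1),
                                  wavelength = g)
    expect_equal(unique(round(out, 12)), 2 * gp * m)
    expect_length(out, length(g) - 2 * gp)
  }
  # second derivative of a line is zero
  out2 <- gap_segment_derivative(line, "2,5,5,1", wavelength = g)
  expect_equal(max(abs(out2)), 0, tolerance = 1e-12)
  # identity treatment
  s <- random_set(3, seed = 4)
  ident <- gap_segment_derivative(s, "0,0,1,1")
  expect_equal(ident$values, s$values)
  # linearity of the operator
  t15 <- parse_math_treatment("1,4,4,1")
  a <- gap_segment_derivative(s[1]$values[1, ], t15)
  b <- gap_segment_derivative(s[2]$values[1, ], t15)
  ab <- gap_segment_derivative(2 * s[1]$values[1, ] - 3 * s[2]$values[1, ], t15)
  expect_equal(as.numeric(ab), as.numeric(2 * a - 3 * b), tolerance = 1e-10)
  # support exceeding the grid
  short <- as.numeric(make_grid(400, 404, 1))
  expect_error(gap_segment_derivative(rnorm(5), "2,5,5,1", wavelength = short),
               "support exceeds")
})

test_that("apply_pretreatment is deterministic, id-preserving, and freezes MSC reference", {
  s <- random_set(10, seed = 5)
  spec <- pretreatment_spec("SNV_D", "1,4,4,1")
  a <- apply_pretreatment(s, spec)
  b <- apply_pretreatment(s, spec)
  expect_identical(a$values, b$values)
  expect_identical(sample_ids(a), sample_ids(s))
  expect_identical(n_spectra(a), n_spectra(s))

  none <- apply_pretreatment(s, pretreatment_spec("NONE", "0,0,1,1"))
  expect_equal(none$values, s$values)

  # frozen calibration reference differs from a recomputed subset reference
  spec_msc <- pretreatment_spec("MSC", "0,0,1,1")
  full_ref <- colMeans(s$values)
  sub <- s[1:4]
  frozen <- apply_pretreatment(sub, spec_msc, reference = full_ref)
  refit <- apply_pretreatment(sub, spec_msc)
  expect_false(isTRUE(all.equal(frozen$values, refit$values)))
  expect_equal(attr(frozen, "msc_reference"), full_ref)

  # serialized form round-trips
  expect_identical(format_pretreatment(parse_pretreatment("SNV_D/1,4,4,1")),
                   "SNV_D/1,4,5,1")  # even window normalized to odd
})
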