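#' Parse a 4-digit derivative math treatment code
#'
#' NIRS calibration software encodes derivative pretreatments as four
#' integers "d,g,s1,s2": the derivative order, the gap (in data points) over
#' which the finite difference is taken, and the window sizes of two boxcar
#' smoothing passes applied before differencing. `"0,0,1,1"` is the identity
#' treatment; `"1,4,4,1"` and `"2,5,5,1"` are common first- and
#' second-derivative choices. Codes may be comma-, space- or
#' digit-separated (`"1441"`). Even smoothing windows larger than 1 are
#' normalized up to the next odd size so the boxcar is centered.
#'
#' @param code Character scalar, e.g. `"1,4,4,1"` or `"1441"`.
#' @return An object of class `math_treatment` with fields
#'   `derivative_order`, `gap`, `smooth1`, `smooth2` and the original `code`.
#' @examples
#' parse_math_treatment("2,5,5,1")
#' parse_math_treatment("0011")   # identity
#' @export
parse_math_treatment <- function(code) {
  if (!is.character(code) || length(code) != 1L)
    stop("math treatment code must be a single character string", call. = FALSE)
  txt <- trimws(code)
  parts <- if (grepl("[,; ]", txt)) {
    strsplit(txt, "[,; ]+")[[1L]]
  } else {
    if (nchar(txt) != 4L)
      stop(sprintf("cannot parse math treatment '%s': expected 4 digits", code),
           call. = FALSE)
    strsplit(txt, "")[[1L]]
  }
  parts <- parts[nzchar(parts)]
  if (length(parts) != 4L)
    stop(sprintf("math treatment '%s' must have exactly 4 fields", code),
         call. = FALSE)
  num <- suppressWarnings(as.integer(parts))
  if (anyNA(num) || any(num < 0))
    stop(sprintf("math treatment '%s' has non-integer or negative fields", code),
         call. = FALSE)
  math_treatment(num[1L], num[2L], num[3L], num[4L], code = txt)
}

#' @rdname parse_math_treatment
#' @param derivative_order Derivative order, 0, 1 or 2.
#' @param gap Gap in data points; must be 0 when `derivative_order` is 0 and
#'   at least 1 otherwise.
#' @param smooth1,smooth2 Boxcar window sizes in data points (>= 1).
#' @export
math_treatment <- function(derivative_order, gap, smooth1, smooth2,
                           code = NULL) {
  if (derivative_order > 2L)
    stop("derivative order above 2 is not supported", call. = FALSE)
  if (derivative_order == 0L && gap != 0L)
    stop("derivative order 0 requires gap 0", call. = FALSE)
  if (derivative_order > 0L && gap < 1L)
    stop("a derivative needs a gap of at least 1 point", call. = FALSE)
  if (smooth1 < 1L || smooth2 < 1L)
    stop("smoothing windows must be >= 1 point", call. = FALSE)
  norm_odd <- function(w) if (w > 1L && w %% 2L == 0L) w + 1L else w
  structure(list(derivative_order = as.integer(derivative_order),
                 gap = as.integer(gap),
                 smooth1 = norm_odd(as.integer(smooth1)),
                 smooth2 = norm_odd(as.integer(smooth2)),
                 code = code %||% paste(derivative_order, gap, smooth1, smooth2,
                                        sep = ",")),
            class = "math_treatment")
}

#' @export
print.math_treatment <- function(x, ...) {
  cat(sprintf("<math_treatment> derivative %d, gap %d, smoothing %d/%d\n",
              x$derivative_order, x$gap, x$smooth1, x$smooth2))
  invisible(x)
}

#' Full pretreatment specification
#'
#' A scatter correction (`NONE`, `SNV`, `SNV_D` = SNV followed by
#' detrending, or `MSC`) combined with a derivative math treatment. In text
#' interfaces the spec is serialized as `"SCATTER/d,g,s1,s2"`, e.g.
#' `"SNV_D/1,4,4,1"`.
#'
#' @param scatter One of `"NONE"`, `"SNV"`, `"SNV_D"`, `"MSC"`.
#' @param math A [math_treatment()] or a code string for
#'   [parse_math_treatment()].
#' @param detrend_order Polynomial order removed by the detrend step of
#'   `SNV_D` (default 2, i.e. quadratic baseline removal).
#' @return An object of class `pretreatment_spec`.
#' @export
pretreatment_spec <- function(scatter = c("NONE", "SNV", "SNV_D", "MSC"),
                              math = "0,0,1,1", detrend_order = 2L) {
  scatter <- match.arg(scatter)
  if (!inherits(math, "math_treatment"))
    math <- parse_math_treatment(math)
  structure(list(scatter = scatter, math = math,
                 detrend_order = as.integer(detrend_order)),
            class = "pretreatment_spec")
}

#' @rdname pretreatment_spec
#' @param text Serialized form `"SCATTER/d,g,s1,s2"`.
#' @export
parse_pretreatment <- function(text) {
  parts <- strsplit(text, "/", fixed = TRUE)[[1L]]
  if (length(parts) != 2L)
    stop(sprintf("cannot parse pretreatment '%s' (expected 'SCATTER/code')",
                 text), call. = FALSE)
  pretreatment_spec(parts[1L], parts[2L])
}

#' @rdname pretreatment_spec
#' @param spec A `pretreatment_spec`.
#' @export
format_pretreatment <- function(spec) {
  sprintf("%s/%d,%d,%d,%d", spec$scatter, spec$math$derivative_order,
          spec$math$gap, spec$math$smooth1, spec$math$smooth2)
}

#' @export
print.pretreatment_spec <- function(x, ...) {
  cat(sprintf("<pretreatment_spec> %s\n", format_pretreatment(x)))
  invisible(x)
}

# ---- scatter corrections ------------------------------------------------

.as_values <- function(x) {
  if (inherits(x, "spectra_set")) x$values else
    matrix(as.numeric(x), nrow = 1L)
}

.rewrap <- function(x, values, wavelength = NULL) {
  if (inherits(x, "spectra_set"))
    spectra_set(values, wavelength %||% x$wavelength, sample_ids(x))
  else
    as.numeric(values[1L, ])
}

#' Standard normal variate (SNV)
#'
#' Centers and scales each spectrum across wavelengths to mean 0 and unit
#' SD (the n-1 SD convention). Removes per-spectrum additive offsets and
#' multiplicative scaling: `snv(a + b * s)` equals `snv(s)` for any `b > 0`.
#'
#' @param x A [spectra_set] or a numeric spectrum.
#' @return Same shape as the input.
#' @export
snv <- function(x) {
  v <- .as_values(x)
  mu <- rowMeans(v)
  s <- sqrt(rowSums((v - mu)^2) / (ncol(v) - 1L))
  if (any(s <= 0))
    stop("SNV is undefined for a constant spectrum (zero variance)",
         call. = FALSE)
  .rewrap(x, (v - mu) / s)
}

#' Polynomial detrend
#'
#' Removes a least-squares polynomial in wavelength (default order 2) from
#' each spectrum; the residuals are orthogonal to the polynomial basis. The
#' `SNV_D` scatter correction is [snv()] followed by `detrend()`.
#'
#' @param x A [spectra_set] or numeric spectrum.
#' @param wavelength Wavelengths; taken from the set if `x` is one.
#' @param order Polynomial order (>= 0); the grid must be longer than
#'   `order + 1`.
#' @return Same shape as the input.
#' @export
detrend <- function(x, wavelength = NULL, order = 2L) {
  v <- .as_values(x)
  wl <- if (inherits(x, "spectra_set")) x$wavelength else
    wavelength %||% seq_len(ncol(v))
  if (ncol(v) <= order + 1L)
    stop("grid too short for the requested detrend order", call. = FALSE)
  basis <- if (order == 0L) matrix(1, length(wl), 1L) else
    cbind(1, stats::poly(wl, order))
  q <- qr.Q(qr(basis))
  .rewrap(x, v - (v %*% q) %*% t(q))
}

#' Multiplicative scatter correction (MSC)
#'
#' Fits each spectrum `s` against a reference spectrum by ordinary least
#' squares, `s ~ a + b * reference`, and returns `(s - a)/b`. Exactly
#' inverts affine distortions of the reference. In calibration the
#' reference is the mean spectrum of the calibration subset, frozen so that
#' held-out or future samples are corrected against the same reference.
#'
#' @param x A [spectra_set] or numeric spectrum.
#' @param reference Numeric reference spectrum (same grid). Defaults to the
#'   mean spectrum of `x` when `x` is a set.
#' @param tol Slopes with absolute value below `tol` raise a degenerate-slope
#'   error.
#' @return Same shape as the input.
#' @export
msc <- function(x, reference = NULL, tol = 1e-10) {
  v <- .as_values(x)
  if (is.null(reference)) {
    if (!inherits(x, "spectra_set") || nrow(v) < 2L)
      stop("msc needs an explicit reference for a single spectrum",
           call. = FALSE)
    reference <- colMeans(v)
  }
  reference <- as.numeric(reference)
  if (length(reference) != ncol(v))
    stop("reference spectrum is not on the same grid", call. = FALSE)
  rc <- reference - mean(reference)
  ssr <- sum(rc^2)
  if (ssr <= 0)
    stop("MSC reference must not be constant", call. = FALSE)
  b <- as.numeric(v %*% rc) / ssr
  a <- rowMeans(v) - b * mean(reference)
  if (any(abs(b) < tol))
    stop("degenerate MSC slope (|b| below tolerance)", call. = FALSE)
  .rewrap(x, (v - a) / b)
}

# ---- gap-segment derivative ---------------------------------------------

# Centered boxcar moving average along wavelengths; trims (w-1)/2 channels
# at each edge rather than imputing.
.boxcar <- function(values, w) {
  if (w <= 1L) return(list(values = values, trim = 0L))
  half <- (w - 1L) %/% 2L
  sm <- t(stats::filter(t(values), rep(1 / w, w), sides = 2))
  keep <- (half + 1L):(ncol(values) - half)
  list(values = sm[, keep, drop = FALSE], trim = half)
}

# Symmetric gap difference: out_i = in_{i+g} - in_{i-g}; trims g per edge.
.gapdiff <- function(values, g) {
  p <- ncol(values)
  if (p < 2L * g + 1L)
    stop("gap derivative support exceeds the spectral region", call. = FALSE)
  hi <- (2L * g + 1L):p
  lo <- 1L:(p - 2L * g)
  list(values = values[, hi, drop = FALSE] - values[, lo, drop = FALSE],
       trim = g)
}

#' Gap-segment derivative with boxcar smoothing
#'
#' Applies the two boxcar smoothing passes of a [math_treatment()], then the
#' symmetric gap difference `out(i) = smoothed(i + gap) - smoothed(i - gap)`
#' once per derivative order. Edge channels without full support are dropped
#' from the active region (the returned wavelengths shrink accordingly); no
#' imputation is performed. The operator is linear in the spectrum.
#'
#' @param x A [spectra_set] or numeric spectrum.
#' @param treatment A [math_treatment()] or code string.
#' @param wavelength Wavelengths for a bare numeric spectrum.
#' @return Same type as the input, on the trimmed active region. For a
#'   numeric input the trimmed wavelengths are attached as attribute
#'   `"wavelength"`.
#' @export
gap_segment_derivative <- function(x, treatment, wavelength = NULL) {
  if (!inherits(treatment, "math_treatment"))
    treatment <- parse_math_treatment(treatment)
  v <- .as_values(x)
  wl <- if (inherits(x, "spectra_set")) x$wavelength else
    wavelength %||% seq_len(ncol(v))
  need <- (treatment$smooth1 - 1L) %/% 2L + (treatment$smooth2 - 1L) %/% 2L +
    treatment$derivative_order * treatment$gap
  if (ncol(v) < 2L * need + 2L)
    stop("smoothing/derivative support exceeds the spectral region",
         call. = FALSE)
  res <- .boxcar(v, treatment$smooth1)
  trim <- res$trim
  res2 <- .boxcar(res$values, treatment$smooth2)
  trim <- trim + res2$trim
  v <- res2$values
  if (treatment$derivative_order > 0L) {
    for (d in seq_len(treatment$derivative_order)) {
      res <- .gapdiff(v, treatment$gap)
      v <- res$values
      trim <- trim + res$trim
    }
  }
  wl_out <- wl[(trim + 1L):(length(wl) - trim)]
  if (inherits(x, "spectra_set"))
    spectra_set(v, wl_out, sample_ids(x))
  else
    structure(as.numeric(v[1L, ]), wavelength = wl_out)
}

#' Apply a full pretreatment to a spectra set
#'
#' Scatter correction first (on raw absorbance shapes), then the derivative
#' math treatment. For `MSC` the reference defaults to the mean spectrum of
#' `set` but should be frozen from the calibration subset when correcting
#' held-out samples; the reference actually used is stored in the
#' `"msc_reference"` attribute of the result.
#'
#' @param set A [spectra_set].
#' @param spec A [pretreatment_spec()] (or serialized text form).
#' @param reference Optional frozen MSC reference spectrum on the raw grid.
#' @return A pretreated [spectra_set] (possibly on a trimmed active region)
#'   with attributes `"pretreatment"` and, for MSC, `"msc_reference"`.
#' @export
apply_pretreatment <- function(set, spec, reference = NULL) {
  if (is.character(spec)) spec <- parse_pretreatment(spec)
  stopifnot(inherits(set, "spectra_set"), inherits(spec, "pretreatment_spec"))
  ref_used <- NULL
  out <- switch(spec$scatter,
    NONE = set,
    SNV = snv(set),
    SNV_D = detrend(snv(set), order = spec$detrend_order),
    MSC = {
      ref_used <- reference %||% colMeans(set$values)
      msc(set, reference = ref_used)
    })
  out <- gap_segment_derivative(out, spec$math)
  attr(out, "pretreatment") <- spec
  if (!is.null(ref_used)) attr(out, "msc_reference") <- ref_used
  out
}
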