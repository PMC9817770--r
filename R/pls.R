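#' Fit a PLS1 regression (standard or modified variant)
#'
#' Single-response partial least-squares by iterative deflation (NIPALS
#' family), fit on internally centered data. Two variants are provided:
#'
#' * `"standard"`: classical PLS1. With as many terms as the rank of the
#'   centered predictor matrix, its training predictions coincide with
#'   ordinary least squares.
#' * `"modified"`: the Shenk--Westerhaus reweighting used by NIRS
#'   calibration software. After each term is extracted, the spectral
#'   residuals at each wavelength are divided by their standard deviation
#'   before the next term is computed, down-weighting wavelengths already
#'   well explained. Per-term scaling vectors are stored so prediction
#'   replays the same transformations.
#'
#' Both variants are deterministic: there is no randomness in the fit, and
#' permuting sample order leaves the coefficients unchanged. Regression
#' coefficients are accumulated back into the original (centered) spectral
#' space for every cumulative term count `1..n_terms`, so predictions at any
#' smaller term count are available without refitting.
#'
#' @param X Numeric matrix of pretreated spectra (samples x channels), or a
#'   [spectra_set].
#' @param y Numeric reference values, one per row of `X`; must not be
#'   constant.
#' @param n_terms Number of latent terms to extract; needs
#'   `nrow(X) >= n_terms + 1`. A rank error is raised if the residual signal
#'   is exhausted before `n_terms` terms.
#' @param variant `"modified"` (default) or `"standard"`.
#' @param tol Relative tolerance for rank/degeneracy checks.
#'
#' @return An object of class `pls_model`: variant, term count, centering
#'   info, per-term weights/loadings/score coefficients, per-term residual
#'   scaling vectors (modified variant), the cumulative coefficient matrix
#'   `coefficients` (channels x terms), the active wavelengths, and training
#'   fitted values.
#' @seealso [predict.pls_model()], [write_pls_model()]
#' @export
pls_fit <- function(X, y, n_terms, variant = c("modified", "standard"),
                    tol = 1e-10) {
  variant <- match.arg(variant)
  wavelength <- if (inherits(X, "spectra_set")) X$wavelength else NULL
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n)
    stop("length of y must match the number of spectra", call. = FALSE)
  n_terms <- as.integer(n_terms)
  if (n_terms < 1L) stop("n_terms must be at least 1", call. = FALSE)
  if (n < n_terms + 1L)
    stop("need at least n_terms + 1 samples", call. = FALSE)
  if (stats::var(y) <= 0)
    stop("reference values have zero variance", call. = FALSE)

  x_center <- colMeans(X)
  y_center <- mean(y)
  Xr <- sweep(X, 2L, x_center)
  yr <- y - y_center
  W <- P <- D <- vector("list", n_terms)
  qv <- numeric(n_terms)
  w_ref <- NA_real_  # norm of the first weight vector, scales the rank check
  for (k in seq_len(n_terms)) {
    d <- rep(1, p)
    if (variant == "modified" && k > 1L) {
      s <- sqrt(colMeans(Xr^2))  # residual SD per wavelength (mean-zero cols)
      smax <- max(s)
      if (smax <= 0)
        stop(sprintf("rank error: spectral residuals exhausted after %d term(s)",
                     k - 1L), call. = FALSE)
      live <- s > smax * 1e-8
      d[live] <- 1 / s[live]
      d[!live] <- 0
      Xr <- sweep(Xr, 2L, d, `*`)
    }
    w <- crossprod(Xr, yr)[, 1L]
    nw <- sqrt(sum(w^2))
    if (is.na(w_ref)) w_ref <- nw
    if (nw <= tol * w_ref || nw == 0)
      stop(sprintf("rank error: cannot extract term %d (residual correlation below tolerance)",
                   k), call. = FALSE)
    w <- w / nw
    tvec <- Xr %*% w
    tt <- sum(tvec^2)
    if (tt <= tol * sum(Xr^2) / p)
      stop(sprintf("rank error: degenerate score at term %d", k), call. = FALSE)
    pvec <- crossprod(Xr, tvec)[, 1L] / tt
    qk <- sum(yr * tvec) / tt
    Xr <- Xr - tcrossprod(tvec, pvec)
    yr <- yr - qk * tvec
    W[[k]] <- w; P[[k]] <- pvec; D[[k]] <- d; qv[k] <- qk
  }

  # Coefficients in the original centered space. Prediction replays
  #   x <- d_k * x; t_k = w_k . x; x <- x - t_k p_k
  # which is linear in x, so t_k = r_k . x with r_k built by applying the
  # adjoint chain to d_k * w_k.
  R <- matrix(0, p, n_terms)
  for (k in seq_len(n_terms)) {
    v <- D[[k]] * W[[k]]
    if (k > 1L) for (j in (k - 1L):1L) {
      v <- v - W[[j]] * sum(P[[j]] * v)
      v <- D[[j]] * v
    }
    R[, k] <- v
  }
  coef_cum <- R %*% (upper.tri(matrix(0, n_terms, n_terms), diag = TRUE) * qv)
  fitted <- y_center + sweep(X, 2L, x_center) %*% coef_cum
  model <- structure(list(variant = variant, n_terms = n_terms,
                          x_center = x_center, y_center = y_center,
                          weights = W, loadings = P, score_coef = qv,
                          residual_scaling = if (variant == "modified") D,
                          coefficients = coef_cum, rotation = R,
                          wavelength = wavelength,
                          fitted = fitted[, n_terms]),
                     class = "pls_model")
  model
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %s variant, %d term(s), %d channel(s)\n",
              x$variant, x$n_terms, nrow(x$coefficients)))
  invisible(x)
}

#' Predict from a fitted PLS model
#'
#' `yhat = y_center + (x - x_center) . coefficients`, vectorized over rows.
#' `X_new` must be on the same active spectral region (and pretreatment) as
#' the training spectra.
#'
#' @param object A [pls_fit()] model.
#' @param newdata Matrix or [spectra_set] of pretreated spectra.
#' @param n_terms Cumulative term count to predict with (default: the
#'   model's full term count).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.pls_model <- function(object, newdata, n_terms = object$n_terms, ...) {
  Xn <- as.matrix(newdata)
  if (ncol(Xn) != length(object$x_center))
    stop("spectral region of newdata does not match the model", call. = FALSE)
  if (n_terms < 1L || n_terms > object$n_terms)
    stop("n_terms outside the fitted range", call. = FALSE)
  as.numeric(object$y_center +
               sweep(Xn, 2L, object$x_center) %*%
                 object$coefficients[, n_terms, drop = TRUE])
}

# Held-out predictions for all cumulative term counts at once (n x K).
.predict_all_terms <- function(object, Xn) {
  Xn <- as.matrix(Xn)
  object$y_center + sweep(Xn, 2L, object$x_center) %*% object$coefficients
}

#' Serialize / restore a PLS model as JSON
#'
#' Self-describing text artifact holding the variant, term count, centering
#' information, per-term vectors and coefficients at full double precision;
#' reloading reproduces predictions on the same platform.
#'
#' @param model A [pls_fit()] model.
#' @param path Output (input) file path.
#' @return `path` invisibly (writer); a `pls_model` (reader).
#' @export
write_pls_model <- function(model, path) {
  payload <- list(
    format = "eggnir_pls_model", version = 1L,
    variant = model$variant, n_terms = model$n_terms,
    x_center = model$x_center, y_center = model$y_center,
    weights = model$weights, loadings = model$loadings,
    score_coef = model$score_coef,
    residual_scaling = model$residual_scaling,
    coefficients = as.vector(model$coefficients),
    n_channels = nrow(model$coefficients),
    wavelength = model$wavelength)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_pls_model
#' @export
read_pls_model <- function(path) {
  pl <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(pl$format, "eggnir_pls_model"))
    stop("not an eggnir PLS model file", call. = FALSE)
  K <- as.integer(pl$n_terms)
  as_list <- function(x) {
    if (is.matrix(x)) lapply(seq_len(ncol(x)), function(j) x[, j])
    else if (is.list(x)) lapply(x, as.numeric)
    else list(as.numeric(x))
  }
  coef_cum <- matrix(as.numeric(pl$coefficients), nrow = pl$n_channels,
                     ncol = K)
  structure(list(variant = pl$variant, n_terms = K,
                 x_center = as.numeric(pl$x_center),
                 y_center = as.numeric(pl$y_center),
                 weights = as_list(pl$weights),
                 loadings = as_list(pl$loadings),
                 score_coef = as.numeric(pl$score_coef),
                 residual_scaling = if (!is.null(pl$residual_scaling))
                   as_list(pl$residual_scaling),
                 coefficients = coef_cum,
                 wavelength = if (!is.null(pl$wavelength))
                   as.numeric(pl$wavelength),
                 fitted = NULL),
            class = "pls_model")
}
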