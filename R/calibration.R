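#' Build a balanced random cross-validation plan
#'
#' Samples are assigned to `n_segments` random groups whose sizes differ by
#' at most one. Random (not contiguous) segments are used because samples
#' are typically blocked by breed in the data file; contiguous segments
#' would confound breed with fold. Deterministic given `seed`.
#'
#' @param sample_ids Character vector of sample ids (`n >= n_segments`).
#' @param n_segments Number of cross-validation segments (default 5).
#' @param seed Integer seed.
#' @return An object of class `cv_plan` with the named `assignment` vector,
#'   `n_segments` and `seed`.
#' @export
make_cv_plan <- function(sample_ids, n_segments = 5L, seed = 1L) {
  n <- length(sample_ids)
  if (anyDuplicated(sample_ids))
    stop("sample ids must be unique", call. = FALSE)
  if (n < n_segments)
    stop("fewer samples than cross-validation segments", call. = FALSE)
  set.seed(seed)
  assignment <- sample(rep_len(seq_len(n_segments), n))
  names(assignment) <- sample_ids
  structure(list(assignment = assignment, n_segments = as.integer(n_segments),
                 seed = as.integer(seed)),
            class = "cv_plan")
}

# Held-out predictions for every cumulative term count.
# Pretreatment references and centering are computed on the training
# portion of each fold only; the MSC reference is the training-fold mean
# raw spectrum. Returns an n x K matrix in the sample order of `set`.
.cv_heldout <- function(set, y, spec, plan, max_terms, variant = "modified") {
  n <- n_spectra(set)
  seg <- plan$assignment[sample_ids(set)]
  if (anyNA(seg))
    stop("cross-validation plan does not cover all samples", call. = FALSE)
  sizes <- tabulate(seg, plan$n_segments)
  if (any(sizes < 2L))
    stop("a cross-validation segment has fewer than 2 samples", call. = FALSE)
  kmax <- min(max_terms, min(n - sizes) - 1L)
  if (kmax < 1L)
    stop("training folds too small to fit even one PLS term", call. = FALSE)
  preds <- matrix(NA_real_, n, kmax)
  for (s in seq_len(plan$n_segments)) {
    te <- which(seg == s)
    tr <- which(seg != s)
    ref <- if (spec$scatter == "MSC") colMeans(set$values[tr, , drop = FALSE])
    Xtr <- apply_pretreatment(set[tr], spec, reference = ref)
    Xte <- apply_pretreatment(set[te], spec, reference = ref)
    fit <- pls_fit(Xtr, y[tr], n_terms = kmax, variant = variant)
    preds[te, ] <- .predict_all_terms(fit, Xte)
  }
  preds
}

# Assemble the CV statistics block from aligned y / held-out / fitted values.
.cv_stats <- function(y, heldout, fitted, n_terms, removed = character(0),
                      secv_divisor = "n") {
  sst <- sum((y - mean(y))^2)
  secv <- .rms(y - heldout, secv_divisor)
  sec <- .rms(y - fitted, secv_divisor)
  structure(list(n = length(y), mean = mean(y), sd = stats::sd(y),
                 sec = sec, r2c = 1 - sum((y - fitted)^2) / sst,
                 secv = secv, r2cv = 1 - sum((y - heldout)^2) / sst,
                 rpdcv = rpd(stats::sd(y), secv),
                 n_terms = n_terms, removed_outliers = removed),
            class = "cv_statistics")
}

#' @export
print.cv_statistics <- function(x, ...) {
  cat(sprintf(paste0("<cv_statistics> n=%d T=%d mean=%.3f SD=%.3f ",
                     "SEC=%.4f R2C=%.3f SECV=%.4f R2CV=%.3f RPDcv=%.2f\n"),
              x$n, x$n_terms, x$mean, x$sd, x$sec, x$r2c, x$secv, x$r2cv,
              x$rpdcv))
  invisible(x)
}

#' Segmented cross-validation of a pretreated PLS calibration
#'
#' For each segment of `plan`, fits on the remaining segments (pretreatment
#' references and centering from the training portion only) and predicts the
#' held-out segment. `SECV` is the root mean squared held-out residual
#' (divisor `n` by default), `R2CV = 1 - SSE_cv/SST` (which can be negative),
#' and `SEC`/`R2C` come from a final fit on all samples. `RPDCV = SD/SECV`.
#'
#' @param set A [spectra_set] of raw spectra.
#' @param y Reference values aligned to `set`.
#' @param spec A [pretreatment_spec()].
#' @param plan A [make_cv_plan()].
#' @param n_terms Number of PLS terms.
#' @param variant PLS variant, `"modified"` or `"standard"`.
#' @param secv_divisor `"n"` (RMSE convention, default) or `"n-1"`.
#' @return List with `heldout` (vector), `heldout_by_terms` (n x terms
#'   matrix), `statistics` (a `cv_statistics`), and `model` (the final
#'   all-sample fit).
#' @export
cross_validate <- function(set, y, spec, plan, n_terms,
                           variant = c("modified", "standard"),
                           secv_divisor = c("n", "n-1")) {
  variant <- match.arg(variant)
  secv_divisor <- match.arg(secv_divisor)
  if (is.character(spec)) spec <- parse_pretreatment(spec)
  preds <- .cv_heldout(set, y, spec, plan, n_terms, variant)
  k <- min(n_terms, ncol(preds))
  Xall <- apply_pretreatment(set, spec)
  fit <- pls_fit(Xall, y, n_terms = k, variant = variant)
  stats <- .cv_stats(y, preds[, k], fit$fitted, k, secv_divisor = secv_divisor)
  list(heldout = preds[, k], heldout_by_terms = preds, statistics = stats,
       model = fit)
}

# Pick the term count minimizing SECV; ties break toward fewer terms
# (which.min returns the first minimum).
.select_terms <- function(preds, y, secv_divisor = "n") {
  secvs <- apply(preds, 2L, function(ph) .rms(y - ph, secv_divisor))
  list(n_terms = which.min(secvs), secv = secvs)
}

#' Iterative cross-validated outlier elimination
#'
#' Per pass: compute cross-validated residuals at `n_terms`, standardize by
#' the residual SD of the current pass, and drop samples whose absolute
#' standardized residual exceeds `threshold_sd` (default 2.5). Repeats until
#' no sample is dropped or `max_passes` is reached. The cross-validation
#' plan is rebuilt (same seed) on the retained samples after each pass.
#'
#' @inheritParams cross_validate
#' @param threshold_sd Exclusion threshold in residual SDs (> 0).
#' @param max_passes Maximum elimination passes; `0` returns the input
#'   unchanged with an empty removal log.
#' @return List with `retained_ids`, `removed` (data frame `sample_id`,
#'   `pass`, `residual`, `z`), `set`, `y` (both restricted to retained
#'   samples), and `plan` (rebuilt on the retained samples).
#' @export
remove_outliers <- function(set, y, spec, plan, n_terms, threshold_sd = 2.5,
                            max_passes = 2L,
                            variant = c("modified", "standard")) {
  variant <- match.arg(variant)
  if (threshold_sd <= 0) stop("threshold_sd must be positive", call. = FALSE)
  if (is.character(spec)) spec <- parse_pretreatment(spec)
  removed <- data.frame(sample_id = character(0), pass = integer(0),
                        residual = numeric(0), z = numeric(0),
                        stringsAsFactors = FALSE)
  pass <- 0L
  while (pass < max_passes) {
    pass <- pass + 1L
    preds <- .cv_heldout(set, y, spec, plan, n_terms, variant)
    k <- min(n_terms, ncol(preds))
    res <- y - preds[, k]
    z <- res / stats::sd(res)
    drop <- which(abs(z) > threshold_sd)
    if (!length(drop)) break
    removed <- rbind(removed, data.frame(
      sample_id = sample_ids(set)[drop], pass = pass,
      residual = res[drop], z = z[drop], stringsAsFactors = FALSE))
    keep <- setdiff(seq_len(n_spectra(set)), drop)
    if (length(keep) < 2L * plan$n_segments)
      stop("outlier elimination removed too many samples to keep the CV plan",
           call. = FALSE)
    set <- set[keep]
    y <- y[keep]
    plan <- make_cv_plan(sample_ids(set), plan$n_segments, plan$seed)
  }
  list(retained_ids = sample_ids(set), removed = removed, set = set, y = y,
       plan = plan)
}

#' Pretreatment grid search
#'
#' Evaluates every scatter x math-treatment combination. For each cell the
#' term count in `1..max_terms` minimizing SECV is selected (ties toward
#' fewer terms); when `outlier_sd` is given, cross-validated outlier
#' elimination is run first (at the initially selected term count) and the
#' term count re-selected on the retained samples. Cells are ranked by SECV
#' ascending, ties broken by fewer terms, then by option-list order.
#'
#' @param set A [spectra_set] of raw spectra.
#' @param y Reference values aligned to `set`.
#' @param scatter_options Character vector of scatter corrections
#'   (subset of `NONE`, `SNV`, `SNV_D`, `MSC`).
#' @param math_options Character vector of math treatment codes, e.g.
#'   `c("0,0,1,1", "1,4,4,1", "2,5,5,1")`.
#' @param max_terms Maximum number of PLS terms (default 10).
#' @param plan A [make_cv_plan()] for the full sample set.
#' @param variant PLS variant.
#' @param outlier_sd Outlier threshold in SDs, or `NULL` to skip
#'   elimination.
#' @param max_passes Maximum outlier passes (used when `outlier_sd` is set).
#' @param secv_divisor SECV divisor convention.
#' @return A data frame of class `calibration_grid`, one row per cell,
#'   ranked by SECV: `scatter`, `math`, `n_terms`, `n`, `mean`, `sd`,
#'   `sec`, `r2c`, `secv`, `r2cv`, `rpdcv`, `n_removed`, `removed_ids`
#'   (comma-separated).
#' @export
grid_search <- function(set, y, scatter_options = c("NONE", "SNV", "SNV_D", "MSC"),
                        math_options = c("0,0,1,1", "1,4,4,1", "2,5,5,1"),
                        max_terms = 10L, plan = NULL,
                        variant = c("modified", "standard"),
                        outlier_sd = NULL, max_passes = 2L,
                        secv_divisor = c("n", "n-1")) {
  variant <- match.arg(variant)
  secv_divisor <- match.arg(secv_divisor)
  if (!length(scatter_options) || !length(math_options))
    stop("scatter_options and math_options must be non-empty", call. = FALSE)
  bad <- setdiff(scatter_options, c("NONE", "SNV", "SNV_D", "MSC"))
  if (length(bad))
    stop(sprintf("unknown scatter correction(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  if (is.null(plan)) plan <- make_cv_plan(sample_ids(set))
  cells <- expand.grid(math = math_options, scatter = scatter_options,
                       stringsAsFactors = FALSE)[, c("scatter", "math")]
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    spec <- pretreatment_spec(cells$scatter[i], cells$math[i])
    cur_set <- set; cur_y <- y; cur_plan <- plan
    removed <- character(0)
    if (!is.null(outlier_sd) && max_passes > 0L) {
      pre <- .cv_heldout(cur_set, cur_y, spec, cur_plan, max_terms, variant)
      k0 <- .select_terms(pre, cur_y, secv_divisor)$n_terms
      elim <- remove_outliers(cur_set, cur_y, spec, cur_plan, n_terms = k0,
                              threshold_sd = outlier_sd,
                              max_passes = max_passes, variant = variant)
      cur_set <- elim$set; cur_y <- elim$y; cur_plan <- elim$plan
      removed <- elim$removed$sample_id
    }
    preds <- .cv_heldout(cur_set, cur_y, spec, cur_plan, max_terms, variant)
    sel <- .select_terms(preds, cur_y, secv_divisor)
    k <- sel$n_terms
    Xall <- apply_pretreatment(cur_set, spec)
    fit <- pls_fit(Xall, cur_y, n_terms = k, variant = variant)
    st <- .cv_stats(cur_y, preds[, k], fit$fitted, k, removed,
                    secv_divisor = secv_divisor)
    rows[[i]] <- data.frame(
      scatter = cells$scatter[i], math = cells$math[i],
      n_terms = st$n_terms, n = st$n, mean = st$mean, sd = st$sd,
      sec = st$sec, r2c = st$r2c, secv = st$secv, r2cv = st$r2cv,
      rpdcv = st$rpdcv, n_removed = length(removed),
      removed_ids = paste(removed, collapse = ","),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$cell <- seq_len(nrow(out))
  out <- out[order(out$secv, out$n_terms, out$cell), ]
  out$cell <- NULL
  rownames(out) <- NULL
  class(out) <- c("calibration_grid", class(out))
  out
}

#' Ratio of performance to deviation
#'
#' `RPD = SD / SECV`, the reference SD divided by the cross-validation
#' standard error; values around 2 or above indicate usable quantitative
#' models. Reported to 2 decimals in calibration tables.
#'
#' @param sd Standard deviation of the reference values (> 0 expected).
#' @param secv Standard error of cross-validation (> 0).
#' @return `sd / secv`.
#' @examples
#' round(rpd(1.14, 0.73), 2)     # 1.56
#' round(rpd(177.45, 129.14), 2) # 1.37
#' @export
rpd <- function(sd, secv) {
  if (any(secv <= 0)) stop("SECV must be positive", call. = FALSE)
  sd / secv
}

#' Full calibration of one trait x part x matrix cell
#'
#' Joins spectra with the composition table for one trait, then runs the
#' pretreatment grid search with cross-validated outlier elimination and
#' SECV-minimizing term selection.
#'
#' @param set A [spectra_set] of raw spectra.
#' @param comp Composition table containing the trait column.
#' @param trait Trait column name, e.g. `"protein_pct_dm"`.
#' @inheritParams grid_search
#' @param n_segments Number of CV segments (default 5).
#' @param seed Seed for the CV plan.
#' @return A `calibration_grid` data frame (see [grid_search()]) with the
#'   trait recorded in attribute `"trait"` and column `trait`.
#' @export
calibrate_trait <- function(set, comp, trait,
                            scatter_options = c("NONE", "SNV", "SNV_D", "MSC"),
                            math_options = c("0,0,1,1", "1,4,4,1", "2,5,5,1"),
                            max_terms = 10L, n_segments = 5L,
                            outlier_sd = 2.5, max_passes = 2L, seed = 1L,
                            variant = c("modified", "standard"),
                            secv_divisor = c("n", "n-1")) {
  joined <- join_spectra_composition(set, comp, trait)
  plan <- make_cv_plan(joined$sample_id, n_segments = n_segments, seed = seed)
  out <- grid_search(joined$spectra, joined$y,
                     scatter_options = scatter_options,
                     math_options = math_options, max_terms = max_terms,
                     plan = plan, variant = match.arg(variant),
                     outlier_sd = outlier_sd, max_passes = max_passes,
                     secv_divisor = match.arg(secv_divisor))
  out <- cbind(trait = trait, out, stringsAsFactors = FALSE)
  attr(out, "trait") <- trait
  class(out) <- c("calibration_grid", "data.frame")
  out
}
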