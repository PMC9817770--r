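#' Construct the shared wavelength grid
#'
#' VIS-NIR spectra in this package live on a single uniform wavelength grid,
#' by default 400--2500 nm sampled every 0.5 nm (4201 channels), the
#' acquisition convention of bench-top monochromator instruments. The grid is
#' a plain numeric vector of wavelengths in nanometers carrying class
#' `"wavelength_grid"`; both endpoints are included.
#'
#' @param start_nm First wavelength (nm).
#' @param stop_nm Last wavelength (nm); must exceed `start_nm`.
#' @param step_nm Step between channels (nm); `(stop_nm - start_nm)` must be
#'   an integer multiple of `step_nm` (within floating-point tolerance).
#'
#' @return Numeric vector of wavelengths of length
#'   `(stop_nm - start_nm)/step_nm + 1`.
#' @examples
#' length(make_grid())            # 4201
#' make_grid(400, 401, 0.5)       # 400.0 400.5 401.0
#' @export
make_grid <- function(start_nm = 400, stop_nm = 2500, step_nm = 0.5) {
  if (!is.numeric(start_nm) || !is.numeric(stop_nm) || !is.numeric(step_nm) ||
      length(start_nm) != 1L || length(stop_nm) != 1L || length(step_nm) != 1L)
    stop("grid endpoints and step must be single numeric values", call. = FALSE)
  if (stop_nm <= start_nm)
    stop("`stop_nm` must be greater than `start_nm`", call. = FALSE)
  if (step_nm <= 0)
    stop("`step_nm` must be positive", call. = FALSE)
  n_steps <- (stop_nm - start_nm) / step_nm
  if (abs(n_steps - round(n_steps)) > 1e-6)
    stop(sprintf(
      "wavelength range [%g, %g] nm is not divisible by step %g nm",
      start_nm, stop_nm, step_nm), call. = FALSE)
  wl <- start_nm + step_nm * seq.int(0L, round(n_steps))
  wl[length(wl)] <- stop_nm  # exact endpoint inclusion
  structure(wl, class = c("wavelength_grid", "numeric"))
}

#' Bundle spectra on a shared wavelength grid
#'
#' A `spectra_set` stores one log(1/reflectance) spectrum per sample as the
#' rows of a numeric matrix, with columns aligned to a common wavelength grid
#' and unique sample identifiers that join against a composition table.
#'
#' @param values Numeric matrix, one row per sample, `length(wavelength)`
#'   columns. All values must be finite.
#' @param wavelength Numeric vector of wavelengths (nm), strictly increasing.
#' @param sample_id Character vector of unique identifiers; defaults to the
#'   rownames of `values`.
#'
#' @return An object of class `spectra_set`: a list with elements
#'   `wavelength` and `values` (rownames are the sample ids).
#' @export
spectra_set <- function(values, wavelength, sample_id = rownames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  wavelength <- as.numeric(wavelength)
  if (ncol(values) != length(wavelength))
    stop("number of spectral channels does not match the wavelength grid",
         call. = FALSE)
  if (is.unsorted(wavelength, strictly = TRUE))
    stop("wavelengths must be strictly increasing", call. = FALSE)
  if (!all(is.finite(values)))
    stop("spectra contain non-finite values", call. = FALSE)
  if (is.null(sample_id))
    sample_id <- sprintf("S%03d", seq_len(nrow(values)))
  sample_id <- as.character(sample_id)
  if (length(sample_id) != nrow(values))
    stop("one sample_id per spectrum is required", call. = FALSE)
  if (anyDuplicated(sample_id))
    stop("duplicate sample ids in spectra set", call. = FALSE)
  rownames(values) <- sample_id
  structure(list(wavelength = wavelength, values = values),
            class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  wl <- x$wavelength
  cat(sprintf("<spectra_set> %d spectra x %d channels (%.1f-%.1f nm)\n",
              nrow(x$values), length(wl), min(wl), max(wl)))
  invisible(x)
}

#' @export
as.matrix.spectra_set <- function(x, ...) x$values

#' Sample identifiers of a spectra set
#' @param set A `spectra_set`.
#' @return Character vector of sample ids.
#' @export
sample_ids <- function(set) rownames(set$values)

#' Number of spectra in a set
#' @param set A `spectra_set`.
#' @return Integer count.
#' @export
n_spectra <- function(set) nrow(set$values)

#' Subset a spectra set by sample
#'
#' @param x A `spectra_set`.
#' @param i Row index or character vector of sample ids.
#' @param ... Unused.
#' @return A `spectra_set` with the selected spectra, order as requested.
#' @export
`[.spectra_set` <- function(x, i, ...) {
  spectra_set(x$values[i, , drop = FALSE], x$wavelength)
}

#' Pair spectra with reference composition values for one trait
#'
#' Joins a [spectra_set] with a composition table by `sample_id`, returning
#' the aligned design used by the calibration engine: the spectra of the
#' matched samples and the numeric reference vector for one trait. Samples
#' whose reference value is missing (`NA`) are dropped and the drop count is
#' reported via `message()`. Every spectrum id must be present in the
#' composition table.
#'
#' @param set A [spectra_set].
#' @param comp Composition data frame with a `sample_id` column and the trait
#'   column (see [generate_composition()] for the column conventions).
#' @param trait Name of the trait column, e.g. `"protein_pct_dm"`.
#'
#' @return List with elements `spectra` (a `spectra_set`), `y` (numeric
#'   reference values, same order), `sample_id`, and `n_dropped`.
#' @export
join_spectra_composition <- function(set, comp, trait) {
  if (!trait %in% names(comp))
    stop(sprintf("trait column '%s' not found in composition table", trait),
         call. = FALSE)
  ids <- sample_ids(set)
  idx <- match(ids, comp$sample_id)
  if (all(is.na(idx)))
    stop("no spectra ids are present in the composition table", call. = FALSE)
  if (anyNA(idx))
    stop(sprintf("%d spectra ids are missing from the composition table",
                 sum(is.na(idx))), call. = FALSE)
  y <- as.numeric(comp[[trait]][idx])
  keep <- !is.na(y)
  if (!any(keep))
    stop(sprintf("no sample has a reference value for trait '%s'", trait),
         call. = FALSE)
  n_drop <- sum(!keep)
  if (n_drop > 0L)
    message(sprintf("join: dropped %d sample(s) without a '%s' reference",
                    n_drop, trait))
  list(spectra = set[which(keep)], y = y[keep],
       sample_id = ids[keep], n_dropped = n_drop)
}
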