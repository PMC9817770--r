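#' Write a spectra set as a wide CSV
#'
#' The canonical on-disk dialect: first column `wavelength_nm`, then one
#' column per sample (header = sample id). UTF-8, `.` decimal separator,
#' LF newlines. Round-tripping through [read_spectra_csv()] reproduces the
#' values at the serialized precision (full double precision by default).
#'
#' @param set A [spectra_set].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(set, path) {
  df <- data.frame(wavelength_nm = set$wavelength, t(set$values),
                   check.names = FALSE)
  con <- file(path, open = "wb")  # LF newlines on every platform
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a spectra set from a wide CSV
#'
#' Inverse of [write_spectra_csv()]. Distinct errors are raised for
#' duplicated sample columns, non-monotone wavelengths, and ragged or
#' non-numeric content.
#'
#' @param path CSV file path (first column wavelength, one column per sample).
#' @return A [spectra_set].
#' @export
read_spectra_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 2L)
    stop("spectra CSV needs a wavelength column plus at least one sample",
         call. = FALSE)
  ids <- names(df)[-1L]
  if (anyDuplicated(ids))
    stop(sprintf("duplicate sample column(s) in spectra CSV: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  wl <- suppressWarnings(as.numeric(df[[1L]]))
  if (anyNA(wl))
    stop("non-numeric wavelength values in spectra CSV", call. = FALSE)
  if (is.unsorted(wl, strictly = TRUE))
    stop("wavelengths in spectra CSV are not strictly increasing", call. = FALSE)
  vals <- as.matrix(df[-1L])
  if (!is.numeric(vals) || anyNA(vals))
    stop("ragged or non-numeric spectral values in CSV", call. = FALSE)
  spectra_set(t(vals), wl, sample_id = ids)
}

#' Read a single-spectrum JCAMP-DX file
#'
#' Minimal read-only import of the `XYDATA=(X++(Y..Y))` AFFN form commonly
#' exported by spectrometer software: honors `##XFACTOR`, `##YFACTOR`,
#' `##FIRSTX`, `##LASTX` and `##NPOINTS`, and uses `##TITLE` as the sample
#' id. The wide CSV remains the canonical dialect; compressed (SQZ/DIF/DUP)
#' encodings are not supported.
#'
#' @param path JCAMP-DX file path.
#' @return A [spectra_set] containing one spectrum.
#' @export
read_jcampdx <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ldr <- function(name) {
    hit <- grep(sprintf("^##%s=", name), lines, ignore.case = TRUE, value = TRUE)
    if (!length(hit)) return(NULL)
    sub(sprintf("^##%s=\\s*", name), "", hit[1L], ignore.case = TRUE)
  }
  title <- ldr("TITLE")
  xfac <- as.numeric(ldr("XFACTOR") %||% "1")
  yfac <- as.numeric(ldr("YFACTOR") %||% "1")
  npt <- as.numeric(ldr("NPOINTS"))
  start <- grep("^##XYDATA=", lines, ignore.case = TRUE)
  if (!length(start))
    stop("no ##XYDATA block found in JCAMP-DX file", call. = FALSE)
  end <- grep("^##END", lines, ignore.case = TRUE)
  end <- if (length(end)) min(end[end > start[1L]]) else length(lines) + 1L
  block <- lines[(start[1L] + 1L):(end - 1L)]
  block <- block[nzchar(trimws(block))]
  xs <- ys <- vector("list", length(block))
  for (i in seq_along(block)) {
    nums <- as.numeric(strsplit(trimws(block[i]), "[\\s,]+", perl = TRUE)[[1L]])
    if (anyNA(nums) || length(nums) < 2L)
      stop("malformed AFFN data line in JCAMP-DX file", call. = FALSE)
    xs[[i]] <- nums[1L]
    ys[[i]] <- nums[-1L]
  }
  y <- unlist(ys) * yfac
  if (!is.na(npt) && length(y) != npt)
    stop(sprintf("JCAMP-DX NPOINTS=%d but %d values read", npt, length(y)),
         call. = FALSE)
  firstx <- as.numeric(ldr("FIRSTX") %||% as.character(xs[[1L]] * xfac))
  lastx <- as.numeric(ldr("LASTX") %||% "NA")
  wl <- if (!is.na(lastx) && length(y) > 1L)
    seq(firstx, lastx, length.out = length(y))
  else
    firstx + (seq_along(y) - 1L) *
      (if (length(xs) > 1L) (xs[[2L]] - xs[[1L]]) * xfac / length(ys[[1L]]) else 1)
  spectra_set(matrix(y, nrow = 1L), wl,
              sample_id = title %||% "jcamp_spectrum")
}

#' Write / read a composition table CSV
#'
#' Plain long-format CSV with columns `sample_id`, `breed`, `shell_group`,
#' `matrix`, `part`, followed by one column per trait with units encoded in
#' the header (e.g. `protein_pct_wb`, `cholesterol_mg100g_dm`).
#'
#' @param comp Composition data frame.
#' @param path File path.
#' @return `path` (writer) or the data frame (reader).
#' @export
write_composition_csv <- function(comp, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.csv(comp, con, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_composition_csv
#' @export
read_composition_csv <- function(path) {
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}
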