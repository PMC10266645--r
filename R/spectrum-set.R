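#' Construct a spectrum set
#'
#' A `spectrum_set` holds per-sample spectra on a common, strictly increasing
#' 1-nm wavelength grid, together with a tag recording which spectral
#' representation the values are in: `"RAW"` (as read), `"R"` (reflectance
#' after Savitzky-Golay smoothing), `"LR"` (log10(1/R)), `"CR"`
#' (continuum-removed), or `"FDR"` (first-derivative reflectance, per nm).
#'
#' @param values numeric matrix, samples in rows, wavelengths in columns.
#' @param wavelengths_nm strictly increasing integer wavelengths (nm), one per
#'   column of `values`, on a constant 1-nm step.
#' @param sample_ids unique sample identifiers, one per row of `values`.
#' @param transform_tag one of `"RAW"`, `"R"`, `"LR"`, `"CR"`, `"FDR"`.
#'
#' @return An object of class `spectrum_set`: a list with elements
#'   `values`, `wavelengths_nm`, `sample_ids`, `transform_tag`.
#' @export
spectrum_set <- function(values, wavelengths_nm, sample_ids,
                         transform_tag = c("RAW", "R", "LR", "CR", "FDR")) {
  transform_tag <- match.arg(transform_tag)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  wavelengths_nm <- as.integer(round(wavelengths_nm))
  sample_ids <- as.character(sample_ids)
  rownames(values) <- sample_ids
  colnames(values) <- wavelengths_nm
  obj <- structure(
    list(values = values, wavelengths_nm = wavelengths_nm,
         sample_ids = sample_ids, transform_tag = transform_tag),
    class = "spectrum_set")
  validate_spectrum_set(obj)
  obj
}

#' Validate a spectrum set
#'
#' Checks the structural invariants: strictly increasing integer grid at a
#' constant 1-nm step, one value row per sample id, no missing values, and the
#' value range implied by the transform tag (`[0, 1]` for RAW/R, `(0, 1]`
#' for CR).
#'
#' @param x a `spectrum_set`.
#' @return `x`, invisibly; errors describe the first violated invariant.
#' @export
validate_spectrum_set <- function(x) {
  stopifnot(inherits(x, "spectrum_set"))
  w <- x$wavelengths_nm
  if (length(w) < 1L || anyNA(w))
    stop("wavelength grid is empty or contains NA", call. = FALSE)
  if (length(w) > 1L) {
    dw <- diff(w)
    if (any(dw <= 0L)) stop("wavelengths must be strictly increasing", call. = FALSE)
    if (any(dw != 1L)) stop("wavelength grid must have a constant 1-nm step", call. = FALSE)
  }
  if (nrow(x$values) != length(x$sample_ids))
    stop("values row count does not match sample_ids", call. = FALSE)
  if (ncol(x$values) != length(w))
    stop("values column count does not match wavelength grid", call. = FALSE)
  if (anyDuplicated(x$sample_ids))
    stop("duplicate sample id: ",
         x$sample_ids[anyDuplicated(x$sample_ids)], call. = FALSE)
  if (anyNA(x$values) || any(!is.finite(x$values)))
    stop("spectra contain missing or non-finite values", call. = FALSE)
  if (x$transform_tag %in% c("RAW", "R")) {
    if (any(x$values < 0 | x$values > 1))
      stop("reflectance values outside [0, 1] for transform_tag ",
           x$transform_tag, call. = FALSE)
  } else if (x$transform_tag == "CR") {
    if (any(x$values <= 0 | x$values > 1 + 1e-12))
      stop("continuum-removed values outside (0, 1]", call. = FALSE)
  }
  invisible(x)
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("<spectrum_set> %d samples x %d bands [%d-%d nm], transform = %s\n",
              nrow(x$values), ncol(x$values),
              min(x$wavelengths_nm), max(x$wavelengths_nm), x$transform_tag))
  invisible(x)
}

#' Construct a soil sample table
#'
#' Pairs sample identifiers with their soil organic matter (SOM)
#' concentrations in g/kg; the regression target throughout the pipeline.
#'
#' @param sample_ids unique identifiers.
#' @param som_g_per_kg SOM concentrations, g/kg; finite and strictly positive.
#' @return A data.frame with columns `sample_id` and `som_g_per_kg`, of class
#'   `soil_sample_table`.
#' @export
soil_sample_table <- function(sample_ids, som_g_per_kg) {
  sample_ids <- as.character(sample_ids)
  som_g_per_kg <- as.numeric(som_g_per_kg)
  if (length(sample_ids) != length(som_g_per_kg))
    stop("sample_ids and som_g_per_kg lengths differ", call. = FALSE)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id: ", sample_ids[anyDuplicated(sample_ids)],
         call. = FALSE)
  if (anyNA(som_g_per_kg) || any(!is.finite(som_g_per_kg)) || any(som_g_per_kg <= 0))
    stop("SOM values must be finite and > 0", call. = FALSE)
  structure(
    data.frame(sample_id = sample_ids, som_g_per_kg = som_g_per_kg,
               stringsAsFactors = FALSE),
    class = c("soil_sample_table", "data.frame"))
}

check_aligned <- function(s, som) {
  if (!identical(s$sample_ids, som$sample_id))
    stop("spectrum_set and soil_sample_table sample ids are not aligned",
         call. = FALSE)
  invisible(TRUE)
}

#' Read a wide spectra table
#'
#' Reads a delimited wide table whose first column is the sample id, second
#' column the SOM concentration (g/kg), and remaining columns reflectance at
#' integer wavelengths named by the header (nm). Wavelength columns are sorted
#' ascending regardless of file order. The delimiter is taken from the file
#' extension (`.tsv`/`.txt` = tab, otherwise comma).
#'
#' Reflectance is expected as a fraction in `[0, 1]`; tables stored in percent
#' are detected (any value > 1.5) and rejected rather than silently rescaled.
#'
#' @param path path to a CSV/TSV file.
#' @return A list with elements `spectra` (a `spectrum_set`, tag `"RAW"`) and
#'   `som` (a `soil_sample_table`).
#' @seealso [write_spectra_table()]
#' @export
read_spectra_table <- function(path) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, encoding = "UTF-8")
  if (ncol(df) < 3L)
    stop("spectra table needs sample id, SOM and at least one wavelength column",
         call. = FALSE)
  header <- names(df)
  if (!identical(tolower(header[2L]), "som_g_per_kg"))
    stop("second column must be 'som_g_per_kg', found '", header[2L], "'",
         call. = FALSE)
  wl_names <- header[-(1:2)]
  wl <- suppressWarnings(as.numeric(wl_names))
  bad <- which(is.na(wl) | wl != round(wl))
  if (length(bad))
    stop("non-integer wavelength column header: '", wl_names[bad[1L]], "'",
         call. = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate sample id: ", ids[anyDuplicated(ids)], call. = FALSE)
  som <- suppressWarnings(as.numeric(df[[2L]]))
  if (anyNA(som))
    stop("non-numeric SOM value in row ", which(is.na(som))[1L], call. = FALSE)
  vals <- as.matrix(df[, -(1:2), drop = FALSE])
  suppressWarnings(storage.mode(vals) <- "double")
  if (anyNA(vals)) {
    idx <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop("non-numeric spectral value at row ", idx[1L], ", column '",
         wl_names[idx[2L]], "'", call. = FALSE)
  }
  ord <- order(wl)
  vals <- vals[, ord, drop = FALSE]
  wl <- wl[ord]
  if (any(vals > 1.5))
    stop("reflectance values > 1.5 found; file appears to be in percent, ",
         "expected fractional reflectance in [0, 1]", call. = FALSE)
  list(spectra = spectrum_set(vals, wl, ids, "RAW"),
       som = soil_sample_table(ids, som))
}

#' Write a wide spectra table
#'
#' Writes the dialect [read_spectra_table()] reads: header
#' `sample_id, som_g_per_kg, <wavelengths...>`. Values are written with full
#' precision so a read/write round trip is bit-identical.
#'
#' @param spectra a `spectrum_set`.
#' @param som a `soil_sample_table` aligned with `spectra`.
#' @param path output path; `.tsv`/`.txt` gives a tab-separated file.
#' @return `path`, invisibly.
#' @export
write_spectra_table <- function(spectra, som, path) {
  check_aligned(spectra, som)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- data.frame(sample_id = spectra$sample_ids,
                   som_g_per_kg = som$som_g_per_kg,
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(spectra$values, check.names = FALSE))
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = sep, quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
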