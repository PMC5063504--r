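# Stable on-disk formats: spectra as two-column CSV with a JSON sidecar
# manifest, titration series and AUC distributions as TSV, fit results and
# run manifests as JSON. Floats are serialized with 17 significant digits so
# every write/read round-trips bit-for-bit.

manifest_path <- function(path) paste0(tools::file_path_sans_ext(path),
                                       ".json")

#' Write an emission scan as CSV with a JSON sidecar manifest
#'
#' The CSV has the header `wavelength_nm,intensity`; the sidecar
#' `<path minus extension>.json` records excitation wavelength, condition,
#' construct and any generator ground truth.
#'
#' @param spectrum a [new_spectrum()] object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "spectrum"))
  df <- data.frame(wavelength_nm = spectrum$wavelength_nm,
                   intensity = spectrum$intensity)
  utils::write.csv(format(df, digits = 17, scientific = FALSE,
                          trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  meta <- list(excitation_nm = spectrum$excitation_nm,
               condition = spectrum$condition,
               construct_id = spectrum$construct_id,
               truth = spectrum$truth)
  jsonlite::write_json(meta, manifest_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read an emission scan from CSV
#'
#' Expects the `wavelength_nm,intensity` header; metadata come from the
#' sidecar manifest when present or from the arguments. Parse failures are
#' reported with the offending line number.
#'
#' @param path CSV path.
#' @param excitation_nm,condition,construct_id metadata overrides when no
#'   sidecar manifest exists.
#' @return A [new_spectrum()] object.
#' @export
read_spectrum_csv <- function(path, excitation_nm = NA_real_,
                              condition = NA_character_,
                              construct_id = NA_character_) {
  header <- utils::read.csv(path, nrows = 1, check.names = FALSE)
  if (!all(c("wavelength_nm", "intensity") %in% names(header)))
    stop("file ", path,
         " lacks the required 'wavelength_nm,intensity' header")
  df <- utils::read.csv(path, colClasses = "character")
  wl <- suppressWarnings(as.numeric(df$wavelength_nm))
  it <- suppressWarnings(as.numeric(df$intensity))
  bad <- which(!is.finite(wl) | !is.finite(it))
  if (length(bad))
    stop("non-numeric or non-finite value in ", path, " at data row ",
         bad[1], " (file line ", bad[1] + 1, ")")
  if (length(wl) < 50)
    stop("insufficient points in ", path, ": ", length(wl),
         " (>= 50 required for the unmixing window)")
  if (any(diff(wl) <= 0))
    stop("wavelength grid not strictly increasing in ", path,
         " at data row ", which(diff(wl) <= 0)[1] + 1)
  mp <- manifest_path(path)
  if (file.exists(mp)) {
    meta <- jsonlite::read_json(mp, simplifyVector = TRUE)
    excitation_nm <- meta$excitation_nm %||% excitation_nm
    condition <- meta$condition %||% condition
    construct_id <- meta$construct_id %||% construct_id
    truth <- meta$truth
  } else truth <- NULL
  new_spectrum(wl, it, excitation_nm, condition, construct_id,
               truth = truth)
}

#' Write / read a titration series as TSV
#'
#' Columns: `ion`, `pX`, `replicate`, `response`.
#'
#' @param series a [titration_series].
#' @param path TSV path.
#' @return `write_titration_tsv`: `path` invisibly; `read_titration_tsv`:
#'   a [titration_series].
#' @export
write_titration_tsv <- function(series, path) {
  stopifnot(inherits(series, "titration_series"))
  df <- data.frame(ion = attr(series, "ion"), pX = series$pX,
                   replicate = series$replicate,
                   response = series$response)
  utils::write.table(format(df, digits = 17, scientific = FALSE,
                            trim = TRUE),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_titration_tsv
#' @param response_kind,construct_id metadata for the returned series.
#' @export
read_titration_tsv <- function(path, response_kind = "fret_ratio",
                               construct_id = NA_character_) {
  df <- utils::read.delim(path)
  if (!all(c("ion", "pX", "replicate", "response") %in% names(df)))
    stop("titration TSV ", path,
         " must have columns ion, pX, replicate, response")
  titration_series(df[c("pX", "response", "replicate")],
                   ion = as.character(df$ion[1]),
                   response_kind = response_kind,
                   construct_id = construct_id)
}

#' Write / read a sedimentation distribution as TSV
#'
#' Columns: `s`, `frequency`.
#'
#' @param dist data frame with columns `s` and `frequency`.
#' @param path TSV path.
#' @return `write_auc_tsv`: `path` invisibly; `read_auc_tsv`: the data
#'   frame.
#' @export
write_auc_tsv <- function(dist, path) {
  stopifnot(all(c("s", "frequency") %in% names(dist)))
  utils::write.table(format(dist[c("s", "frequency")], digits = 17,
                            scientific = FALSE, trim = TRUE),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_auc_tsv
#' @export
read_auc_tsv <- function(path) {
  df <- utils::read.delim(path)
  if (!all(c("s", "frequency") %in% names(df)))
    stop("AUC TSV ", path, " must have columns s, frequency")
  df
}
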