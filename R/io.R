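#' Save / load a subject as NIfTI plus JSON sidecar
#'
#' The intensity volume is written as 32-bit float NIfTI, the label volume as
#' 16-bit signed integer NIfTI, and the remaining metadata (disease status,
#' confounds, disk degeneration flags, spacing, subject id) as a JSON
#' sidecar. `path` is a file-path stem: `<path>_vol.nii.gz`,
#' `<path>_lab.nii.gz` and `<path>.json` are produced.
#'
#' @param record a [SpineSubject-class].
#' @param path file-path stem (directories must exist).
#' @return `saveSubject` returns `path` invisibly; `loadSubject` returns the
#'   reconstructed [SpineSubject-class].
#' @export
saveSubject <- function(record, path) {
  volFile <- paste0(path, "_vol.nii.gz")
  labFile <- paste0(path, "_lab.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(record@voxels, datatype = "float"),
                     volFile)
  RNifti::writeNifti(RNifti::asNifti(record@labels, datatype = "int16"),
                     labFile)
  meta <- list(subjectId = record@subjectId,
               diseaseStatus = record@diseaseStatus,
               confounds = as.list(record@confounds),
               diskDegenerated = as.list(record@diskDegenerated),
               spacing = record@spacing)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname saveSubject
#' @export
loadSubject <- function(path) {
  volFile <- paste0(path, "_vol.nii.gz")
  labFile <- paste0(path, "_lab.nii.gz")
  jsonFile <- paste0(path, ".json")
  for (f in c(volFile, labFile, jsonFile))
    if (!file.exists(f)) stop("missing file: ", f)
  vol <- tryCatch(suppressWarnings({
    x <- RNifti::readNifti(volFile)
    array(as.numeric(x), dim = dim(x))
  }), error = function(e)
    stop("failed to read ", volFile, ": ", conditionMessage(e)))
  lab <- tryCatch(suppressWarnings({
    x <- RNifti::readNifti(labFile)
    array(as.integer(x), dim = dim(x))
  }), error = function(e)
    stop("failed to read ", labFile, ": ", conditionMessage(e)))
  meta <- jsonlite::read_json(jsonFile, simplifyVector = TRUE)
  new("SpineSubject",
      voxels = vol, labels = lab,
      spacing = as.numeric(meta$spacing),
      diskDegenerated = as.logical(unlist(meta$diskDegenerated,
                                          use.names = FALSE) %||% logical()),
      diseaseStatus = as.integer(meta$diseaseStatus),
      confounds = as.character(unlist(meta$confounds, use.names = FALSE) %||%
                                 character()),
      subjectId = meta$subjectId)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a cohort manifest CSV
#'
#' @param records list of [SpineSubject-class].
#' @param paths file-path stems used with [saveSubject].
#' @param file output CSV path.
#' @return the manifest data.frame, invisibly.
#' @export
writeManifest <- function(records, paths, file) {
  df <- data.frame(
    subject_id = vapply(records, subjectId, character(1)),
    disease_status = vapply(records, diseaseStatus, integer(1)),
    confounds = vapply(records, function(r)
      paste(confounds(r), collapse = ";"), character(1)),
    path = paths,
    stringsAsFactors = FALSE)
  utils::write.csv(df, file, row.names = FALSE)
  invisible(df)
}
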