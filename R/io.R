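#' Read a CT volume
#'
#' Reads a NIfTI volume (.nii or .nii.gz) into a \linkS4class{VolumeGrid},
#' taking the voxel spacing from the header. NIfTI intensities are assumed
#' to be in Hounsfield units already (any scl_slope/scl_inter in the header
#' is applied by the reader). Slices are kept in stored order; by the
#' package convention slice 1 of the third dimension is the most cranial
#' slice, so volumes stored caudal-first must be flipped upstream.
#'
#' @param path Path to a NIfTI file.
#' @param formatHint \code{"auto"}, \code{"nifti"} or \code{"dicom_dir"}.
#'   DICOM series directories are not supported by this reader; convert the
#'   series to NIfTI (e.g. with dcm2niix, which applies the DICOM rescale
#'   slope/intercept) and pass the resulting file.
#' @return A \linkS4class{VolumeGrid}.
#' @export
readVolume <- function(path, formatHint = c("auto", "nifti", "dicom_dir")) {
  formatHint <- match.arg(formatHint)
  if (formatHint == "dicom_dir" ||
      (formatHint == "auto" && dir.exists(path)))
    stop("DICOM series input is not supported; convert the series to NIfTI ",
         "(e.g. with dcm2niix) and pass the .nii/.nii.gz file")
  if (!file.exists(path)) stop(sprintf("no such file or directory: %s", path))
  img <- RNifti::readNifti(path)
  arr <- .as3d(img, path)
  sp <- RNifti::pixdim(img)[1:3]
  if (length(sp) < 3L || any(!is.finite(sp)) || any(sp <= 0))
    stop(sprintf("missing or invalid voxel spacing metadata in %s", path))
  VolumeGrid(arr, sp)
}

.as3d <- function(img, path) {
  arr <- array(as.numeric(img), dim = dim(img))
  d <- dim(arr)
  if (length(d) > 3L) {
    if (all(d[-(1:3)] == 1L)) {
      arr <- array(arr, dim = d[1:3])
    } else {
      stop(sprintf("%s is not a 3D volume (dims %s)", path,
                   paste(d, collapse = "x")))
    }
  }
  if (length(dim(arr)) != 3L)
    stop(sprintf("%s is not a 3D volume", path))
  arr
}

#' Write a CT volume as NIfTI
#'
#' Values are stored as float64 so a written volume re-reads bit-identically.
#'
#' @param grid A \linkS4class{VolumeGrid}.
#' @param path Destination .nii or .nii.gz path.
#' @return The path, invisibly.
#' @export
writeVolume <- function(grid, path) {
  img <- RNifti::asNifti(grid@values)
  RNifti::pixdim(img) <- grid@spacing
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read a lung mask
#'
#' Reads a NIfTI mask or label image and checks congruence with the CT
#' grid. Any nonzero label counts as a member (parenchyma) voxel, so both
#' binary masks and multi-label segmentations are accepted.
#'
#' @param path Path to a NIfTI mask.
#' @param grid The \linkS4class{VolumeGrid} the mask belongs to.
#' @return A \linkS4class{LungMask}.
#' @export
readMask <- function(path, grid) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  img <- RNifti::readNifti(path)
  arr <- .as3d(img, path)
  if (!identical(dim(arr), dim(grid@values)))
    stop(sprintf("mask shape (%s) does not match volume shape (%s)",
                 paste(dim(arr), collapse = "x"),
                 paste(dim(grid@values), collapse = "x")))
  LungMask(arr)
}

#' Write a lung mask as NIfTI
#'
#' @param mask A \linkS4class{LungMask}.
#' @param spacing Voxel spacing (mm) to record in the header, typically
#'   \code{gridSpacing(grid)}.
#' @param path Destination .nii or .nii.gz path.
#' @return The path, invisibly.
#' @export
writeMask <- function(mask, spacing, path) {
  arr <- array(as.integer(mask@member), dim = dim(mask@member))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

## CSV/JSON header names carry units where a field has a fixed unit.
.SUMMARY_COLS <- c(V_total = "V_total_ml", M_total = "M_total_g",
                   V_gas_ml = "V_gas_ml", V_gas_pct = "V_gas_pct")

.recordRow <- function(rec, label) {
  if (is(rec, "LungSummary")) {
    df <- as.data.frame(rec)
    names(df)[match(names(.SUMMARY_COLS), names(df))] <- .SUMMARY_COLS
    cbind(data.frame(label = label, record = "LungSummary"), df)
  } else if (is(rec, "AgreementResult")) {
    cbind(data.frame(label = label, record = "AgreementResult"),
          as.data.frame(rec))
  } else {
    stop("records must be LungSummary or AgreementResult objects")
  }
}

#' Write labelled results to a delimited table
#'
#' Flattens a list of \linkS4class{LungSummary} and/or
#' \linkS4class{AgreementResult} objects into one table, one row per
#' record, with units encoded in the column names (\code{V_total_ml},
#' \code{M_total_g}, percentages as \code{pct_*}). Mixed record types get
#' the union of columns, with empty cells where a field does not apply.
#'
#' @param records A single record or a (preferably named) list of records;
#'   must be non-empty.
#' @param path Destination path.
#' @param format \code{"csv"} or \code{"json"}.
#' @return The path, invisibly.
#' @export
writeSummary <- function(records, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (is(records, "LungSummary") || is(records, "AgreementResult"))
    records <- list(records)
  if (!is.list(records) || !length(records))
    stop("'records' must be a non-empty list of result objects")
  labels <- names(records) %||% paste0("record_", seq_along(records))
  if (is.null(names(records))) names(records) <- labels
  labels[labels == ""] <- paste0("record_", which(labels == ""))
  rows <- Map(.recordRow, records, labels)
  allCols <- Reduce(union, lapply(rows, names))
  rows <- lapply(rows, function(r) {
    r[setdiff(allCols, names(r))] <- NA
    r[allCols]
  })
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (format == "csv") {
    ok <- tryCatch({
      utils::write.csv(tab, path, row.names = FALSE)
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok)) stop(sprintf("cannot write %s: %s", path,
                                  conditionMessage(ok)))
  } else {
    jsonlite::write_json(tab, path, dataframe = "rows", digits = NA,
                         na = "null")
  }
  invisible(path)
}

#' Re-read a results table written by writeSummary
#'
#' @param path Path to a CSV or JSON table.
#' @param format \code{"auto"} infers from the file extension.
#' @return A data.frame with one row per record.
#' @export
readSummaryTable <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (format == "csv")
    utils::read.csv(path, check.names = FALSE)
  else
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
}
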