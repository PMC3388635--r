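## ---- Reference-slice extrapolation -----------------------------------
##
## Whole-lung quantities are estimated from N reference slices: the most
## cranial and most caudal lung-bearing slices plus equidistant interior
## slices. For each absolute quantity Q the estimate is the pairwise
## trapezoid sum over consecutive reference slices, in units of slices,
## plus the two half-slice end caps:
##
##   Q_extra = sum_{i=1}^{N-1} (Q_i + Q_{i+1})/2 * (z_{i+1} - z_i)/t
##           + (Q_1 + Q_N)/2
##
## with slice centers z_i = index_i * t for contiguous acquisitions, so the
## interval weight is simply the index gap and the nominal thickness t
## cancels. The end-cap term makes the estimator exact when every slice is
## a reference slice (the sum telescopes to sum(Q_i)) and for profiles
## affine in slice index.

#' Cranio-caudal extent of the lung
#'
#' @param profile A \code{\link{sliceProfile}} data.frame.
#' @return Integer length-2: 1-based indices of the most cranial and most
#'   caudal slices with positive lung volume. Interior slices with zero
#'   volume are allowed (the extent spans them).
#' @export
lungExtent <- function(profile) {
  .checkProfile(profile)
  has <- which(profile$V > 0)
  if (!length(has)) stop("empty lung: no slice has positive volume")
  c(first = profile$slice[min(has)], last = profile$slice[max(has)])
}

#' Select equidistant reference slices
#'
#' Picks \code{nRef} slices between the lung extremes: the first and last
#' are fixed to the extremes and the interior ones are equidistant,
#' \code{index_k = first + round(k (last - first)/(nRef - 1))} for
#' \code{k = 0..nRef-1}, rounding ties toward the caudal end.
#'
#' @param first,last 1-based indices of the cranial-most and caudal-most
#'   lung-bearing slices.
#' @param nRef Number of reference slices (>= 2, <= available slices).
#' @param thicknessMm Nominal slice thickness (mm); recorded on the result.
#' @return A \linkS4class{ReferenceSelection}.
#' @examples
#' selectReferenceSlices(1, 55, 10)@indices
#' @export
selectReferenceSlices <- function(first, last, nRef, thicknessMm = 1) {
  first <- as.integer(first); last <- as.integer(last)
  nRef <- as.integer(nRef)
  if (nRef < 2L) stop("at least 2 reference slices are required")
  avail <- last - first + 1L
  if (avail < nRef)
    stop(sprintf("%d reference slices requested but only %d slices span the lung",
                 nRef, avail))
  k <- seq_len(nRef) - 1L
  idx <- first + as.integer(floor(k * (last - first) / (nRef - 1L) + 0.5))
  new("ReferenceSelection", indices = idx, thicknessMm = thicknessMm)
}

#' @describeIn ReferenceSelection number of reference slices.
#' @param x,object A \code{ReferenceSelection}.
#' @export
nRef <- function(x) length(x@indices)

#' @describeIn ReferenceSelection the selected 1-based slice indices.
#' @export
refIndices <- function(x) x@indices

setMethod("show", "ReferenceSelection", function(object) {
  cat(sprintf("ReferenceSelection: %d slices at t = %g mm\n  [%s]\n",
              length(object@indices), object@thicknessMm,
              paste(object@indices, collapse = ", ")))
})

#' Extrapolate whole-lung quantities from reference slices
#'
#' Applies the trapezoid-plus-end-caps estimator (see
#' \code{\link{selectReferenceSlices}}) to every absolute quantity of the
#' profile (V, M, gas volume and each compartment's volume and mass), then
#' derives compartment percentages from the extrapolated absolutes exactly
#' as \code{\link{wholeLungSummary}} does.
#'
#' @param profile A \code{\link{sliceProfile}} data.frame containing at
#'   least the rows at the selected indices (the full profile is fine; only
#'   the selected rows are used).
#' @param selection A \linkS4class{ReferenceSelection}, or an integer vector
#'   of strictly increasing 1-based slice indices.
#' @return A \linkS4class{LungSummary} of extrapolated quantities.
#' @export
extrapolate <- function(profile, selection) {
  .checkProfile(profile)
  if (is(selection, "ReferenceSelection")) {
    idx <- selection@indices
  } else {
    idx <- as.integer(selection)
    if (length(idx) < 2L || any(diff(idx) <= 0L))
      stop("'selection' must give at least 2 strictly increasing slice indices")
  }
  pos <- match(idx, profile$slice)
  if (anyNA(idx) || anyNA(pos))
    stop("profile does not contain every selected reference slice")

  gaps <- diff(idx) # (z_{i+1} - z_i)/t for contiguous slices at z = index*t
  est <- vapply(.PROFILE_QTY, function(q) {
    Q <- profile[[q]][pos]
    sum((Q[-length(Q)] + Q[-1L]) / 2 * gaps) + (Q[1L] + Q[length(Q)]) / 2
  }, 0)

  .lungSummary(est[["V"]], est[["M"]], est[["Vgas"]],
               est[paste0("V_", COMPARTMENTS)],
               est[paste0("M_", COMPARTMENTS)])
}

#' Extrapolation for a range of reference-slice counts
#'
#' Runs reference-slice selection and extrapolation for every slice count N
#' in \code{nMin..nMax}, the sweep used to study how accuracy degrades as
#' fewer slices are analyzed.
#'
#' @param profile A full \code{\link{sliceProfile}} data.frame.
#' @param nMin,nMax Range of reference-slice counts (defaults 5 and 15).
#' @param thicknessMm Nominal slice thickness (mm), recorded on selections.
#' @return A named list (\code{"N5"}, \code{"N6"}, ...) of
#'   \linkS4class{LungSummary} objects. If fewer lung-bearing slices than
#'   \code{nMax} are available the sweep truncates with a warning.
#' @export
sweepReferenceCounts <- function(profile, nMin = 5L, nMax = 15L,
                                 thicknessMm = 1) {
  if (nMin < 2L || nMax < nMin) stop("need 2 <= nMin <= nMax")
  ext <- lungExtent(profile)
  avail <- ext[["last"]] - ext[["first"]] + 1L
  top <- min(nMax, avail)
  if (top < nMax)
    warning(sprintf(
      "only %d slices span the lung; sweep truncated at N = %d", avail, top))
  if (top < nMin) stop("too few lung-bearing slices for the requested sweep")
  ns <- seq.int(nMin, top)
  out <- lapply(ns, function(n) {
    extrapolate(profile, selectReferenceSlices(ext[["first"]], ext[["last"]],
                                               n, thicknessMm))
  })
  names(out) <- paste0("N", ns)
  out
}
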