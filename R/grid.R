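#' Construct a VolumeGrid
#'
#' @param values 3D numeric array of attenuation values (HU); slice 1 of the
#'   third dimension is the most cranial slice.
#' @param spacing Numeric length-3: in-plane row, in-plane column and axial
#'   voxel spacing in mm. The axial component is the nominal slice thickness.
#' @return A \linkS4class{VolumeGrid}.
#' @examples
#' g <- VolumeGrid(array(-700, dim = c(4, 4, 3)), spacing = c(0.7, 0.7, 10))
#' nSlices(g)
#' @export
VolumeGrid <- function(values, spacing) {
  storage.mode(values) <- "double"
  new("VolumeGrid", values = values, spacing = as.numeric(spacing))
}

#' Construct a LungMask
#'
#' Nonzero values are treated as member (parenchyma) voxels, so integer label
#' images can be supplied directly.
#'
#' @param member 3D logical or numeric array; nonzero/\code{TRUE} marks lung.
#' @return A \linkS4class{LungMask}.
#' @export
LungMask <- function(member) {
  if (!is.logical(member)) {
    d <- dim(member)
    member <- array(member != 0, dim = d)
  }
  new("LungMask", member = member)
}

#' @describeIn VolumeGrid the attenuation array (HU).
#' @param x,object A \code{VolumeGrid}.
#' @export
gridValues <- function(x) x@values

#' @describeIn VolumeGrid voxel spacing (row, column, axial) in mm.
#' @export
gridSpacing <- function(x) x@spacing

#' @describeIn VolumeGrid number of axial slices.
#' @export
nSlices <- function(x) dim(x@values)[3L]

#' @describeIn LungMask the logical membership array.
#' @param x,object A \code{LungMask}.
#' @export
maskArray <- function(x) x@member

#' @describeIn LungMask number of member voxels.
#' @export
nMember <- function(x) sum(x@member)

## Congruence between a grid and its mask is a precondition of every
## analysis; checked at the point of use rather than at construction so a
## mask can outlive the grid it was read against.
.checkCongruent <- function(grid, mask) {
  dg <- dim(grid@values)
  dm <- dim(mask@member)
  if (!identical(dg, dm))
    stop(sprintf(
      "mask shape (%s) does not match volume shape (%s)",
      paste(dm, collapse = "x"), paste(dg, collapse = "x")), call. = FALSE)
  invisible(TRUE)
}

setMethod("show", "VolumeGrid", function(object) {
  d <- dim(object@values)
  cat(sprintf("VolumeGrid: %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], object@spacing[1], object@spacing[2],
              object@spacing[3]))
  cat(sprintf("  HU range [%.1f, %.1f]; slice 1 = most cranial\n",
              min(object@values), max(object@values)))
})

setMethod("show", "LungMask", function(object) {
  d <- dim(object@member)
  cat(sprintf("LungMask: %d x %d x %d voxels, %d member (%.1f%%)\n",
              d[1], d[2], d[3], sum(object@member),
              100 * mean(object@member)))
})

setMethod("dim", "VolumeGrid", function(x) dim(x@values))
setMethod("dim", "LungMask", function(x) dim(x@member))
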