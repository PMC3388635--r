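#' @import methods
NULL

#' The four aeration compartments on the Hounsfield scale
#'
#' Lung voxels within the analyzable \eqn{[-1000, +100]} HU window are
#' classified into four disjoint compartments whose closed integer ranges
#' exactly tile the window:
#' \describe{
#'   \item{non}{nonaerated, \eqn{[-100, +100]} HU}
#'   \item{poor}{poorly aerated, \eqn{[-500, -101]} HU}
#'   \item{normal}{normally aerated, \eqn{[-900, -501]} HU}
#'   \item{hyper}{hyperaerated, \eqn{[-1000, -901]} HU}
#' }
#' @format Character vector of the four compartment labels, ordered from
#'   densest (nonaerated) to most aerated (hyperaerated).
#' @export
COMPARTMENTS <- c("non", "poor", "normal", "hyper")

## Upper (inclusive) integer HU bound of each compartment, densest first.
.COMP_UPPER <- c(non = 100L, poor = -101L, normal = -501L, hyper = -901L)
.HU_MIN <- -1000L
.HU_MAX <- 100L

#' VolumeGrid: a 3D CT attenuation lattice
#'
#' Holds a 3D array of CT attenuation values in Hounsfield units together
#' with the voxel spacing. The third array dimension is axial, with slice 1
#' the most cranial slice; the axial spacing is the nominal slice thickness.
#'
#' @slot values 3D numeric array of attenuation values (HU); all finite.
#' @slot spacing Numeric length-3 vector (row mm, column mm, axial mm),
#'   all strictly positive.
#' @export
setClass("VolumeGrid",
  representation(values = "array", spacing = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@values)) != 3L)
      msg <- c(msg, "'values' must be a 3D array")
    if (length(object@spacing) != 3L || !all(is.finite(object@spacing)) ||
        any(object@spacing <= 0))
      msg <- c(msg, "'spacing' must be 3 strictly positive finite numbers (mm)")
    if (!all(is.finite(object@values)))
      msg <- c(msg, "all attenuation values must be finite")
    if (length(msg)) msg else TRUE
  }
)

#' LungMask: a binary lung-parenchyma mask
#'
#' A boolean lattice congruent with its \linkS4class{VolumeGrid}, marking the
#' voxels that belong to lung parenchyma. Masks are produced by external
#' segmentation with major pulmonary vessels, trachea and main bronchi
#' excluded; this package treats them as given.
#'
#' @slot member 3D logical array; \code{TRUE} marks a parenchyma voxel.
#' @export
setClass("LungMask",
  representation(member = "array"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@member)) != 3L)
      msg <- c(msg, "'member' must be a 3D array")
    if (!is.logical(object@member))
      msg <- c(msg, "'member' must be logical")
    if (anyNA(object@member))
      msg <- c(msg, "'member' must not contain NA")
    if (length(msg)) msg else TRUE
  }
)

#' LungSummary: whole-lung (or extrapolated) totals and compartment shares
#'
#' Totals are in absolute units (ml, g); compartment breakdowns are carried
#' both absolutely and as percentages of the respective total, the form the
#' aeration literature reports.
#'
#' @slot vTotal Total lung volume (ml).
#' @slot mTotal Total lung mass (g).
#' @slot vGasMl Gas volume (ml).
#' @slot vGasPct Gas volume as percent of \code{vTotal}.
#' @slot vComp,mComp Named numeric length-4 (names \code{COMPARTMENTS}):
#'   absolute compartment volume (ml) and mass (g).
#' @slot pctV,pctM Named numeric length-4: compartment volume and mass as
#'   percent of the totals.
#' @export
setClass("LungSummary",
  representation(vTotal = "numeric", mTotal = "numeric",
                 vGasMl = "numeric", vGasPct = "numeric",
                 vComp = "numeric", mComp = "numeric",
                 pctV = "numeric", pctM = "numeric"),
  validity = function(object) {
    msg <- character()
    for (s in c("vTotal", "mTotal", "vGasMl", "vGasPct"))
      if (length(slot(object, s)) != 1L || !is.finite(slot(object, s)) ||
          slot(object, s) < 0)
        msg <- c(msg, sprintf("'%s' must be one finite non-negative number", s))
    for (s in c("vComp", "mComp", "pctV", "pctM")) {
      v <- slot(object, s)
      if (length(v) != 4L || !identical(names(v), COMPARTMENTS) ||
          any(!is.finite(v)) || any(v < 0))
        msg <- c(msg, sprintf(
          "'%s' must be 4 non-negative values named non/poor/normal/hyper", s))
    }
    if (!length(msg)) {
      if (abs(sum(object@pctV) - 100) > 1e-6)
        msg <- c(msg, "compartment volume percentages must sum to 100")
      if (abs(sum(object@pctM) - 100) > 1e-6)
        msg <- c(msg, "compartment mass percentages must sum to 100")
      if (object@vGasMl > object@vTotal * (1 + 1e-9))
        msg <- c(msg, "gas volume cannot exceed total volume")
    }
    if (length(msg)) msg else TRUE
  }
)

#' ReferenceSelection: the reference slices used for extrapolation
#'
#' The most cranial and most caudal lung-bearing slices plus equidistant
#' interior slices, as chosen by \code{\link{selectReferenceSlices}}.
#'
#' @slot indices Strictly increasing 1-based axial slice indices; first and
#'   last are the lung extremes.
#' @slot thicknessMm Nominal slice thickness t (mm); slice centers are
#'   assumed contiguous at positions \code{index * t}.
#' @export
setClass("ReferenceSelection",
  representation(indices = "integer", thicknessMm = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@indices) < 2L)
      msg <- c(msg, "at least 2 reference slices are required")
    if (any(diff(object@indices) <= 0L))
      msg <- c(msg, "'indices' must be strictly increasing")
    if (length(object@thicknessMm) != 1L || !is.finite(object@thicknessMm) ||
        object@thicknessMm <= 0)
      msg <- c(msg, "'thicknessMm' must be one positive number")
    if (length(msg)) msg else TRUE
  }
)

#' AgreementResult: Bland-Altman bias and 95% limits of agreement
#'
#' Differences are reference minus test (whole-lung minus extrapolated), so a
#' positive bias means the test method underestimates.
#'
#' @slot metric Name of the compared metric.
#' @slot n Number of pairs.
#' @slot bias Mean difference, in the metric's units.
#' @slot sdDiff Sample standard deviation of the differences (n - 1).
#' @slot loaLower,loaUpper \code{bias -/+ 1.96 * sdDiff}.
#' @export
setClass("AgreementResult",
  representation(metric = "character", n = "integer", bias = "numeric",
                 sdDiff = "numeric", loaLower = "numeric",
                 loaUpper = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@n < 3L)
      msg <- c(msg, "limits of agreement need at least 3 pairs")
    if (abs(object@loaLower - (object@bias - 1.96 * object@sdDiff)) > 1e-9 ||
        abs(object@loaUpper - (object@bias + 1.96 * object@sdDiff)) > 1e-9)
      msg <- c(msg, "limits of agreement must equal bias +/- 1.96 * sdDiff")
    if (length(msg)) msg else TRUE
  }
)

#' PhantomSpec: parameters of one synthetic lung phantom
#'
#' Describes a whole-lung CT phantom: two ellipsoidal lung fields inside a
#' water-equivalent thorax, with a ventro-dorsal aeration gradient, Gaussian
#' HU noise, and an optional dependent (dorsal, caudally weighted when
#' opacified) atelectatic region set to water-like attenuation.
#'
#' @slot preset One of \code{"sheep_normal"}, \code{"sheep_opacified"},
#'   \code{"pig_normal"}, \code{"pig_opacified"}.
#' @slot lungHeightMm Cranio-caudal lung extent (mm), within 218--320.
#' @slot sliceThicknessMm Nominal slice thickness (mm), one of 5, 6, 7.5, 10.
#' @slot inPlaneMm In-plane voxel spacing (mm).
#' @slot targetVTotalMl Target total lung volume (ml).
#' @slot atelectasisFraction Fraction of lung voxels assigned dependent
#'   nonaerated attenuation, in [0, 0.6].
#' @slot baseHu Mean attenuation of aerated lung (HU).
#' @slot gradientSlopeHuPerMm Ventro-dorsal attenuation gradient (HU/mm).
#' @slot noiseSdHu Gaussian attenuation noise SD (HU).
#' @slot seed RNG seed for the phantom's noise field.
#' @export
setClass("PhantomSpec",
  representation(preset = "character", lungHeightMm = "numeric",
                 sliceThicknessMm = "numeric", inPlaneMm = "numeric",
                 targetVTotalMl = "numeric", atelectasisFraction = "numeric",
                 baseHu = "numeric", gradientSlopeHuPerMm = "numeric",
                 noiseSdHu = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (!object@preset %in% names(.PRESETS))
      msg <- c(msg, paste("unknown preset; use one of:",
                          paste(names(.PRESETS), collapse = ", ")))
    if (object@lungHeightMm < 218 || object@lungHeightMm > 320)
      msg <- c(msg, "'lungHeightMm' must lie within 218-320 mm")
    if (!object@sliceThicknessMm %in% c(5, 6, 7.5, 10))
      msg <- c(msg, "'sliceThicknessMm' must be one of 5, 6, 7.5, 10 mm")
    if (object@inPlaneMm <= 0)
      msg <- c(msg, "'inPlaneMm' must be positive")
    if (object@targetVTotalMl <= 0)
      msg <- c(msg, "'targetVTotalMl' must be positive")
    if (object@atelectasisFraction < 0 || object@atelectasisFraction > 0.6)
      msg <- c(msg, "'atelectasisFraction' must lie in [0, 0.6]")
    if (object@noiseSdHu < 0)
      msg <- c(msg, "'noiseSdHu' must be non-negative")
    if (length(msg)) msg else TRUE
  }
)
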