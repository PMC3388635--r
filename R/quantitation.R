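## ---- Voxel-level density model ---------------------------------------
##
## Standard quantitative-CT linear gas/tissue mixture: a voxel at HU h is a
## mixture of gas (-1000 HU) and water-equivalent tissue (0 HU), so
##   tissue density rho(h) = (h + 1000)/1000 g/ml,
##   gas fraction      f(h) = max(0, -h/1000).
## Voxels above 0 HU carry density > 1 g/ml and no gas.

#' Voxel volume in millilitres
#'
#' @param spacing Numeric length-3 voxel spacing (mm).
#' @return The voxel volume in ml (1 ml = 1000 mm^3).
#' @examples
#' voxelVolumeMl(c(0.5, 0.5, 10)) # 0.0025
#' @export
voxelVolumeMl <- function(spacing) {
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be 3 strictly positive numbers (mm)")
  prod(spacing) / 1000
}

## Round to nearest integer, ties away from zero (commercial rounding), the
## convention under which the printed compartment ranges tile the HU window.
.roundHU <- function(hu) sign(hu) * floor(abs(hu) + 0.5)

#' Classify Hounsfield values into aeration compartments
#'
#' Values are rounded to the nearest integer (ties away from zero) and
#' assigned to the unique compartment whose closed integer range contains the
#' result: nonaerated \eqn{[-100, +100]}, poorly aerated \eqn{[-500, -101]},
#' normally aerated \eqn{[-900, -501]}, hyperaerated \eqn{[-1000, -901]}.
#'
#' @param hu Numeric vector of attenuation values (HU).
#' @return Factor with levels \code{COMPARTMENTS}; \code{NA} flags values
#'   outside \eqn{[-1000, +100]} after rounding (the caller excludes them).
#' @examples
#' compartmentOf(c(-950, -500, -100, 0, 150))
#' @export
compartmentOf <- function(hu) {
  r <- .roundHU(hu)
  ## breaks at the lower edge of each compartment, most aerated first
  idx <- findInterval(r, c(-1000, -900, -500, -100, 101))
  idx[idx < 1L | idx > 4L] <- NA_integer_
  ## findInterval counts from the hyper end; flip to the COMPARTMENTS order
  factor(COMPARTMENTS[5L - idx], levels = COMPARTMENTS)
}

#' Tissue density of a lung voxel
#'
#' Linear gas/tissue mixture model: \eqn{\rho(h) = (h + 1000)/1000} g/ml,
#' applied across the whole analyzable window including (0, +100] HU.
#'
#' @param hu Numeric vector of attenuation values within \eqn{[-1000, +100]}.
#' @return Tissue density in g/ml.
#' @export
tissueDensity <- function(hu) {
  if (any(hu < -1000 | hu > 100))
    stop("attenuation outside [-1000, +100] HU has no defined tissue density")
  (hu + 1000) / 1000
}

#' Gas fraction of a lung voxel
#'
#' \eqn{f(h) = \max(0, -h/1000)}: pure gas at -1000 HU, no gas at or above
#' water density.
#'
#' @inheritParams tissueDensity
#' @return Gas fraction in [0, 1].
#' @export
gasFraction <- function(hu) {
  if (any(hu < -1000 | hu > 100))
    stop("attenuation outside [-1000, +100] HU has no defined gas fraction")
  pmax(0, -hu / 1000)
}

## Column layout of a slice profile; absolute quantities that extrapolation
## operates on are everything except slice/nVoxels/nExcluded.
.PROFILE_QTY <- c("V", "M", "Vgas",
                  paste0("V_", COMPARTMENTS), paste0("M_", COMPARTMENTS))

#' Per-slice quantitative CT profile
#'
#' Computes, for every axial slice, the absolute volume (ml), tissue mass
#' (g) and gas volume (ml) of the lung, overall and per aeration
#' compartment, by summing voxel volume, voxel volume times tissue density
#' and voxel volume times gas fraction over the member voxels whose rounded
#' attenuation lies in \eqn{[-1000, +100]} HU. Member voxels outside that
#' window are excluded from every quantity and counted in \code{nExcluded}.
#'
#' @param grid A \linkS4class{VolumeGrid}.
#' @param mask A congruent \linkS4class{LungMask}.
#' @return A data.frame with one row per axial slice (cranial to caudal) and
#'   columns \code{slice} (1-based), \code{nVoxels} (included member voxels),
#'   \code{nExcluded}, \code{V}, \code{M}, \code{Vgas}, and \code{V_<c>},
#'   \code{M_<c>} for each compartment. Slices without member voxels are
#'   all-zero rows.
#' @export
sliceProfile <- function(grid, mask) {
  .checkCongruent(grid, mask)
  d <- dim(grid@values)
  nz <- d[3L]
  vv <- voxelVolumeMl(grid@spacing)

  idx <- which(mask@member)
  out <- data.frame(slice = seq_len(nz), nVoxels = 0L, nExcluded = 0L)
  for (q in .PROFILE_QTY) out[[q]] <- 0
  if (!length(idx)) return(out)

  slice <- ((idx - 1L) %/% (d[1L] * d[2L])) + 1L
  hu <- grid@values[idx]
  r <- .roundHU(hu)
  keep <- r >= .HU_MIN & r <= .HU_MAX

  exc <- tabulate(slice[!keep], nbins = nz)
  out$nExcluded <- exc

  slice <- slice[keep]
  hu <- hu[keep]
  if (length(hu)) {
    out$nVoxels <- tabulate(slice, nbins = nz)
    dens <- pmax(0, (hu + 1000) / 1000)
    gas <- pmax(0, -hu / 1000)
    base <- rowsum(cbind(dens, gas), slice)
    sl <- as.integer(rownames(base))
    out$V[out$nVoxels > 0] <- out$nVoxels[out$nVoxels > 0] * vv
    out$M[sl] <- base[, 1L] * vv
    out$Vgas[sl] <- base[, 2L] * vv

    comp <- compartmentOf(hu) # cannot be NA after the keep filter
    key <- (slice - 1L) * 4L + as.integer(comp)
    per <- rowsum(cbind(1, dens), key)
    k <- as.integer(rownames(per))
    ksl <- ((k - 1L) %/% 4L) + 1L
    kc <- ((k - 1L) %% 4L) + 1L
    for (ci in 1:4) {
      sel <- kc == ci
      out[[paste0("V_", COMPARTMENTS[ci])]][ksl[sel]] <- per[sel, 1L] * vv
      out[[paste0("M_", COMPARTMENTS[ci])]][ksl[sel]] <- per[sel, 2L] * vv
    }
  }
  out
}

#' Quantities of a single axial slice
#'
#' @inheritParams sliceProfile
#' @param sliceIndex 1-based axial slice index.
#' @return A one-row data.frame in the \code{\link{sliceProfile}} layout.
#' @export
sliceQuantities <- function(grid, mask, sliceIndex) {
  nz <- dim(grid@values)[3L]
  if (length(sliceIndex) != 1L || sliceIndex < 1L || sliceIndex > nz)
    stop(sprintf("'sliceIndex' must lie in 1..%d", nz))
  p <- sliceProfile(grid, mask)
  p[p$slice == as.integer(sliceIndex), , drop = FALSE]
}

## Assemble a LungSummary from absolute totals (ml, g). Shared by the
## whole-lung and extrapolated paths so both derive percentages identically.
.lungSummary <- function(V, M, Vgas, vComp, mComp) {
  if (V <= 0) stop("empty lung: total volume is zero")
  names(vComp) <- names(mComp) <- COMPARTMENTS
  if (M <= 0)
    stop("degenerate lung: zero tissue mass, percentages undefined")
  new("LungSummary",
      vTotal = V, mTotal = M, vGasMl = Vgas, vGasPct = 100 * Vgas / V,
      vComp = vComp, mComp = mComp,
      pctV = 100 * vComp / V,
      pctM = 100 * mComp / M)
}

#' Whole-lung summary from a per-slice profile
#'
#' Sums the absolute per-slice quantities over all slices and derives the
#' compartment percentages from the summed absolutes (not from per-slice
#' percentages): \eqn{\%V_c = 100 \Sigma V_c / V_{total}} and analogously
#' for masses and gas.
#'
#' @param profile A data.frame as returned by \code{\link{sliceProfile}} (any
#'   subset of rows; typically all slices covering the lung).
#' @return A \linkS4class{LungSummary}.
#' @export
wholeLungSummary <- function(profile) {
  .checkProfile(profile)
  .lungSummary(sum(profile$V), sum(profile$M), sum(profile$Vgas),
               vapply(paste0("V_", COMPARTMENTS),
                      function(cn) sum(profile[[cn]]), 0),
               vapply(paste0("M_", COMPARTMENTS),
                      function(cn) sum(profile[[cn]]), 0))
}

.checkProfile <- function(profile) {
  need <- c("slice", .PROFILE_QTY)
  miss <- setdiff(need, names(profile))
  if (length(miss))
    stop("profile is missing columns: ", paste(miss, collapse = ", "))
  if (!nrow(profile)) stop("empty profile")
  invisible(TRUE)
}

#' Analyze a CT volume and mask in one step
#'
#' @inheritParams sliceProfile
#' @return A list with elements \code{profile} (the
#'   \code{\link{sliceProfile}} data.frame) and \code{summary} (the
#'   whole-lung \linkS4class{LungSummary}).
#' @export
analyzeVolume <- function(grid, mask) {
  profile <- sliceProfile(grid, mask)
  list(profile = profile, summary = wholeLungSummary(profile))
}

## ---- LungSummary accessors -------------------------------------------

#' @describeIn LungSummary total lung volume (ml).
#' @param x,object A \code{LungSummary}.
#' @export
vTotal <- function(x) x@vTotal

#' @describeIn LungSummary total lung mass (g).
#' @export
mTotal <- function(x) x@mTotal

#' @describeIn LungSummary gas volume, in ml or as percent of total volume.
#' @param percent Return the percentage form?
#' @export
vGas <- function(x, percent = FALSE) if (percent) x@vGasPct else x@vGasMl

#' @describeIn LungSummary compartment percentages of total volume or mass.
#' @param what \code{"volume"} or \code{"mass"}.
#' @export
compartmentPct <- function(x, what = c("volume", "mass")) {
  what <- match.arg(what)
  if (what == "volume") x@pctV else x@pctM
}

## Metric names accepted by metricValue(); the vocabulary used throughout
## the agreement and study layers.
.METRICS <- c("V_total", "M_total", "V_gas_ml", "V_gas_pct",
              paste0("pct_V_", COMPARTMENTS), paste0("pct_M_", COMPARTMENTS))

#' Extract a named metric from a LungSummary
#'
#' @param x A \linkS4class{LungSummary}.
#' @param metric One of \code{"V_total"}, \code{"M_total"},
#'   \code{"V_gas_ml"}, \code{"V_gas_pct"}, \code{"pct_V_<c>"} or
#'   \code{"pct_M_<c>"} with \code{<c>} a compartment label.
#' @return The metric value (ml, g or percent).
#' @export
metricValue <- function(x, metric) {
  metric <- match.arg(metric, .METRICS)
  switch(metric,
    V_total = x@vTotal, M_total = x@mTotal,
    V_gas_ml = x@vGasMl, V_gas_pct = x@vGasPct,
    if (startsWith(metric, "pct_V_"))
      x@pctV[[sub("pct_V_", "", metric)]]
    else
      x@pctM[[sub("pct_M_", "", metric)]])
}

#' @rdname metricValue
#' @export
lungMetrics <- function() .METRICS

#' Flatten a LungSummary to a one-row data.frame
#'
#' @param x A \linkS4class{LungSummary}.
#' @param row.names,optional,... Passed for S3 compatibility; unused.
#' @export
as.data.frame.LungSummary <- function(x, row.names = NULL, optional = FALSE,
                                      ...) {
  vals <- vapply(.METRICS, function(m) metricValue(x, m), 0)
  as.data.frame(as.list(vals), row.names = row.names)
}

setMethod("show", "LungSummary", function(object) {
  cat("LungSummary\n")
  cat(sprintf("  V_total %.1f ml   M_total %.1f g   V_gas %.1f ml (%.1f%%)\n",
              object@vTotal, object@mTotal, object@vGasMl, object@vGasPct))
  cat(sprintf("  %%V  non %.1f  poor %.1f  normal %.1f  hyper %.1f\n",
              object@pctV[1], object@pctV[2], object@pctV[3], object@pctV[4]))
  cat(sprintf("  %%M  non %.1f  poor %.1f  normal %.1f  hyper %.1f\n",
              object@pctM[1], object@pctM[2], object@pctM[3], object@pctM[4]))
})
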