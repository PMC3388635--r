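## ---- Synthetic whole-lung CT phantoms --------------------------------
##
## Each phantom is a pair of ellipsoidal lung fields inside a
## water-equivalent (0 HU) thorax. Aerated lung attenuation is Gaussian
## around a base value near -700 HU with a ventro-dorsal gradient (denser
## dorsally, as in supine mechanically ventilated animals). Opacified
## presets add a dependent region -- the most dorsal (and, for opacified
## lungs, caudally weighted) fraction of lung voxels -- set to water-like
## attenuation, emulating dependent atelectasis. Preset parameter ranges
## follow whole-lung measurements reported for mechanically ventilated
## sheep and pigs.

## Per-preset sampling ranges: total lung volume (ml), nonaerated volume
## fraction (of lung volume), cranio-caudal height (mm), default slice
## thickness (mm), plus the single-phantom default volume/height/fraction.
.PRESETS <- list(
  sheep_normal = list(
    vTotal = c(2245, 5638), vNonFrac = c(0.000, 0.008),
    height = c(222, 320), thickness = 10,
    defVTotal = 3748, defHeight = 278, defFrac = 0.005),
  sheep_opacified = list(
    vTotal = c(1338, 4252), vNonFrac = c(0.003, 0.322),
    height = c(222, 320), thickness = 10,
    defVTotal = 2827, defHeight = 278, defFrac = 0.039),
  pig_normal = list(
    vTotal = c(1114, 3061), vNonFrac = c(0.000, 0.012),
    height = c(218, 308), thickness = 7.5,
    defVTotal = 2308, defHeight = 270, defFrac = 0.001),
  pig_opacified = list(
    vTotal = c(698, 3184), vNonFrac = c(0.000, 0.435),
    height = c(218, 308), thickness = 7.5,
    defVTotal = 1868, defHeight = 270, defFrac = 0.036)
)

#' Available phantom presets
#' @return Character vector of preset names.
#' @export
phantomPresets <- function() names(.PRESETS)

#' Construct a PhantomSpec
#'
#' Unspecified parameters default to the preset's typical values: the
#' species-typical total volume, lung height, nonaerated fraction and slice
#' thickness, 0.7 mm in-plane spacing, -700 HU base aeration, a 1 HU/mm
#' ventro-dorsal gradient and 50 HU noise.
#'
#' @param preset Preset name, see \code{\link{phantomPresets}}.
#' @param lungHeightMm,sliceThicknessMm,inPlaneMm,targetVTotalMl,atelectasisFraction,baseHu,gradientSlopeHuPerMm,noiseSdHu
#'   Overrides for the slots of \linkS4class{PhantomSpec}.
#' @param seed RNG seed for the phantom noise field.
#' @return A validated \linkS4class{PhantomSpec}.
#' @export
phantomSpec <- function(preset = "sheep_normal", lungHeightMm = NULL,
                        sliceThicknessMm = NULL, inPlaneMm = 0.7,
                        targetVTotalMl = NULL, atelectasisFraction = NULL,
                        baseHu = -700, gradientSlopeHuPerMm = 1,
                        noiseSdHu = 50, seed = 1L) {
  if (!preset %in% names(.PRESETS))
    stop(sprintf("unknown preset '%s'; use one of: %s", preset,
                 paste(names(.PRESETS), collapse = ", ")))
  p <- .PRESETS[[preset]]
  new("PhantomSpec", preset = preset,
      lungHeightMm = lungHeightMm %||% p$defHeight,
      sliceThicknessMm = sliceThicknessMm %||% p$thickness,
      inPlaneMm = inPlaneMm,
      targetVTotalMl = targetVTotalMl %||% p$defVTotal,
      atelectasisFraction = atelectasisFraction %||% p$defFrac,
      baseHu = baseHu, gradientSlopeHuPerMm = gradientSlopeHuPerMm,
      noiseSdHu = noiseSdHu, seed = as.integer(seed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Run code with a locally seeded Mersenne-Twister, restoring the caller's
## RNG state afterwards; all phantom randomness flows through this.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

## Deterministic child seed i of a master seed, kept within 32-bit range.
.childSeed <- function(master, i) {
  as.integer((as.double(master) + as.double(i) * 100003) %% 2147483647)
}

## Axial layout: ceil(H/t) lung-bearing slices flanked by 2 empty slices on
## each side. Per lung slice, the in-plane scale factor of the ellipsoid
## cross-section is evaluated at the midpoint of the overlap between the
## slice slab and the lung's axial span, so the caudal tip slab (possibly
## partial) still receives a nonempty cross-section.
.axialScales <- function(H, t) {
  nzLung <- as.integer(ceiling(H / t - 1e-9))
  zlo <- (seq_len(nzLung) - 1) * t
  zhi <- pmin(seq_len(nzLung) * t, H)
  zmid <- (zlo + zhi) / 2
  s <- (zmid - H / 2) / (H / 2)
  list(nzLung = nzLung, scale = sqrt(pmax(0, 1 - s^2)))
}

#' Generate a synthetic whole-lung CT phantom
#'
#' Builds the attenuation volume, the lung mask and the exact ground-truth
#' summary. The ground truth is computed by direct voxel bookkeeping over
#' the generated attenuation values (one flat pass, no slice bucketing), so
#' it is an oracle for the analysis pipeline rather than a re-analysis.
#'
#' @param spec A \linkS4class{PhantomSpec}.
#' @return A list with elements \code{grid} (\linkS4class{VolumeGrid}),
#'   \code{mask} (\linkS4class{LungMask}), \code{truth}
#'   (\linkS4class{LungSummary}) and \code{spec}.
#' @examples
#' ph <- generatePhantom(phantomSpec("sheep_normal", seed = 7))
#' ph$truth
#' @export
generatePhantom <- function(spec) {
  validObject(spec)
  .withSeed(spec@seed, .generatePhantomImpl(spec))
}

.generatePhantomImpl <- function(spec) {
  t <- spec@sliceThicknessMm
  dxy <- spec@inPlaneMm
  H <- spec@lungHeightMm
  ax <- .axialScales(H, t)
  nzLung <- ax$nzLung
  scale <- ax$scale
  nPad <- 2L
  nz <- nzLung + 2L * nPad

  ## size the two ellipses so the summed cross-sections hit the volume target
  aspect <- 0.75 # dorso-ventral semi-axis relative to lateral
  sumSc2 <- sum(scale^2)
  a <- sqrt(spec@targetVTotalMl * 1000 / (2 * pi * aspect * t * sumSc2))
  b <- aspect * a
  cx <- a + 4 # lateral lung-center offset; 8 mm mediastinal gap

  nx <- as.integer(ceiling(2 * (cx + a + 10) / dxy))
  ny <- as.integer(ceiling(2 * (b + 10) / dxy))
  x <- (seq_len(nx) - (nx + 1) / 2) * dxy
  y <- (seq_len(ny) - (ny + 1) / 2) * dxy # +y = dorsal

  vol <- array(0, dim = c(nx, ny, nz)) # water-equivalent thorax
  mask <- array(FALSE, dim = c(nx, ny, nz))
  huBase <- matrix(spec@baseHu + spec@gradientSlopeHuPerMm * y,
                   nrow = nx, ncol = ny, byrow = TRUE)
  for (k in seq_len(nzLung)) {
    sc <- scale[k]
    if (sc <= 0) next
    qx2 <- ((abs(x) - cx) / (a * sc))^2
    qy2 <- (y / (b * sc))^2
    member <- outer(qx2, qy2, "+") <= 1
    n <- sum(member)
    if (!n) next
    hu <- huBase[member] + stats::rnorm(n, 0, spec@noiseSdHu)
    sl <- vol[, , k + nPad]
    sl[member] <- pmin(100, pmax(-1000, hu))
    vol[, , k + nPad] <- sl
    msl <- mask[, , k + nPad]
    msl[member] <- TRUE
    mask[, , k + nPad] <- msl
  }

  idx <- which(mask)
  if (!length(idx)) stop("degenerate phantom: no lung voxels generated")

  ## dependent atelectasis: most dorsal voxels, caudally weighted when the
  ## preset is opacified
  nAt <- round(spec@atelectasisFraction * length(idx))
  if (nAt > 0) {
    iy <- ((idx - 1L) %/% nx) %% ny + 1L
    iz <- (idx - 1L) %/% (nx * ny) + 1L
    caudalWeight <- if (grepl("opacified", spec@preset)) 0.4 else 0
    score <- y[iy] + caudalWeight * (iz * t)
    sel <- idx[order(score, idx, decreasing = TRUE)[seq_len(nAt)]]
    vol[sel] <- pmin(100, pmax(-100, stats::rnorm(nAt, 0, 20)))
  }

  grid <- VolumeGrid(vol, c(dxy, dxy, t))
  lmask <- new("LungMask", member = mask)

  ## constructive ground truth: flat pass over the member voxels
  hu <- vol[idx]
  vv <- voxelVolumeMl(c(dxy, dxy, t))
  dens <- pmax(0, (hu + 1000) / 1000)
  gas <- pmax(0, -hu / 1000)
  comp <- compartmentOf(hu)
  vC <- vapply(COMPARTMENTS, function(cc) sum(comp == cc) * vv, 0)
  mC <- vapply(COMPARTMENTS, function(cc) sum(dens[comp == cc]) * vv, 0)
  truth <- .lungSummary(length(idx) * vv, sum(dens) * vv, sum(gas) * vv,
                        vC, mC)

  list(grid = grid, mask = lmask, truth = truth, spec = spec)
}

#' Sample the per-phantom specs of a cohort
#'
#' Total volume, lung height and atelectasis fraction are drawn uniformly
#' within the central 90% of the preset's range (the margin absorbs
#' voxelization error at the range edges); each phantom receives a child
#' seed derived from the master seed by counter.
#'
#' @param n Cohort size.
#' @param preset Preset name.
#' @param seed Master seed.
#' @param ... Further overrides passed to \code{\link{phantomSpec}}.
#' @return List of \code{n} \linkS4class{PhantomSpec} objects.
#' @export
cohortSpecs <- function(n, preset = "sheep_normal", seed = 1L, ...) {
  if (n < 1L) stop("'n' must be at least 1")
  if (!preset %in% names(.PRESETS))
    stop(sprintf("unknown preset '%s'", preset))
  p <- .PRESETS[[preset]]
  inner <- function(r) r[1] + c(0.05, 0.95) * diff(r)
  .withSeed(seed, {
    vT <- stats::runif(n, inner(p$vTotal)[1], inner(p$vTotal)[2])
    hh <- stats::runif(n, inner(p$height)[1], inner(p$height)[2])
    fr <- stats::runif(n, inner(p$vNonFrac)[1], inner(p$vNonFrac)[2])
    lapply(seq_len(n), function(i)
      phantomSpec(preset, targetVTotalMl = vT[i], lungHeightMm = hh[i],
                  atelectasisFraction = fr[i],
                  seed = .childSeed(seed, i), ...))
  })
}

#' Generate a cohort of phantoms
#'
#' @inheritParams cohortSpecs
#' @return List of \code{n} phantoms as returned by
#'   \code{\link{generatePhantom}}. For large cohorts consider iterating
#'   over \code{\link{cohortSpecs}} instead to avoid holding every volume
#'   in memory.
#' @export
generateCohort <- function(n, preset = "sheep_normal", seed = 1L, ...) {
  lapply(cohortSpecs(n, preset, seed, ...), generatePhantom)
}

#' Generate a pre/post-recruitment phantom pair
#'
#' Emulates consecutive CTs before and after an airway-pressure increase:
#' the second phantom shares the first one's geometry parameters and noise
#' seed, with a fraction \code{recruit} of the atelectatic volume
#' re-aerated and the total lung volume inflated by the factor
#' \code{1 + inflate}.
#'
#' @param spec \linkS4class{PhantomSpec} of the baseline (pre) phantom.
#' @param deltaAeration List with elements \code{recruit} and \code{inflate},
#'   both in [0, 1].
#' @param seed Optional seed override for the pair (defaults to the spec's).
#' @return List with phantoms \code{t1} and \code{t2} and the ground-truth
#'   metric changes \code{truthDelta} (named numeric over
#'   \code{\link{lungMetrics}}).
#' @export
generateRecruitmentPair <- function(spec,
                                    deltaAeration = list(recruit = 0.8,
                                                         inflate = 0.2),
                                    seed = NULL) {
  recruit <- deltaAeration$recruit
  inflate <- deltaAeration$inflate
  if (is.null(recruit) || is.null(inflate) ||
      recruit < 0 || recruit > 1 || inflate < 0 || inflate > 1)
    stop("'deltaAeration' needs elements recruit and inflate, both in [0, 1]")
  if (!is.null(seed)) spec@seed <- as.integer(seed)
  spec2 <- spec
  spec2@atelectasisFraction <- spec@atelectasisFraction * (1 - recruit)
  spec2@targetVTotalMl <- spec@targetVTotalMl * (1 + inflate)
  t1 <- generatePhantom(spec)
  t2 <- generatePhantom(spec2)
  delta <- vapply(lungMetrics(), function(m)
    metricValue(t2$truth, m) - metricValue(t1$truth, m), 0)
  list(t1 = t1, t2 = t2, truthDelta = delta)
}

#' Sample the specs and recruitment parameters of a paired-CT cohort
#'
#' Baseline phantoms are drawn as in \code{\link{cohortSpecs}} (with a
#' nonzero atelectasis floor so recruitment has something to act on);
#' recruited fractions are uniform in [0.3, 1] and volume inflation uniform
#' in [0.05, 0.5].
#'
#' @inheritParams cohortSpecs
#' @param preset Preset name; pairs are most meaningful for opacified
#'   presets.
#' @return List of \code{n} elements, each with \code{spec} and
#'   \code{deltaAeration} ready for \code{\link{generateRecruitmentPair}}.
#' @export
recruitmentPairSpecs <- function(n, preset = "sheep_opacified", seed = 1L,
                                 ...) {
  specs <- cohortSpecs(n, preset, seed, ...)
  .withSeed(.childSeed(seed, 999983), {
    recruit <- stats::runif(n, 0.3, 1)
    inflate <- stats::runif(n, 0.05, 0.5)
    lapply(seq_len(n), function(i) {
      sp <- specs[[i]]
      ## guarantee a recruitable baseline
      sp@atelectasisFraction <- max(sp@atelectasisFraction, 0.02)
      list(spec = sp,
           deltaAeration = list(recruit = recruit[i], inflate = inflate[i]))
    })
  })
}
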