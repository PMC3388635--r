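#' Configuration for an end-to-end validation study
#'
#' @param preset Phantom preset for the cohort.
#' @param nCohort Number of phantoms for the single-scan agreement stages
#'   (at least 3, since limits of agreement need 3 pairs).
#' @param nPairs Number of pre/post-recruitment pairs for the
#'   consecutive-CT stage; 0 skips it.
#' @param nRefRange Length-2 integer range of reference-slice counts for
#'   the sweep, within [2, 15].
#' @param nRefPrimary Reference-slice count used for the headline agreement
#'   and relative-deviation tables (default 10).
#' @param metrics Metric names (see \code{\link{lungMetrics}}) to compare.
#' @param seed Master seed; the whole study is deterministic given it.
#' @param verbose Log stage progress to stderr?
#' @return A validated configuration list of class \code{"StudyConfig"}.
#' @export
studyConfig <- function(preset = "sheep_opacified", nCohort = 30L,
                        nPairs = 0L, nRefRange = c(5L, 15L),
                        nRefPrimary = 10L,
                        metrics = c("V_total", "M_total", "V_gas_ml",
                                    "pct_V_non", "pct_M_non"),
                        seed = 1L, verbose = TRUE) {
  if (!preset %in% phantomPresets()) stop("unknown preset")
  if (nCohort < 3L) stop("'nCohort' must be at least 3 for agreement analysis")
  if (length(nRefRange) != 2L || nRefRange[1] < 2L || nRefRange[2] > 15L ||
      nRefRange[1] > nRefRange[2])
    stop("'nRefRange' must be an increasing range within [2, 15]")
  if (nRefPrimary < nRefRange[1] || nRefPrimary > nRefRange[2])
    stop("'nRefPrimary' must lie inside 'nRefRange'")
  metrics <- vapply(metrics, function(m) match.arg(m, lungMetrics()), "")
  structure(list(preset = preset, nCohort = as.integer(nCohort),
                 nPairs = as.integer(nPairs),
                 nRefRange = as.integer(nRefRange),
                 nRefPrimary = as.integer(nRefPrimary),
                 metrics = unname(metrics), seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "StudyConfig")
}

.studyLog <- function(config, fmt, ...) {
  if (config$verbose)
    message(sprintf(paste0("[lungqct] ", fmt), ...))
}

#' Run the phantom validation study end to end
#'
#' Simulates a cohort, performs whole-lung analysis and reference-slice
#' extrapolation for every slice count in the configured range, and
#' summarizes method agreement per metric and slice count by Bland-Altman
#' analysis. Optionally repeats the comparison on intra-individual changes
#' across simulated pre/post-recruitment pairs. Phantoms are generated,
#' analyzed and discarded one at a time, so memory stays flat in the cohort
#' size.
#'
#' @param config A \code{\link{studyConfig}}.
#' @param outDir Optional directory; when given, each result table is also
#'   written there as CSV.
#' @return A list of class \code{"lungqctStudy"}:
#'   \describe{
#'     \item{agreementByN}{data.frame of bias/LOA per metric and per
#'       reference-slice count.}
#'     \item{agreementPrimary}{the rows at \code{nRefPrimary}.}
#'     \item{relativeDeviation}{median (min to max) absolute percent
#'       deviation of V_total and M_total at \code{nRefPrimary}.}
#'     \item{deltaAgreement}{Bland-Altman on pre/post changes per metric,
#'       or NULL when \code{nPairs} is 0.}
#'     \item{config}{the configuration used.}
#'   }
#' @export
runValidationStudy <- function(config = studyConfig(), outDir = NULL) {
  if (!inherits(config, "StudyConfig"))
    stop("'config' must come from studyConfig()")
  nMin <- config$nRefRange[1]; nMax <- config$nRefRange[2]
  ns <- seq.int(nMin, nMax)

  .studyLog(config, "simulating %d '%s' phantoms (seed %d)",
            config$nCohort, config$preset, config$seed)
  specs <- cohortSpecs(config$nCohort, config$preset, config$seed)
  whole <- matrix(NA_real_, config$nCohort, length(config$metrics),
                  dimnames = list(NULL, config$metrics))
  extra <- array(NA_real_,
                 c(config$nCohort, length(ns), length(config$metrics)),
                 dimnames = list(NULL, paste0("N", ns), config$metrics))
  for (i in seq_len(config$nCohort)) {
    ph <- generatePhantom(specs[[i]])
    profile <- sliceProfile(ph$grid, ph$mask)
    ws <- wholeLungSummary(profile)
    sw <- sweepReferenceCounts(profile, nMin, nMax,
                               specs[[i]]@sliceThicknessMm)
    for (m in config$metrics) {
      whole[i, m] <- metricValue(ws, m)
      for (nn in names(sw)) extra[i, nn, m] <- metricValue(sw[[nn]], m)
    }
  }

  agreementByN <- do.call(rbind, lapply(config$metrics, function(m) {
    do.call(rbind, lapply(ns, function(N) {
      ba <- blandAltman(whole[, m], extra[, paste0("N", N), m], m)
      cbind(nRef = N, as.data.frame(ba))
    }))
  }))
  rownames(agreementByN) <- NULL

  primaryCol <- paste0("N", config$nRefPrimary)
  agreementPrimary <- agreementByN[agreementByN$nRef == config$nRefPrimary, ]

  relativeDeviation <- do.call(rbind, lapply(
    intersect(c("V_total", "M_total"), config$metrics), function(m) {
      rd <- relativeDeviationSummary(whole[, m], extra[, primaryCol, m])
      data.frame(metric = m, nRef = config$nRefPrimary,
                 median_pct = rd[["median"]], min_pct = rd[["min"]],
                 max_pct = rd[["max"]])
    }))

  deltaAgreement <- NULL
  if (config$nPairs >= 3L) {
    .studyLog(config, "simulating %d pre/post-recruitment pairs",
              config$nPairs)
    pairSpecs <- recruitmentPairSpecs(config$nPairs, config$preset,
                                      .childSeed(config$seed, 424243))
    pairSummaries <- lapply(pairSpecs, function(ps) {
      pr <- generateRecruitmentPair(ps$spec, ps$deltaAeration)
      out <- lapply(list(t1 = pr$t1, t2 = pr$t2), function(ph) {
        profile <- sliceProfile(ph$grid, ph$mask)
        ext <- lungExtent(profile)
        sel <- selectReferenceSlices(ext[["first"]], ext[["last"]],
                                     config$nRefPrimary,
                                     ps$spec@sliceThicknessMm)
        list(whole = wholeLungSummary(profile),
             extra = extrapolate(profile, sel))
      })
      list(t1Whole = out$t1$whole, t1Extra = out$t1$extra,
           t2Whole = out$t2$whole, t2Extra = out$t2$extra)
    })
    deltaAgreement <- do.call(rbind, lapply(config$metrics, function(m) {
      as.data.frame(pairedDeltaAgreement(pairSummaries, m))
    }))
    rownames(deltaAgreement) <- NULL
  }

  report <- structure(list(agreementByN = agreementByN,
                           agreementPrimary = agreementPrimary,
                           relativeDeviation = relativeDeviation,
                           deltaAgreement = deltaAgreement,
                           config = config),
                      class = "lungqctStudy")
  if (!is.null(outDir)) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    utils::write.csv(agreementByN,
                     file.path(outDir, "agreement_by_n.csv"),
                     row.names = FALSE)
    utils::write.csv(agreementPrimary,
                     file.path(outDir, "agreement_primary.csv"),
                     row.names = FALSE)
    utils::write.csv(relativeDeviation,
                     file.path(outDir, "relative_deviation.csv"),
                     row.names = FALSE)
    if (!is.null(deltaAgreement))
      utils::write.csv(deltaAgreement,
                       file.path(outDir, "delta_agreement.csv"),
                       row.names = FALSE)
  }
  report
}

#' @export
print.lungqctStudy <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("lungqct validation study: %d x %s phantoms, N in [%d, %d]\n",
              cfg$nCohort, cfg$preset, cfg$nRefRange[1], cfg$nRefRange[2]))
  cat(sprintf("Agreement at N = %d (bias, 95%% LOA):\n", cfg$nRefPrimary))
  ap <- x$agreementPrimary
  for (i in seq_len(nrow(ap)))
    cat(sprintf("  %-10s %8.2f  (%8.2f, %8.2f)\n", ap$metric[i], ap$bias[i],
                ap$loaLower[i], ap$loaUpper[i]))
  if (!is.null(x$deltaAgreement)) {
    cat("Consecutive-CT delta agreement:\n")
    da <- x$deltaAgreement
    for (i in seq_len(nrow(da)))
      cat(sprintf("  %-16s %8.2f  (%8.2f, %8.2f)\n", da$metric[i],
                  da$bias[i], da$loaLower[i], da$loaUpper[i]))
  }
  invisible(x)
}
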