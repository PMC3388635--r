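# Small in-code fixtures shared across test files.

# A toy grid whose voxels are 1 ml each (10 mm cube), with given HU values
# per slice supplied as a list of matrices or scalars.
toyGrid <- function(sliceHU, nx = 2, ny = 2) {
  nz <- length(sliceHU)
  vals <- array(0, dim = c(nx, ny, nz))
  for (k in seq_len(nz)) vals[, , k] <- sliceHU[[k]]
  VolumeGrid(vals, spacing = c(10, 10, 10))
}

fullMask <- function(grid) LungMask(array(TRUE, dim = dim(grid)))

# Random toy volume + mask for property tests: HU spanning beyond the
# analyzable window so exclusion paths are exercised.
randomToy <- function(seed, nx = 6, ny = 5, nz = 7) {
  set.seed(seed)
  vals <- array(runif(nx * ny * nz, -1100, 200), dim = c(nx, ny, nz))
  mask <- array(runif(nx * ny * nz) < 0.7, dim = c(nx, ny, nz))
  list(grid = VolumeGrid(vals, spacing = c(0.7, 0.8, 5)),
       mask = LungMask(mask))
}

# Independent single-loop oracle for the per-slice quantitation: iterates
# voxel by voxel with scalar arithmetic, no bucketing tricks.
bruteForceProfile <- function(grid, mask) {
  d <- dim(gridValues(grid))
  vals <- gridValues(grid)
  mem <- maskArray(mask)
  vv <- prod(gridSpacing(grid)) / 1000
  qty <- c("V", "M", "Vgas",
           paste0("V_", COMPARTMENTS), paste0("M_", COMPARTMENTS))
  out <- data.frame(slice = seq_len(d[3]), nVoxels = 0L, nExcluded = 0L)
  for (q in qty) out[[q]] <- 0
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (!mem[i, j, k]) next
    h <- vals[i, j, k]
    r <- sign(h) * floor(abs(h) + 0.5)
    if (r < -1000 || r > 100) {
      out$nExcluded[k] <- out$nExcluded[k] + 1L
      next
    }
    out$nVoxels[k] <- out$nVoxels[k] + 1L
    dens <- max(0, (h + 1000) / 1000)
    gas <- max(0, -h / 1000)
    cc <- if (r >= -100) "non" else if (r >= -500) "poor" else
      if (r >= -900) "normal" else "hyper"
    out$V[k] <- out$V[k] + vv
    out$M[k] <- out$M[k] + dens * vv
    out$Vgas[k] <- out$Vgas[k] + gas * vv
    out[[paste0("V_", cc)]][k] <- out[[paste0("V_", cc)]][k] + vv
    out[[paste0("M_", cc)]][k] <- out[[paste0("M_", cc)]][k] + dens * vv
  }
  out
}

# A synthetic slice-quantity profile (no volume behind it) for extrapolation
# arithmetic tests: every absolute quantity column set from V so that the
# LungSummary constructor stays happy.
syntheticProfile <- function(V) {
  out <- data.frame(slice = seq_along(V), nVoxels = 0L, nExcluded = 0L)
  out$V <- V
  out$M <- 0.3 * V
  out$Vgas <- 0.7 * V
  for (cc in COMPARTMENTS) {
    out[[paste0("V_", cc)]] <- V / 4
    out[[paste0("M_", cc)]] <- 0.3 * V / 4
  }
  out
}

expect_summary_equal <- function(a, b, tol = 1e-9) {
  for (m in lungMetrics()) {
    va <- metricValue(a, m); vb <- metricValue(b, m)
    expect_equal(va, vb, tolerance = tol, info = m)
  }
}
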