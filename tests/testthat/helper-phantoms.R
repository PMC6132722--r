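# Shared fixtures: all synthetic, built in code at test time.

# compact two-ventricle phantom that fits a 28 x 28 x 22 grid
smallPhantom <- function(regurgFraction = 0.36, noiseSd = 0, seed = NA,
                         jetSpeeds = c(ao = 100, mi = 60, pa = 70, tv = 55,
                                       pr = 95),
                         restrictive = FALSE, nPhases = 20L, ...) {
  generateVentriclePhantom(phantomSpec(
    dims = c(28L, 28L, 22L), spacing = c(3, 3, 3), nPhases = nPhases,
    rr = 800, lvEdv = 28, rvEdv = 34, jetSpeeds = jetSpeeds,
    regurgFraction = regurgFraction, restrictive = restrictive,
    noiseSd = noiseSd, seed = seed, ...))
}

# run the LCS partition on a bundle at its RV diastolic KE peak and score
# it against the generator's jet-membership truth
runPartition <- function(bundle, ridgePct = 80, ...) {
  vols <- computeVolumeCurve(bundle$segmentation)
  ke <- voxelKE(bundle$velocity)
  cur <- keCurve(ke, bundle$segmentation,
                 esPhase = c(lv = vols$lv$esPhase, rv = vols$rv$esPhase))
  peak <- cur$rv$diastolicPhase
  fte <- ftleAtPhase(bundle$velocity, bundle$segmentation, peak,
                     cur$rv$esPhase)
  dims <- gridDim(bundle$segmentation)
  nvox <- prod(dims)
  rvMask <- labelData(bundle$segmentation)[, , , peak] == RV_LABEL
  keP <- array(ke[(peak - 1) * nvox + seq_len(nvox)], dim = dims)
  part <- partitionRV(fte, rvMask, bundle$truth$markers$pa,
                      bundle$truth$markers$tv, keP, ridgePct = ridgePct, ...)
  truthPr <- bundle$truth$prVoxels[[peak]]
  prIdx <- which(part$labels == 1L)
  keTruthPr <- sum(keP[truthPr])
  list(partition = part, peakPhase = peak,
       capture = if (keTruthPr > 0)
         sum(keP[intersect(prIdx, truthPr)]) / keTruthPr else NA_real_,
       contamination = if (length(prIdx))
         sum(keP[setdiff(prIdx, truthPr)]) / sum(keP[prIdx]) else 0,
       nPr = length(prIdx), truthFracPct = bundle$truth$keFracPRPct)
}

# boundary-voxel count of a logical mask (6-connectivity surface shell)
shellVoxelCount <- function(mask) {
  d <- dim(mask)
  pad <- array(FALSE, d + 2L)
  pad[1 + seq_len(d[1]), 1 + seq_len(d[2]), 1 + seq_len(d[3])] <- mask
  inner <- pad[1 + seq_len(d[1]), 1 + seq_len(d[2]), 1 + seq_len(d[3])] &
    pad[seq_len(d[1]), 1 + seq_len(d[2]), 1 + seq_len(d[3])] &
    pad[2 + seq_len(d[1]), 1 + seq_len(d[2]), 1 + seq_len(d[3])] &
    pad[1 + seq_len(d[1]), seq_len(d[2]), 1 + seq_len(d[3])] &
    pad[1 + seq_len(d[1]), 2 + seq_len(d[2]), 1 + seq_len(d[3])] &
    pad[1 + seq_len(d[1]), 1 + seq_len(d[2]), seq_len(d[3])] &
    pad[1 + seq_len(d[1]), 1 + seq_len(d[2]), 2 + seq_len(d[3])]
  sum(mask) - sum(inner)
}

# uniform-velocity field fixture
uniformField <- function(u = c(30, -20, 0), dims = c(12, 12, 12),
                         nPhases = 4L, spacing = 3) {
  arr <- array(0, dim = c(dims, nPhases, 3))
  for (cmp in 1:3) arr[, , , , cmp] <- u[cmp]
  newVelocityField(arr, rep(spacing, 3), (seq_len(nPhases) - 1) * 100,
                   period = nPhases * 100)
}
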