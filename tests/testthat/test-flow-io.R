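test_that("velocity volumes round-trip through NIfTI + sidecar", {
  b <- smallPhantom(noiseSd = 1.5, seed = 3, nPhases = 10)
  td <- withr::local_tempdir()
  pre <- file.path(td, "subj")
  writeVelocity(b$velocity, pre)
  paths <- sprintf("%s_%s.nii.gz", pre, c("vx", "vy", "vz"))
  f2 <- readVelocity(paths, sprintf("%s_meta.json", pre))
  expect_equal(velocityData(f2), velocityData(b$velocity), tolerance = 1e-12)
  expect_equal(voxelSpacing(f2), c(3, 3, 3))
  expect_equal(voxelVolume(f2), 27)
  expect_equal(venc(f2), 100)
  expect_equal(timeStamps(f2), timeStamps(b$velocity))
})

test_that("an independent NIfTI reader agrees with what we wrote", {
  b <- smallPhantom(noiseSd = 0, nPhases = 10)
  td <- withr::local_tempdir()
  pre <- file.path(td, "x")
  writeVelocity(b$velocity, pre)
  alt <- oro.nifti::readNIfTI(sprintf("%s_vz.nii.gz", pre), reorient = FALSE)
  expect_equal(as.vector(oro.nifti::img_data(alt)),
               as.vector(velocityData(b$velocity)[, , , , 3]),
               tolerance = 1e-12)
})

test_that("declared source units are converted to cm/s on read", {
  b <- smallPhantom(noiseSd = 0, nPhases = 10)
  td <- withr::local_tempdir()
  pre <- file.path(td, "u")
  writeVelocity(b$velocity, pre)
  meta <- jsonlite::read_json(sprintf("%s_meta.json", pre),
                              simplifyVector = TRUE)
  meta$velocity_units <- "m/s"
  jsonlite::write_json(meta, sprintf("%s_meta.json", pre), auto_unbox = TRUE,
                       digits = NA, na = "null")
  f2 <- readVelocity(sprintf("%s_%s.nii.gz", pre, c("vx", "vy", "vz")),
                     sprintf("%s_meta.json", pre))
  expect_equal(velocityData(f2), velocityData(b$velocity) * 100,
               tolerance = 1e-12)
})

test_that("malformed velocity inputs are rejected with informative errors", {
  b <- smallPhantom(noiseSd = 0, nPhases = 10)
  td <- withr::local_tempdir()
  pre <- file.path(td, "bad")
  writeVelocity(b$velocity, pre)
  paths <- sprintf("%s_%s.nii.gz", pre, c("vx", "vy", "vz"))
  meta <- sprintf("%s_meta.json", pre)

  # mismatched phase counts between components
  short <- velocityData(b$velocity)[, , , 1:5, 1]
  RNifti::writeNifti(RNifti::asNifti(short), paths[2])
  expect_error(readVelocity(paths, meta), "does not match")

  # NaN voxels
  bad <- velocityData(b$velocity)[, , , , 2]
  bad[1, 1, 1, 1] <- NaN
  RNifti::writeNifti(RNifti::asNifti(bad), paths[2])
  expect_error(readVelocity(paths, meta), "NaN/Inf")

  # missing VENC
  RNifti::writeNifti(RNifti::asNifti(velocityData(b$velocity)[, , , , 2]),
                     paths[2])
  m <- jsonlite::read_json(meta, simplifyVector = TRUE)
  m$venc_cms <- NULL
  jsonlite::write_json(m, meta, auto_unbox = TRUE, digits = NA, na = "null")
  expect_error(readVelocity(paths, meta), "VENC")
})

test_that("segmentation and flow-curve files round-trip", {
  b <- smallPhantom(noiseSd = 0, nPhases = 10)
  td <- withr::local_tempdir()
  pre <- file.path(td, "s")
  writeSegmentation(b$segmentation, pre)
  s2 <- readSegmentation(sprintf("%s_mask.nii.gz", pre),
                         sprintf("%s_mask_meta.json", pre))
  expect_identical(labelData(s2), labelData(b$segmentation))
  fcsv <- file.path(td, "flows.csv")
  writeFlowCurves(b$flows, fcsv)
  f2 <- readFlowCurves(fcsv, period = cyclePeriod(b$flows))
  expect_equal(f2@pa, b$flows@pa, tolerance = 1e-9)
  expect_equal(f2@ao, b$flows@ao, tolerance = 1e-9)
})

test_that("segmentation transfer is an identity on matching grids and idempotent", {
  b <- smallPhantom(noiseSd = 0, nPhases = 10)
  tr <- transferSegmentation(b$segmentation, b$velocity)
  expect_identical(labelData(tr), labelData(b$segmentation))
  tr2 <- transferSegmentation(tr, b$velocity)
  expect_identical(labelData(tr2), labelData(tr))
})

test_that("temporal transfer picks the nearest cine phase in RR fraction", {
  # 30-phase cine onto a 40-phase 4D grid (same spatial grid)
  dims <- c(8, 8, 6)
  mk <- function(nt, rr) {
    lab <- array(0L, dim = c(dims, nt))
    lab[2, 2, 2, ] <- LV_LABEL
    lab[6, 6, 4, ] <- RV_LABEL
    # encode the phase id in an extra RV voxel column height
    for (ph in seq_len(nt)) lab[7, 7, seq_len(1 + (ph - 1) %% 3), ph] <- RV_LABEL
    newSegmentation(lab, c(3, 3, 3), (seq_len(nt) - 1) * rr / nt, period = rr)
  }
  cine <- mk(30, 900)
  arr <- array(0, dim = c(dims, 40, 3))
  target <- newVelocityField(arr, c(3, 3, 3), (0:39) * 900 / 40, period = 900)
  tr <- transferSegmentation(cine, target)
  cFrac <- timeStamps(cine) / 900
  tFrac <- timeStamps(target) / 900
  expected <- vapply(tFrac, function(f) which.min(abs(cFrac - f)), 0L)
  expect_true(all(diff(expected) >= 0))  # monotone mapping
  for (ph in seq_len(40)) {
    expect_identical(tr@labels[, , , ph], cine@labels[, , , expected[ph]])
  }
})

test_that("dilating the cine mask never shrinks the transferred mask", {
  b <- smallPhantom(noiseSd = 0, nPhases = 10)
  lab <- labelData(b$segmentation)
  dil <- lab
  # one-voxel dilation of RV along +x
  rv <- lab == RV_LABEL
  shifted <- array(FALSE, dim(rv))
  shifted[-1, , , ] <- rv[-dim(rv)[1], , , ]
  dil[shifted & lab == 0L] <- RV_LABEL
  cine <- newSegmentation(dil, voxelSpacing(b$segmentation),
                          timeStamps(b$segmentation),
                          period = cyclePeriod(b$segmentation))
  tr0 <- transferSegmentation(b$segmentation, b$velocity)
  tr1 <- transferSegmentation(cine, b$velocity)
  expect_gt(sum(labelData(tr1) == RV_LABEL), sum(labelData(tr0) == RV_LABEL))
})

test_that("non-overlapping fields of view are a transfer error", {
  b <- smallPhantom(noiseSd = 0, nPhases = 10)
  far <- newSegmentation(labelData(b$segmentation),
                         voxelSpacing(b$segmentation),
                         timeStamps(b$segmentation),
                         period = cyclePeriod(b$segmentation),
                         origin = c(5000, 5000, 5000))
  expect_error(transferSegmentation(far, b$velocity), "overlap")
})

test_that("result tables have the published schema shape", {
  td <- withr::local_tempdir()
  p <- file.path(td, "res.csv")

  writeResults(data.frame(), p)
  empty <- utils::read.csv(p)
  expect_equal(nrow(empty), 0)
  expect_equal(ncol(empty), 13)

  fakeResult <- function(id, group) {
    ix <- list(peakKe = 1, kePerSv = 0.1, kePerCo = 0.2, kePerBsa = 0.5,
               qPerKe = 10, qPerKeBsa = 5)
    structure(list(
      subject = list(id = id, group = group, bsa = 2, hr = 60),
      indexed = setNames(rep(list(ix), 4),
                         c("lv.systole", "lv.diastole", "rv.systole",
                           "rv.diastole")),
      sdRatio = c(lv = 0.9, rv = 1.4), restrictive = FALSE,
      partition = NULL), class = "subjectResult")
  }
  one <- cohortTable(list(fakeResult("P01", "patient")))
  expect_equal(nrow(one), 4)  # 2 ventricles x 2 phase types
  ids <- c(sprintf("P%02d", 1:15), sprintf("C%02d", 1:14))
  tab <- cohortTable(mapply(fakeResult, ids,
                            rep(c("patient", "control"), c(15, 14)),
                            SIMPLIFY = FALSE))
  expect_equal(nrow(tab), 116)  # 29 subjects x 4 rows
  writeResults(tab, p, summaryPath = file.path(td, "sum.csv"))
  out <- utils::read.csv(p)
  expect_equal(names(out),
               c("subject_id", "group", "ventricle", "phase_type",
                 "peak_ke_mJ", "ke_per_sv_mJ_per_ml", "ke_per_co",
                 "ke_per_bsa", "q_per_ke", "q_per_ke_per_bsa", "sd_ratio",
                 "restrictive", "pr_ke_fraction"))
  expect_true(file.exists(file.path(td, "sum.csv")))
})
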