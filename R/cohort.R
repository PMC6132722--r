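# Synthetic study cohort: patient-like phantoms (pulmonary regurgitation
# > 20%, a 10:15 restrictive quota) versus control-like phantoms (no PR).
# Distributional settings mirror the group structure of a repaired-tetralogy
# cohort; absolute ventricular volumes are scaled down so the phantoms fit
# desk-size grids (the group contrasts, not the absolute millilitres, are
# the modelled quantity).

.truncNorm <- function(n, mean, sd, lo, hi) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      x <- stats::rnorm(1, mean, sd)
      if (x >= lo && x <= hi) break
    }
    out[i] <- x
  }
  out
}

#' Default cohort generator settings
#'
#' Returns the per-group distributional settings used by [generateCohort()]:
#' grid geometry, regurgitant-fraction distribution (truncated normal,
#' patients only, support above the 20% inclusion threshold), the
#' restrictive-physiology prevalence (assigned deterministically by quota),
#' scaled-down ventricular volume distributions, heart rate, body surface
#' area, and peak jet speeds with a per-subject log-normal jitter.
#'
#' @return a named list; override entries via the `settings` argument of
#'   [generateCohort()]
#' @export
cohortSettings <- function() {
  list(
    dims = c(32L, 32L, 26L), spacing = c(3, 3, 3), nPhases = 24L,
    noiseSd = 1.5, venc = 100,
    prFraction = c(mean = 0.36, sd = 0.13, lo = 0.21, hi = 0.65),
    restrictivePrevalence = 10 / 15,
    restrictiveSpeedFactor = 0.6,
    patient = list(lvEdv = c(42, 7, 32, 55), rvEdv = c(55, 10, 42, 64),
                   lvEsvRatio = 0.46, rvEsvRatio = 0.57,
                   hr = c(71, 10, 50, 100), bsa = c(1.9, 0.2, 1.4, 2.6),
                   jetSpeeds = c(ao = 95, mi = 60, pa = 75, tv = 50, pr = 95)),
    control = list(lvEdv = c(48, 8, 38, 58), rvEdv = c(42, 8, 32, 54),
                   lvEsvRatio = 0.42, rvEsvRatio = 0.44,
                   hr = c(60, 9, 45, 90), bsa = c(2.0, 0.2, 1.4, 2.6),
                   jetSpeeds = c(ao = 100, mi = 65, pa = 70, tv = 55, pr = 0)),
    speedJitterSdLog = 0.12
  )
}

#' Generate a synthetic patient/control cohort
#'
#' Draws per-subject phantom parameters from the group distributions in
#' [cohortSettings()] and realizes each subject with
#' [generateVentriclePhantom()]. Patients carry a pulmonary regurgitant
#' fraction above 0.20 (study inclusion criterion) and restrictive RV
#' physiology is assigned by quota (first `round(prevalence * nPatients)`
#' patients), so label counts are deterministic. Controls have no PR.
#' Fully reproducible for a fixed seed.
#'
#' @param nPatients,nControls group sizes (>= 1)
#' @param settings optional list overriding entries of [cohortSettings()]
#' @param seed integer RNG seed
#' @return list of `phantomBundle`s, each with a `subject` element
#'   (`id`, `group`, `bsa`, `hr`, `restrictiveTruth`)
#' @export
generateCohort <- function(nPatients = 15, nControls = 14, settings = list(),
                           seed = 1) {
  if (nPatients < 1 || nControls < 1) stopf("need at least one subject per group")
  cfg <- utils::modifyList(cohortSettings(), settings)
  set.seed(as.integer(seed))
  nRestr <- round(cfg$restrictivePrevalence * nPatients)
  subjects <- list()
  draw <- function(p) .truncNorm(1, p[1], p[2], p[3], p[4])
  for (grp in c("patient", "control")) {
    n <- if (grp == "patient") nPatients else nControls
    g <- cfg[[grp]]
    for (i in seq_len(n)) {
      jitter <- exp(stats::rnorm(length(g$jetSpeeds), 0, cfg$speedJitterSdLog))
      subjects[[length(subjects) + 1L]] <- list(
        id = sprintf("%s%02d", toupper(substr(grp, 1, 1)), i), group = grp,
        lvEdv = draw(g$lvEdv), rvEdv = draw(g$rvEdv),
        lvEsvRatio = g$lvEsvRatio, rvEsvRatio = g$rvEsvRatio,
        hr = draw(g$hr), bsa = draw(g$bsa),
        jetSpeeds = g$jetSpeeds * jitter,
        regurgFraction = if (grp == "patient") {
          p <- cfg$prFraction; .truncNorm(1, p["mean"], p["sd"], p["lo"], p["hi"])
        } else 0,
        restrictive = grp == "patient" && i <= nRestr,
        phantomSeed = sample.int(.Machine$integer.max, 1)
      )
    }
  }
  lapply(subjects, function(s) {
    spec <- phantomSpec(
      dims = cfg$dims, spacing = cfg$spacing, nPhases = cfg$nPhases,
      rr = 60000 / s$hr,
      lvEdv = s$lvEdv, lvEsvRatio = s$lvEsvRatio,
      rvEdv = s$rvEdv, rvEsvRatio = s$rvEsvRatio,
      jetSpeeds = s$jetSpeeds, regurgFraction = s$regurgFraction,
      restrictive = s$restrictive,
      restrictiveSpeedFactor = cfg$restrictiveSpeedFactor,
      venc = cfg$venc, noiseSd = cfg$noiseSd, seed = s$phantomSeed)
    b <- generateVentriclePhantom(spec)
    b$subject <- list(id = s$id, group = s$group, bsa = s$bsa, hr = s$hr,
                      restrictiveTruth = s$restrictive)
    b
  })
}
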