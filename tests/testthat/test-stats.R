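test_that("restrictive classification depends only on the end-diastolic segment", {
  tms <- seq(0, 780, length.out = 40)
  # flow identically zero in diastole -> not restrictive
  q <- ifelse(tms / 800 < 0.3, 150 * sin(pi * tms / 240)^2, 0)
  expect_false(as.logical(classifyRestrictive(q, times = tms, period = 800)))

  # clear end-diastolic forward flow -> restrictive
  qr <- q + ifelse(tms / 800 >= 0.87, 30, 0)
  expect_true(as.logical(classifyRestrictive(qr, times = tms, period = 800)))

  # a regurgitant offset that drives the end-diastolic segment negative
  # flips the call, regardless of what mid-diastole does
  qneg <- qr - ifelse(tms / 800 >= 0.4, 45, 0)
  expect_false(as.logical(classifyRestrictive(qneg, times = tms,
                                              period = 800)))
})

test_that("phantom restrictive physiology is classified from its flow curve", {
  br <- smallPhantom(regurgFraction = 0.36, restrictive = TRUE, noiseSd = 0)
  bn <- smallPhantom(regurgFraction = 0.36, restrictive = FALSE, noiseSd = 0)
  expect_true(as.logical(classifyRestrictive(br$flows)))
  expect_false(as.logical(classifyRestrictive(bn$flows)))
  # controls (no PR at all) are never restrictive
  b0 <- smallPhantom(regurgFraction = 0, noiseSd = 0)
  expect_false(as.logical(classifyRestrictive(b0$flows)))
})

test_that("Cohen's kappa: closed form, invariances and degenerate cases", {
  expect_equal(cohensKappa(matrix(c(7, 0, 0, 5), 2)), 1)
  # swapping both raters' label order leaves kappa unchanged
  tb <- matrix(c(10, 3, 2, 9), 2)
  expect_equal(cohensKappa(tb), cohensKappa(tb[2:1, 2:1]))
  # kappa of independent raters converges to zero
  set.seed(13)
  a <- stats::rbinom(10000, 1, 0.4); b <- stats::rbinom(10000, 1, 0.6)
  expect_lt(abs(cohensKappa(table(factor(a, 0:1), factor(b, 0:1)))), 0.05)
  # bounds over random tables
  for (i in 1:50) {
    tb <- matrix(stats::rpois(4, 5) + c(1, 0, 0, 1), 2)
    k <- cohensKappa(tb)
    expect_true(is.na(k) || (k >= -1 && k <= 1))
  }
  # degenerate marginals are undefined
  expect_true(is.na(cohensKappa(matrix(c(12, 0, 0, 0), 2))))
  expect_error(cohensKappa(matrix(1:9, 3)), "2 x 2")
})

test_that("group comparison matches hand-computed pooled t statistics", {
  a <- c(1, 2, 3, 4); b <- c(2, 4, 6, 8)
  r <- compareGroups(a, b)
  # hand computation: means 2.5 / 5, pooled var = (3*5/3 + 3*20/3)/6 = 25/6
  sp2 <- (3 * stats::var(a) + 3 * stats::var(b)) / 6
  tHand <- (2.5 - 5) / sqrt(sp2 * (1 / 4 + 1 / 4))
  expect_equal(r$t, tHand, tolerance = 1e-12)
  expect_equal(r$t, -1.7320508, tolerance = 1e-6)
  expect_equal(r$df, 6)
  expect_equal(r$p, 2 * stats::pt(tHand, 6), tolerance = 1e-12)

  # identical groups
  same <- compareGroups(c(5, 6, 7), c(5, 6, 7))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1, tolerance = 1e-9)

  # paired shift recovers the constant exactly
  x <- stats::rnorm(10)
  pr <- compareGroups(x + 3.25, x, paired = TRUE)
  expect_equal(pr$meanDiff, 3.25, tolerance = 1e-12)
  expect_lt(pr$p, 1e-10)
  expect_error(compareGroups(1:3, 1:4, paired = TRUE), "equal-length")
})

test_that("group comparison has power at the study's effect sizes", {
  # RV diastolic peak KE distributions: 7.7 +- 4.3 (n=15) vs 3.1 +- 1.3 (n=14)
  set.seed(29)
  rejections <- mean(replicate(60, {
    compareGroups(stats::rnorm(15, 7.7, 4.3),
                  stats::rnorm(14, 3.1, 1.3))$p < 0.05
  }))
  expect_gt(rejections, 0.8)
})

test_that("Spearman correlation: exact small-sample p matches an independent oracle", {
  expect_equal(spearmanCorr(1:6, c(2, 4, 5, 7, 10, 20))$rho, 1)
  expect_equal(spearmanCorr(1:6, rev(c(2, 4, 5, 7, 10, 20)))$rho, -1)
  cst <- spearmanCorr(1:5, rep(2, 5))
  expect_true(is.na(cst$rho))

  set.seed(55)
  for (i in 1:5) {
    x <- stats::rnorm(8); y <- stats::rnorm(8)
    mine <- spearmanCorr(x, y)
    oracle <- stats::cor.test(x, y, method = "spearman", exact = TRUE)
    expect_equal(mine$rho, unname(oracle$estimate), tolerance = 1e-12)
    expect_equal(mine$p, oracle$p.value, tolerance = 1e-9)
  }
})

test_that("cohort statistics wire the dichotomy agreement correctly", {
  # synthetic table: 10 restrictive patients with ratio > 1, 5 non-restrictive
  # of which 4 have ratio <= 1 (one borderline above), mirrors a 2x2 with
  # one off-diagonal count
  tab <- do.call(rbind, lapply(seq_len(15), function(i) {
    restr <- i <= 10
    ratio <- if (restr) 1.5 else if (i <= 14) 0.8 else 1.1
    data.frame(subject_id = sprintf("P%02d", i), group = "patient",
               ventricle = rep(c("LV", "LV", "RV", "RV"), 1),
               phase_type = c("systole", "diastole", "systole", "diastole"),
               peak_ke_mJ = 1, ke_per_sv_mJ_per_ml = 0.1, ke_per_co = 1,
               ke_per_bsa = 1, q_per_ke = 1, q_per_ke_per_bsa = 1,
               sd_ratio = ratio, restrictive = restr, pr_ke_fraction = NA)
  }))
  ctl <- tab[tab$subject_id == "P01", ][rep(1:4, 3), ]
  ctl$group <- "control"; ctl$subject_id <- rep(c("C1", "C2", "C3"), each = 4)
  ctl$peak_ke_mJ <- c(0.5, 0.6, 0.7)[rep(1:3, each = 4)]
  st <- cohortStats(rbind(tab, ctl))
  # rows: ratio <=1 / >1, columns: non-restrictive / restrictive
  expect_equal(unclass(st$kappaTable)[1:4], c(4, 1, 0, 10))
  expect_equal(st$kappa, 80 / 95, tolerance = 1e-12)
})
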