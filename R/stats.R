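# Restrictive-physiology classification and cohort statistics.

#' Classify restrictive RV physiology from the pulmonary flow curve
#'
#' Restrictive right-ventricular physiology is identified by end-diastolic
#' forward flow in the pulmonary artery (atrial contraction transmitted
#' through a stiff RV). Operationally: the mean flow over the final
#' fraction `endFrac` of the cardiac cycle must exceed a noise threshold,
#' taken as `2 x` the SD of the flow over a designated quiescent window
#' (with an absolute floor), so the decision depends only on the
#' end-diastolic segment.
#'
#' @param flows a [FlowCurveSet-class], or a numeric PA flow vector
#'   (ml/s, forward positive)
#' @param times time stamps ms (required for a bare vector)
#' @param period cycle duration ms (default: inferred)
#' @param endFrac fraction of the cycle forming the end-diastolic window
#'   (default 0.15)
#' @param quiescentWindow fractions of the cycle bounding the quiescent
#'   reference window (default `c(0.70, 0.85)`)
#' @param floorThreshold absolute minimum threshold, ml/s (default 1)
#' @return logical; `NA` if the curve has no samples in the end-diastolic
#'   window. The threshold used is attached as attribute `threshold`.
#' @export
classifyRestrictive <- function(flows, times = NULL, period = NA_real_,
                                endFrac = 0.15,
                                quiescentWindow = c(0.70, 0.85),
                                floorThreshold = 1) {
  if (is(flows, "FlowCurveSet")) {
    times <- flows@times
    period <- cyclePeriod(flows)
    q <- flows@pa
  } else {
    q <- flows
    if (is.null(times)) stopf("times are required with a bare flow vector")
    period <- .inferPeriod(times, period)
  }
  frac <- times / period
  endSel <- frac >= 1 - endFrac
  if (!any(endSel)) return(NA)
  quiet <- q[frac >= quiescentWindow[1] & frac <= quiescentWindow[2]]
  noiseSd <- if (length(quiet) >= 2L) stats::sd(quiet) else 0
  threshold <- max(floorThreshold, 2 * noiseSd)
  out <- mean(q[endSel]) > threshold
  attr(out, "threshold") <- threshold
  out
}

#' Cohen's kappa for a 2 x 2 agreement table
#'
#' \eqn{\kappa = (p_o - p_e) / (1 - p_e)} with `p_o` the observed agreement
#' proportion and `p_e` the chance agreement from the marginals.
#'
#' @param table 2 x 2 matrix of counts, raters on the two dimensions
#' @return kappa; `NA` when the marginals are degenerate (`p_e = 1`)
#' @export
cohensKappa <- function(table) {
  table <- as.matrix(table)
  if (!identical(dim(table), c(2L, 2L)) || any(table < 0)) {
    stopf("a 2 x 2 matrix of nonnegative counts is required")
  }
  n <- sum(table)
  if (n == 0) stopf("empty agreement table")
  po <- sum(diag(table)) / n
  pe <- sum(rowSums(table) * colSums(table)) / n^2
  if (abs(1 - pe) < .Machine$double.eps * 4) return(NA_real_)
  (po - pe) / (1 - pe)
}

#' Two-group comparison (Student / paired t test)
#'
#' Group means and SDs with a two-sided Student t test (classical,
#' pooled-variance) or, for linked pre/post samples, a paired t test.
#'
#' @param a,b numeric vectors (equal length and linked order when paired)
#' @param paired logical
#' @return list: `meanA`, `sdA`, `meanB`, `sdB`, `meanDiff` (paired only),
#'   `t`, `df`, `p`, `paired`, `significant` (p < 0.05)
#' @export
compareGroups <- function(a, b, paired = FALSE) {
  if (length(a) < 2L || length(b) < 2L) stopf("need n >= 2 per group")
  if (paired && length(a) != length(b)) {
    stopf("paired comparison requires equal-length linked samples")
  }
  if (paired && stats::sd(a - b) <= 1e-12 * max(abs(mean(a - b)), 1)) {
    # constant shift: the difference is exact, the t statistic degenerate
    d <- mean(a - b)
    return(list(meanA = mean(a), sdA = stats::sd(a), meanB = mean(b),
                sdB = stats::sd(b), meanDiff = d,
                t = if (d == 0) 0 else sign(d) * Inf, df = length(a) - 1,
                p = if (d == 0) 1 else 0, paired = TRUE,
                significant = d != 0, degenerate = TRUE))
  }
  if (!paired && stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) {
      return(list(meanA = mean(a), sdA = 0, meanB = mean(b), sdB = 0,
                  meanDiff = NULL, t = 0, df = NA_real_, p = 1,
                  paired = FALSE, significant = FALSE, degenerate = TRUE))
    }
    stopf("zero variance in both groups with unequal means: test undefined")
  }
  tt <- stats::t.test(a, b, paired = paired, var.equal = TRUE)
  list(meanA = mean(a), sdA = stats::sd(a), meanB = mean(b),
       sdB = stats::sd(b),
       meanDiff = if (paired) mean(a - b) else NULL,
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, paired = paired, significant = tt$p.value < 0.05)
}

# all permutations of 1..n (n small), as an n! x n matrix
.allPerms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .allPerms(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (pos in seq_len(n)) {
    blk <- matrix(0L, nrow(sub), n)
    blk[, pos] <- n
    blk[, -pos] <- sub
    out[r + seq_len(nrow(sub)), ] <- blk
    r <- r + nrow(sub)
  }
  out
}

#' Spearman rank correlation with small-sample exact p
#'
#' Rank correlation with mid-ranks for ties. The two-sided p-value is
#' computed by exhaustive permutation enumeration for `n <= 8` without
#' ties, and by the t approximation otherwise (ties always use the
#' approximation, flagged in the result).
#'
#' @param x,y paired observations, `n >= 3`
#' @return list: `rho`, `p`, `n`, `method`; `rho` is `NA` (flagged) for
#'   constant input
#' @export
spearmanCorr <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must be paired")
  n <- length(x)
  if (n < 3L) stopf("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n, method = "undefined",
                constantInput = TRUE))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  if (!ties && n <= 8L) {
    perms <- .allPerms(n)
    # correlate every permutation of y-ranks against the fixed x-ranks
    rhoAll <- apply(perms, 1L, function(p) stats::cor(seq_len(n), p))
    p <- mean(abs(rhoAll) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- if (!is.finite(tstat)) {
      if (abs(rho) >= 1) 2 / factorial(n) else NA_real_
    } else 2 * stats::pt(-abs(tstat), n - 2)
    method <- if (ties) "t approximation (ties)" else "t approximation"
  }
  list(rho = rho, p = min(p, 1), n = n, method = method)
}
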