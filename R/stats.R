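## Volcano comparison, PCA overview, BCA calibration.

## Row-wise Welch two-sample t-test in closed form (means, n-1 variances,
## Welch-Satterthwaite df, two-sided p via pt). Vectorised over features;
## cross-checked against stats::t.test in the test suite.
.rowWelch <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1, stats::var); vb <- apply(b, 1, stats::var)
  se2 <- va / na + vb / nb
  t <- (mb - ma) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t), df)
  ## degenerate rows: both groups constant
  deg <- se2 == 0
  p[deg] <- ifelse(ma[deg] == mb[deg], 1, 0)
  data.frame(statistic = t, df = df, pvalue = p)
}

#' Volcano comparison of two extraction protocols
#'
#' Per-feature comparison of a consecutive (two-step) extraction against a
#' single extraction: fold change is the ratio of group means on the
#' linear, sum-normalized scale (positive direction = higher in
#' `consecutive`), and the p-value comes from a two-sided Welch t-test on
#' log10-transformed normalized intensities. A feature is significant when
#' `p < pCut` and its fold change is at least `fcCut` in either direction
#' (|log2 FC| >= log2 fcCut). Raw inputs are sum-normalized internally;
#' zeros are replaced by the half-minimum rule before the log test.
#' Features detected in neither group are excluded and counted.
#'
#' @param single,consecutive [SpotExperiment-class] tables with identical
#'   features and >= 2 replicates each.
#' @param pCut P-value threshold (default 0.05, unadjusted).
#' @param fcCut Linear fold-change threshold (default 1.5).
#' @param pAdjust Multiple-testing correction passed to
#'   [stats::p.adjust()]; `"none"` (default) matches the raw-p convention
#'   of volcano displays.
#' @return `data.frame` with columns `feature_id`, `compound_class`,
#'   `log2fc`, `pvalue`, `significant`; excluded-feature count in
#'   `attr(, "n_excluded")`, thresholds in `attr(, "thresholds")`.
#' @export
volcanoCompare <- function(single, consecutive, pCut = 0.05, fcCut = 1.5,
                           pAdjust = "none") {
  stopifnot(is(single, "SpotExperiment"), is(consecutive, "SpotExperiment"),
            pCut > 0, fcCut >= 1)
  if (!identical(rownames(single), rownames(consecutive)))
    stop("the two tables must share the same features in the same order",
         call. = FALSE)
  if (ncol(single) < 2L || ncol(consecutive) < 2L)
    stop("at least 2 replicates per group are required", call. = FALSE)
  if (!isNormalized(single)) single <- normalizeSum(single)
  if (!isNormalized(consecutive)) consecutive <- normalizeSum(consecutive)
  a <- assay(single, "intensity")
  b <- assay(consecutive, "intensity")

  keep <- rowSums(a) > 0 | rowSums(b) > 0
  nExcluded <- sum(!keep)
  a <- a[keep, , drop = FALSE]; b <- b[keep, , drop = FALSE]

  ma <- rowMeans(a); mb <- rowMeans(b)
  log2fc <- log2(mb / ma)  # -Inf/Inf when one group is all-zero

  halfMin <- min(c(a[a > 0], b[b > 0])) / 2
  la <- log10(pmax(a, halfMin)); lb <- log10(pmax(b, halfMin))
  w <- .rowWelch(la, lb)
  p <- stats::p.adjust(w$pvalue, method = pAdjust)

  out <- data.frame(
    feature_id = rownames(single)[keep],
    compound_class = compoundClass(single)[keep],
    log2fc = log2fc, pvalue = p,
    significant = p < pCut & abs(log2fc) >= log2(fcCut),
    stringsAsFactors = FALSE)
  attr(out, "n_excluded") <- nExcluded
  attr(out, "thresholds") <- c(p = pCut, fc = fcCut)
  out
}

#' PCA overview of an experiment
#'
#' Principal component analysis of the samples (features mean-centered, no
#' unit-variance scaling by default) of a normalized, log-transformed
#' table, via singular value decomposition. Reports per-PC variance
#' explained and the PC1+PC2 sum conventionally quoted as a clustering
#' summary.
#'
#' @param x A [SpotExperiment-class], typically after [normalizeSum()] and
#'   [log10Transform()].
#' @param scale Autoscale features to unit variance before decomposition
#'   (default `FALSE`, centering only).
#' @return `list(scores, varianceExplained, pc12Sum)`: `scores` is the
#'   samples x PCs matrix, `varianceExplained` percentages summing to 100
#'   over all PCs.
#' @export
pcaOverview <- function(x, scale = FALSE) {
  stopifnot(is(x, "SpotExperiment"))
  if (nrow(x) < 2L || ncol(x) < 2L)
    stop("PCA needs at least 2 features and 2 samples", call. = FALSE)
  m <- t(assay(x, "intensity"))
  sds <- apply(m, 2, stats::sd)
  if (all(sds == 0))
    stop("constant matrix: no variance to decompose", call. = FALSE)
  if (scale) m <- m[, sds > 0, drop = FALSE]
  fit <- stats::prcomp(m, center = TRUE, scale. = scale)
  ve <- 100 * fit$sdev^2 / sum(fit$sdev^2)
  list(scores = fit$x,
       varianceExplained = ve,
       pc12Sum = sum(ve[seq_len(min(2L, length(ve)))]))
}

#' Fit a BCA calibration line
#'
#' Ordinary least-squares fit of absorbance at 562 nm against standard
#' concentration. The standard series conventionally spans 0-2000 ug/mL;
#' predictions outside the fitted standards' range are flagged as
#' extrapolation by [bcaConcentration()].
#'
#' @param standards `data.frame` with columns `concentration_ug_ml` (or
#'   `concentration`) and `absorbance`; >= 2 distinct concentrations.
#' @param degree 1 (default, linear) or 2 (quadratic, for the mild
#'   curvature BCA can show at the top of range; inversion then takes the
#'   quadratic root on the monotone branch).
#' @return A [BcaFit-class].
#' @export
bcaFit <- function(standards, degree = 1L) {
  conc <- standards[["concentration_ug_ml"]]
  if (is.null(conc)) conc <- standards[["concentration"]]
  absb <- standards[["absorbance"]]
  if (is.null(conc) || is.null(absb))
    stop("standards need columns concentration_ug_ml and absorbance",
         call. = FALSE)
  if (any(conc < 0)) stop("standard concentrations must be >= 0", call. = FALSE)
  if (any(!is.finite(absb))) stop("absorbances must be finite", call. = FALSE)
  if (length(unique(conc)) < 2L)
    stop("at least 2 distinct standard concentrations are required",
         call. = FALSE)
  if (!degree %in% c(1L, 2L))
    stop("degree must be 1 or 2", call. = FALSE)
  if (degree == 2L && length(unique(conc)) < 3L)
    stop("quadratic calibration needs >= 3 distinct concentrations",
         call. = FALSE)
  fit <- if (degree == 1L) stats::lm(absb ~ conc)
         else stats::lm(absb ~ conc + I(conc^2))
  cf <- unname(stats::coef(fit))
  slope <- cf[2]
  if (!is.finite(slope) || slope <= 0)
    stop("calibration slope is not positive: assay failure", call. = FALSE)
  ssTot <- sum((absb - mean(absb))^2)
  r2 <- if (ssTot > 0) 1 - sum(stats::residuals(fit)^2) / ssTot else 1
  .BcaFit(slope = slope, intercept = cf[1],
          quad = if (degree == 2L) cf[3] else 0,
          rSquared = r2, workingRange = range(conc),
          nStandards = length(conc))
}

#' Invert absorbances into protein concentrations
#'
#' `concentration = dilution_factor x (A - intercept) / slope`. Values whose
#' undiluted concentration falls outside the standards' working range are
#' flagged as extrapolation.
#'
#' @param fit A [BcaFit-class] from [bcaFit()].
#' @param absorbance Absorbance readings (AU at 562 nm).
#' @param dilutionFactor Dilution factor(s) >= 1, recycled.
#' @return `data.frame` with columns `absorbance`, `dilution_factor`,
#'   `concentration_ug_ml`, `extrapolated`.
#' @export
bcaConcentration <- function(fit, absorbance, dilutionFactor = 1) {
  stopifnot(is(fit, "BcaFit"))
  dilutionFactor <- rep_len(dilutionFactor, length(absorbance))
  if (any(dilutionFactor < 1))
    stop("dilution factors must be >= 1", call. = FALSE)
  if (fit@quad == 0) {
    raw <- (absorbance - fit@intercept) / fit@slope
  } else {
    ## invert intercept + slope*C + quad*C^2 = A on the branch through C = 0
    disc <- fit@slope^2 - 4 * fit@quad * (fit@intercept - absorbance)
    if (any(disc < 0))
      stop("absorbance outside the invertible range of the quadratic fit",
           call. = FALSE)
    raw <- (-fit@slope + sqrt(disc)) / (2 * fit@quad)
  }
  ## numeric slack so standards at the range limits are not flagged
  tol <- 1e-9 * max(1, abs(fit@workingRange[2]))
  data.frame(absorbance = absorbance,
             dilution_factor = dilutionFactor,
             concentration_ug_ml = dilutionFactor * raw,
             extrapolated = raw < fit@workingRange[1] - tol |
                            raw > fit@workingRange[2] + tol)
}
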