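## Extraction score.
##
## For each feature, every sample's raw intensity is expressed as a
## percentage of that feature's maximum over the in-scope samples; the
## percentage is then binned into a 0-4 score: 0 for not detected
## (intensity exactly 0), 1 for < 25%, 2 for [25, 50), 3 for [50, 75),
## 4 for >= 75%. Per-sample totals are the column sums of these scores,
## and each extraction condition is summarised as mean +/- SD of its
## replicate totals.

.scopeFactor <- function(x, scope) {
  if (is.factor(scope) || (is.atomic(scope) && length(scope) == ncol(x)))
    return(factor(scope))
  scope <- match.arg(scope, c("device", "all"))
  cd <- colData(x)
  if (scope == "device") factor(paste(cd$device, cd$assay))
  else factor(rep("all", ncol(x)))
}

#' Relative intensity (% of the per-feature maximum)
#'
#' Divides each raw intensity by the maximum intensity of that feature over
#' the in-scope samples and expresses it as a percentage. Features that are
#' zero everywhere in scope return 0% (no division by zero). The default
#' scope `"device"` anchors the maximum within each device (and assay)
#' across its solvents and replicates, because devices are evaluated
#' separately; `"all"` pools every sample, and a factor over the columns
#' gives full control.
#'
#' @param x A raw [SpotExperiment-class] (`normalized = FALSE`).
#' @param scope `"device"`, `"all"`, or a grouping vector/factor of length
#'   `ncol(x)`.
#' @return Numeric matrix of percentages, same dimensions as the table.
#' @export
relativeIntensity <- function(x, scope = "device") {
  stopifnot(is(x, "SpotExperiment"))
  if (isNormalized(x) || isLogTransformed(x))
    stop("the extraction score is defined on raw intensities", call. = FALSE)
  if (!ncol(x)) stop("scope selects no samples", call. = FALSE)
  g <- .scopeFactor(x, scope)
  m <- assay(x, "intensity")
  rel <- m
  for (lev in levels(g)) {
    j <- which(g == lev)
    mx <- apply(m[, j, drop = FALSE], 1, max)
    mx[mx == 0] <- 1  # all-zero rows stay 0%
    ## divide first: x/max is exactly 1 at the maximum, so rel tops at 100
    rel[, j] <- (m[, j, drop = FALSE] / mx) * 100
  }
  rel
}

#' Bin a relative intensity into a 0-4 score
#'
#' `detected` distinguishes a true zero signal (score 0, "not detected")
#' from a detected-but-tiny one (score 1): the zero score is keyed to the
#' raw intensity being 0, not to the percentage.
#'
#' @param relPct Relative intensities in [0, 100].
#' @param detected Logical, recycled; `FALSE` forces score 0.
#' @return Integer scores in {0, 1, 2, 3, 4}.
#' @examples
#' scoreBin(c(10, 25, 50, 75, 100))           # 1 2 3 4 4
#' scoreBin(0, detected = FALSE)              # 0
#' @export
scoreBin <- function(relPct, detected = TRUE) {
  if (any(!is.finite(relPct)) || any(relPct < 0 | relPct > 100))
    stop("relative intensities must lie in [0, 100]", call. = FALSE)
  s <- ifelse(relPct < 25, 1L, ifelse(relPct < 50, 2L, ifelse(relPct < 75, 3L, 4L)))
  s[!rep_len(detected, length(relPct))] <- 0L
  s
}

#' Per-feature extraction scores
#'
#' @inheritParams relativeIntensity
#' @return Integer matrix of scores in {0,...,4}, features x samples.
#' @seealso [totalScores()], [classScoreHeatmap()], [scoreReport()]
#' @export
scoreFeatures <- function(x, scope = "device") {
  rel <- relativeIntensity(x, scope)
  m <- assay(x, "intensity")
  s <- matrix(scoreBin(as.vector(rel), detected = as.vector(m) > 0),
              nrow(rel), ncol(rel), dimnames = dimnames(rel))
  s
}

.conditionKey <- function(cd)
  interaction(cd$device, cd$solvent, cd$assay, cd$day, cd$extraction_mode,
              drop = TRUE, lex.order = TRUE)

#' Total extraction score per condition
#'
#' The per-sample total is the sum of that sample's feature scores; each
#' condition (device, solvent, assay, day, extraction mode) is then
#' summarised as the mean of its replicate totals with the n-1 sample
#' standard deviation. Conditions with a single replicate report sd = 0 and
#' are flagged.
#'
#' @param x The scored [SpotExperiment-class].
#' @param scores Score matrix from [scoreFeatures()]; computed if omitted.
#' @param scope Passed to [scoreFeatures()] when `scores` is missing.
#' @return `data.frame` with columns `device`, `solvent`, `assay`, `day`,
#'   `extraction_mode`, `n`, `mean_score`, `sd_score`,
#'   `single_replicate` (flag).
#' @export
totalScores <- function(x, scores = scoreFeatures(x, scope), scope = "device") {
  cd <- as.data.frame(colData(x))
  perSample <- colSums(scores)
  key <- .conditionKey(cd)
  idx <- split(seq_len(ncol(x)), key)
  rows <- lapply(idx, function(j) {
    tot <- perSample[j]
    data.frame(device = cd$device[j[1]], solvent = cd$solvent[j[1]],
               assay = cd$assay[j[1]], day = cd$day[j[1]],
               extraction_mode = cd$extraction_mode[j[1]],
               n = length(j), mean_score = mean(tot),
               sd_score = if (length(j) > 1) stats::sd(tot) else 0,
               single_replicate = length(j) == 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (any(out$single_replicate))
    warning("condition(s) with a single replicate: sd reported as 0")
  out
}

#' Class-average score heatmap
#'
#' Mean per-feature score per (compound class, solvent) within each device
#' — the numeric content of the class-level heatmaps used to compare
#' solvents. Classes without features yield `NA` cells (missing, not 0);
#' zero-intensity features contribute score 0.
#'
#' @inheritParams totalScores
#' @return Named list, one `class x solvent` matrix per device.
#' @export
classScoreHeatmap <- function(x, scores = scoreFeatures(x, scope), scope = "device") {
  cd <- as.data.frame(colData(x))
  classes <- compoundClasses(assayType(x))
  cls <- factor(compoundClass(x), levels = classes)
  devices <- unique(cd$device)
  solvents <- unique(cd$solvent)
  out <- lapply(devices, function(d) {
    h <- matrix(NA_real_, length(classes), length(solvents),
                dimnames = list(classes, solvents))
    for (s in solvents) {
      j <- which(cd$device == d & cd$solvent == s)
      if (!length(j)) next
      sub <- scores[, j, drop = FALSE]
      mu <- tapply(rowMeans(sub), cls, mean)
      h[names(mu), s] <- mu
    }
    h
  })
  names(out) <- devices
  out
}

#' Full score report
#'
#' Convenience wrapper returning the per-feature score matrix, the
#' per-condition totals and the per-device class heatmaps in one list.
#'
#' @inheritParams relativeIntensity
#' @return `list(perFeature, totals, heatmaps, scope)`.
#' @export
scoreReport <- function(x, scope = "device") {
  s <- scoreFeatures(x, scope)
  list(perFeature = s,
       totals = totalScores(x, scores = s),
       heatmaps = classScoreHeatmap(x, scores = s),
       scope = if (is.character(scope) && length(scope) == 1L) scope else "custom")
}
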