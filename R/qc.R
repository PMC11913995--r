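## Reproducibility and short-term stability QC.
##
## Reproducibility: per-feature CV% over replicate spots of one extraction
## condition, summarised as the percentage of features falling in the
## conventional buckets CV < 10%, 10-30%, > 30% (< 30% being the usual
## acceptance bound for untargeted work). Stability: percent variation of
## each compound class at storage day d relative to the day-0 baseline,
## with |variation| <= 20% (default band) calling the class stable.

#' Coefficient of variation (%)
#'
#' 100 x sample standard deviation (n-1) / mean. Undefined (`NA`) when the
#' mean is not positive or fewer than 2 replicate values are detected
#' (nonzero); such features are flagged and excluded from bucket
#' percentages.
#'
#' @param values Numeric replicate values.
#' @return CV in percent, or `NA_real_` when undefined.
#' @examples
#' cvPercent(c(5, 5, 5))   # 0
#' cvPercent(c(1, 2, 3))   # 50
#' @export
cvPercent <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L || sum(values > 0) < 2L) return(NA_real_)
  mu <- mean(values)
  if (mu <= 0) return(NA_real_)
  100 * stats::sd(values) / mu
}

.BUCKETS <- c("cv_lt_10", "cv_10_30", "cv_gt_30")

## Bucket boundaries [0,10), [10,30], (30,Inf): the printed bucket labels
## leave CV = 10 and CV = 30 unassigned; assigning both to the middle
## bucket keeps "> 30%" meaning strictly greater.
.cvBucket <- function(cv) {
  ifelse(cv < 10, .BUCKETS[1], ifelse(cv <= 30, .BUCKETS[2], .BUCKETS[3]))
}

#' Reproducibility profile: per-feature CV% and bucket percentages
#'
#' Computes each feature's CV% over the replicates of every extraction
#' condition (device, solvent, assay, day, extraction mode) and the
#' percentage of defined-CV features per bucket. By default CVs are
#' computed on raw intensities (CV% is scale-invariant, so per-sample
#' normalization is unnecessary); pass a normalized table to profile
#' normalized values instead.
#'
#' @param x A [SpotExperiment-class].
#' @return `list(cv, buckets)`: `cv` is a long `data.frame` (`feature_id`,
#'   condition columns, `cv`, `defined`); `buckets` has one row per
#'   condition with columns `cv_lt_10`, `cv_10_30`, `cv_gt_30` (percent,
#'   summing to 100), `n_features_used` and `n_undefined`.
#' @export
cvProfile <- function(x) {
  stopifnot(is(x, "SpotExperiment"))
  cd <- as.data.frame(colData(x))
  m <- assay(x, "intensity")
  key <- .conditionKey(cd)
  idx <- split(seq_len(ncol(x)), key)
  cvRows <- list(); bkRows <- list()
  for (g in names(idx)) {
    j <- idx[[g]]
    cv <- apply(m[, j, drop = FALSE], 1, cvPercent)
    cvRows[[g]] <- data.frame(
      feature_id = rownames(x), device = cd$device[j[1]],
      solvent = cd$solvent[j[1]], assay = cd$assay[j[1]], day = cd$day[j[1]],
      extraction_mode = cd$extraction_mode[j[1]], cv = cv,
      defined = !is.na(cv), stringsAsFactors = FALSE)
    def <- cv[!is.na(cv)]
    if (!length(def))
      stop("no feature has a defined CV in condition ", g, call. = FALSE)
    pct <- 100 * table(factor(.cvBucket(def), levels = .BUCKETS)) / length(def)
    bk <- data.frame(device = cd$device[j[1]], solvent = cd$solvent[j[1]],
                     assay = cd$assay[j[1]], day = cd$day[j[1]],
                     extraction_mode = cd$extraction_mode[j[1]],
                     stringsAsFactors = FALSE)
    bk[.BUCKETS] <- as.numeric(pct)
    bk$n_features_used <- length(def)
    bk$n_undefined <- sum(is.na(cv))
    bkRows[[g]] <- bk
  }
  list(cv = do.call(rbind, c(cvRows, list(make.row.names = FALSE))),
       buckets = do.call(rbind, c(bkRows, list(make.row.names = FALSE))))
}

#' Variation to baseline and stability calls
#'
#' For a storage series of one device and assay: each feature's percent
#' variation at day d is `100 x (mean_d - mean_0) / mean_0` over replicate
#' spots; a class's variation is the mean of its features' variations
#' (`aggregation = "feature_mean"`, default — so a few high-abundance
#' features cannot mask class-wide degradation) or the variation of the
#' class-summed signal (`"class_sum"`). A class is stable at day d when
#' |variation| <= `band` (percent, default 20).
#'
#' Features not detected at baseline (day-0 mean 0) are excluded from the
#' class aggregate and counted in `n_excluded`.
#'
#' @param x A [SpotExperiment-class] holding one device and one assay, with
#'   day 0 present.
#' @param band Acceptance band in percent.
#' @param aggregation `"feature_mean"` or `"class_sum"`.
#' @return `list(variation, classSummary, band)`: `variation` has one row
#'   per (compound_class, day) with `variation_pct`, `stable`,
#'   `n_features`, `n_excluded`; `classSummary` gives each class's first
#'   unstable day (`NA` if none) and whether it is stable throughout.
#' @export
variationToBaseline <- function(x, band = 20,
                                aggregation = c("feature_mean", "class_sum")) {
  stopifnot(is(x, "SpotExperiment"), band > 0)
  aggregation <- match.arg(aggregation)
  cd <- as.data.frame(colData(x))
  if (length(unique(cd$device)) != 1L)
    stop("stability is assessed per device; subset to one device first",
         call. = FALSE)
  days <- sort(unique(cd$day))
  if (!0 %in% days)
    stop("day 0 (baseline) is required", call. = FALSE)
  m <- assay(x, "intensity")
  ## per-feature mean per day
  dayMeans <- vapply(days, function(d)
    rowMeans(m[, cd$day == d, drop = FALSE]), numeric(nrow(m)))
  colnames(dayMeans) <- days
  base <- dayMeans[, "0"]
  cls <- compoundClass(x)
  classes <- intersect(compoundClasses(assayType(x)), cls)

  rows <- list()
  summ <- list()
  for (cc in classes) {
    f <- which(cls == cc)
    ok <- f[base[f] > 0]
    nExcl <- length(f) - length(ok)
    if (!length(ok))
      stop("class '", cc, "' has no feature detected at baseline", call. = FALSE)
    v <- vapply(seq_along(days), function(k) {
      if (aggregation == "feature_mean")
        mean(100 * (dayMeans[ok, k] - base[ok]) / base[ok])
      else
        100 * (sum(dayMeans[ok, k]) - sum(base[ok])) / sum(base[ok])
    }, numeric(1))
    rows[[cc]] <- data.frame(
      compound_class = cc, day = days, variation_pct = v,
      stable = abs(v) <= band, n_features = length(ok), n_excluded = nExcl,
      stringsAsFactors = FALSE)
    unst <- days[abs(v) > band]
    summ[[cc]] <- data.frame(
      compound_class = cc,
      first_unstable_day = if (length(unst)) min(unst) else NA_integer_,
      stable_throughout = !length(unst), n_excluded = nExcl,
      stringsAsFactors = FALSE)
  }
  list(variation = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       classSummary = do.call(rbind, c(summ, list(make.row.names = FALSE))),
       band = band)
}
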