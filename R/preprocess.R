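#' Sum normalization
#'
#' Divides every sample column by its total signal, the "normalization by
#' the sum of the signals" conventional in untargeted metabolomics, so each
#' column sums to 1. Applied before PCA and volcano analysis; the extraction
#' score and CV% profiling operate on raw intensities.
#'
#' @param x A raw [SpotExperiment-class] (`isNormalized(x)` is `FALSE`).
#' @return The normalized table with `normalized = TRUE`.
#' @export
normalizeSum <- function(x) {
  stopifnot(is(x, "SpotExperiment"))
  if (isNormalized(x))
    stop("table is already normalized", call. = FALSE)
  m <- assay(x, "intensity")
  tot <- colSums(m)
  bad <- colnames(m)[tot <= 0]
  if (length(bad))
    stop("cannot normalize all-zero sample(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  assays(x)[["intensity"]] <- sweep(m, 2, tot, "/")
  metadata(x)$normalized <- TRUE
  x
}

#' Log10 transformation
#'
#' Applies log10 to every intensity. Zeros ("not detected") are handled by
#' `zeroPolicy`: `"half_min"` (default, common metabolomics practice)
#' replaces them with half the smallest positive value in the table before
#' taking logs; `"error"` refuses, reporting how many cells offend.
#'
#' @param x A [SpotExperiment-class] with `isLogTransformed(x)` `FALSE`
#'   (typically sum-normalized first).
#' @param zeroPolicy `"half_min"` or `"error"`.
#' @return The transformed table with `logTransformed = TRUE`.
#' @export
log10Transform <- function(x, zeroPolicy = c("half_min", "error")) {
  stopifnot(is(x, "SpotExperiment"))
  zeroPolicy <- match.arg(zeroPolicy)
  if (isLogTransformed(x))
    stop("table is already log-transformed", call. = FALSE)
  m <- assay(x, "intensity")
  nz <- sum(m == 0)
  if (nz > 0) {
    if (zeroPolicy == "error")
      stop("log10 transform with zeroPolicy='error': ", nz,
           " zero cell(s) present", call. = FALSE)
    pos <- m[m > 0]
    if (!length(pos))
      stop("cannot log-transform an all-zero table", call. = FALSE)
    m[m == 0] <- min(pos) / 2
  }
  assays(x)[["intensity"]] <- log10(m)
  metadata(x)$logTransformed <- TRUE
  x
}
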