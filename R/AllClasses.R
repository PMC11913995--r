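#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays assays<- rowData colData
NULL

## ---- controlled vocabularies -------------------------------------------

#' Controlled vocabularies of the dried-spot study design
#'
#' Helper constants naming the microsampling devices, extraction solvents,
#' assay types and compound classes the package recognises. Polar-metabolite
#' features fall into six classes and lipid features into eight (the standard
#' lipid-class abbreviations: Cer ceramides, LPC lysophosphatidylcholines,
#' PC phosphatidylcholines, PE phosphatidylethanolamines,
#' PI phosphatidylinositols, PS phosphatidylserines, SM sphingomyelins,
#' TG triacylglycerols).
#'
#' @return A character vector of admissible values.
#' @examples
#' polarClasses()
#' compoundClasses("lipid")
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
spotDevices <- function() c("Capitainer", "Whatman", "Telimmune")

#' @rdname vocabularies
#' @export
extractionSolvents <- function() c("CH3OH100", "CH3OH80", "CH3OH50", "ISO", "BuMe")

#' @rdname vocabularies
#' @export
assayTypes <- function() c("polar", "lipid")

#' @rdname vocabularies
#' @export
polarClasses <- function() {
  c("purine/pyrimidines", "carboxylic acids", "amino acids",
    "sugars", "carnitines", "phosphorylated compounds")
}

#' @rdname vocabularies
#' @export
lipidClasses <- function() c("Cer", "LPC", "PC", "PE", "PI", "PS", "SM", "TG")

#' @rdname vocabularies
#' @param assay `"polar"` or `"lipid"`.
#' @export
compoundClasses <- function(assay = c("polar", "lipid")) {
  assay <- match.arg(assay)
  if (assay == "polar") polarClasses() else lipidClasses()
}

.FEATURE_COLS <- c("feature_id", "assay", "compound_class")
.SAMPLE_COLS  <- c("sample_id", "device", "solvent", "replicate", "day",
                   "assay", "extraction_mode")
.MODES <- c("single", "consecutive")

## ---- SpotExperiment -----------------------------------------------------

#' SpotExperiment: an annotated dried-spot feature table
#'
#' `SpotExperiment` extends [SummarizedExperiment::SummarizedExperiment] and
#' is the single input currency of every analysis stage. The `"intensity"`
#' assay holds the feature x sample signal matrix; `rowData` carries the
#' feature annotations (`feature_id`, `assay`, `compound_class`); `colData`
#' carries the sample metadata (`sample_id`, `device`, `solvent`,
#' `replicate`, `day`, `assay`, `extraction_mode`); and two logical flags in
#' `metadata()` record whether the table has been sum-normalized and/or
#' log10-transformed.
#'
#' Validity rules: intensities are non-negative (until log transformation)
#' and finite; feature and sample identifiers are unique, case-sensitive
#' opaque strings; every `compound_class` belongs to the class set of its
#' assay; all features (and samples) of one table share a single assay type;
#' the sample key (device, solvent, replicate, day, extraction_mode) is
#' unique; `day >= 0` and `replicate >= 1`. A zero intensity means
#' "not detected" — there is no separate missing-value state, and missing
#' cells read from file become 0.
#'
#' @aliases SpotExperiment-class
#' @exportClass SpotExperiment
.SpotExperiment <- setClass("SpotExperiment", contains = "SummarizedExperiment")

.validSpotExperiment <- function(object) {
  msg <- character(0)
  if (!"intensity" %in% names(assays(object)))
    return("assay 'intensity' is missing")
  m <- assay(object, "intensity")
  rd <- rowData(object)
  cd <- colData(object)

  if (!all(.FEATURE_COLS %in% colnames(rd)))
    msg <- c(msg, paste0("rowData must contain columns: ",
                         paste(.FEATURE_COLS, collapse = ", ")))
  if (!all(.SAMPLE_COLS %in% colnames(cd)))
    msg <- c(msg, paste0("colData must contain columns: ",
                         paste(.SAMPLE_COLS, collapse = ", ")))
  if (length(msg)) return(msg)

  norm <- isNormalized(object)
  logt <- isLogTransformed(object)
  if (!is.logical(norm) || length(norm) != 1L || is.na(norm))
    msg <- c(msg, "metadata flag 'normalized' must be TRUE or FALSE")
  if (!is.logical(logt) || length(logt) != 1L || is.na(logt))
    msg <- c(msg, "metadata flag 'logTransformed' must be TRUE or FALSE")

  if (anyNA(m) || any(!is.finite(m)))
    msg <- c(msg, "intensities must be finite and non-missing")
  else if (!isTRUE(logt) && nrow(m) && ncol(m) && any(m < 0))
    msg <- c(msg, "intensities must be >= 0 (negative value found)")

  if (anyDuplicated(rd$feature_id))
    msg <- c(msg, paste0("duplicate feature_id: ",
                         paste(unique(rd$feature_id[duplicated(rd$feature_id)]),
                               collapse = ", ")))
  if (anyDuplicated(cd$sample_id))
    msg <- c(msg, paste0("duplicate sample_id: ",
                         paste(unique(cd$sample_id[duplicated(cd$sample_id)]),
                               collapse = ", ")))

  badEnum <- function(x, allowed, what) {
    bad <- setdiff(unique(as.character(x)), allowed)
    if (length(bad))
      paste0("unknown ", what, ": ", paste(bad, collapse = ", "),
             " (accepted: ", paste(allowed, collapse = ", "), ")")
    else character(0)
  }
  msg <- c(msg,
           badEnum(cd$device, spotDevices(), "device"),
           badEnum(cd$solvent, extractionSolvents(), "solvent"),
           badEnum(cd$assay, assayTypes(), "sample assay"),
           badEnum(cd$extraction_mode, .MODES, "extraction_mode"),
           badEnum(rd$assay, assayTypes(), "feature assay"))
  if (length(msg)) return(msg)

  for (a in unique(as.character(rd$assay))) {
    bad <- setdiff(unique(as.character(rd$compound_class[rd$assay == a])),
                   compoundClasses(a))
    if (length(bad))
      msg <- c(msg, paste0("compound_class not in the ", a, " class set: ",
                           paste(bad, collapse = ", ")))
  }
  if (length(unique(as.character(rd$assay))) > 1L)
    msg <- c(msg, "a table must hold features of a single assay type")
  if (nrow(rd) && ncol(m) &&
      !all(as.character(cd$assay) == as.character(rd$assay[1L])))
    msg <- c(msg, "sample assay must match the feature assay of the table")

  if (any(cd$day < 0) || any(cd$day != round(cd$day)))
    msg <- c(msg, "day must be a non-negative integer")
  if (any(cd$replicate < 1) || any(cd$replicate != round(cd$replicate)))
    msg <- c(msg, "replicate must be a positive integer")

  key <- paste(cd$device, cd$solvent, cd$replicate, cd$day,
               cd$extraction_mode, sep = "\r")
  if (anyDuplicated(key))
    msg <- c(msg, "duplicate sample key (device, solvent, replicate, day, extraction_mode)")

  if (length(msg)) msg else TRUE
}

setValidity("SpotExperiment", .validSpotExperiment)

#' Construct a SpotExperiment
#'
#' @param intensities Numeric matrix, features x samples, non-negative
#'   (arbitrary intensity units). Row and column names are taken from
#'   `featureData$feature_id` and `sampleData$sample_id`.
#' @param featureData `data.frame` (or `DataFrame`) with columns
#'   `feature_id`, `assay`, `compound_class`, one row per matrix row.
#' @param sampleData `data.frame` (or `DataFrame`) with columns `sample_id`,
#'   `device`, `solvent`, `replicate`, `day`, `assay`, `extraction_mode`,
#'   one row per matrix column.
#' @param normalized,logTransformed Logical flags recording the
#'   preprocessing state of `intensities`.
#'
#' @return A validated [SpotExperiment-class] object.
#' @examples
#' x <- SpotExperiment(
#'   matrix(c(10, 20, 5, 40, 2, 80), nrow = 2),
#'   featureData = data.frame(feature_id = c("f1", "f2"), assay = "polar",
#'                            compound_class = c("sugars", "amino acids")),
#'   sampleData  = data.frame(sample_id = c("s1", "s2", "s3"),
#'                            device = "Capitainer", solvent = "CH3OH100",
#'                            replicate = 1:3, day = 0, assay = "polar",
#'                            extraction_mode = "single"))
#' x
#' @export
SpotExperiment <- function(intensities, featureData, sampleData,
                           normalized = FALSE, logTransformed = FALSE) {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  featureData <- DataFrame(as.data.frame(featureData))
  sampleData <- as.data.frame(sampleData)
  if (!is.null(sampleData$replicate) &&
      all(sampleData$replicate == round(sampleData$replicate)))
    sampleData$replicate <- as.integer(sampleData$replicate)
  if (!is.null(sampleData$day) && all(sampleData$day == round(sampleData$day)))
    sampleData$day <- as.integer(sampleData$day)
  sampleData <- DataFrame(sampleData)
  if (nrow(featureData) != nrow(intensities))
    stop("featureData has ", nrow(featureData), " rows but the matrix has ",
         nrow(intensities), call. = FALSE)
  if (nrow(sampleData) != ncol(intensities))
    stop("sampleData has ", nrow(sampleData), " rows but the matrix has ",
         ncol(intensities), " columns", call. = FALSE)
  if (nrow(featureData)) rownames(intensities) <- featureData$feature_id
  if (nrow(sampleData)) colnames(intensities) <- sampleData$sample_id
  se <- SummarizedExperiment(
    assays = list(intensity = intensities),
    rowData = featureData, colData = sampleData)
  metadata(se)$normalized <- isTRUE(normalized)
  metadata(se)$logTransformed <- isTRUE(logTransformed)
  out <- .SpotExperiment(se)
  validObject(out)
  out
}

## ---- accessors ----------------------------------------------------------

#' Preprocessing-state and annotation accessors
#'
#' `isNormalized()` and `isLogTransformed()` report the preprocessing flags;
#' `compoundClass()` returns the per-feature class vector and `assayType()`
#' the single assay type of the table.
#'
#' @param x A [SpotExperiment-class].
#' @return A logical flag, or a character vector for `compoundClass()`.
#' @name accessors
NULL

#' @rdname accessors
#' @export
isNormalized <- function(x) isTRUE(metadata(x)$normalized)

#' @rdname accessors
#' @export
isLogTransformed <- function(x) isTRUE(metadata(x)$logTransformed)

#' @rdname accessors
#' @export
compoundClass <- function(x) as.character(rowData(x)$compound_class)

#' @rdname accessors
#' @export
assayType <- function(x) {
  a <- unique(as.character(rowData(x)$assay))
  if (length(a) != 1L) stop("table does not have a single assay type")
  a
}

setMethod("show", "SpotExperiment", function(object) {
  cat("class: SpotExperiment\n")
  cat("assay:", if (nrow(object)) assayType(object) else "(empty)",
      "|", nrow(object), "features x", ncol(object), "samples\n")
  cd <- colData(object)
  if (ncol(object)) {
    cat("devices:", paste(unique(as.character(cd$device)), collapse = ", "), "\n")
    cat("solvents:", paste(unique(as.character(cd$solvent)), collapse = ", "), "\n")
    cat("days:", paste(sort(unique(cd$day)), collapse = ", "),
        "| modes:", paste(unique(as.character(cd$extraction_mode)), collapse = ", "), "\n")
  }
  cat("normalized:", isNormalized(object),
      "| logTransformed:", isLogTransformed(object), "\n")
  invisible(NULL)
})

## ---- BcaFit -------------------------------------------------------------

#' BcaFit: a BCA protein-assay calibration line
#'
#' Ordinary least-squares fit of absorbance (562 nm) against standard
#' concentration, used to invert unknown absorbances into protein
#' concentrations. Slots: `slope`, `intercept` and `quad` of the curve
#' absorbance = intercept + slope x C + quad x C^2 (`quad` is 0 for the
#' default linear fit), `rSquared`, the `workingRange` spanned by the
#' standards (predictions outside it are flagged as extrapolation), and
#' `nStandards`.
#'
#' @aliases BcaFit-class
#' @seealso [bcaFit()], [bcaConcentration()]
#' @exportClass BcaFit
.BcaFit <- setClass("BcaFit", representation(
  slope = "numeric", intercept = "numeric", quad = "numeric",
  rSquared = "numeric", workingRange = "numeric", nStandards = "integer"),
  prototype(quad = 0))

setValidity("BcaFit", function(object) {
  msg <- character(0)
  if (length(object@slope) != 1L || !is.finite(object@slope) || object@slope <= 0)
    msg <- c(msg, "slope must be a single positive finite number")
  if (length(object@workingRange) != 2L || object@workingRange[1] > object@workingRange[2])
    msg <- c(msg, "workingRange must be an increasing pair")
  if (object@nStandards < 2L)
    msg <- c(msg, "at least 2 standards required")
  if (length(msg)) msg else TRUE
})

setMethod("show", "BcaFit", function(object) {
  cat("BcaFit: A =", signif(object@intercept, 4), "+",
      signif(object@slope, 4), "x C\n")
  cat("R-squared:", signif(object@rSquared, 4),
      "| working range:", object@workingRange[1], "-",
      object@workingRange[2], "ug/mL |", object@nStandards, "standards\n")
  invisible(NULL)
})
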