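## Plain-text interchange formats.
##
## Matrix: RFC-4180 CSV (TSV when the extension is .tsv), UTF-8, first column
## `feature_id`, one column per sample_id; decimal point, no thousands
## separators. Missing cells mean "not detected" and are read as 0.
## Sample metadata: TSV, columns sample_id, device, solvent, replicate, day,
## assay, extraction_mode; the preprocessing flags are persisted as
## `#key=value` header lines. Feature annotation: TSV, columns feature_id,
## assay, compound_class.

.delim <- function(path) if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","

#' Read an annotated feature table from its three text files
#'
#' Reads the wide intensity matrix, the per-sample metadata and the
#' per-feature annotations, cross-references the identifiers, and returns a
#' validated [SpotExperiment-class]. Empty or missing matrix cells are read
#' as 0 ("not detected"); there is no separate not-measured state. Column
#' order of the returned table follows the metadata row order.
#'
#' @param matrixPath CSV (or TSV) intensity matrix: first column
#'   `feature_id`, then one column per sample.
#' @param sampleMetaPath TSV sample metadata with columns `sample_id`,
#'   `device`, `solvent`, `replicate`, `day`, `assay`, `extraction_mode`.
#'   `#normalized=` / `#logTransformed=` header lines restore the
#'   preprocessing flags written by [writeFeatureTable()].
#' @param annotationPath TSV feature annotations with columns `feature_id`,
#'   `assay`, `compound_class`.
#'
#' @return A [SpotExperiment-class].
#' @seealso [writeFeatureTable()]
#' @export
readFeatureTable <- function(matrixPath, sampleMetaPath, annotationPath) {
  for (p in c(matrixPath, sampleMetaPath, annotationPath))
    if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)

  matLines <- readLines(matrixPath)
  mat <- if (length(matLines) > 1L) {
    utils::read.table(matrixPath, sep = .delim(matrixPath), header = TRUE,
                      check.names = FALSE, quote = "\"",
                      colClasses = NA, comment.char = "")
  } else {  # header-only file (empty table)
    nm <- scan(text = matLines, what = character(), sep = .delim(matrixPath),
               quiet = TRUE)
    stats::setNames(as.data.frame(matrix(numeric(0), 0, length(nm))), nm)
  }
  if (!ncol(mat) || colnames(mat)[1] != "feature_id")
    stop("matrix file must have 'feature_id' as its first column", call. = FALSE)

  hdr <- readLines(sampleMetaPath, n = 10L)
  flags <- hdr[startsWith(hdr, "#")]
  readFlag <- function(key) {
    ln <- grep(paste0("^#", key, "="), flags, value = TRUE)
    length(ln) && toupper(sub(".*=", "", ln[1])) == "TRUE"
  }
  meta <- utils::read.table(sampleMetaPath, sep = "\t", header = TRUE,
                            check.names = FALSE, comment.char = "#",
                            colClasses = "character")
  anno <- utils::read.table(annotationPath, sep = "\t", header = TRUE,
                            check.names = FALSE, comment.char = "#",
                            colClasses = "character")
  need <- setdiff(.SAMPLE_COLS, colnames(meta))
  if (length(need))
    stop("sample metadata is missing columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  need <- setdiff(.FEATURE_COLS, colnames(anno))
  if (length(need))
    stop("feature annotation is missing columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  meta$replicate <- as.integer(meta$replicate)
  meta$day <- as.integer(meta$day)

  fid <- as.character(mat$feature_id)
  m <- as.matrix(mat[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  m[is.na(m)] <- 0
  rownames(m) <- fid

  missSamp <- setdiff(meta$sample_id, colnames(m))
  if (length(missSamp))
    stop("sample_id in metadata not found in the matrix: ",
         paste(missSamp, collapse = ", "), call. = FALSE)
  extraSamp <- setdiff(colnames(m), meta$sample_id)
  if (length(extraSamp))
    stop("matrix column without sample metadata: ",
         paste(extraSamp, collapse = ", "), call. = FALSE)
  missFeat <- setdiff(anno$feature_id, fid)
  if (length(missFeat))
    stop("feature_id in annotation not found in the matrix: ",
         paste(missFeat, collapse = ", "), call. = FALSE)
  extraFeat <- setdiff(fid, anno$feature_id)
  if (length(extraFeat))
    stop("matrix row without feature annotation: ",
         paste(extraFeat, collapse = ", "), call. = FALSE)

  m <- m[match(anno$feature_id, rownames(m)), match(meta$sample_id, colnames(m)),
         drop = FALSE]
  SpotExperiment(m, featureData = anno, sampleData = meta,
                 normalized = readFlag("normalized"),
                 logTransformed = readFlag("logTransformed"))
}

#' Write a feature table to its three text files
#'
#' Inverse of [readFeatureTable()]: the written files round-trip (values
#' within 1e-9 relative tolerance, metadata exactly). Sample columns are
#' canonicalized on write — sorted by device, solvent (in the standard
#' solvent order), extraction mode, day and replicate — so file diffs are
#' stable regardless of in-memory column order.
#'
#' @param x A [SpotExperiment-class].
#' @inheritParams readFeatureTable
#' @return Invisibly, the three paths.
#' @export
writeFeatureTable <- function(x, matrixPath, sampleMetaPath, annotationPath) {
  stopifnot(is(x, "SpotExperiment"))
  validObject(x)
  cd <- as.data.frame(colData(x))
  ord <- order(match(cd$device, spotDevices()),
               match(cd$solvent, extractionSolvents()),
               match(cd$extraction_mode, .MODES),
               cd$day, cd$replicate)
  cd <- cd[ord, , drop = FALSE]
  m <- assay(x, "intensity")[, ord, drop = FALSE]

  df <- data.frame(feature_id = as.character(rowData(x)$feature_id),
                   check.names = FALSE)
  if (ncol(m)) df <- cbind(df, as.data.frame(format(m, digits = 15, trim = TRUE,
                                                    scientific = FALSE)))
  utils::write.table(df, matrixPath, sep = .delim(matrixPath), quote = TRUE,
                     row.names = FALSE, qmethod = "double")

  con <- file(sampleMetaPath, "w")
  writeLines(c(paste0("#normalized=", isNormalized(x)),
               paste0("#logTransformed=", isLogTransformed(x))), con)
  utils::write.table(cd[, .SAMPLE_COLS, drop = FALSE], con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  close(con)

  rd <- as.data.frame(rowData(x))
  utils::write.table(rd[, .FEATURE_COLS, drop = FALSE], annotationPath,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(matrixPath, sampleMetaPath, annotationPath))
}

#' Read BCA plate files
#'
#' `readBcaStandards()` expects columns `concentration_ug_ml, absorbance`;
#' `readBcaUnknowns()` expects `sample_id, absorbance, dilution_factor`.
#'
#' @param path CSV file path.
#' @return A `data.frame`.
#' @seealso [bcaFit()]
#' @export
readBcaStandards <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- setdiff(c("concentration_ug_ml", "absorbance"), colnames(df))
  if (length(need))
    stop("standards file is missing columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  df
}

#' @rdname readBcaStandards
#' @export
readBcaUnknowns <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- setdiff(c("sample_id", "absorbance", "dilution_factor"), colnames(df))
  if (length(need))
    stop("unknowns file is missing columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  df
}
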