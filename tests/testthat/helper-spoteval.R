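suppressPackageStartupMessages(library(SummarizedExperiment))

## Minimal valid table around an intensity matrix. Each column gets its own
## replicate number by default so the sample key stays unique.
toyTable <- function(m, compound_class = "sugars", solvent = "CH3OH100",
                     replicate = NULL, device = "Capitainer", day = 0L,
                     mode = "single", assayName = "polar",
                     normalized = FALSE, logTransformed = FALSE) {
  m <- as.matrix(m)
  if (is.null(replicate)) replicate <- seq_len(ncol(m))
  fd <- data.frame(feature_id = paste0("f", seq_len(nrow(m))),
                   assay = assayName,
                   compound_class = rep_len(compound_class, nrow(m)),
                   stringsAsFactors = FALSE)
  sm <- data.frame(sample_id = paste0("s", seq_len(ncol(m))),
                   device = rep_len(device, ncol(m)),
                   solvent = rep_len(solvent, ncol(m)),
                   replicate = rep_len(replicate, ncol(m)),
                   day = rep_len(day, ncol(m)),
                   assay = assayName,
                   extraction_mode = rep_len(mode, ncol(m)),
                   stringsAsFactors = FALSE)
  SpotExperiment(m, fd, sm, normalized = normalized,
                 logTransformed = logTransformed)
}

## Independent brute-force reimplementation of the extraction score:
## explicit loops and an explicit if-chain over the printed bin boundaries.
## Deliberately shares no code with scoreFeatures().
bruteScoreMatrix <- function(m) {
  s <- matrix(0L, nrow(m), ncol(m), dimnames = dimnames(m))
  for (i in seq_len(nrow(m))) {
    mx <- 0
    for (j in seq_len(ncol(m))) if (m[i, j] > mx) mx <- m[i, j]
    for (j in seq_len(ncol(m))) {
      v <- m[i, j]
      if (v == 0) {
        s[i, j] <- 0L
      } else {
        pct <- v / mx * 100
        if (pct < 25) s[i, j] <- 1L
        else if (pct < 50) s[i, j] <- 2L
        else if (pct < 75) s[i, j] <- 3L
        else s[i, j] <- 4L
      }
    }
  }
  s
}

## Random non-negative matrix with planted zeros and exact ties, to probe
## the 25/50/75 boundaries and the not-detected rule.
randomScoreMatrix <- function(nrMax = 10, ncMax = 15) {
  nr <- sample(1:nrMax, 1)
  nc <- sample(2:ncMax, 1)
  m <- matrix(round(stats::runif(nr * nc, 0, 100), 1), nr, nc)
  m[stats::runif(nr * nc) < 0.15] <- 0
  ## plant exact bin-boundary ratios of the row maximum
  for (i in seq_len(nr)) {
    if (max(m[i, ]) == 0) next
    j <- sample(nc, 1)
    m[i, j] <- max(m[i, ]) * sample(c(0.25, 0.5, 0.75, 1), 1)
  }
  m
}

## Yield table assigning one yield vector (over the 5 solvents) to every
## polar class on one device.
uniformYield <- function(yields, device = "Capitainer") {
  stopifnot(length(yields) == 5L)
  g <- expand.grid(compound_class = polarClasses(),
                   solvent = extractionSolvents(), device = device,
                   stringsAsFactors = FALSE)
  g$yield <- yields[match(g$solvent, extractionSolvents())]
  g
}
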