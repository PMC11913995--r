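## Synthetic feature-table generator.
##
## Emulates the statistical structure the analysis stages assume: per-class
## extraction yields that depend on solvent and device, a per-feature base
## abundance, multiplicative lognormal replicate noise, a detection limit
## producing "not detected" zeros, geometric per-day storage decay, and a
## class-wise gain for the consecutive (two-step) extraction. The realized
## ground truth is returned alongside the table for parameter-recovery tests.

#' Default class-yield table
#'
#' Relative extraction yields in [0, 1] per (compound_class, solvent,
#' device), identical across devices by default. The polar defaults follow
#' the qualitative behaviour of methanol/water mixtures: methanol-based
#' solvents extract most polar classes well, pure isopropanol poorly, and
#' the yield of highly polar phosphorylated compounds rises with the water
#' fraction. Lipid yields fall as the water fraction rises, with pure
#' organic solvents (CH3OH 100%, ISO, BuMe) strongest; TG, the most
#' hydrophobic class, collapses fastest with water.
#'
#' @param assay `"polar"` or `"lipid"`.
#' @param devices Devices to cover.
#' @return `data.frame` with columns `compound_class`, `solvent`, `device`,
#'   `yield`.
#' @export
defaultClassYield <- function(assay = c("polar", "lipid"), devices = spotDevices()) {
  assay <- match.arg(assay)
  ## columns: CH3OH100, CH3OH80, CH3OH50, ISO, BuMe
  y <- if (assay == "polar") rbind(
    "purine/pyrimidines"       = c(0.90, 0.95, 1.00, 0.20, 0.50),
    "carboxylic acids"         = c(0.90, 0.95, 1.00, 0.20, 0.50),
    "amino acids"              = c(0.90, 1.00, 0.95, 0.25, 0.50),
    "sugars"                   = c(0.85, 0.95, 1.00, 0.20, 0.45),
    "carnitines"               = c(0.95, 1.00, 0.90, 0.30, 0.55),
    "phosphorylated compounds" = c(0.40, 0.70, 1.00, 0.10, 0.30)
  ) else rbind(
    "Cer" = c(1.00, 0.60, 0.20, 0.95, 0.90),
    "LPC" = c(1.00, 0.80, 0.40, 0.85, 0.70),
    "PC"  = c(1.00, 0.60, 0.25, 0.95, 0.90),
    "PE"  = c(1.00, 0.55, 0.20, 0.90, 0.95),
    "PI"  = c(1.00, 0.60, 0.25, 0.90, 0.90),
    "PS"  = c(1.00, 0.55, 0.20, 0.90, 0.90),
    "SM"  = c(1.00, 0.65, 0.30, 0.95, 0.85),
    "TG"  = c(1.00, 0.35, 0.10, 0.95, 0.80)
  )
  colnames(y) <- extractionSolvents()
  grid <- expand.grid(compound_class = rownames(y), solvent = colnames(y),
                      device = devices, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid$yield <- y[cbind(grid$compound_class, grid$solvent)]
  grid
}

#' Configuration of the synthetic study design
#'
#' Bundles the design and noise parameters for the generators.
#'
#' @param assay Assay type simulated, `"polar"` (default) or `"lipid"`.
#' @param nFeaturesPerClass Features simulated per compound class. The
#'   defaults (27 polar, 41 lipid) give totals close to the class sizes of a
#'   typical annotated dried-spot data set (~160 polar metabolites, ~330
#'   lipids).
#' @param classYield `data.frame` mapping (compound_class, solvent, device)
#'   to a relative yield in [0, 1]; defaults to [defaultClassYield()].
#' @param baseLog10Range Range (low, high) of log10 base abundance from
#'   which per-feature base intensities are drawn uniformly; default
#'   c(4, 7), i.e. 1e4–1e7 arbitrary units.
#' @param noiseCv Target replicate coefficient of variation of the
#'   multiplicative lognormal noise (0 disables noise); default 0.15.
#' @param detectionLimit Intensities below this value (after noise) are set
#'   to 0, "not detected"; default 5e3.
#' @param decayRate Named vector, fractional signal loss per storage day in
#'   [0, 1) per compound class; unnamed scalars are recycled to all classes.
#'   Default 0 (no decay).
#' @param nReplicates Replicate spots per condition; default 3.
#' @param devices,solvents Design levels; default all 3 devices x 5 solvents.
#' @param seed Integer seed; generation is deterministic given the config.
#'
#' @return A validated list of class `"SyntheticConfig"`.
#' @seealso [simulateExtractionExperiment()], [simulateStabilitySeries()],
#'   [simulateConsecutivePair()]
#' @export
syntheticConfig <- function(assay = c("polar", "lipid"),
                            nFeaturesPerClass = NULL,
                            classYield = NULL,
                            baseLog10Range = c(4, 7),
                            noiseCv = 0.15,
                            detectionLimit = 5e3,
                            decayRate = 0,
                            nReplicates = 3L,
                            devices = spotDevices(),
                            solvents = extractionSolvents(),
                            seed = 1L) {
  assay <- match.arg(assay)
  classes <- compoundClasses(assay)
  if (is.null(nFeaturesPerClass))
    nFeaturesPerClass <- if (assay == "polar") 27L else 41L
  if (is.null(classYield)) classYield <- defaultClassYield(assay, devices)
  if (is.null(names(decayRate))) {
    stopifnot(length(decayRate) == 1L)
    decayRate <- stats::setNames(rep(decayRate, length(classes)), classes)
  }
  cfg <- list(assay = assay,
              classes = classes,
              nFeaturesPerClass = as.integer(nFeaturesPerClass),
              classYield = classYield,
              baseLog10Range = as.numeric(baseLog10Range),
              noiseCv = as.numeric(noiseCv),
              detectionLimit = as.numeric(detectionLimit),
              decayRate = decayRate,
              nReplicates = as.integer(nReplicates),
              devices = devices,
              solvents = solvents,
              seed = as.integer(seed))
  class(cfg) <- "SyntheticConfig"
  .validateConfig(cfg)
  cfg
}

.validateConfig <- function(cfg) {
  with(cfg, {
    if (nFeaturesPerClass < 1L) stop("nFeaturesPerClass must be >= 1", call. = FALSE)
    if (noiseCv < 0) stop("noiseCv must be >= 0", call. = FALSE)
    if (detectionLimit < 0) stop("detectionLimit must be >= 0", call. = FALSE)
    if (length(baseLog10Range) != 2L || baseLog10Range[1] > baseLog10Range[2])
      stop("baseLog10Range must be an increasing pair", call. = FALSE)
    if (any(classYield$yield < 0 | classYield$yield > 1))
      stop("class yields must lie in [0, 1]", call. = FALSE)
    if (any(decayRate < 0 | decayRate >= 1))
      stop("decay rates must lie in [0, 1)", call. = FALSE)
    if (!all(classes %in% names(decayRate)))
      stop("decayRate must cover every compound class", call. = FALSE)
    if (nReplicates < 1L) stop("nReplicates must be >= 1", call. = FALSE)
  })
  invisible(cfg)
}

## lognormal sigma giving a target CV: cv^2 = exp(sigma^2) - 1
.sigmaFromCv <- function(cv) sqrt(log(1 + cv^2))

.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.yieldLookup <- function(classYield, classes, solvents, devices) {
  key <- paste(classYield$compound_class, classYield$solvent, classYield$device,
               sep = "\r")
  want <- expand.grid(compound_class = classes, solvent = solvents,
                      device = devices, stringsAsFactors = FALSE)
  wkey <- paste(want$compound_class, want$solvent, want$device, sep = "\r")
  idx <- match(wkey, key)
  if (anyNA(idx)) {
    miss <- want[is.na(idx), ][1, ]
    stop("classYield has no entry for (", miss$compound_class, ", ",
         miss$solvent, ", ", miss$device, ")", call. = FALSE)
  }
  stats::setNames(classYield$yield[idx], wkey)
}

## Draw base abundances (one pass over features), then one noise draw per
## cell in column-major sample order — the documented RNG consumption order.
.simulateCore <- function(cfg, sampleData, dayDecay = NULL, modeBoost = NULL) {
  classes <- cfg$classes
  nf <- cfg$nFeaturesPerClass * length(classes)
  featureData <- data.frame(
    feature_id = sprintf("%s_F%03d", substr(cfg$assay, 1, 3), seq_len(nf)),
    assay = cfg$assay,
    compound_class = rep(classes, each = cfg$nFeaturesPerClass),
    stringsAsFactors = FALSE)
  yield <- .yieldLookup(cfg$classYield, classes,
                        unique(sampleData$solvent), unique(sampleData$device))
  sigma <- .sigmaFromCv(cfg$noiseCv)

  .withSeed(cfg$seed, {
    base <- 10^stats::runif(nf, cfg$baseLog10Range[1], cfg$baseLog10Range[2])
    ns <- nrow(sampleData)
    eps <- if (sigma > 0) matrix(exp(stats::rnorm(nf * ns, 0, sigma)), nf, ns)
           else matrix(1, nf, ns)
    expected <- matrix(0, nf, ns)
    for (j in seq_len(ns)) {
      k <- paste(featureData$compound_class, sampleData$solvent[j],
                 sampleData$device[j], sep = "\r")
      mu <- base * yield[k]
      if (!is.null(dayDecay))
        mu <- mu * (1 - cfg$decayRate[featureData$compound_class])^sampleData$day[j]
      if (!is.null(modeBoost) && sampleData$extraction_mode[j] == "consecutive")
        mu <- mu * modeBoost[featureData$compound_class]
      expected[, j] <- mu
    }
    m <- expected * eps
    m[m < cfg$detectionLimit] <- 0
    x <- SpotExperiment(m, featureData = featureData, sampleData = sampleData)
    truth <- list(baseIntensity = stats::setNames(base, featureData$feature_id),
                  expected = `dimnames<-`(expected, dimnames(assay(x, "intensity"))),
                  classYield = cfg$classYield,
                  decayRate = cfg$decayRate,
                  noiseCv = cfg$noiseCv,
                  seed = cfg$seed)
    list(table = x, truth = truth)
  })
}

#' Simulate the extraction-solvent screening experiment
#'
#' One sample per (device, solvent, replicate) at day 0, single extraction:
#' the design used to screen five extraction solvents in triplicate on each
#' microsampling device. Per-cell intensity is
#' base_f x yield(class, solvent, device) x LN(0, sigma) with
#' sigma = sqrt(ln(1 + noiseCv^2)); values below the detection limit become
#' 0. Deterministic for a fixed config.
#'
#' @param config A [syntheticConfig()].
#' @return `list(table = SpotExperiment, truth = list)`; `truth` carries the
#'   realized base intensities, the noise-free expected matrix, the yield
#'   and decay maps and the seed — enough to recompute every cell's
#'   expectation.
#' @export
simulateExtractionExperiment <- function(config) {
  .validateConfig(config)
  grid <- expand.grid(replicate = seq_len(config$nReplicates),
                      solvent = config$solvents, device = config$devices,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  sampleData <- data.frame(
    sample_id = sprintf("%s_%s_R%d", substr(grid$device, 1, 3), grid$solvent,
                        grid$replicate),
    device = grid$device, solvent = grid$solvent, replicate = grid$replicate,
    day = 0L, assay = config$assay, extraction_mode = "single",
    stringsAsFactors = FALSE)
  .simulateCore(config, sampleData)
}

#' Simulate the short-term room-temperature stability series
#'
#' Spots stored at room temperature for 0–5 days before freezing, extracted
#' with pure methanol: expected intensity at day t is the day-0 expectation
#' times (1 - decayRate_class)^t (geometric per-day loss), with the same
#' multiplicative noise as the extraction experiment. Day 0 (immediate
#' freeze) is the baseline and must be present.
#'
#' @param config A [syntheticConfig()]; `config$solvents[1]` is the
#'   extraction solvent used for the whole series.
#' @param days Integer storage days, must include 0.
#' @return `list(table, truth)` as in [simulateExtractionExperiment()].
#' @export
simulateStabilitySeries <- function(config, days = 0:5) {
  .validateConfig(config)
  days <- as.integer(days)
  if (!0L %in% days)
    stop("days must include 0 (the baseline is required)", call. = FALSE)
  solvent <- config$solvents[1]
  grid <- expand.grid(replicate = seq_len(config$nReplicates), day = days,
                      device = config$devices,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  sampleData <- data.frame(
    sample_id = sprintf("%s_D%d_R%d", substr(grid$device, 1, 3), grid$day,
                        grid$replicate),
    device = grid$device, solvent = solvent, replicate = grid$replicate,
    day = grid$day, assay = config$assay, extraction_mode = "single",
    stringsAsFactors = FALSE)
  .simulateCore(config, sampleData, dayDecay = TRUE)
}

#' Simulate paired single versus consecutive extraction
#'
#' Emulates the two-step protocol comparison: per device, `nReplicates`
#' spots extracted once with pure methanol and `nReplicates` spots given an
#' additional water extraction, pooled to improve polar-metabolite coverage.
#' The expected intensity of a consecutive sample is the single-extraction
#' expectation times `boost[class]` (>= 1; the design only models gains).
#'
#' @param config A [syntheticConfig()]; `config$solvents[1]` is the base
#'   solvent.
#' @param boost Named multiplicative gain per compound class (>= 1), or an
#'   unnamed scalar recycled to all classes. Default 1 (null comparison).
#' @return `list(table, truth)`; the table holds both extraction modes and
#'   can be split by `colData(x)$extraction_mode` for [volcanoCompare()].
#' @export
simulateConsecutivePair <- function(config, boost = 1) {
  .validateConfig(config)
  if (is.null(names(boost))) {
    stopifnot(length(boost) == 1L)
    boost <- stats::setNames(rep(boost, length(config$classes)), config$classes)
  }
  if (!all(config$classes %in% names(boost)))
    stop("boost must cover every compound class", call. = FALSE)
  if (any(boost < 1))
    stop("boost must be >= 1 for every class", call. = FALSE)
  solvent <- config$solvents[1]
  grid <- expand.grid(replicate = seq_len(config$nReplicates),
                      extraction_mode = .MODES, device = config$devices,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  sampleData <- data.frame(
    sample_id = sprintf("%s_%s_R%d", substr(grid$device, 1, 3),
                        substr(grid$extraction_mode, 1, 4), grid$replicate),
    device = grid$device, solvent = solvent, replicate = grid$replicate,
    day = 0L, assay = config$assay, extraction_mode = grid$extraction_mode,
    stringsAsFactors = FALSE)
  .simulateCore(config, sampleData, modeBoost = boost)
}
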