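## Core S4 classes shared by all pipeline stages.

## Host groups that are relevant for the host-restriction designation:
## the four wild-ape species plus humans (either lifestyle). Captive apes
## never contribute to the designation.
.WILD_APES <- c("bonobo", "chimpanzee", "gorilla", "orangutan")
.HOST_GROUPS <- c(.WILD_APES, "human")
.APE_LIFESTYLES <- c("wild", "captive")
.HUMAN_LIFESTYLES <- c("industrialized", "non_industrialized")
.LIFESTYLES <- c(.APE_LIFESTYLES, .HUMAN_LIFESTYLES)
.CATEGORIES <- c("host_restricted", "mixed_host", "unique_to_captive")
.SAMPLE_COLUMNS <- c("sample_id", "host_species", "lifestyle", "site",
                     "enclosure", "study")

#' Analysis configuration
#'
#' Thresholds and permutation settings used across the pipeline. Defaults
#' follow the study design this package models: clades must have bootstrap
#' support strictly greater than 50 (on a 0--100 scale) and be present in at
#' least 5 individuals; prominence requires presence in more than 25% of the
#' individuals of at least one sample group; permutation nulls use 999
#' permutations.
#'
#' @slot minSupport numeric, support threshold (strict `>`), 0--100 scale.
#' @slot minIndividuals integer, minimum number of distinct samples in which a
#'   clade's members must occur.
#' @slot prevalenceThreshold numeric in (0, 1], prominence cut-off (strict `>`).
#' @slot nPermutations integer, number of permutations for empirical p-values.
#' @slot curveballTrials integer, number of curveball trades per matrix
#'   permutation; `NA` means the default `5 * nrow(matrix)`.
#'
#' @export
setClass("AnalysisConfig",
  representation(
    minSupport = "numeric",
    minIndividuals = "integer",
    prevalenceThreshold = "numeric",
    nPermutations = "integer",
    curveballTrials = "integer"
  ),
  prototype(
    minSupport = 50,
    minIndividuals = 5L,
    prevalenceThreshold = 0.25,
    nPermutations = 999L,
    curveballTrials = NA_integer_
  )
)

setValidity("AnalysisConfig", function(object) {
  msg <- character(0)
  if (length(object@minSupport) != 1L || is.na(object@minSupport) ||
      object@minSupport < 0 || object@minSupport > 100)
    msg <- c(msg, "'minSupport' must be a single value in [0, 100]")
  if (length(object@minIndividuals) != 1L || is.na(object@minIndividuals) ||
      object@minIndividuals < 1L)
    msg <- c(msg, "'minIndividuals' must be a single integer >= 1")
  if (length(object@prevalenceThreshold) != 1L ||
      is.na(object@prevalenceThreshold) ||
      object@prevalenceThreshold <= 0 || object@prevalenceThreshold > 1)
    msg <- c(msg, "'prevalenceThreshold' must be in (0, 1]")
  if (length(object@nPermutations) != 1L || is.na(object@nPermutations) ||
      object@nPermutations < 1L)
    msg <- c(msg, "'nPermutations' must be a single integer >= 1")
  if (length(object@curveballTrials) != 1L ||
      (!is.na(object@curveballTrials) && object@curveballTrials < 1L))
    msg <- c(msg, "'curveballTrials' must be NA or a single integer >= 1")
  if (length(msg)) msg else TRUE
})

#' @param minSupport,minIndividuals,prevalenceThreshold,nPermutations,curveballTrials
#'   see the corresponding slots.
#' @return `analysisConfig()` returns an `AnalysisConfig` object.
#' @rdname AnalysisConfig-class
#' @examples
#' analysisConfig(minIndividuals = 1, nPermutations = 199)
#' @export
analysisConfig <- function(minSupport = 50, minIndividuals = 5L,
                           prevalenceThreshold = 0.25, nPermutations = 999L,
                           curveballTrials = NA) {
  new("AnalysisConfig",
      minSupport = as.numeric(minSupport),
      minIndividuals = as.integer(minIndividuals),
      prevalenceThreshold = as.numeric(prevalenceThreshold),
      nPermutations = as.integer(nPermutations),
      curveballTrials = as.integer(curveballTrials))
}

setMethod("show", "AnalysisConfig", function(object) {
  cat("AnalysisConfig\n",
      "  support > ", object@minSupport,
      ", individuals >= ", object@minIndividuals,
      ", prevalence > ", object@prevalenceThreshold, "\n",
      "  permutations: ", object@nPermutations,
      ", curveball trades: ",
      if (is.na(object@curveballTrials)) "5 x nrow" else object@curveballTrials,
      "\n", sep = "")
})

#' Binary ASV-by-sample incidence experiment
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding one assay named
#' `"incidence"`: a binary (0/1) matrix with ASVs as rows and samples as
#' columns, plus per-sample metadata in `colData` (`host_species`, `lifestyle`,
#' `site`, `enclosure`, `study`). Validity enforces: binary entries, unique
#' non-empty row/column names, no all-zero ASV rows, legal host/lifestyle
#' combinations (apes are `wild`/`captive`, humans `industrialized`/
#' `non_industrialized`), a non-missing `site` for every captive sample, and
#' enclosures nested within a single site.
#'
#' @export
setClass("IncidenceExperiment", contains = "SummarizedExperiment")

setValidity("IncidenceExperiment", function(object) {
  msg <- character(0)
  if (!"incidence" %in% SummarizedExperiment::assayNames(object))
    return("assay 'incidence' is missing")
  m <- SummarizedExperiment::assay(object, "incidence")
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)) ||
      any(!nzchar(rownames(m))))
    msg <- c(msg, "ASV row names must be unique and non-empty")
  if (is.null(colnames(m)) || anyDuplicated(colnames(m)) ||
      any(!nzchar(colnames(m))))
    msg <- c(msg, "sample column names must be unique and non-empty")
  if (!is.numeric(m) || anyNA(m) || !all(m %in% c(0, 1)))
    msg <- c(msg, "incidence entries must be 0/1 with no missing values")
  else if (nrow(m) > 0L) {
    zero <- rownames(m)[rowSums(m) == 0]
    if (length(zero))
      msg <- c(msg, paste0("ASV rows with no presence: ",
                           paste(utils::head(zero, 5L), collapse = ", ")))
  }
  cd <- SummarizedExperiment::colData(object)
  need <- setdiff(c("host_species", "lifestyle", "site", "enclosure", "study"),
                  colnames(cd))
  if (length(need))
    return(c(msg, paste0("missing sample columns: ",
                         paste(need, collapse = ", "))))
  sp <- as.character(cd$host_species)
  lf <- as.character(cd$lifestyle)
  if (!all(sp %in% .HOST_GROUPS))
    msg <- c(msg, paste0("unknown host_species: ",
                         paste(unique(setdiff(sp, .HOST_GROUPS)), collapse = ", ")))
  if (!all(lf %in% .LIFESTYLES))
    msg <- c(msg, paste0("unknown lifestyle: ",
                         paste(unique(setdiff(lf, .LIFESTYLES)), collapse = ", ")))
  bad <- (sp == "human" & !lf %in% .HUMAN_LIFESTYLES) |
    (sp %in% .WILD_APES & !lf %in% .APE_LIFESTYLES)
  if (any(bad, na.rm = TRUE))
    msg <- c(msg, paste0("illegal host/lifestyle combination for sample(s): ",
                         paste(utils::head(rownames(cd)[bad], 5L), collapse = ", ")))
  cap <- lf == "captive"
  if (any(cap & is.na(cd$site)))
    msg <- c(msg, paste0("captive sample(s) without a site: ",
                         paste(utils::head(rownames(cd)[cap & is.na(cd$site)], 5L),
                               collapse = ", ")))
  has.enc <- !is.na(cd$enclosure)
  if (any(has.enc)) {
    map <- unique(data.frame(enclosure = as.character(cd$enclosure[has.enc]),
                             site = as.character(cd$site[has.enc])))
    if (anyDuplicated(map$enclosure))
      msg <- c(msg, "an enclosure maps to more than one site")
    if (anyNA(map$site))
      msg <- c(msg, "enclosure present without a site")
  }
  if (length(msg)) msg else TRUE
})

#' @param incidence numeric matrix, ASVs x samples; entries are binarized as
#'   `value > 0` (counts are accepted and coerced to presence/absence).
#' @param samples `data.frame` or `DataFrame` of sample metadata with columns
#'   `sample_id`, `host_species`, `lifestyle`, `site`, `enclosure`, `study`
#'   (or row names in place of `sample_id`). May contain extra samples; it is
#'   matched to the incidence columns and must cover all of them.
#' @return `IncidenceExperiment()` returns an `IncidenceExperiment`.
#' @rdname IncidenceExperiment-class
#' @export
IncidenceExperiment <- function(incidence, samples) {
  if (!is.matrix(incidence) || !is.numeric(incidence))
    stop("'incidence' must be a numeric matrix")
  if (anyNA(incidence) || any(incidence < 0))
    stop("'incidence' must be non-negative with no missing values")
  storage.mode(incidence) <- "integer"
  incidence[incidence > 0L] <- 1L
  samples <- as.data.frame(samples)
  if ("sample_id" %in% colnames(samples)) {
    if (anyDuplicated(samples$sample_id))
      stop("duplicated sample_id in 'samples'")
    rownames(samples) <- samples$sample_id
  }
  miss <- setdiff(colnames(incidence), rownames(samples))
  if (length(miss))
    stop("samples missing metadata: ", paste(utils::head(miss, 5L), collapse = ", "))
  samples <- samples[colnames(incidence), , drop = FALSE]
  keep <- setdiff(c("host_species", "lifestyle", "site", "enclosure", "study"),
                  colnames(samples))
  if (length(keep))
    stop("metadata lacks required column(s): ", paste(keep, collapse = ", "))
  cd <- S4Vectors::DataFrame(samples[, c("host_species", "lifestyle", "site",
                                         "enclosure", "study"), drop = FALSE])
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(incidence = incidence), colData = cd)
  new("IncidenceExperiment", se)
}

setMethod("show", "IncidenceExperiment", function(object) {
  cd <- SummarizedExperiment::colData(object)
  grp <- table(paste(cd$lifestyle, cd$host_species, sep = "_"))
  cat("IncidenceExperiment: ", nrow(object), " ASVs x ", ncol(object),
      " samples\n", sep = "")
  cat("  sample groups: ",
      paste(names(grp), grp, sep = "=", collapse = ", "), "\n", sep = "")
})

#' Set of detected monophyletic clades
#'
#' Result container for [findMaximalClades()]. Holds one row per accepted
#' clade (id, category, host species for host-restricted clades, bootstrap
#' support of the subtending node, number of member ASVs, number of distinct
#' individuals carrying any member), the member ASV sets, and a clade-by-group
#' prevalence matrix (fraction of each sample group's individuals harboring at
#' least one member ASV).
#'
#' @slot clades `data.frame` with columns `clade_id`, `category`,
#'   `host_species`, `support`, `n_asvs`, `n_individuals`.
#' @slot members named `list` of character vectors (member ASV ids), parallel
#'   to `clades`.
#' @slot prevalence numeric matrix, clades x sample groups, values in [0, 1].
#' @slot config the `AnalysisConfig` used for detection.
#'
#' @export
setClass("CladeSet",
  representation(clades = "data.frame", members = "list",
                 prevalence = "matrix", config = "AnalysisConfig"))

setValidity("CladeSet", function(object) {
  msg <- character(0)
  n <- nrow(object@clades)
  need <- c("clade_id", "category", "host_species", "support", "n_asvs",
            "n_individuals")
  if (!all(need %in% colnames(object@clades)))
    return("clade table lacks required columns")
  if (length(object@members) != n)
    msg <- c(msg, "'members' length must match clade table rows")
  if (n && !identical(names(object@members), object@clades$clade_id))
    msg <- c(msg, "'members' names must equal clade_id")
  if (n && anyDuplicated(unlist(object@members)))
    msg <- c(msg, "clades must have pairwise disjoint member sets")
  if (n && nrow(object@prevalence) != n)
    msg <- c(msg, "'prevalence' rows must match clade table rows")
  if (length(object@prevalence) &&
      any(object@prevalence < 0 | object@prevalence > 1, na.rm = TRUE))
    msg <- c(msg, "prevalence values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CladeSet", function(object) {
  tab <- table(factor(object@clades$category, levels = .CATEGORIES))
  cat("CladeSet with ", nrow(object@clades), " clades (",
      paste(names(tab), tab, sep = "=", collapse = ", "), ")\n", sep = "")
  if (nrow(object@clades))
    print(utils::head(object@clades, 5L), row.names = FALSE)
})

#' @param x a `CladeSet`.
#' @rdname CladeSet-class
#' @export
setMethod("length", "CladeSet", function(x) nrow(x@clades))

#' Clade-size calibration against the fixed-margins null
#'
#' Result of [cladeSizeNull()]: per-permutation summaries of the
#' host-restricted clade scan re-run on curveball-permuted incidence matrices,
#' and the add-one empirical p-value for each observed host-restricted clade
#' size (probability, under the fixed-margins null, of a permuted maximum
#' clade size at least as large).
#'
#' @slot nPermutations integer.
#' @slot permMaxSize numeric, maximum host-restricted clade size per
#'   permutation (0 when none detected).
#' @slot permNClades numeric, number of accepted host-restricted clades per
#'   permutation.
#' @slot observedSizes numeric, distinct observed host-restricted clade sizes.
#' @slot empiricalP named numeric, add-one empirical p per observed size.
#' @slot observedMaxSize numeric, observed maximum host-restricted clade size.
#'
#' @export
setClass("CladeSizeNull",
  representation(nPermutations = "integer", permMaxSize = "numeric",
                 permNClades = "numeric", observedSizes = "numeric",
                 empiricalP = "numeric", observedMaxSize = "numeric"))

setValidity("CladeSizeNull", function(object) {
  msg <- character(0)
  if (length(object@permMaxSize) != object@nPermutations ||
      length(object@permNClades) != object@nPermutations)
    msg <- c(msg, "per-permutation summaries must have length nPermutations")
  if (length(object@empiricalP) &&
      any(object@empiricalP <= 0 | object@empiricalP > 1))
    msg <- c(msg, "empirical p-values must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CladeSizeNull", function(object) {
  cat("CladeSizeNull: ", object@nPermutations, " fixed-margins permutations\n",
      "  observed max host-restricted clade size: ", object@observedMaxSize,
      " (null max: ", max(object@permMaxSize), ")\n", sep = "")
  if (length(object@empiricalP)) {
    cat("  empirical p by observed clade size:\n")
    print(object@empiricalP)
  }
})

#' Co-diversification test result
#'
#' Common container for [hommolaTest()], [parafitGlobal()] and [pacoTest()].
#' `direction` records the tail of the permutation test: `"ge"` (large
#' statistic = congruence; Hommola r, ParaFitGlobal) or `"le"` (small
#' statistic = congruence; PACo residual m2).
#'
#' @slot test character, one of `"hommola"`, `"parafit"`, `"paco"`.
#' @slot statistic numeric, the observed statistic (`NA` when degenerate).
#' @slot nullValues numeric, the permutation null distribution.
#' @slot p numeric in (0, 1], add-one empirical p-value.
#' @slot direction character, `"ge"` or `"le"`.
#' @slot degenerate logical, `TRUE` when the statistic was undefined (e.g.
#'   zero variance in a distance vector); then `p` is reported as 1.
#' @slot nPermutations integer.
#'
#' @export
setClass("CospeciationResult",
  representation(test = "character", statistic = "numeric",
                 nullValues = "numeric", p = "numeric", direction = "character",
                 degenerate = "logical", nPermutations = "integer"))

setValidity("CospeciationResult", function(object) {
  msg <- character(0)
  if (!object@test %in% c("hommola", "parafit", "paco"))
    msg <- c(msg, "unknown test")
  if (!object@direction %in% c("ge", "le"))
    msg <- c(msg, "direction must be 'ge' or 'le'")
  if (length(object@p) != 1L || object@p <= 0 || object@p > 1)
    msg <- c(msg, "p must be a single value in (0, 1]")
  if (!object@degenerate && !is.finite(object@statistic))
    msg <- c(msg, "statistic must be finite unless degenerate")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CospeciationResult", function(object) {
  cat("CospeciationResult [", object@test, "]\n",
      "  statistic = ", format(object@statistic, digits = 6),
      ", p = ", format(object@p, digits = 4),
      " (", object@nPermutations, " permutations, tail '", object@direction,
      "')", if (object@degenerate) "  [degenerate]", "\n", sep = "")
})

#' Synthetic-data scenario configuration
#'
#' Parameters of the generative scenarios used to exercise the pipeline:
#' `codiversification` (symbiont backbone mirrors the host phylogeny, one
#' within-host radiation per host per backbone copy), `host_switch`
#' (host-restricted radiations attached at random tree positions with hosts
#' drawn independently of position), `filtering` (host labels i.i.d. across
#' tips, no clade structure), and `captive_mixing` (adds captive groups whose
#' individuals acquire human-origin ASVs).
#'
#' @slot scenario character, one of the four scenario names.
#' @slot nIndividualsPerGroup integer, samples per host group (default 20).
#' @slot nCladesPerHost integer, planted radiations per host group (default 3).
#' @slot asvsPerClade integer, ASV tips per planted radiation (default 4).
#' @slot withinHostPrevalence numeric in (0, 1], probability that an ASV is
#'   present in an individual of its generating host group (default 0.6).
#' @slot crossColonizationRate numeric in [0, 1), probability of presence in
#'   an individual of any other wild/human group (default 0).
#' @slot captiveHumanAcquisition numeric in [0, 1], probability that a captive
#'   individual carries a given human-origin ASV (default 0.8);
#'   conspecific wild ASVs are carried with probability
#'   `withinHostPrevalence * (1 - captiveHumanAcquisition)`.
#' @slot divergenceTimes named numeric, host split times in Myr along the
#'   human lineage: `chimpanzee_bonobo`, `human`, `gorilla`, `orangutan`.
#' @slot supportDistribution character: `"high"` draws supports in
#'   U\[80, 100\] on planted-radiation nodes and U\[0, 100\] elsewhere;
#'   `"noise"` draws U\[0, 100\] everywhere.
#' @slot rngSeed integer seed applied by [simulateScenario()] (`NA` = leave
#'   the session RNG untouched).
#'
#' @export
setClass("ScenarioConfig",
  representation(scenario = "character", nIndividualsPerGroup = "integer",
                 nCladesPerHost = "integer", asvsPerClade = "integer",
                 withinHostPrevalence = "numeric",
                 crossColonizationRate = "numeric",
                 captiveHumanAcquisition = "numeric",
                 divergenceTimes = "numeric", supportDistribution = "character",
                 rngSeed = "integer"),
  prototype(scenario = "codiversification", nIndividualsPerGroup = 20L,
            nCladesPerHost = 3L, asvsPerClade = 4L,
            withinHostPrevalence = 0.6, crossColonizationRate = 0,
            captiveHumanAcquisition = 0.8,
            divergenceTimes = c(chimpanzee_bonobo = 1.8, human = 6.4,
                                gorilla = 8.6, orangutan = 15.2),
            supportDistribution = "high", rngSeed = NA_integer_))

setValidity("ScenarioConfig", function(object) {
  msg <- character(0)
  if (!object@scenario %in% c("codiversification", "host_switch", "filtering",
                              "captive_mixing"))
    msg <- c(msg, "unknown scenario")
  if (object@nIndividualsPerGroup < 1L)
    msg <- c(msg, "nIndividualsPerGroup must be >= 1")
  if (object@nCladesPerHost < 1L)
    msg <- c(msg, "nCladesPerHost must be >= 1")
  if (object@asvsPerClade < 2L)
    msg <- c(msg, "asvsPerClade must be >= 2 (clades need >= 2 tips)")
  if (object@withinHostPrevalence <= 0 || object@withinHostPrevalence > 1)
    msg <- c(msg, "withinHostPrevalence must be in (0, 1]")
  if (object@crossColonizationRate < 0 || object@crossColonizationRate >= 1)
    msg <- c(msg, "crossColonizationRate must be in [0, 1)")
  if (object@captiveHumanAcquisition < 0 || object@captiveHumanAcquisition > 1)
    msg <- c(msg, "captiveHumanAcquisition must be in [0, 1]")
  need <- c("chimpanzee_bonobo", "human", "gorilla", "orangutan")
  if (!all(need %in% names(object@divergenceTimes)))
    msg <- c(msg, "divergenceTimes must name chimpanzee_bonobo, human, gorilla, orangutan")
  else {
    tt <- object@divergenceTimes[need]
    if (any(tt <= 0)) msg <- c(msg, "divergence times must be positive")
    if (any(diff(tt) <= 0))
      msg <- c(msg, "divergence times must be strictly nested (chimpanzee_bonobo < human < gorilla < orangutan)")
  }
  if (!object@supportDistribution %in% c("high", "noise"))
    msg <- c(msg, "supportDistribution must be 'high' or 'noise'")
  if (length(msg)) msg else TRUE
})

#' @param scenario,nIndividualsPerGroup,nCladesPerHost,asvsPerClade see slots.
#' @param withinHostPrevalence,crossColonizationRate,captiveHumanAcquisition
#'   see slots.
#' @param divergenceTimes,supportDistribution,rngSeed see slots.
#' @return `scenarioConfig()` returns a `ScenarioConfig` object.
#' @rdname ScenarioConfig-class
#' @examples
#' scenarioConfig("host_switch", nCladesPerHost = 10, rngSeed = 1)
#' @export
scenarioConfig <- function(scenario = c("codiversification", "host_switch",
                                        "filtering", "captive_mixing"),
                           nIndividualsPerGroup = 20L, nCladesPerHost = 3L,
                           asvsPerClade = 4L, withinHostPrevalence = 0.6,
                           crossColonizationRate = 0,
                           captiveHumanAcquisition = 0.8,
                           divergenceTimes = c(chimpanzee_bonobo = 1.8,
                                               human = 6.4, gorilla = 8.6,
                                               orangutan = 15.2),
                           supportDistribution = c("high", "noise"),
                           rngSeed = NA) {
  new("ScenarioConfig",
      scenario = match.arg(scenario),
      nIndividualsPerGroup = as.integer(nIndividualsPerGroup),
      nCladesPerHost = as.integer(nCladesPerHost),
      asvsPerClade = as.integer(asvsPerClade),
      withinHostPrevalence = as.numeric(withinHostPrevalence),
      crossColonizationRate = as.numeric(crossColonizationRate),
      captiveHumanAcquisition = as.numeric(captiveHumanAcquisition),
      divergenceTimes = divergenceTimes,
      supportDistribution = match.arg(supportDistribution),
      rngSeed = as.integer(rngSeed))
}

setMethod("show", "ScenarioConfig", function(object) {
  cat("ScenarioConfig [", object@scenario, "]\n",
      "  ", object@nCladesPerHost, " clades/host x ", object@asvsPerClade,
      " ASVs/clade, ", object@nIndividualsPerGroup, " individuals/group\n",
      "  pi = ", object@withinHostPrevalence,
      ", epsilon = ", object@crossColonizationRate,
      ", rho = ", object@captiveHumanAcquisition, "\n", sep = "")
})
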