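## Synthetic host trees, symbiont trees, incidence matrices and metadata with
## planted statistical structure, so every pipeline stage is testable without
## external sequence data.

## depths in arbitrary substitution units: planted within-host radiations are
## shallow (strain-level variation); the backbone connecting independent
## lineages is deep, with long pendant stems so that inter-lineage distances
## are large and mutually comparable (amplicon distances between lineages of
## an order-level phylogeny are near-saturated)
.RADIATION_DEPTH <- 0.05
.BACKBONE_DEPTH <- 0.5
.HS_BACKBONE_DEPTH <- 0.1
.HS_STEM_LENGTH <- 0.45

#' Simulate the great-ape + human host phylogeny
#'
#' Builds the fixed hominid topology
#' `((((bonobo,chimpanzee),human),gorilla),orangutan)` with the configured
#' divergence times (Myr); the result is ultrametric with root age equal to
#' the deepest split.
#'
#' @param config a [ScenarioConfig]; only `divergenceTimes` is used.
#' @return an `ape::phylo` with 5 tips.
#' @examples
#' simulateHostTree(scenarioConfig())
#' @export
simulateHostTree <- function(config = scenarioConfig()) {
  stopifnot(is(config, "ScenarioConfig"))
  tt <- config@divergenceTimes
  t1 <- tt[["chimpanzee_bonobo"]]; t2 <- tt[["human"]]
  t3 <- tt[["gorilla"]]; t4 <- tt[["orangutan"]]
  nwk <- sprintf(
    "((((bonobo:%.10g,chimpanzee:%.10g):%.10g,human:%.10g):%.10g,gorilla:%.10g):%.10g,orangutan:%.10g);",
    t1, t1, t2 - t1, t2, t3 - t2, t3, t4 - t3, t4)
  readNewickTree(text = nwk, kind = "host")
}

## newick fragment (no branch length, no trailing ';') for a random
## coalescent radiation over the given tip ids, rescaled to the given depth;
## callers append ":<length>" to graft it
.subtreeNewick <- function(ids, depth) {
  n <- length(ids)
  if (n == 1L) return(ids)
  tr <- ape::rcoal(n, tip.label = ids)
  tr$edge.length <- tr$edge.length * depth / max(ape::node.depth.edgelength(tr))
  sub(";$", "", ape::write.tree(tr))
}

## mirror of the fixed host topology with tips replaced by newick fragments;
## branch lengths are host divergence times rescaled into substitution units
.mirrorNewick <- function(frag, tt, scale = .BACKBONE_DEPTH / 15.2) {
  t1 <- tt[["chimpanzee_bonobo"]] * scale; t2 <- tt[["human"]] * scale
  t3 <- tt[["gorilla"]] * scale; t4 <- tt[["orangutan"]] * scale
  sprintf("((((%s:%.10g,%s:%.10g):%.10g,%s:%.10g):%.10g,%s:%.10g):%.10g,%s:%.10g)",
          frag[["bonobo"]], t1, frag[["chimpanzee"]], t1, t2 - t1,
          frag[["human"]], t2, t3 - t2, frag[["gorilla"]], t3, t4 - t3,
          frag[["orangutan"]], t4)
}

#' Simulate a symbiont phylogeny with planted host structure
#'
#' Three generative regimes. `codiversification`: the symbiont backbone
#' mirrors the host topology (repeated `nCladesPerHost` times, like ancient
#' gene duplicates), each host tip subtending a within-host radiation of
#' `asvsPerClade` ASVs -- host-restricted and topologically concordant.
#' `host_switch`: the same `nCladesPerHost x 5` radiations hang off a random
#' backbone, with the generating host drawn independently of position --
#' host-restricted but discordant. `filtering`: host labels are assigned
#' i.i.d. across the tips of a random tree -- no clade structure at all.
#' `captive_mixing` reuses the codiversification tree (the mixing happens in
#' the incidence step). Bootstrap supports are simulated, not estimated: with
#' `supportDistribution = "high"`, nodes inside planted radiations draw
#' U\[80, 100\] and all other nodes U\[0, 100\].
#'
#' @param config a [ScenarioConfig].
#' @return list with `tree` (`ape::phylo`) and `truth`, a `data.frame` with
#'   columns `asv_id`, `host`, `clade_id` (`NA` under `filtering`).
#' @export
simulateSymbiontTree <- function(config = scenarioConfig()) {
  stopifnot(is(config, "ScenarioConfig"))
  hosts <- .HOST_GROUPS
  nC <- config@nCladesPerHost
  nA <- config@asvsPerClade

  if (config@scenario == "filtering") {
    n <- length(hosts) * nC * nA
    ids <- sprintf("asv%04d", seq_len(n))
    tr <- ape::rcoal(n, tip.label = ids)
    tr$edge.length <- tr$edge.length *
      .BACKBONE_DEPTH / max(ape::node.depth.edgelength(tr))
    truth <- data.frame(asv_id = ids,
                        host = sample(hosts, n, replace = TRUE),
                        clade_id = NA_character_, stringsAsFactors = FALSE)
    tr$node.label <- formatC(stats::runif(tr$Nnode, 0, 100),
                             format = "f", digits = 1)
    return(list(tree = tr, truth = truth))
  }

  cladeHost <- if (config@scenario == "host_switch")
    sample(rep(hosts, each = nC)) # host drawn independently of position
  else rep(hosts, times = nC)     # copy-major order: mirrors host topology
  cladeId <- sprintf("%s_c%02d", cladeHost,
                     as.integer(stats::ave(seq_along(cladeHost), cladeHost,
                                           FUN = seq_along)))
  memberIds <- lapply(seq_along(cladeId), function(k)
    sprintf("%s_a%02d", cladeId[k], seq_len(nA)))

  if (config@scenario == "host_switch") {
    nS <- length(cladeId)
    slots <- sprintf("SLOT%04d", seq_len(nS))
    bb <- ape::rcoal(nS, tip.label = slots)
    bb$edge.length <- bb$edge.length *
      .HS_BACKBONE_DEPTH / max(ape::node.depth.edgelength(bb))
    tipEdge <- match(seq_len(nS), bb$edge[, 2L])
    bb$edge.length[tipEdge] <- bb$edge.length[tipEdge] + .HS_STEM_LENGTH
    nwk <- ape::write.tree(bb)
    for (k in seq_len(nS))
      nwk <- sub(paste0(slots[k], ":"),
                 paste0(.subtreeNewick(memberIds[[k]], .RADIATION_DEPTH), ":"),
                 nwk, fixed = TRUE)
  } else {
    copyOf <- (seq_along(cladeId) - 1L) %/% length(hosts) + 1L
    copies <- vapply(seq_len(nC), function(cp) {
      sel <- which(copyOf == cp)
      frag <- vapply(sel, function(k)
        .subtreeNewick(memberIds[[k]], .RADIATION_DEPTH), character(1L))
      names(frag) <- cladeHost[sel]
      .mirrorNewick(frag, config@divergenceTimes)
    }, character(1L))
    nwk <- if (nC == 1L) paste0(copies, ";")
    else paste0("(", paste0(copies, ":0.1", collapse = ","), ");")
  }
  tr <- ape::read.tree(text = nwk)

  ## supports: noise everywhere, then high on planted-radiation nodes
  sup <- stats::runif(tr$Nnode, 0, 100)
  if (config@supportDistribution == "high") {
    idx <- .treeIndex(tr)
    tipClade <- rep(NA_character_, idx$ntip)
    for (k in seq_along(cladeId))
      tipClade[match(memberIds[[k]], tr$tip.label)] <- cladeId[k]
    for (nd in (idx$ntip + 1L):(idx$ntip + idx$nnode)) {
      cl <- unique(tipClade[idx$tips[[nd]]])
      if (length(cl) == 1L && !is.na(cl))
        sup[nd - idx$ntip] <- stats::runif(1L, 80, 100)
    }
  }
  tr$node.label <- formatC(sup, format = "f", digits = 1)
  truth <- data.frame(asv_id = unlist(memberIds),
                      host = rep(cladeHost, each = nA),
                      clade_id = rep(cladeId, each = nA),
                      stringsAsFactors = FALSE)
  list(tree = tr, truth = truth)
}

#' Simulate an incidence matrix and sample metadata
#'
#' Each ASV is present in an individual of its generating host group with
#' probability `withinHostPrevalence` (pi) and in individuals of the other
#' wild/human groups with probability `crossColonizationRate` (epsilon).
#' Under `captive_mixing`, each ape species additionally gets a captive group
#' (split across two zoo sites with enclosures of three individuals) whose
#' individuals carry human-origin ASVs with probability
#' `captiveHumanAcquisition` (rho) and conspecific wild ASVs with probability
#' `pi * (1 - rho)`. ASVs that end up present in no sample are dropped with a
#' warning (rather than resampled, keeping draws i.i.d.-interpretable).
#'
#' @param truth `data.frame` with columns `asv_id`, `host` (the generating
#'   host per ASV), as produced by [simulateSymbiontTree()].
#' @param config a [ScenarioConfig].
#' @return list with `incidence` (binary matrix) and `samples` (metadata
#'   `data.frame`).
#' @export
simulateIncidence <- function(truth, config = scenarioConfig()) {
  stopifnot(is(config, "ScenarioConfig"))
  nInd <- config@nIndividualsPerGroup
  pi0 <- config@withinHostPrevalence
  eps <- config@crossColonizationRate
  rho <- config@captiveHumanAcquisition

  groups <- data.frame(
    species = .HOST_GROUPS,
    lifestyle = c(rep("wild", 4L), "industrialized"),
    stringsAsFactors = FALSE)
  if (config@scenario == "captive_mixing")
    groups <- rbind(groups, data.frame(species = .WILD_APES,
                                       lifestyle = "captive"))

  samples <- do.call(rbind, lapply(seq_len(nrow(groups)), function(g) {
    sp <- groups$species[g]; lf <- groups$lifestyle[g]
    id <- sprintf("%s_%s_%02d", lf, sp, seq_len(nInd))
    site <- enclosure <- rep(NA_character_, nInd)
    if (lf == "captive") {
      site <- rep(c("zoo_a", "zoo_b"), length.out = nInd)
      pos <- as.integer(stats::ave(seq_len(nInd), site, FUN = seq_along))
      enclosure <- sprintf("%s_%s_e%d", site, sp, (pos - 1L) %/% 3L + 1L)
    }
    data.frame(sample_id = id, host_species = sp, lifestyle = lf,
               site = site, enclosure = enclosure, study = "simulation",
               stringsAsFactors = FALSE)
  }))
  rownames(samples) <- samples$sample_id

  asvHost <- truth$host
  nAsv <- length(asvHost)
  prob <- matrix(0, nAsv, nrow(samples),
                 dimnames = list(truth$asv_id, samples$sample_id))
  for (g in seq_len(nrow(groups))) {
    sp <- groups$species[g]; lf <- groups$lifestyle[g]
    cols <- samples$host_species == sp & samples$lifestyle == lf
    p <- if (lf == "captive")
      ifelse(asvHost == "human", rho, ifelse(asvHost == sp, pi0 * (1 - rho), 0))
    else
      ifelse(asvHost == sp, pi0, eps)
    prob[, cols] <- p
  }
  inc <- matrix(as.integer(stats::runif(length(prob)) < prob), nAsv,
                ncol(prob), dimnames = dimnames(prob))
  zero <- rowSums(inc) == 0L
  if (any(zero)) {
    warning(sum(zero), " ASV(s) present in no sample were dropped")
    inc <- inc[!zero, , drop = FALSE]
  }
  list(incidence = inc, samples = samples)
}

#' Simulate a complete scenario
#'
#' Runs [simulateHostTree()], [simulateSymbiontTree()] and
#' [simulateIncidence()] under one configuration, prunes any dropped
#' (all-zero) ASVs from the symbiont tree and truth table, and bundles the
#' incidence and metadata into an [IncidenceExperiment]. When
#' `config@rngSeed` is not `NA` the session RNG is seeded first, making the
#' whole draw reproducible.
#'
#' @param config a [ScenarioConfig].
#' @return list with `hostTree`, `symbiontTree`, `truth`, `experiment`,
#'   `config`.
#' @examples
#' sim <- simulateScenario(scenarioConfig("codiversification", rngSeed = 1))
#' sim$experiment
#' @export
simulateScenario <- function(config = scenarioConfig()) {
  stopifnot(is(config, "ScenarioConfig"))
  if (!is.na(config@rngSeed)) set.seed(config@rngSeed)
  hostTree <- simulateHostTree(config)
  symb <- simulateSymbiontTree(config)
  sim <- simulateIncidence(symb$truth, config)
  tree <- symb$tree
  truth <- symb$truth
  dropped <- setdiff(truth$asv_id, rownames(sim$incidence))
  if (length(dropped)) {
    tree <- ape::drop.tip(tree, dropped)
    truth <- truth[!truth$asv_id %in% dropped, , drop = FALSE]
  }
  experiment <- IncidenceExperiment(sim$incidence, sim$samples)
  list(hostTree = hostTree, symbiontTree = tree, truth = truth,
       experiment = experiment, config = config)
}
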