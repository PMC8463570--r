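## Host-source classification of ASVs and extraction of maximal well-supported
## monophyletic clades of same-category ASVs.

## Designation-relevant host group per sample: each wild-ape species, plus
## humans of either lifestyle. Captive apes return NA (they never alter the
## designation).
.designationGroups <- function(samples) {
  sp <- as.character(samples$host_species)
  lf <- as.character(samples$lifestyle)
  out <- rep(NA_character_, length(sp))
  out[sp == "human"] <- "human"
  wild <- sp %in% .WILD_APES & lf == "wild"
  out[wild] <- sp[wild]
  out
}

## Sample-group label per sample, lifestyle x species; captive groups are
## optionally split by site.
.sampleGroups <- function(samples, bySite = FALSE) {
  g <- paste(as.character(samples$lifestyle),
             as.character(samples$host_species), sep = "_")
  if (bySite) {
    cap <- as.character(samples$lifestyle) == "captive"
    g[cap] <- paste(g[cap], as.character(samples$site)[cap], sep = "@")
  }
  g
}

## Classification on plain objects (matrix + data.frame); the exported method
## unwraps the IncidenceExperiment. Returns a data.frame with a list column
## `wild_profile`.
.classify <- function(inc, samples) {
  grp <- .designationGroups(samples)
  lev <- .HOST_GROUPS
  ## ASV x group presence: any sample of that designation group contains it
  prof <- vapply(lev, function(g) {
    idx <- which(!is.na(grp) & grp == g)
    if (!length(idx)) return(logical(nrow(inc)))
    rowSums(inc[, idx, drop = FALSE]) > 0L
  }, logical(nrow(inc)))
  if (nrow(inc) == 1L) prof <- matrix(prof, nrow = 1L, dimnames = list(rownames(inc), lev))
  k <- rowSums(prof)
  category <- ifelse(k == 0L, "unique_to_captive",
                     ifelse(k == 1L, "host_restricted", "mixed_host"))
  restricted <- rep(NA_character_, nrow(inc))
  one <- which(k == 1L)
  if (length(one))
    restricted[one] <- lev[apply(prof[one, , drop = FALSE], 1L, which.max)]
  profiles <- apply(prof, 1L, function(z) lev[z], simplify = FALSE)
  data.frame(asv_id = rownames(inc), category = category,
             restricted_host = restricted,
             wild_profile = I(unname(profiles)),
             row.names = rownames(inc), stringsAsFactors = FALSE)
}

#' Classify ASVs by host-source pattern
#'
#' For each ASV, the wild profile is the set of designation-relevant host
#' groups (each wild-ape species, plus humans of either lifestyle) whose
#' samples contain the ASV. A profile of size one makes the ASV
#' `host_restricted` to that group, size two or more `mixed_host`, and an
#' empty profile (the ASV occurs only in captive apes) `unique_to_captive`.
#' Occurrences in captive apes never alter the designation.
#'
#' @param experiment an [IncidenceExperiment].
#' @param asv optional character vector restricting the output to given ASVs
#'   (error if unknown).
#' @return `data.frame` with columns `asv_id`, `category`, `restricted_host`
#'   (`NA` unless host-restricted) and list column `wild_profile`.
#' @examples
#' sim <- simulateScenario(scenarioConfig("codiversification", rngSeed = 1))
#' table(classifyAsvs(sim$experiment)$category)
#' @export
classifyAsvs <- function(experiment, asv = NULL) {
  stopifnot(is(experiment, "IncidenceExperiment"))
  cls <- .classify(incidence(experiment), sampleData(experiment))
  if (!is.null(asv)) {
    bad <- setdiff(asv, cls$asv_id)
    if (length(bad))
      stop("unknown ASV id(s): ", paste(utils::head(bad, 5L), collapse = ", "))
    cls <- cls[asv, , drop = FALSE]
  }
  cls
}

## ---- tree bookkeeping -----------------------------------------------------

## children lists and per-node descendant tip indices for an ape phylo.
.treeIndex <- function(tree) {
  nt <- length(tree$tip.label)
  nn <- tree$Nnode
  kids <- vector("list", nt + nn)
  for (i in seq_len(nrow(tree$edge)))
    kids[[tree$edge[i, 1L]]] <- c(kids[[tree$edge[i, 1L]]], tree$edge[i, 2L])
  tips <- vector("list", nt + nn)
  for (i in seq_len(nt)) tips[[i]] <- i
  ## visit internal nodes in order of their last postorder edge occurrence, so
  ## every child subtree is complete before its parent is accumulated
  parents <- tree$edge[ape::postorder(tree), 1L]
  for (nd in rev(unique(rev(parents))))
    tips[[nd]] <- unlist(tips[kids[[nd]]], use.names = FALSE)
  root <- nt + 1L
  list(ntip = nt, nnode = nn, root = root, children = kids, tips = tips)
}

## number of distinct samples containing >= 1 of the member ASVs
.nIndividuals <- function(inc, members) {
  sum(colSums(inc[members, , drop = FALSE]) > 0L)
}

## ---- the three-pass maximal clade scan ------------------------------------

## One greedy top-down pass: preorder from the root; accept a node as soon as
## the predicate holds and do not descend into it (maximality). `consumed`
## marks tips claimed by earlier passes; members are the unconsumed tips.
.greedyPass <- function(tree, idx, predicate, consumed) {
  accepted <- list()
  stack <- idx$root
  while (length(stack)) {
    nd <- stack[[1L]]
    stack <- stack[-1L]
    if (nd <= idx$ntip) next
    utips <- idx$tips[[nd]]
    utips <- utips[!consumed[utips]]
    res <- predicate(nd, utips)
    if (isTRUE(res$accept)) {
      consumed[utips] <- TRUE
      accepted[[length(accepted) + 1L]] <-
        list(node = nd, tips = utips, host = res$host,
             support = res$support, n_individuals = res$n_individuals)
    } else {
      stack <- c(idx$children[[nd]], stack)
    }
  }
  list(accepted = accepted, consumed = consumed)
}

.findClades <- function(tree, cls, inc, samples, config) {
  miss <- setdiff(tree$tip.label, cls$asv_id)
  if (length(miss))
    stop("tree tip(s) without classification: ",
         paste(utils::head(miss, 5L), collapse = ", "))
  miss <- setdiff(tree$tip.label, rownames(inc))
  if (length(miss))
    stop("tree tip(s) missing from incidence: ",
         paste(utils::head(miss, 5L), collapse = ", "))
  idx <- .treeIndex(tree)
  sup <- nodeSupport(tree)
  sup[is.na(sup)] <- 0 # unlabeled nodes cannot anchor clades
  supOf <- function(nd) sup[nd - idx$ntip]
  tipCat <- cls[tree$tip.label, "category"]
  tipHost <- cls[tree$tip.label, "restricted_host"]
  tipProf <- cls[tree$tip.label, "wild_profile"]
  minSup <- config@minSupport
  minInd <- config@minIndividuals

  common <- function(nd, utips) {
    if (length(utips) < 2L) return(NULL)
    if (!(supOf(nd) > minSup)) return(NULL)
    ni <- .nIndividuals(inc, tree$tip.label[utips])
    if (ni < minInd) return(NULL)
    ni
  }
  predHR <- function(nd, utips) {
    if (length(utips) < 2L || !all(tipCat[utips] == "host_restricted"))
      return(list(accept = FALSE))
    hosts <- unique(tipHost[utips])
    if (length(hosts) != 1L) return(list(accept = FALSE))
    ni <- common(nd, utips)
    if (is.null(ni)) return(list(accept = FALSE))
    list(accept = TRUE, host = hosts, support = supOf(nd), n_individuals = ni)
  }
  predMixed <- function(nd, utips) {
    if (length(utips) < 2L) return(list(accept = FALSE))
    span <- unique(unlist(tipProf[utips], use.names = FALSE))
    if (length(span) < 2L) return(list(accept = FALSE))
    ni <- common(nd, utips)
    if (is.null(ni)) return(list(accept = FALSE))
    list(accept = TRUE, host = NA_character_, support = supOf(nd),
         n_individuals = ni)
  }
  predCaptive <- function(nd, utips) {
    if (length(utips) < 2L || !all(tipCat[utips] == "unique_to_captive"))
      return(list(accept = FALSE))
    ni <- common(nd, utips)
    if (is.null(ni)) return(list(accept = FALSE))
    list(accept = TRUE, host = NA_character_, support = supOf(nd),
         n_individuals = ni)
  }

  consumed <- logical(idx$ntip)
  out <- list()
  for (pass in seq_along(.CATEGORIES)) {
    pred <- switch(.CATEGORIES[pass], host_restricted = predHR,
                   mixed_host = predMixed, unique_to_captive = predCaptive)
    res <- .greedyPass(tree, idx, pred, consumed)
    consumed <- res$consumed
    for (cl in res$accepted)
      out[[length(out) + 1L]] <- c(cl, list(category = .CATEGORIES[pass]))
  }
  out
}

## canonical ordering: category, then lexicographically first member ASV
.orderClades <- function(raw, tree) {
  if (!length(raw)) return(raw)
  keys <- vapply(raw, function(cl)
    min(tree$tip.label[cl$tips]), character(1L))
  catRank <- match(vapply(raw, `[[`, character(1L), "category"), .CATEGORIES)
  raw[order(catRank, keys)]
}

#' Find maximal well-supported monophyletic clades
#'
#' Three sequential greedy passes over the symbiont phylogeny, mirroring the
#' order in which clade categories are defined: (1) host-restricted -- accept
#' a node iff all descendant tips are host-restricted to the same host group,
#' its support exceeds `minSupport` (strict), and its members occur in at
#' least `minIndividuals` distinct samples; on acceptance the subtree is not
#' descended (maximality) and its tips are consumed. (2) mixed-host -- on the
#' remaining tips, accept maximal supported nodes whose unconsumed tips span
#' two or more designation groups under the same thresholds. (3)
#' unique-to-captive -- likewise on the remaining captive-only tips. Clades
#' require an internal node (>= 2 member tips): single ASVs carry no bootstrap
#' support and are reported only in the classification table. Accepted clades
#' are pairwise disjoint, and the result is independent of the child order of
#' the input newick.
#'
#' @param tree symbiont phylogeny (`ape::phylo`, rooted, with support labels).
#' @param experiment an [IncidenceExperiment].
#' @param config an [AnalysisConfig].
#' @param classification optional precomputed result of [classifyAsvs()].
#' @return a [CladeSet].
#' @examples
#' sim <- simulateScenario(scenarioConfig("codiversification", rngSeed = 1))
#' findMaximalClades(sim$symbiontTree, sim$experiment)
#' @export
findMaximalClades <- function(tree, experiment, config = analysisConfig(),
                              classification = NULL) {
  stopifnot(is(experiment, "IncidenceExperiment"), is(config, "AnalysisConfig"))
  inc <- incidence(experiment)
  samples <- sampleData(experiment)
  if (is.null(classification)) classification <- .classify(inc, samples)
  raw <- .findClades(tree, classification, inc, samples, config)
  raw <- .orderClades(raw, tree)
  .cladeSetFrom(raw, tree, inc, samples, config)
}

.cladeSetFrom <- function(raw, tree, inc, samples, config) {
  n <- length(raw)
  ids <- sprintf("clade_%03d", seq_len(n))
  members <- lapply(raw, function(cl) sort(tree$tip.label[cl$tips]))
  names(members) <- ids
  clades <- data.frame(
    clade_id = ids,
    category = vapply(raw, `[[`, character(1L), "category"),
    host_species = vapply(raw, `[[`, character(1L), "host"),
    support = vapply(raw, `[[`, numeric(1L), "support"),
    n_asvs = vapply(raw, function(cl) length(cl$tips), integer(1L)),
    n_individuals = vapply(raw, `[[`, integer(1L), "n_individuals"),
    stringsAsFactors = FALSE)
  if (n == 0L)
    clades <- data.frame(clade_id = character(0), category = character(0),
                         host_species = character(0), support = numeric(0),
                         n_asvs = integer(0), n_individuals = integer(0))
  prev <- .prevalenceMatrix(members, inc, samples)
  new("CladeSet", clades = clades, members = members, prevalence = prev,
      config = config)
}

.prevalenceMatrix <- function(members, inc, samples, bySite = FALSE) {
  grp <- .sampleGroups(samples, bySite = bySite)
  lev <- sort(unique(grp))
  out <- matrix(NA_real_, nrow = length(members), ncol = length(lev),
                dimnames = list(names(members), lev))
  for (i in seq_along(members)) {
    present <- colSums(inc[members[[i]], , drop = FALSE]) > 0L
    out[i, ] <- vapply(lev, function(g) mean(present[grp == g]), numeric(1L))
  }
  out
}

#' Per-group prevalence of a clade
#'
#' Fraction of each sample group's individuals (host species x lifestyle;
#' captive groups optionally split by site) whose sample contains at least one
#' member ASV -- presence is the union over members. Empty groups cannot occur
#' (groups are derived from the samples present).
#'
#' @param members character vector of member ASV ids (must be incidence rows).
#' @param experiment an [IncidenceExperiment].
#' @param bySite split captive groups by site.
#' @return named numeric vector of fractions in \[0, 1\].
#' @export
cladePrevalence <- function(members, experiment, bySite = FALSE) {
  stopifnot(is(experiment, "IncidenceExperiment"))
  inc <- incidence(experiment)
  bad <- setdiff(members, rownames(inc))
  if (length(bad))
    stop("unknown ASV id(s): ", paste(utils::head(bad, 5L), collapse = ", "))
  drop(.prevalenceMatrix(list(clade = members), inc, sampleData(experiment),
                         bySite = bySite)[1L, ])
}

#' Filter clades by prominence
#'
#' Keeps clades whose prevalence strictly exceeds the threshold in at least
#' one sample group (the reporting filter "present in more than 25% of the
#' individuals of some sample type"; a prevalence exactly at the threshold is
#' excluded).
#'
#' @param clades a [CladeSet].
#' @param threshold prevalence cut-off; defaults to the `prevalenceThreshold`
#'   of the config the clades were built with.
#' @return a [CladeSet] containing the retained clades.
#' @export
prominentClades <- function(clades, threshold = NULL) {
  stopifnot(is(clades, "CladeSet"))
  if (is.null(threshold)) threshold <- clades@config@prevalenceThreshold
  if (!length(clades)) return(clades)
  keep <- apply(clades@prevalence > threshold, 1L, any, na.rm = TRUE)
  new("CladeSet",
      clades = clades@clades[keep, , drop = FALSE],
      members = clades@members[keep],
      prevalence = clades@prevalence[keep, , drop = FALSE],
      config = clades@config)
}
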