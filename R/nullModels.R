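## Fixed-margins permutation of the incidence matrix (curveball trades) and
## randomized host phylogenies for the co-speciation control.

#' Curveball permutation of a binary matrix
#'
#' Samples a binary matrix with exactly the row and column sums of the input
#' by a sequence of curveball trades: pick two rows at random, take the
#' symmetric difference of their presence columns, and re-deal it at random
#' between the two rows while keeping each row's total. Margins are conserved
#' by construction after any number of trades. The default number of trades,
#' `5 * nrow(m)`, is a standard mixing heuristic.
#'
#' Randomness comes from the session RNG; call `set.seed()` for
#' reproducibility.
#'
#' @param m binary (0/1) matrix.
#' @param nTrials number of trades (>= 1).
#' @return a 0/1 matrix with the same dimnames, row sums and column sums.
#' @examples
#' set.seed(1)
#' m <- matrix(rbinom(50, 1, 0.4), 5, 10)
#' p <- curveballPermute(m)
#' stopifnot(identical(rowSums(p), rowSums(m)), identical(colSums(p), colSums(m)))
#' @export
curveballPermute <- function(m, nTrials = 5L * nrow(m)) {
  if (!is.matrix(m) || anyNA(m) || !all(m == 0L | m == 1L))
    stop("'m' must be a binary 0/1 matrix with no missing values")
  nTrials <- as.integer(nTrials)
  if (is.na(nTrials) || nTrials < 1L) stop("'nTrials' must be >= 1")
  storage.mode(m) <- "integer"
  n <- nrow(m)
  if (n < 2L) return(m)
  for (t in seq_len(nTrials)) {
    rr <- sample.int(n, 2L)
    r1 <- m[rr[1L], ]
    r2 <- m[rr[2L], ]
    d <- which(r1 != r2)
    nd <- length(d)
    if (nd < 2L) next
    k <- sum(r1[d])
    if (k == 0L || k == nd) next
    one <- d[sample.int(nd, k)]
    r1[d] <- 0L
    r1[one] <- 1L
    r2[d] <- 1L
    r2[one] <- 0L
    m[rr[1L], ] <- r1
    m[rr[2L], ] <- r2
  }
  m
}

#' Calibrate host-restricted clade sizes against the fixed-margins null
#'
#' Re-runs ASV classification and the maximal clade scan on `nPermutations`
#' curveball-permuted incidence matrices (the tree is held fixed) and records,
#' per permutation, the maximum host-restricted clade size and the number of
#' accepted host-restricted clades. Each observed host-restricted clade size
#' `s` receives the add-one empirical p-value
#' `(1 + #\{permuted max >= s\}) / (1 + nPermutations)`, which is never zero
#' and has floor `1/(nPermutations + 1)`.
#'
#' @param tree symbiont phylogeny (`ape::phylo`).
#' @param experiment an [IncidenceExperiment].
#' @param config an [AnalysisConfig]; `nPermutations` and `curveballTrials`
#'   are taken from it.
#' @return a [CladeSizeNull].
#' @examples
#' sim <- simulateScenario(scenarioConfig("codiversification", rngSeed = 1))
#' set.seed(2)
#' cladeSizeNull(sim$symbiontTree, sim$experiment,
#'               analysisConfig(nPermutations = 19))
#' @export
cladeSizeNull <- function(tree, experiment, config = analysisConfig()) {
  stopifnot(is(experiment, "IncidenceExperiment"), is(config, "AnalysisConfig"))
  inc <- incidence(experiment)
  samples <- sampleData(experiment)
  nPerm <- config@nPermutations
  trials <- if (is.na(config@curveballTrials)) 5L * nrow(inc)
            else config@curveballTrials

  observed <- .findClades(tree, .classify(inc, samples), inc, samples, config)
  obsSizes <- vapply(Filter(function(cl) cl$category == "host_restricted",
                            observed),
                     function(cl) length(cl$tips), integer(1L))
  obsMax <- if (length(obsSizes)) max(obsSizes) else 0

  permMax <- numeric(nPerm)
  permN <- numeric(nPerm)
  for (b in seq_len(nPerm)) {
    pm <- curveballPermute(inc, trials)
    cl <- .findClades(tree, .classify(pm, samples), pm, samples, config)
    hr <- Filter(function(z) z$category == "host_restricted", cl)
    permN[b] <- length(hr)
    permMax[b] <- if (length(hr))
      max(vapply(hr, function(z) length(z$tips), integer(1L))) else 0
  }
  sizes <- sort(unique(obsSizes))
  emp <- vapply(sizes, function(s) (1 + sum(permMax >= s)) / (1 + nPerm),
                numeric(1L))
  names(emp) <- as.character(sizes)
  new("CladeSizeNull", nPermutations = as.integer(nPerm), permMaxSize = permMax,
      permNClades = permN, observedSizes = as.numeric(sizes), empiricalP = emp,
      observedMaxSize = as.numeric(obsMax))
}

#' Randomize a host phylogeny
#'
#' `mode = "shuffle"` (default) keeps the topology and branch lengths and
#' permutes the tip labels uniformly over non-identity permutations, which
#' preserves the multiset of patristic distances and isolates topology--label
#' concordance. `mode = "yule"` draws a random coalescent topology over the
#' same labels and rescales it to the original root age (ultrametric).
#'
#' @param host host phylogeny (`ape::phylo`, >= 3 tips).
#' @param mode `"shuffle"` or `"yule"`.
#' @return an `ape::phylo`.
#' @examples
#' host <- simulateHostTree(scenarioConfig())
#' set.seed(1)
#' randomizeHostTree(host)$tip.label
#' @export
randomizeHostTree <- function(host, mode = c("shuffle", "yule")) {
  mode <- match.arg(mode)
  labels <- host$tip.label
  n <- length(labels)
  if (n < 3L) stop("host tree must have >= 3 tips")
  if (mode == "shuffle") {
    out <- host
    repeat {
      perm <- sample.int(n)
      if (any(perm != seq_len(n))) break
    }
    out$tip.label <- labels[perm]
    out
  } else {
    out <- ape::rcoal(n, tip.label = sample(labels))
    depth <- max(ape::node.depth.edgelength(out))
    rootAge <- max(ape::node.depth.edgelength(host))
    out$edge.length <- out$edge.length * rootAge / depth
    out
  }
}
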