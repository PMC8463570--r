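## Distance-based co-phylogenetic congruence tests (Hommola correlation test,
## ParaFitGlobal, PACo Procrustes m2) and the true-vs-randomized host battery.

#' Patristic distance matrix
#'
#' Pairwise sums of branch lengths along tip-to-tip paths.
#'
#' @param tree an `ape::phylo` with branch lengths.
#' @return symmetric numeric matrix with zero diagonal, labelled by tips.
#' @examples
#' patristicMatrix(readNewickTree(text = "((A:1,B:1):1,C:2);"))
#' @export
patristicMatrix <- function(tree) {
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("tree must have complete branch lengths")
  as.matrix(stats::cophenetic(tree))
}

#' Principal-coordinate embedding of a distance matrix
#'
#' Embeds a symmetric distance matrix into coordinates whose Euclidean
#' distances reproduce the input (exactly, for Euclidean input). Wraps
#' `ape::pcoa`. With `correction = "cailliez"` the additive constant removes
#' negative eigenvalues before embedding; `"auto"` applies Cailliez only when
#' the smallest eigenvalue is below `-1e-8` times the largest.
#'
#' @param D symmetric distance matrix (or `dist`), zero diagonal.
#' @param correction `"auto"`, `"none"` or `"cailliez"`.
#' @return numeric coordinate matrix (rows = objects, positive-eigenvalue
#'   axes), with attributes `eigenvalues` (of the uncorrected embedding) and
#'   `correction` (the correction actually applied).
#' @export
pcoaEmbed <- function(D, correction = c("auto", "none", "cailliez")) {
  correction <- match.arg(correction)
  D <- as.matrix(D)
  if (nrow(D) != ncol(D) || max(abs(D - t(D))) > 1e-8)
    stop("'D' must be a symmetric square matrix")
  if (any(diag(D) != 0)) stop("'D' must have a zero diagonal")
  n <- nrow(D)
  if (is.null(rownames(D))) rownames(D) <- colnames(D) <- as.character(seq_len(n))
  eig <- .gowerEigen(D)
  tol <- 1e-8 * max(abs(eig$values), .Machine$double.eps)
  hasNeg <- min(eig$values) < -tol
  applyCailliez <- correction == "cailliez" || (correction == "auto" && hasNeg)
  if (!applyCailliez || !hasNeg) {
    keep <- eig$values > tol
    X <- if (any(keep))
      eig$vectors[, keep, drop = FALSE] %*%
        diag(sqrt(eig$values[keep]), sum(keep))
    else matrix(0, n, 1L)
    applied <- "none"
  } else {
    pc <- ape::pcoa(D, correction = "cailliez")
    X <- if (!is.null(pc$vectors.cor)) pc$vectors.cor else pc$vectors
    applied <- "cailliez"
  }
  rownames(X) <- rownames(D)
  attr(X, "eigenvalues") <- eig$values
  attr(X, "correction") <- applied
  X
}

## Gower-centered eigendecomposition of -0.5 * D^2
.gowerEigen <- function(D) {
  n <- nrow(D)
  A <- -0.5 * D^2
  J <- diag(n) - matrix(1 / n, n, n)
  eigen(J %*% A %*% J, symmetric = TRUE)
}

#' Build a symbiont-by-host association matrix
#'
#' Entry (s, h) is 1 when symbiont `s` is observed in at least one sample of
#' designation-relevant host group `h` (wild individuals of each ape species;
#' humans of either lifestyle). ASVs observed only in captive apes have no
#' association and are dropped with a message.
#'
#' @param experiment an [IncidenceExperiment].
#' @param hosts optional host order for the columns (e.g. host-tree tip
#'   labels); defaults to the groups observed.
#' @return binary matrix, symbionts x hosts, every row with >= 1 association.
#' @export
buildAssociations <- function(experiment, hosts = NULL) {
  stopifnot(is(experiment, "IncidenceExperiment"))
  inc <- incidence(experiment)
  grp <- .designationGroups(sampleData(experiment))
  lev <- if (is.null(hosts)) .HOST_GROUPS[.HOST_GROUPS %in% grp] else hosts
  A <- vapply(lev, function(g) {
    idx <- which(!is.na(grp) & grp == g)
    as.integer(rowSums(inc[, idx, drop = FALSE]) > 0L)
  }, integer(nrow(inc)))
  if (nrow(inc) == 1L)
    A <- matrix(A, nrow = 1L, dimnames = list(rownames(inc), lev))
  rownames(A) <- rownames(inc)
  drop0 <- rowSums(A) == 0L
  if (any(drop0)) {
    message(sum(drop0), " symbiont(s) without a designation-group association dropped")
    A <- A[!drop0, , drop = FALSE]
  }
  A
}

## links of an association matrix mapped onto distance-matrix indices
.assocLinks <- function(hostD, symbD, assoc) {
  if (is.null(rownames(assoc)) || is.null(colnames(assoc)))
    stop("association matrix must have row (symbiont) and column (host) names")
  if (anyNA(assoc) || !all(assoc %in% c(0, 1)))
    stop("association matrix must be binary 0/1")
  if (any(rowSums(assoc) == 0))
    stop("association row(s) without any host: ",
         paste(utils::head(rownames(assoc)[rowSums(assoc) == 0], 5L),
               collapse = ", "))
  hIdx <- match(colnames(assoc), rownames(hostD))
  sIdx <- match(rownames(assoc), rownames(symbD))
  if (anyNA(hIdx))
    stop("association hosts missing from host distance matrix: ",
         paste(utils::head(colnames(assoc)[is.na(hIdx)], 5L), collapse = ", "))
  if (anyNA(sIdx))
    stop("association symbionts missing from symbiont distance matrix: ",
         paste(utils::head(rownames(assoc)[is.na(sIdx)], 5L), collapse = ", "))
  w <- which(assoc == 1, arr.ind = TRUE)
  list(s = sIdx[w[, 1L]], h = hIdx[w[, 2L]], n = nrow(w))
}

## restrict both distance matrices to the taxa named by the association matrix
.alignToAssoc <- function(hostD, symbD, assoc) {
  hostD <- as.matrix(hostD); symbD <- as.matrix(symbD)
  miss <- setdiff(colnames(assoc), rownames(hostD))
  if (length(miss))
    stop("association hosts missing from host distance matrix: ",
         paste(utils::head(miss, 5L), collapse = ", "))
  miss <- setdiff(rownames(assoc), rownames(symbD))
  if (length(miss))
    stop("association symbionts missing from symbiont distance matrix: ",
         paste(utils::head(miss, 5L), collapse = ", "))
  list(hostD = hostD[colnames(assoc), colnames(assoc), drop = FALSE],
       symbD = symbD[rownames(assoc), rownames(assoc), drop = FALSE])
}

.addOneP <- function(null, obs, direction) {
  hit <- if (direction == "ge") null >= obs else null <= obs
  hit[!is.finite(null)] <- TRUE # conservative for degenerate permutations
  (1 + sum(hit)) / (1 + length(null))
}

#' Hommola correlation test of co-diversification
#'
#' Enumerates all unordered pairs of host--symbiont association links and
#' correlates the symbiont patristic distances with the host patristic
#' distances across link pairs (Pearson r). The null permutes the host labels
#' and the symbiont labels independently; large r indicates congruence
#' (`direction = "ge"`). When either distance vector has zero variance (e.g.
#' all symbionts equidistant on a star tree) the statistic is undefined: the
#' result is flagged degenerate and p is reported as 1.
#'
#' @param hostD,symbD labelled patristic (or other) distance matrices.
#' @param assoc binary association matrix, symbionts x hosts; labels must
#'   match the distance matrices.
#' @param nPerm number of permutations.
#' @return a [CospeciationResult].
#' @references Hommola K, Smith JE, Qiu Y, Gilks WR (2009) A permutation test
#'   of host-parasite cospeciation. Mol Biol Evol 26:1457-1468.
#' @export
hommolaTest <- function(hostD, symbD, assoc, nPerm = 999L) {
  al <- .alignToAssoc(hostD, symbD, assoc)
  hostD <- al$hostD; symbD <- al$symbD
  lk <- .assocLinks(hostD, symbD, assoc)
  if (lk$n < 3L) stop("need >= 3 association links")
  pr <- utils::combn(lk$n, 2L)
  s1 <- lk$s[pr[1L, ]]; s2 <- lk$s[pr[2L, ]]
  h1 <- lk$h[pr[1L, ]]; h2 <- lk$h[pr[2L, ]]
  x <- symbD[cbind(s1, s2)]
  y <- hostD[cbind(h1, h2)]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(new("CospeciationResult", test = "hommola", statistic = NA_real_,
               nullValues = numeric(0), p = 1, direction = "ge",
               degenerate = TRUE, nPermutations = as.integer(nPerm)))
  robs <- stats::cor(x, y)
  nH <- nrow(hostD); nS <- nrow(symbD)
  rnull <- numeric(nPerm)
  for (b in seq_len(nPerm)) {
    ph <- sample.int(nH)
    ps <- sample.int(nS)
    xb <- symbD[cbind(ps[s1], ps[s2])]
    yb <- hostD[cbind(ph[h1], ph[h2])]
    rnull[b] <- if (stats::sd(xb) == 0 || stats::sd(yb) == 0) NA_real_
                else stats::cor(xb, yb)
  }
  new("CospeciationResult", test = "hommola", statistic = robs,
      nullValues = rnull, p = .addOneP(rnull, robs, "ge"), direction = "ge",
      degenerate = FALSE, nPermutations = as.integer(nPerm))
}

#' ParaFit global test of co-diversification
#'
#' Embeds hosts and symbionts by principal coordinates (B and C) and computes
#' the fourth-corner matrix D = C' A B, where A is the binary symbiont-by-host
#' association matrix; ParaFitGlobal is the sum of squared entries of D. The
#' null permutes each symbiont's associations independently across hosts
#' (the classical row permutation); large values indicate congruence.
#'
#' @inheritParams hommolaTest
#' @param correction PCoA correction passed to [pcoaEmbed()].
#' @return a [CospeciationResult].
#' @references Legendre P, Desdevises Y, Bazin E (2002) A statistical test for
#'   host-parasite coevolution. Syst Biol 51:217-234.
#' @export
parafitGlobal <- function(hostD, symbD, assoc, nPerm = 999L,
                          correction = "auto") {
  al <- .alignToAssoc(hostD, symbD, assoc)
  hostD <- al$hostD; symbD <- al$symbD
  if (nrow(hostD) < 2L || nrow(symbD) < 2L)
    stop("need >= 2 hosts and >= 2 symbionts")
  lk <- .assocLinks(hostD, symbD, assoc) # validates labels and rows
  B <- pcoaEmbed(hostD, correction)
  C <- pcoaEmbed(symbD, correction)
  A <- assoc[rownames(C), rownames(B), drop = FALSE]
  Ct <- t(C)
  stat <- sum((Ct %*% A %*% B)^2)
  null <- numeric(nPerm)
  nh <- ncol(A)
  for (b in seq_len(nPerm)) {
    Ap <- t(apply(A, 1L, function(z) z[sample.int(nh)]))
    null[b] <- sum((Ct %*% Ap %*% B)^2)
  }
  new("CospeciationResult", test = "parafit", statistic = stat,
      nullValues = null, p = .addOneP(null, stat, "ge"), direction = "ge",
      degenerate = FALSE, nPermutations = as.integer(nPerm))
}

## Procrustes residual after superimposing configuration Y onto X with
## translation, scaling and rotation: m2 = tr(Xc'Xc) - (sum sigma)^2/tr(Yc'Yc),
## sigma the singular values of Yc'Xc. Matches vegan::procrustes(X, Y,
## symmetric = FALSE)$ss (zero-padding of the narrower configuration does not
## change the singular values).
.procrustesM2 <- function(X, Y) {
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  tx <- sum(Xc^2)
  ty <- sum(Yc^2)
  if (ty <= .Machine$double.eps * max(1, tx))
    return(list(m2 = tx, degenerate = TRUE))
  s <- sum(svd(crossprod(Yc, Xc), nu = 0L, nv = 0L)$d)
  list(m2 = tx - s^2 / ty, degenerate = FALSE)
}

#' PACo Procrustes test of co-diversification
#'
#' Embeds hosts and symbionts by principal coordinates (Cailliez correction
#' applied automatically when needed), builds one paired coordinate row per
#' association link, and Procrustes-superimposes the symbiont configuration
#' onto the host configuration (translation, scaling, rotation) -- the
#' asymmetric orientation of symbionts tracking hosts. The statistic m2 is the
#' residual sum of squares; small values indicate congruence
#' (`direction = "le"`). The null re-draws which host each link touches by
#' permuting the host side of the link list, preserving the number of links.
#'
#' @inheritParams parafitGlobal
#' @return a [CospeciationResult].
#' @references Balbuena JA, Miguez-Lozano R, Blasco-Costa I (2013) PACo: a
#'   novel Procrustes application to cophylogenetic analysis. PLoS ONE
#'   8:e61048.
#' @export
pacoTest <- function(hostD, symbD, assoc, nPerm = 999L, correction = "auto") {
  al <- .alignToAssoc(hostD, symbD, assoc)
  hostD <- al$hostD; symbD <- al$symbD
  if (nrow(hostD) < 2L || nrow(symbD) < 2L)
    stop("need >= 2 hosts and >= 2 symbionts")
  lk <- .assocLinks(hostD, symbD, assoc)
  B <- pcoaEmbed(hostD, correction)
  C <- pcoaEmbed(symbD, correction)
  X <- B[lk$h, , drop = FALSE]
  Y <- C[lk$s, , drop = FALSE]
  obs <- .procrustesM2(X, Y)
  null <- numeric(nPerm)
  degenerate <- obs$degenerate
  for (b in seq_len(nPerm)) {
    Xp <- X[sample.int(lk$n), , drop = FALSE]
    null[b] <- .procrustesM2(Xp, Y)$m2
  }
  p <- if (degenerate) 1 else .addOneP(null, obs$m2, "le")
  new("CospeciationResult", test = "paco", statistic = obs$m2,
      nullValues = null, p = p, direction = "le",
      degenerate = degenerate, nPermutations = as.integer(nPerm))
}

#' True-host versus randomized-host test battery
#'
#' Runs all three co-diversification tests twice -- once against the true host
#' phylogeny and once against a randomized one -- and tabulates the six
#' (statistic, p) pairs. A test that is also significant under the randomized
#' host tree cannot be discriminating co-diversification from host-restricted
#' diversification: with many closely related symbionts restricted to
#' different hosts, within-host clustering alone drives all three statistics.
#'
#' @param hostTree,symbiontTree `ape::phylo` objects with branch lengths.
#' @param assoc binary association matrix, symbionts x hosts (host columns
#'   must match host tree tips).
#' @param config an [AnalysisConfig]; `nPermutations` is taken from it.
#' @param mode randomization mode for [randomizeHostTree()].
#' @return `data.frame` with columns `test`, `host_tree` (`true`/`randomized`),
#'   `statistic`, `p`, `degenerate`.
#' @examples
#' sim <- simulateScenario(scenarioConfig("host_switch", nCladesPerHost = 10,
#'                                        asvsPerClade = 3, rngSeed = 1))
#' assoc <- buildAssociations(sim$experiment, hosts = sim$hostTree$tip.label)
#' set.seed(1)
#' hostRandomizationBattery(sim$hostTree, sim$symbiontTree, assoc,
#'                          analysisConfig(nPermutations = 99))
#' @export
hostRandomizationBattery <- function(hostTree, symbiontTree, assoc,
                                     config = analysisConfig(),
                                     mode = c("shuffle", "yule")) {
  stopifnot(is(config, "AnalysisConfig"))
  mode <- match.arg(mode)
  nPerm <- config@nPermutations
  symbD <- patristicMatrix(symbiontTree)
  trees <- list(true = hostTree,
                randomized = randomizeHostTree(hostTree, mode))
  rows <- list()
  for (label in names(trees)) {
    hostD <- patristicMatrix(trees[[label]])
    fits <- list(hommolaTest(hostD, symbD, assoc, nPerm),
                 parafitGlobal(hostD, symbD, assoc, nPerm),
                 pacoTest(hostD, symbD, assoc, nPerm))
    for (f in fits)
      rows[[length(rows) + 1L]] <- data.frame(
        test = f@test, host_tree = label, statistic = f@statistic,
        p = f@p, degenerate = f@degenerate, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
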