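test_that("patristic distances sum branch lengths along paths", {
  d1 <- patristicMatrix(ape::read.tree(text = "(A:1,B:2);"))
  expect_equal(d1["A", "B"], 3)
  d2 <- patristicMatrix(ape::read.tree(text = "((A:1,B:1):1,C:2);"))
  expect_equal(d2["A", "B"], 2)
  expect_equal(d2["A", "C"], 4)
  expect_equal(d2["B", "C"], 4)
  ## tree metric: triangle inequality on a random tree
  set.seed(1)
  d <- patristicMatrix(ape::rtree(8))
  for (i in 1:8) for (j in 1:8) for (k in 1:8)
    expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
})

test_that("principal coordinates reproduce Euclidean distances", {
  ## three equidistant points
  D <- matrix(1, 3, 3) - diag(3)
  X <- pcoaEmbed(D)
  expect_equal(as.matrix(dist(X)), D, ignore_attr = TRUE, tolerance = 1e-8)
  ## points on a line
  pts <- c(0, 1, 3)
  D2 <- as.matrix(dist(pts))
  X2 <- pcoaEmbed(D2)
  expect_equal(as.matrix(dist(X2)), D2, ignore_attr = TRUE, tolerance = 1e-8)
})

test_that("cailliez correction removes negative eigenvalues", {
  ## a metric that is not Euclidean-embeddable (violates the four-point
  ## Euclidean condition): verify via the Gower eigendecomposition directly
  D <- matrix(c(0, 2, 2, 1.1,
                2, 0, 2, 1.1,
                2, 2, 0, 1.1,
                1.1, 1.1, 1.1, 0), 4, 4)
  gower <- function(M) {
    n <- nrow(M); J <- diag(n) - 1 / n
    eigen(J %*% (-0.5 * M^2) %*% J, symmetric = TRUE)$values
  }
  expect_lt(min(gower(D)), -1e-8 * max(gower(D)))
  Xc <- pcoaEmbed(D, correction = "cailliez")
  expect_equal(attr(Xc, "correction"), "cailliez")
  Dc <- as.matrix(dist(Xc))
  expect_lt(min(gower(Dc)), 1e-6) # corrected embedding has no negative part
  expect_gt(min(gower(Dc)), -1e-6)
  ## auto applies the correction for this input
  expect_equal(attr(pcoaEmbed(D, "auto"), "correction"), "cailliez")
  expect_error(pcoaEmbed(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("mirrored trees with one-to-one links give Hommola r = 1", {
  mi <- mirroredInstance()
  set.seed(2)
  res <- hommolaTest(mi$hostD, mi$symbD, mi$assoc, nPerm = 99)
  expect_equal(statistic(res), 1)
  expect_false(isDegenerate(res))
  expect_true(statistic(res) >= -1 && statistic(res) <= 1)
})

test_that("equidistant symbionts make the Hommola statistic degenerate", {
  host <- ape::read.tree(text = "((h1:1,h2:1):1,h3:2);")
  star <- ape::read.tree(text = "(s1:1,s2:1,s3:1);")
  A <- diag(1L, 3)
  dimnames(A) <- list(paste0("s", 1:3), paste0("h", 1:3))
  res <- hommolaTest(patristicMatrix(host), patristicMatrix(star), A,
                     nPerm = 19)
  expect_true(isDegenerate(res))
  expect_equal(pValue(res), 1)
  expect_true(is.na(statistic(res)))
})

test_that("hommola r stays in [-1, 1] and ignores association ordering", {
  set.seed(3)
  for (rep in 1:5) {
    host <- ape::rcoal(4, tip.label = paste0("h", 1:4))
    symb <- ape::rcoal(7, tip.label = paste0("s", 1:7))
    A <- matrix(0L, 7, 4, dimnames = list(paste0("s", 1:7), paste0("h", 1:4)))
    A[cbind(1:7, sample(1:4, 7, replace = TRUE))] <- 1L
    hD <- patristicMatrix(host); sD <- patristicMatrix(symb)
    r1 <- statistic(hommolaTest(hD, sD, A, nPerm = 9))
    expect_true(r1 >= -1 && r1 <= 1)
    ## permute rows and columns of the association matrix
    A2 <- A[sample(1:7), sample(1:4), drop = FALSE]
    r2 <- statistic(hommolaTest(hD, sD, A2, nPerm = 9))
    expect_equal(r2, r1, tolerance = 1e-12)
  }
})

test_that("parafit matches the canonical implementation and its invariances", {
  set.seed(4)
  host <- ape::rcoal(4, tip.label = paste0("h", 1:4))
  symb <- ape::rcoal(5, tip.label = paste0("s", 1:5))
  A <- matrix(0L, 5, 4, dimnames = list(paste0("s", 1:5), paste0("h", 1:4)))
  A[cbind(1:5, c(1, 2, 3, 4, 4))] <- 1L
  hD <- patristicMatrix(host); sD <- patristicMatrix(symb)
  mine <- statistic(parafitGlobal(hD, sD, A, nPerm = 1,
                                  correction = "cailliez"))
  ## ape::parafit matches taxa by position, not label: align explicitly
  ref <- ape::parafit(hD[colnames(A), colnames(A)],
                      sD[rownames(A), rownames(A)], t(A), nperm = 1,
                      correction = "cailliez", silent = TRUE)$ParaFitGlobal
  expect_equal(mine, ref, tolerance = 1e-6)

  ## statistic ordering of association rows/columns is immaterial
  A2 <- A[sample(1:5), sample(1:4)]
  expect_equal(statistic(parafitGlobal(hD, sD, A2, nPerm = 1)),
               statistic(parafitGlobal(hD, sD, A, nPerm = 1)),
               tolerance = 1e-9)

  ## scaling host branch lengths by c scales distances by c, principal
  ## coordinates by c, and the sum of squared fourth-corner entries by c^2;
  ## the p-value is unchanged
  s1 <- statistic(parafitGlobal(hD, sD, A, nPerm = 1, correction = "none"))
  s3 <- statistic(parafitGlobal(3 * hD, sD, A, nPerm = 1,
                                correction = "none"))
  expect_equal(s3, 9 * s1, tolerance = 1e-8)
  set.seed(5)
  p1 <- pValue(parafitGlobal(hD, sD, A, nPerm = 99, correction = "none"))
  set.seed(5)
  p3 <- pValue(parafitGlobal(3 * hD, sD, A, nPerm = 99, correction = "none"))
  expect_equal(p1, p3)
})

test_that("mirrored identity links push parafit above its null mean", {
  mi <- mirroredInstance()
  set.seed(6)
  res <- parafitGlobal(mi$hostD, mi$symbD, mi$assoc, nPerm = 499)
  expect_gt(statistic(res), mean(nullValues(res)))
  expect_gte(statistic(res), 0)
})

test_that("a symbiont associated with every host is null-invariant (p = 1)", {
  mi <- mirroredInstance()
  A <- mi$assoc
  A[] <- 1L # every row associated with all hosts: row permutation is identity
  set.seed(7)
  res <- parafitGlobal(mi$hostD, mi$symbD, A, nPerm = 99)
  expect_equal(pValue(res), 1)
  expect_true(all(nullValues(res) == statistic(res)))
})

test_that("procrustes residual matches vegan and is similarity-invariant", {
  set.seed(8)
  X <- matrix(rnorm(30), 10, 3)
  Y <- matrix(rnorm(50), 10, 5)
  mine <- cophylorestrict:::.procrustesM2(X, Y)$m2
  ref <- suppressWarnings(vegan::procrustes(X, Y, symmetric = FALSE))$ss
  expect_equal(mine, ref, tolerance = 1e-10)

  ## identical configurations -> zero residual
  expect_lt(cophylorestrict:::.procrustesM2(X, X)$m2, 1e-10)
  ## rotation + scaling + translation of Y leaves the residual at zero
  th <- pi / 2
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  X2 <- matrix(rnorm(20), 10, 2)
  Y2 <- sweep(2 * X2 %*% R, 2, c(5, -3), "+")
  expect_lt(cophylorestrict:::.procrustesM2(X2, Y2)$m2, 1e-10)
})

test_that("paco m2 is zero for congruent configurations and >= 0 generally", {
  mi <- mirroredInstance()
  set.seed(9)
  res <- pacoTest(mi$hostD, mi$symbD, mi$assoc, nPerm = 99)
  expect_lt(statistic(res), 1e-10) # identical shapes, identity links
  expect_equal(res@direction, "le")
  host <- ape::rcoal(4, tip.label = paste0("h", 1:4))
  symb <- ape::rcoal(6, tip.label = paste0("s", 1:6))
  A <- matrix(0L, 6, 4, dimnames = list(paste0("s", 1:6), paste0("h", 1:4)))
  A[cbind(1:6, sample(1:4, 6, replace = TRUE))] <- 1L
  r2 <- pacoTest(patristicMatrix(host), patristicMatrix(symb), A, nPerm = 9)
  expect_gte(statistic(r2), 0)
})

test_that("paco p-values are uniform under random link assignment", {
  set.seed(10)
  host <- ape::rcoal(5, tip.label = paste0("h", 1:5))
  symb <- ape::rcoal(8, tip.label = paste0("s", 1:8))
  hD <- patristicMatrix(host); sD <- patristicMatrix(symb)
  ps <- replicate(100, {
    A <- matrix(0L, 8, 5, dimnames = list(paste0("s", 1:8), paste0("h", 1:5)))
    A[cbind(1:8, sample(1:5, 8, replace = TRUE))] <- 1L
    pValue(pacoTest(hD, sD, A, nPerm = 199))
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
  ## level control: rejection rate at 0.05 stays near nominal
  expect_lte(mean(ps <= 0.05), 0.12)
})

test_that("the battery reports all six test-by-tree combinations", {
  sim <- simulateScenario(scenarioConfig("host_switch", nCladesPerHost = 2,
                                         asvsPerClade = 3, rngSeed = 11))
  assoc <- buildAssociations(sim$experiment,
                             hosts = sim$hostTree$tip.label)
  set.seed(12)
  bat <- hostRandomizationBattery(sim$hostTree, sim$symbiontTree, assoc,
                                  analysisConfig(nPermutations = 49))
  expect_equal(nrow(bat), 6L)
  expect_setequal(bat$test, c("hommola", "parafit", "paco"))
  expect_setequal(bat$host_tree, c("true", "randomized"))
  expect_true(all(bat$p > 0 & bat$p <= 1))
})
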