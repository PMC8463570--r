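test_that("the host tree has the configured divergence times", {
  host <- simulateHostTree(scenarioConfig())
  expect_setequal(host$tip.label,
                  c("bonobo", "chimpanzee", "gorilla", "orangutan", "human"))
  expect_true(ape::is.ultrametric(host, tol = 1e-6))
  expect_equal(max(ape::node.depth.edgelength(host)), 15.2)
  d <- patristicMatrix(host)
  expect_equal(d["bonobo", "chimpanzee"], 2 * 1.8)
  expect_equal(d["human", "chimpanzee"], 2 * 6.4)
  expect_equal(d["gorilla", "human"], 2 * 8.6)
  ## nesting violations are rejected
  expect_error(scenarioConfig(divergenceTimes = c(chimpanzee_bonobo = 7,
                                                  human = 6.4, gorilla = 8.6,
                                                  orangutan = 15.2)),
               "nested")
})

test_that("one codiversifying clade per host mirrors the host topology", {
  sim <- simulateScenario(scenarioConfig("codiversification",
                                         nCladesPerHost = 1, rngSeed = 1))
  ## prune to one representative ASV per planted clade and relabel by host
  rep1 <- sim$truth[!duplicated(sim$truth$clade_id), ]
  pruned <- ape::keep.tip(sim$symbiontTree, rep1$asv_id)
  pruned$tip.label <- rep1$host[match(pruned$tip.label, rep1$asv_id)]
  expect_equal(unname(suppressWarnings(ape::dist.topo(pruned,
                                                      sim$hostTree))[1]), 0)
})

test_that("host-switch radiations are monophyletic single-host groups", {
  sim <- simulateScenario(scenarioConfig("host_switch", nCladesPerHost = 3,
                                         rngSeed = 2))
  expect_equal(length(unique(sim$truth$clade_id)), 15L) # 5 hosts x 3
  for (cl in unique(sim$truth$clade_id)) {
    tips <- sim$truth$asv_id[sim$truth$clade_id == cl]
    expect_true(ape::is.monophyletic(sim$symbiontTree, tips))
    expect_equal(length(unique(sim$truth$host[sim$truth$clade_id == cl])), 1L)
  }
})

test_that("filtering assigns hosts independently of the tree", {
  ## under i.i.d. host assignment a cherry is single-host with prob 1/5
  set.seed(3)
  hits <- 0L; tot <- 0L
  for (rep in 1:30) {
    sim <- simulateSymbiontTree(scenarioConfig("filtering"))
    idx <- cophylorestrict:::.treeIndex(sim$tree)
    hostOf <- setNames(sim$truth$host, sim$truth$asv_id)
    for (nd in (idx$ntip + 1L):(idx$ntip + idx$nnode)) {
      tips <- idx$tips[[nd]]
      if (length(tips) == 2L) {
        tot <- tot + 1L
        if (length(unique(hostOf[sim$tree$tip.label[tips]])) == 1L)
          hits <- hits + 1L
      }
    }
    expect_true(all(is.na(sim$truth$clade_id)))
  }
  expect_gt(tot, 200L)
  se <- sqrt(0.2 * 0.8 / tot)
  expect_lt(abs(hits / tot - 0.2), 4 * se)
})

test_that("no cross-colonization means perfectly host-restricted ASVs", {
  sim <- simulateScenario(scenarioConfig("codiversification",
                                         crossColonizationRate = 0,
                                         rngSeed = 4))
  cls <- classifyAsvs(sim$experiment)
  expect_true(all(cls$category == "host_restricted"))
  expect_equal(unname(cls[sim$truth$asv_id, "restricted_host"]),
               sim$truth$host)
})

test_that("full cross-colonization makes every ASV mixed-host", {
  sim <- simulateScenario(scenarioConfig("codiversification",
                                         crossColonizationRate = 0.999,
                                         rngSeed = 5))
  cls <- classifyAsvs(sim$experiment)
  expect_true(all(cls$category == "mixed_host"))
})

test_that("home-group prevalence concentrates around pi", {
  cfg <- scenarioConfig("host_switch", nCladesPerHost = 10, asvsPerClade = 5,
                        withinHostPrevalence = 0.5, rngSeed = 6)
  sim <- simulateScenario(cfg)
  inc <- incidence(sim$experiment)
  samples <- sampleData(sim$experiment)
  grp <- paste(samples$lifestyle, samples$host_species, sep = "_")
  homeGroup <- ifelse(sim$truth$host == "human", "industrialized_human",
                      paste0("wild_", sim$truth$host))
  prev <- vapply(seq_len(nrow(sim$truth)), function(i) {
    cols <- grp == homeGroup[i]
    mean(inc[sim$truth$asv_id[i], cols])
  }, numeric(1))
  ## 250 ASVs x 20 individuals: the mean prevalence is within binomial error
  se <- sqrt(0.5 * 0.5 / (length(prev) * 20))
  expect_lt(abs(mean(prev) - 0.5), 4 * se)
})

test_that("captive microbiomes converge on the human ASV pool as rho -> 1", {
  sim <- simulateScenario(scenarioConfig("captive_mixing",
                                         captiveHumanAcquisition = 0.9,
                                         rngSeed = 7))
  inc <- incidence(sim$experiment)
  samples <- sampleData(sim$experiment)
  setOf <- function(j) rownames(inc)[inc[, j] > 0]
  lf <- as.character(samples$lifestyle)
  sp <- as.character(samples$host_species)
  capIdx <- which(lf == "captive")
  humIdx <- which(sp == "human")
  meanSor <- function(ii, jj)
    mean(vapply(ii, function(i) mean(vapply(jj, function(j)
      sorensonIndex(setOf(i), setOf(j)), numeric(1))), numeric(1)))
  capHuman <- meanSor(capIdx, humIdx)
  capWildCon <- mean(vapply(capIdx, function(i) {
    wi <- which(lf == "wild" & sp == sp[i])
    mean(vapply(wi, function(j) sorensonIndex(setOf(i), setOf(j)), numeric(1)))
  }, numeric(1)))
  expect_gt(capHuman, capWildCon)
})

test_that("ASVs present in no sample are dropped consistently", {
  expect_warning(
    sim <- simulateScenario(scenarioConfig("codiversification",
                                           nIndividualsPerGroup = 2,
                                           withinHostPrevalence = 0.1,
                                           rngSeed = 8)),
    "dropped")
  expect_setequal(rownames(incidence(sim$experiment)),
                  sim$symbiontTree$tip.label)
  expect_setequal(sim$truth$asv_id, sim$symbiontTree$tip.label)
  expect_true(validObject(sim$experiment))
})
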