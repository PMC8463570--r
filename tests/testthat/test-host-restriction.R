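test_that("ASV designation follows the wild-profile rule", {
  ex <- toyExperiment(list(
    onlyWildChimp = c("wc1", "wc2"),
    chimpPlusHuman = c("wc1", "hu1"),
    chimpPlusCaptiveOrang = c("wc2", "co1"), # captive never alters designation
    captiveOnly = c("cg1", "cg2"),
    humanOnly = c("hu1", "hu2"),
    chimpGorilla = c("wc1", "wg1")))
  cls <- classifyAsvs(ex)
  expect_equal(cls["onlyWildChimp", "category"], "host_restricted")
  expect_equal(cls["onlyWildChimp", "restricted_host"], "chimpanzee")
  expect_equal(cls["chimpPlusHuman", "category"], "mixed_host")
  expect_equal(cls["chimpPlusCaptiveOrang", "category"], "host_restricted")
  expect_equal(cls["chimpPlusCaptiveOrang", "restricted_host"], "chimpanzee")
  expect_equal(cls["captiveOnly", "category"], "unique_to_captive")
  expect_equal(length(cls[["captiveOnly", "wild_profile"]]), 0L)
  expect_equal(cls["humanOnly", "category"], "host_restricted")
  expect_equal(cls["humanOnly", "restricted_host"], "human")
  expect_equal(cls["chimpGorilla", "category"], "mixed_host")
  expect_setequal(cls[["chimpGorilla", "wild_profile"]],
                  c("chimpanzee", "gorilla"))
  expect_error(classifyAsvs(ex, asv = "nope"), "unknown ASV")
})

test_that("clade scan accepts maximal same-host nodes and rejects mixed ones", {
  ex <- toyExperiment(list(a1 = "wc1", a2 = "wc2", a3 = "wc3",
                           b1 = "hu1", b2 = "hu2"))
  tree <- readNewickTree(
    text = "((a1:1,a2:1)90:1,(a3:1,(b1:1,b2:1)80:1)70:1);")
  cs <- findMaximalClades(tree, ex, analysisConfig(minIndividuals = 1))
  tab <- cladeTable(cs)
  expect_equal(nrow(tab), 2L)
  mem <- cladeMembers(cs)
  expect_true(any(vapply(mem, setequal, logical(1), c("a1", "a2"))))
  expect_true(any(vapply(mem, setequal, logical(1), c("b1", "b2"))))
  expect_setequal(tab$support, c(90, 80))
  expect_setequal(tab$host_species, c("chimpanzee", "human"))
  expect_false("a3" %in% unlist(mem)) # leftover singleton is never a clade
})

test_that("maximality reaches the root and the support threshold is strict", {
  ex <- toyExperiment(list(g1 = "wg1", g2 = "wg1", g3 = "wg1", g4 = "wg1"))
  tree <- readNewickTree(text = "((g1:1,g2:1)60:1,(g3:1,g4:1)70:1)100;")
  cs <- findMaximalClades(tree, ex, analysisConfig(minIndividuals = 1))
  expect_equal(length(cs), 1L)
  expect_setequal(cladeMembers(cs)[[1]], c("g1", "g2", "g3", "g4"))
  expect_equal(cladeTable(cs)$support, 100)

  low <- readNewickTree(text = "((g1:1,g2:1)40:1,(g3:1,g4:1)50:1);")
  expect_equal(length(findMaximalClades(low, ex,
                                        analysisConfig(minIndividuals = 1))),
               0L) # 40 and 50 both fail the strict > 50 rule

  ## unlabeled nodes count as support 0
  nolab <- readNewickTree(text = "((g1:1,g2:1):1,(g3:1,g4:1):1);")
  expect_equal(length(findMaximalClades(nolab, ex,
                                        analysisConfig(minIndividuals = 1))),
               0L)
})

test_that("greedy scan equals brute-force enumeration on random cases", {
  set.seed(101)
  for (rep in 1:30) {
    rc <- randomCladeCase(sample(4:32, 1))
    cfg <- analysisConfig(minIndividuals = sample(1:3, 1))
    cs <- findMaximalClades(rc$tree, rc$experiment, cfg)
    bf <- bruteForceClades(rc$tree,
                           classifyAsvs(rc$experiment),
                           incidence(rc$experiment), cfg)
    expect_identical(cladeSetKeys(cs), bruteKeys(bf))
    ## disjointness across all passes
    expect_false(anyDuplicated(unlist(cladeMembers(cs))) > 0)
  }
})

test_that("stricter thresholds only shrink or split host-restricted clades", {
  ## Raising minIndividuals can only remove host-restricted clades: a node
  ## failing the count has no descendant that can pass it. Raising minSupport
  ## refines them instead -- a rejected maximal node may be replaced by
  ## several supported descendants -- so the correct invariant is nesting,
  ## not a non-increasing total count.
  hrMembers <- function(cs) {
    tab <- cladeTable(cs)
    cladeMembers(cs)[tab$category == "host_restricted"]
  }
  set.seed(202)
  for (rep in 1:10) {
    rc <- randomCladeCase(sample(8:24, 1))
    loose <- findMaximalClades(rc$tree, rc$experiment,
                               analysisConfig(minIndividuals = 1))
    tight <- findMaximalClades(rc$tree, rc$experiment,
                               analysisConfig(minIndividuals = 3))
    expect_lte(length(hrMembers(tight)), length(hrMembers(loose)))
    strict <- findMaximalClades(rc$tree, rc$experiment,
                                analysisConfig(minSupport = 80,
                                               minIndividuals = 1))
    for (m in hrMembers(strict))
      expect_true(any(vapply(hrMembers(loose),
                             function(big) all(m %in% big), logical(1))))
  }
})

test_that("clade detection is independent of newick child order", {
  set.seed(303)
  rc <- randomCladeCase(16)
  cfg <- analysisConfig(minIndividuals = 1)
  cs1 <- findMaximalClades(rc$tree, rc$experiment, cfg)
  rot <- rc$tree
  for (nd in (ape::Ntip(rot) + 1L):(ape::Ntip(rot) + rot$Nnode))
    rot <- ape::rotate(rot, nd)
  rot <- readNewickTree(text = ape::write.tree(rot))
  cs2 <- findMaximalClades(rot, rc$experiment, cfg)
  expect_identical(cladeSetKeys(cs1), cladeSetKeys(cs2))
})

test_that("prevalence is a per-group union over clade members", {
  ex <- toyExperiment(list(a1 = c("wc1", "wc2"), a2 = c("wc2", "wc3"),
                           b1 = "hu1"))
  prev <- cladePrevalence(c("a1", "a2"), ex)
  expect_equal(prev[["wild_chimpanzee"]], 1) # union covers wc1-wc3
  expect_equal(prev[["industrialized_human"]], 0)
  expect_equal(prev[["captive_gorilla"]], 0)
  ## brute-force union check on a random case
  set.seed(404)
  rc <- randomCladeCase(10)
  inc <- incidence(rc$experiment)
  members <- rownames(inc)[1:4]
  prev2 <- cladePrevalence(members, rc$experiment)
  grp <- paste(sampleData(rc$experiment)$lifestyle,
               sampleData(rc$experiment)$host_species, sep = "_")
  manual <- vapply(sort(unique(grp)), function(g) {
    cols <- which(grp == g)
    mean(vapply(cols, function(j) any(inc[members, j] > 0), logical(1)))
  }, numeric(1))
  expect_equal(prev2, manual)
  expect_error(cladePrevalence("nope", ex), "unknown ASV")
})

test_that("prominence filtering is strictly greater-than", {
  ex <- toyExperiment(list(a1 = c("wc1", "wc2"), a2 = c("wc1", "wc2"),
                           b1 = "hu1", b2 = "hu1"))
  tree <- readNewickTree(text = "((a1:1,a2:1)90:1,(b1:1,b2:1)90:1);")
  cs <- findMaximalClades(tree, ex, analysisConfig(minIndividuals = 1))
  ## {a1,a2}: 2/3 of wild chimps; {b1,b2}: 1/1 industrialized humans
  expect_equal(length(prominentClades(cs, threshold = 0.5)), 2L)
  ## a prevalence exactly at the threshold is excluded (strict >):
  ## the chimp clade sits exactly at 2/3
  kept <- prominentClades(cs, threshold = 2 / 3)
  expect_equal(length(kept), 1L)
  expect_equal(cladeTable(kept)$host_species, "human")
  ## prevalence exactly 1 is excluded at threshold 1
  empty <- prominentClades(cs, threshold = 1)
  expect_equal(length(empty), 0L)
  expect_equal(length(prominentClades(empty, threshold = 0.1)), 0L)
})
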