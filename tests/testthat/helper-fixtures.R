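## Fixtures built in code: a small deterministic experiment covering every
## designation case, and a fully random generator for oracle-equivalence
## property tests.

## deterministic toy: wild chimps/gorillas, humans, captive orangutan/gorilla
toySamples <- function() {
  data.frame(
    sample_id = c("wc1", "wc2", "wc3", "wg1", "hu1", "hu2", "co1", "cg1", "cg2"),
    host_species = c("chimpanzee", "chimpanzee", "chimpanzee", "gorilla",
                     "human", "human", "orangutan", "gorilla", "gorilla"),
    lifestyle = c("wild", "wild", "wild", "wild", "industrialized",
                  "non_industrialized", "captive", "captive", "captive"),
    site = c(NA, NA, NA, NA, NA, NA, "zoo_a", "zoo_a", "zoo_b"),
    enclosure = c(NA, NA, NA, NA, NA, NA, "zoo_a_e1", "zoo_a_e2", "zoo_b_e1"),
    study = "toy", stringsAsFactors = FALSE)
}

toyExperiment <- function(rows) {
  samples <- toySamples()
  m <- matrix(0L, length(rows), nrow(samples),
              dimnames = list(names(rows), samples$sample_id))
  for (i in seq_along(rows)) m[i, rows[[i]]] <- 1L
  IncidenceExperiment(m, samples)
}

## random experiment + random supported tree over its ASVs, for property tests
randomCladeCase <- function(ntip, blankFrac = 0.15) {
  samples <- toySamples()
  repeat {
    p <- stats::runif(ntip, 0.05, 0.5)
    m <- matrix(stats::rbinom(ntip * nrow(samples), 1L, rep(p, nrow(samples))),
                nrow = ntip,
                dimnames = list(sprintf("t%02d", seq_len(ntip)),
                                samples$sample_id))
    if (all(rowSums(m) > 0L)) break
  }
  tree <- ape::rtree(ntip, tip.label = sprintf("t%02d", seq_len(ntip)))
  lab <- as.character(round(stats::runif(tree$Nnode, 0, 100), 1))
  lab[stats::runif(tree$Nnode) < blankFrac] <- ""
  tree$node.label <- lab
  list(tree = tree, experiment = IncidenceExperiment(m, samples))
}

## mirrored 3-tip host/symbiont trees with one-to-one links
mirroredInstance <- function() {
  host <- readNewickTree(text = "((h1:1,h2:1):2,h3:3);", kind = "host")
  symb <- ape::read.tree(text = "((s1:1,s2:1):2,s3:3);")
  A <- matrix(0L, 3, 3, dimnames = list(paste0("s", 1:3), paste0("h", 1:3)))
  diag(A) <- 1L
  list(host = host, symb = symb, assoc = A,
       hostD = patristicMatrix(host), symbD = patristicMatrix(symb))
}
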