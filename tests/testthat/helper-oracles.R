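## Independent oracles used to check the package implementations. These are
## deliberately written with different mechanics (phangorn descendant lists,
## explicit loops, full enumeration) than the package code paths they verify.

## Brute-force clade scan: evaluate the acceptance predicate at EVERY internal
## node, keep candidates with no candidate ancestor in the same pass
## (explicit maximality filtering), consume tips between passes.
bruteForceClades <- function(tree, cls, inc, config) {
  nt <- length(tree$tip.label)
  nodes <- (nt + 1L):(nt + tree$Nnode)
  desc <- phangorn::Descendants(tree, nodes, type = "tips")
  anc <- phangorn::Ancestors(tree, nodes, type = "all")
  sup <- nodeSupport(tree)
  sup[is.na(sup)] <- 0
  cat <- cls[tree$tip.label, "category"]
  host <- cls[tree$tip.label, "restricted_host"]
  prof <- cls[tree$tip.label, "wild_profile"]
  consumed <- logical(nt)
  out <- list()
  for (pass in c("host_restricted", "mixed_host", "unique_to_captive")) {
    ok <- vapply(seq_along(nodes), function(i) {
      ut <- desc[[i]][!consumed[desc[[i]]]]
      if (length(ut) < 2L) return(FALSE)
      if (pass == "host_restricted") {
        if (!all(cat[ut] == "host_restricted")) return(FALSE)
        if (length(unique(host[ut])) != 1L) return(FALSE)
      } else if (pass == "mixed_host") {
        if (length(unique(unlist(prof[ut]))) < 2L) return(FALSE)
      } else {
        if (!all(cat[ut] == "unique_to_captive")) return(FALSE)
      }
      if (!(sup[i] > config@minSupport)) return(FALSE)
      n_ind <- sum(colSums(inc[tree$tip.label[ut], , drop = FALSE]) > 0L)
      n_ind >= config@minIndividuals
    }, logical(1L))
    cand <- nodes[ok]
    for (nd in cand) {
      if (any(anc[[match(nd, nodes)]] %in% cand)) next # not maximal
      ut <- desc[[match(nd, nodes)]]
      ut <- ut[!consumed[ut]]
      consumed[ut] <- TRUE
      out[[length(out) + 1L]] <- list(
        category = pass,
        members = sort(tree$tip.label[ut]),
        host = if (pass == "host_restricted") unique(host[ut]) else NA_character_)
    }
  }
  out
}

## canonical string form of a clade list for set comparison
cladeKey <- function(category, host, members)
  paste(category, ifelse(is.na(host), "-", host),
        vapply(members, paste, character(1L), collapse = ","))

cladeSetKeys <- function(cs)
  sort(cladeKey(cladeTable(cs)$category, cladeTable(cs)$host_species,
                cladeMembers(cs)))

bruteKeys <- function(bf)
  sort(cladeKey(vapply(bf, `[[`, character(1L), "category"),
                vapply(bf, `[[`, character(1L), "host"),
                lapply(bf, `[[`, "members")))

## all permutations of 1..n (n small)
allPerms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in allPerms(n - 1L))
    for (k in 0:(n - 1L))
      out[[length(out) + 1L]] <- append(p, n, after = k)
  out
}

## Exact Hommola permutation null by full enumeration of all relabelings of
## hosts and symbionts; returns the exact p (fraction of relabelings with
## r >= observed r, identity included) and the observed r.
exhaustiveHommola <- function(hD, sD, A) {
  w <- which(A == 1, arr.ind = TRUE)
  hIdx <- match(colnames(A), rownames(hD))[w[, 2L]]
  sIdx <- match(rownames(A), rownames(sD))[w[, 1L]]
  nL <- nrow(w)
  rFor <- function(ph, ps) {
    x <- c(); y <- c()
    for (i in 1:(nL - 1L)) for (j in (i + 1L):nL) {
      x <- c(x, sD[ps[sIdx[i]], ps[sIdx[j]]])
      y <- c(y, hD[ph[hIdx[i]], ph[hIdx[j]]])
    }
    stats::cor(x, y)
  }
  idH <- seq_len(nrow(hD)); idS <- seq_len(nrow(sD))
  robs <- rFor(idH, idS)
  rall <- c()
  for (ph in allPerms(nrow(hD)))
    for (ps in allPerms(nrow(sD)))
      rall <- c(rall, rFor(ph, ps))
  list(r = robs, rall = rall, pExact = mean(rall >= robs))
}
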