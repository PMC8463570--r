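## Pairwise Sorenson ASV sharing between individuals, stratified by
## enclosure/site/species relationship, with permutation t-tests.

#' Sorenson similarity of two presence sets
#'
#' `2|A intersect B| / (|A| + |B|)` on sets of ASV ids.
#'
#' @param a,b character vectors of ASV ids (duplicates ignored); at least one
#'   must be non-empty.
#' @return similarity in \[0, 1\].
#' @examples
#' sorensonIndex(c("a", "b", "c"), c("b", "c", "d")) # 4/6
#' @export
sorensonIndex <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (!length(a) && !length(b))
    stop("Sorenson similarity is undefined for two empty sets")
  2 * length(intersect(a, b)) / (length(a) + length(b))
}

.RELATIONSHIPS <- c("same_enclosure", "same_site_diff_enclosure",
                    "same_species_diff_site", "diff_species_diff_site")

## four-way relationship rule (enclosure nested within site)
.pairRelationship <- function(sp1, sp2, site1, site2, enc1, enc2) {
  sameSite <- !is.na(site1) & !is.na(site2) & site1 == site2
  sameEnc <- sameSite & !is.na(enc1) & !is.na(enc2) & enc1 == enc2
  ifelse(sameEnc, "same_enclosure",
         ifelse(sameSite, "same_site_diff_enclosure",
                ifelse(sp1 == sp2, "same_species_diff_site",
                       "diff_species_diff_site")))
}

#' Pairwise ASV sharing between individuals
#'
#' Computes the Sorenson similarity of the ASV presence sets of every
#' unordered pair of in-scope samples and labels each pair with its
#' relationship: `same_enclosure`, `same_site_diff_enclosure`,
#' `same_species_diff_site` or `diff_species_diff_site` (enclosure is nested
#' within site). The default scope is captive individuals, matching the
#' comparisons reported for zoo apes; pairs spanning lifestyles are then
#' excluded by construction.
#'
#' @param experiment an [IncidenceExperiment].
#' @param scope `"captive"` (default) or `"all"`.
#' @return `data.frame` with one row per unordered pair: `sample_a`,
#'   `sample_b`, `sorenson`, `relationship`.
#' @export
pairwiseSharing <- function(experiment, scope = c("captive", "all")) {
  stopifnot(is(experiment, "IncidenceExperiment"))
  scope <- match.arg(scope)
  samples <- sampleData(experiment)
  sel <- if (scope == "captive")
    which(as.character(samples$lifestyle) == "captive")
  else seq_len(nrow(samples))
  if (length(sel) < 2L) stop("need >= 2 samples in scope")
  inc <- incidence(experiment)[, sel, drop = FALSE]
  ids <- colnames(inc)
  sets <- lapply(seq_along(ids), function(j) rownames(inc)[inc[, j] > 0L])
  pr <- utils::combn(length(ids), 2L)
  i <- pr[1L, ]; j <- pr[2L, ]
  sor <- vapply(seq_len(ncol(pr)), function(k) {
    if (!length(sets[[i[k]]]) && !length(sets[[j[k]]])) return(NA_real_)
    sorensonIndex(sets[[i[k]]], sets[[j[k]]])
  }, numeric(1L))
  if (anyNA(sor))
    warning("pair(s) of samples with empty ASV sets: similarity set to NA")
  sp <- as.character(samples$host_species)[sel]
  site <- as.character(samples$site)[sel]
  enc <- as.character(samples$enclosure)[sel]
  data.frame(sample_a = ids[i], sample_b = ids[j], sorenson = sor,
             relationship = .pairRelationship(sp[i], sp[j], site[i], site[j],
                                              enc[i], enc[j]),
             stringsAsFactors = FALSE)
}

## pooled-variance two-sample t; 0/0 (identical groups with zero spread) is 0,
## nonzero difference with zero spread is signed Inf
.tStatistic <- function(v1, v2) {
  n1 <- length(v1); n2 <- length(v2)
  md <- mean(v1) - mean(v2)
  sp2 <- (sum((v1 - mean(v1))^2) + sum((v2 - mean(v2))^2)) / (n1 + n2 - 2L)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  if (se == 0) {
    if (md == 0) 0 else sign(md) * Inf
  } else md / se
}

#' Two-sided permutation t-test
#'
#' Computes the pooled-variance two-sample t statistic and builds its null by
#' permuting the group labels over the observations, with a two-sided add-one
#' empirical p-value `(1 + #\{|t*| >= |t|\}) / (1 + nPerm)`. When the
#' observations are non-independent pair rows derived from samples, use
#' [pairSharingTests()], which permutes sample-level identities instead.
#'
#' @param values numeric observations.
#' @param groups two-level factor (or character), each level with >= 2 values.
#' @param nPerm number of permutations.
#' @return `htest`-like list with `statistic`, `p.value`, `nPerm`.
#' @examples
#' set.seed(1)
#' permutationTTest(c(rnorm(8), rnorm(8, 2)), rep(c("a", "b"), each = 8),
#'                  nPerm = 199)$p.value
#' @export
permutationTTest <- function(values, groups, nPerm = 999L) {
  groups <- as.character(groups)
  lev <- unique(groups)
  if (length(lev) != 2L) stop("need exactly two groups")
  g1 <- groups == lev[1L]
  if (sum(g1) < 2L || sum(!g1) < 2L) stop("each group needs >= 2 values")
  tobs <- .tStatistic(values[g1], values[!g1])
  tnull <- numeric(nPerm)
  for (b in seq_len(nPerm)) {
    gp <- sample(g1)
    tnull[b] <- .tStatistic(values[gp], values[!gp])
  }
  p <- (1 + sum(abs(tnull) >= abs(tobs))) / (1 + nPerm)
  structure(list(statistic = c(t = tobs), p.value = p, nPerm = nPerm,
                 null = tnull,
                 method = "two-sided permutation t-test (label permutation)",
                 data.name = deparse(substitute(values))),
            class = "htest")
}

.DEFAULT_COMPARISONS <- list(
  c("same_enclosure", "same_site_diff_enclosure"),
  c("same_enclosure", "same_species_diff_site"),
  c("same_enclosure", "diff_species_diff_site"),
  c("same_site_diff_enclosure", "diff_species_diff_site"),
  c("same_species_diff_site", "diff_species_diff_site"))

#' Permutation t-tests over pair-sharing relationship groups
#'
#' For each comparison of two relationship classes, computes the pooled t
#' statistic between the Sorenson values of the two classes and a permutation
#' null that permutes SAMPLE-level identities -- each sample is dealt another
#' sample's (species, site, enclosure) attributes and the pair relationships
#' are recomputed -- which respects the non-independence of pair rows.
#' Comparisons that isolate the enclosure effect (both classes within the same
#' site) permute enclosure assignments within each site (restricted
#' permutations); all other comparisons permute the full attribute tuples over
#' the in-scope samples. Raw p-values are Bonferroni-corrected across the
#' family of comparisons.
#'
#' @param experiment an [IncidenceExperiment].
#' @param comparisons list of length-2 character vectors of relationship
#'   classes; defaults to the enclosure/site/species family.
#' @param nPerm number of permutations.
#' @param scope passed to [pairwiseSharing()].
#' @return `data.frame` with columns `group_a`, `group_b`, `n_a`, `n_b`, `t`,
#'   `p`, `p_bonferroni`.
#' @export
pairSharingTests <- function(experiment, comparisons = .DEFAULT_COMPARISONS,
                             nPerm = 999L, scope = "captive") {
  stopifnot(is(experiment, "IncidenceExperiment"))
  sharing <- pairwiseSharing(experiment, scope = scope)
  samples <- sampleData(experiment)
  ids <- unique(c(sharing$sample_a, sharing$sample_b))
  attr0 <- data.frame(
    species = as.character(samples[ids, "host_species"]),
    site = as.character(samples[ids, "site"]),
    enclosure = as.character(samples[ids, "enclosure"]),
    row.names = ids, stringsAsFactors = FALSE)
  ia <- match(sharing$sample_a, ids)
  ib <- match(sharing$sample_b, ids)
  ok <- !is.na(sharing$sorenson)
  val <- sharing$sorenson

  relOf <- function(attr) {
    .pairRelationship(attr$species[ia], attr$species[ib],
                      attr$site[ia], attr$site[ib],
                      attr$enclosure[ia], attr$enclosure[ib])
  }
  tFor <- function(rel, cmp) {
    v1 <- val[ok & rel == cmp[1L]]
    v2 <- val[ok & rel == cmp[2L]]
    if (length(v1) < 2L || length(v2) < 2L) return(NA_real_)
    .tStatistic(v1, v2)
  }

  out <- lapply(comparisons, function(cmp) {
    cmp <- as.character(cmp)
    if (!all(cmp %in% .RELATIONSHIPS)) stop("unknown relationship class")
    withinSite <- all(cmp %in% c("same_enclosure", "same_site_diff_enclosure"))
    rel0 <- relOf(attr0)
    tobs <- tFor(rel0, cmp)
    if (is.na(tobs))
      stop("comparison ", paste(cmp, collapse = " vs "),
           ": a group has fewer than 2 pairs")
    tnull <- numeric(nPerm)
    for (b in seq_len(nPerm)) {
      attrP <- attr0
      if (withinSite) {
        for (s in unique(attr0$site[!is.na(attr0$site)])) {
          w <- which(!is.na(attr0$site) & attr0$site == s)
          attrP$enclosure[w] <- attr0$enclosure[w[sample.int(length(w))]]
        }
      } else {
        pm <- sample.int(nrow(attr0))
        attrP <- attr0[pm, , drop = FALSE]
      }
      tnull[b] <- tFor(relOf(attrP), cmp)
    }
    hit <- abs(tnull) >= abs(tobs)
    hit[is.na(tnull)] <- TRUE # conservative: degenerate permutations count
    data.frame(group_a = cmp[1L], group_b = cmp[2L],
               n_a = sum(ok & rel0 == cmp[1L]), n_b = sum(ok & rel0 == cmp[2L]),
               t = tobs, p = (1 + sum(hit)) / (1 + nPerm),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$p_bonferroni <- pmin(1, out$p * nrow(out))
  out
}
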