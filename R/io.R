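## Readers/writers for the standard formats the pipeline touches: newick for
## trees (via ape), TSV for incidence, sample metadata and clade tables.

#' Read a phylogeny from a newick file
#'
#' Parses a rooted newick tree with `ape::read.tree` and validates it as
#' either a symbiont tree (ASV tips, branch lengths >= 0, internal-node labels
#' interpreted as bootstrap support in \[0, 100\]) or a host tree (ultrametric
#' divergence-time tree, tolerance 1e-6 relative). Numeric internal labels on
#' a 0--1 scale are auto-rescaled to 0--100 (both support dialects occur in
#' the wild; thresholds are quoted on the 0--100 scale). Missing labels are
#' recorded as `NA` support and treated as 0 by the clade scan.
#'
#' @param path file path, or a newick string via `text`.
#' @param kind `"symbiont"` or `"host"`.
#' @param text optional newick string, used instead of `path`.
#' @return an `ape::phylo` object.
#' @seealso [nodeSupport()]
#' @examples
#' tr <- readNewickTree(text = "((a:1,b:1)90:1,c:2);")
#' nodeSupport(tr)
#' @export
readNewickTree <- function(path, kind = c("symbiont", "host"), text = NULL) {
  kind <- match.arg(kind)
  tree <- if (is.null(text)) {
    if (!file.exists(path)) stop("file not found: ", path)
    tryCatch(ape::read.tree(path),
             error = function(e) stop("newick parse error in '", path, "': ",
                                      conditionMessage(e), call. = FALSE))
  } else {
    tryCatch(ape::read.tree(text = text),
             error = function(e) stop("newick parse error: ",
                                      conditionMessage(e), call. = FALSE))
  }
  if (is.null(tree)) stop("newick parse error: no tree found")
  if (kind == "symbiont") .checkSymbiontTree(tree) else .checkHostTree(tree)
  tree
}

.checkTipLabels <- function(tree) {
  if (any(!nzchar(tree$tip.label)))
    stop("tree has empty tip labels")
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup))
    stop("duplicate tip labels: ", paste(utils::head(dup, 5L), collapse = ", "))
  invisible(TRUE)
}

.checkSymbiontTree <- function(tree) {
  .checkTipLabels(tree)
  if (!ape::is.rooted(tree)) stop("symbiont tree must be rooted")
  if (is.null(tree$edge.length))
    stop("symbiont tree must have branch lengths")
  if (any(tree$edge.length < 0))
    stop("negative branch lengths in symbiont tree")
  sup <- nodeSupport(tree)
  if (any(!is.na(sup) & (sup < 0 | sup > 100)))
    stop("support values outside [0, 100]")
  invisible(TRUE)
}

.checkHostTree <- function(tree, tol = 1e-6) {
  .checkTipLabels(tree)
  if (!ape::is.rooted(tree)) stop("host tree must be rooted")
  if (is.null(tree$edge.length)) stop("host tree must have branch lengths")
  if (!ape::is.ultrametric(tree, tol = tol, option = 2))
    stop("host tree is not ultrametric (divergence-time tree expected)")
  invisible(TRUE)
}

#' Bootstrap support values of internal nodes
#'
#' Interprets internal-node labels as bootstrap support. Non-numeric or
#' missing labels give `NA`. When every numeric label is at most 1 the values
#' are taken to be on a 0--1 scale and rescaled by 100.
#'
#' @param tree an `ape::phylo` object.
#' @return numeric vector of length `tree$Nnode` (support per internal node,
#'   in node-number order), `NA` where absent.
#' @export
nodeSupport <- function(tree) {
  n <- tree$Nnode
  if (is.null(tree$node.label)) return(rep(NA_real_, n))
  lab <- tree$node.label
  lab[!nzchar(lab)] <- NA_character_
  sup <- suppressWarnings(as.numeric(lab))
  ok <- !is.na(sup)
  if (any(ok) && all(sup[ok] <= 1) && all(sup[ok] >= 0))
    sup[ok] <- sup[ok] * 100
  sup
}

#' Read a binary incidence matrix from TSV
#'
#' Expects a header row of sample ids and a first column of ASV ids. Numeric
#' entries are binarized as `value > 0` (counts become presence/absence).
#' All-zero ASV rows are rejected, naming the offending ASVs.
#'
#' @param path TSV file path.
#' @return integer 0/1 matrix with ASV row names and sample column names.
#' @seealso [writeIncidence()], [IncidenceExperiment()]
#' @export
readIncidence <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, row.names = 1L)
  m <- as.matrix(tab)
  if (!is.numeric(m))
    stop("non-numeric incidence entries in ", path)
  if (anyNA(m)) stop("missing incidence entries in ", path)
  if (any(m < 0)) stop("negative incidence entries in ", path)
  storage.mode(m) <- "integer"
  m[m > 0L] <- 1L
  zero <- rownames(m)[rowSums(m) == 0L]
  if (length(zero))
    stop("ASV row(s) with no presence: ",
         paste(utils::head(zero, 5L), collapse = ", "))
  if (anyDuplicated(rownames(m))) stop("duplicated ASV ids")
  if (anyDuplicated(colnames(m))) stop("duplicated sample ids")
  m
}

#' @rdname readIncidence
#' @param m binary matrix as returned by `readIncidence`.
#' @param path output TSV path.
#' @export
writeIncidence <- function(m, path) {
  df <- data.frame(asv_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata from TSV
#'
#' Requires columns `sample_id`, `host_species`, `lifestyle`, `site`,
#' `enclosure`, `study`. Host species must be one of bonobo, chimpanzee,
#' gorilla, orangutan, human; lifestyle one of wild, captive, industrialized,
#' non_industrialized (the last two for humans only). Captive samples must
#' carry a site. Empty strings and `"NA"` are read as missing.
#'
#' @param path TSV file path.
#' @return `data.frame` of validated sample metadata, row names = sample ids.
#' @export
readSampleMetadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           na.strings = c("NA", ""))
  need <- setdiff(.SAMPLE_COLUMNS, colnames(tab))
  if (length(need))
    stop("metadata lacks required column(s): ", paste(need, collapse = ", "))
  tab <- tab[, .SAMPLE_COLUMNS, drop = FALSE]
  if (anyDuplicated(tab$sample_id))
    stop("duplicated sample ids in metadata")
  badsp <- !tab$host_species %in% .HOST_GROUPS
  if (any(badsp))
    stop("unknown host_species in row(s): ",
         paste(utils::head(which(badsp), 5L), collapse = ", "))
  badlf <- !tab$lifestyle %in% .LIFESTYLES |
    (tab$host_species == "human" & !tab$lifestyle %in% .HUMAN_LIFESTYLES) |
    (tab$host_species != "human" & !tab$lifestyle %in% .APE_LIFESTYLES)
  if (any(badlf))
    stop("unknown or illegal lifestyle in row(s): ",
         paste(utils::head(which(badlf), 5L), collapse = ", "))
  nosite <- tab$lifestyle == "captive" & is.na(tab$site)
  if (any(nosite))
    stop("captive sample(s) without a site in row(s): ",
         paste(utils::head(which(nosite), 5L), collapse = ", "))
  rownames(tab) <- tab$sample_id
  tab
}

#' @rdname readSampleMetadata
#' @param samples metadata `data.frame` (or `DataFrame`).
#' @param path output TSV path.
#' @export
writeSampleMetadata <- function(samples, path) {
  samples <- as.data.frame(samples)
  if (!"sample_id" %in% colnames(samples))
    samples <- cbind(sample_id = rownames(samples), samples)
  utils::write.table(samples[, .SAMPLE_COLUMNS, drop = FALSE], path,
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write a clade table to TSV
#'
#' One row per clade: `clade_id`, `category`, `host_species`, `n_asvs`,
#' `support`, `n_individuals`, the member ASVs (semicolon-separated, sorted)
#' and one `prev_<group>` column per sample group. Rows are ordered by
#' `clade_id`, so equal inputs produce byte-identical files.
#'
#' @param clades a [CladeSet].
#' @param path output TSV path.
#' @export
writeCladeTable <- function(clades, path) {
  stopifnot(is(clades, "CladeSet"))
  tab <- cladeTable(clades)
  tab <- cbind(tab[, c("clade_id", "category", "host_species", "n_asvs",
                       "support", "n_individuals"), drop = FALSE],
               member_asvs = vapply(cladeMembers(clades),
                                    function(m) paste(sort(m), collapse = ";"),
                                    character(1L), USE.NAMES = FALSE),
               tab[, grep("^prev_", colnames(tab)), drop = FALSE])
  if (nrow(tab)) tab <- tab[order(tab$clade_id), , drop = FALSE]
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
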