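#' Neighbor-joining gene tree from one locus
#'
#' Builds an unrooted gene tree for up to six representative sequences by
#' neighbor joining on Jukes-Cantor-corrected p-distances,
#' `d = -3/4 log(1 - 4p/3)`. Saturated distances (p >= 0.75) are capped at
#' the correction of p = 0.749 with a warning. Tie handling is made
#' deterministic by presenting taxa to NJ in the order given.
#'
#' @param ds A `mlbc_dataset`.
#' @param locus_id Locus to use.
#' @param taxa Named character vector: names are taxon labels for the tree
#'   tips, values are individual keys present at the locus (>= 4 taxa).
#' @return An unrooted `phylo`, or `NULL` (with a warning) when a pairwise
#'   distance is undefined at this locus.
#' @export
nj_gene_tree <- function(ds, locus_id, taxa) {
  stopifnot(length(taxa) >= 4L, !is.null(names(taxa)))
  if (!locus_id %in% locus_ids(ds)) stop("unknown locus: ", locus_id)
  codes <- ds$loci[[locus_id]]$codes
  absent <- setdiff(taxa, rownames(codes))
  if (length(absent)) {
    warning("locus ", locus_id, " skipped: individual(s) absent: ",
            paste(absent, collapse = ", "))
    return(NULL)
  }
  n <- length(taxa)
  D <- matrix(0, n, n, dimnames = list(names(taxa), names(taxa)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      t <- locus_pair_tally(codes, taxa[[i]], taxa[[j]])
      if (t[["valid"]] == 0L) {
        warning("locus ", locus_id, " skipped: no shared valid sites between ",
                names(taxa)[i], " and ", names(taxa)[j])
        return(NULL)
      }
      D[i, j] <- D[j, i] <- jc_correct(t[["mism"]] / t[["valid"]])
    }
  }
  ape::unroot(ape::nj(D))
}

jc_correct <- function(p) {
  capped <- p >= 0.75
  if (any(capped)) {
    warning("p-distance at or beyond Jukes-Cantor saturation; capped")
    p[capped] <- 0.749
  }
  -0.75 * log(1 - 4 * p / 3)
}

# Topology-only pairwise distances between the given tips (all branch
# lengths 1); rows/cols in `taxa` order.
topo_dist <- function(tree, taxa) {
  t2 <- tree
  t2$edge.length <- rep(1, nrow(t2$edge))
  D <- ape::cophenetic.phylo(t2)
  D[taxa, taxa, drop = FALSE]
}

# Induced quartet splits of a tree, one code per 4-subset of `taxa` in
# combn(n, 4) order: 1 = (1,2|3,4), 2 = (1,3|2,4), 3 = (1,4|2,3),
# 0 = unresolved. Decided by the four-point condition on the topological
# distance matrix: the pairing with the strictly smallest sum is the split.
quartet_codes <- function(tree, taxa) {
  D <- topo_dist(tree, taxa)
  q <- utils::combn(length(taxa), 4L)
  apply(q, 2L, function(s) {
    a <- s[1L]; b <- s[2L]; c <- s[3L]; d <- s[4L]
    sums <- c(D[a, b] + D[c, d], D[a, c] + D[b, d], D[a, d] + D[b, c])
    lo <- which(sums == min(sums))
    if (length(lo) == 1L) lo else 0L
  })
}

#' Exact quartet-amalgamation species tree
#'
#' Enumerates every unrooted topology on the taxon set (15 for five taxa,
#' 105 for six) and scores each by the total number of induced four-taxon
#' subtrees of the gene trees that agree with it — the maximum-quartet-
#' support criterion, solved exactly at this scale rather than
#' heuristically. Ties break on the lexicographically smallest newick
#' string.
#'
#' @param gene_trees List of unrooted `phylo` objects (NULL entries from
#'   skipped loci are dropped). Gene trees missing some taxa contribute only
#'   the quartets they contain.
#' @param taxa Character vector of 4-6 taxon labels (default: union of gene
#'   tree tips).
#' @return A `mlbc_speciestree`: list with `best_topology` (`phylo`),
#'   `quartet_score`, `scores` (tibble of all topologies), `n_gene_trees`,
#'   `taxa`.
#' @export
quartet_species_tree <- function(gene_trees, taxa = NULL) {
  gene_trees <- Filter(Negate(is.null), gene_trees)
  if (length(gene_trees) == 0L) stop("no usable gene trees")
  taxa <- sort(taxa %||% unique(unlist(lapply(gene_trees, `[[`, "tip.label"))))
  if (length(taxa) < 4L) stop("need at least four taxa")
  if (length(taxa) > 6L) stop("exact enumeration supports at most six taxa")
  nq <- choose(length(taxa), 4L)
  # tally of gene-tree quartet codes: nq x 3 counts
  tally <- matrix(0L, nrow = nq, ncol = 3L)
  for (gt in gene_trees) {
    present <- taxa %in% gt$tip.label
    if (sum(present) < 4L) next
    sub <- taxa[present]
    codes <- quartet_codes(gt, sub)
    # map sub-quartets back to the full quartet index
    qs_full <- utils::combn(length(taxa), 4L)
    idx_present <- which(present)
    qs_sub <- utils::combn(idx_present, 4L)
    full_key <- apply(qs_full, 2L, paste, collapse = ".")
    sub_key <- apply(qs_sub, 2L, paste, collapse = ".")
    pos <- match(sub_key, full_key)
    for (k in seq_along(pos)) {
      if (codes[k] > 0L) tally[pos[k], codes[k]] <- tally[pos[k], codes[k]] + 1L
    }
  }
  cands <- phangorn::allTrees(length(taxa), rooted = FALSE, tip.label = taxa)
  scores <- vapply(cands, function(tp) {
    cc <- quartet_codes(tp, taxa)
    sum(tally[cbind(seq_len(nq), cc)])
  }, 0)
  newicks <- vapply(cands, function(tp) ape::write.tree(tp), "")
  best_score <- max(scores)
  tied <- which(scores == best_score)
  best <- tied[order(newicks[tied])][1L]
  structure(
    list(best_topology = cands[[best]], quartet_score = best_score,
         scores = tibble::tibble(topology = newicks, score = scores) |>
           dplyr::arrange(dplyr::desc(.data$score), .data$topology),
         n_gene_trees = length(gene_trees), taxa = taxa),
    class = "mlbc_speciestree"
  )
}

#' @export
print.mlbc_speciestree <- function(x, ...) {
  cat("<quartet species tree> ", length(x$taxa), " taxa, ",
      x$n_gene_trees, " gene trees\n", sep = "")
  cat("  best topology: ", ape::write.tree(x$best_topology), "\n", sep = "")
  cat("  quartet score: ", x$quartet_score, "\n", sep = "")
  invisible(x)
}

#' @export
#' @importFrom generics tidy
tidy.mlbc_speciestree <- function(x, ...) x$scores

#' @export
#' @importFrom generics glance
glance.mlbc_speciestree <- function(x, ...) {
  tibble::tibble(
    n_taxa = length(x$taxa), n_gene_trees = x$n_gene_trees,
    best_topology = ape::write.tree(x$best_topology),
    quartet_score = x$quartet_score,
    max_possible = x$n_gene_trees * choose(length(x$taxa), 4L)
  )
}
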