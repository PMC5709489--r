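# Fixtures are built in code; nothing is read from disk except temp FASTA
# files written by the tests themselves.

# A locus from a named character vector of sequences (names = keys).
toy_locus <- function(locus_id, seqs) {
  codes <- do.call(rbind, lapply(seqs, multibarcode:::encode_seq))
  rownames(codes) <- names(seqs)
  multibarcode:::new_locus(locus_id, codes, seqs = seqs)
}

# Dataset of identical structure: each element of `loci` is a named
# character vector of aligned sequences.
toy_dataset <- function(loci) {
  as_dataset(purrr::imap(loci, function(seqs, id) toy_locus(id, seqs)))
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T", "N", "-"), n,
                                       replace = TRUE,
                                       prob = c(.23, .23, .23, .23, .04, .04)),
                                collapse = "")

# Independent per-site brute-force p-distance oracle (character scan).
pdist_oracle <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  ok <- ca %in% c("A", "C", "G", "T") & cb %in% c("A", "C", "G", "T")
  list(value = sum(ca[ok] != cb[ok]) / sum(ok), valid_sites = sum(ok))
}

# Two species with fixed diagnostic differences at every locus.
diagnostic_dataset <- function(n_loci = 5, n_per_species = 3, len = 60) {
  loci <- lapply(seq_len(n_loci), function(i) {
    base <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
    alt <- base
    substr(alt, 1, 5) <- paste(rep("T", 5), collapse = "")
    substr(base, 1, 5) <- paste(rep("A", 5), collapse = "")
    seqs <- c(
      stats::setNames(rep(base, n_per_species),
                      paste0("spX|x", seq_len(n_per_species))),
      stats::setNames(rep(alt, n_per_species),
                      paste0("spY|y", seq_len(n_per_species)))
    )
    seqs
  })
  names(loci) <- sprintf("loc%02d", seq_len(n_loci))
  toy_dataset(loci)
}

# Quadrature oracle for the between-pair difference distribution: the
# geometric component is an exponential mixture of Poissons, so
# P(K = k) = E_lambda[ dpois(k, 2 tau L + lambda) ], lambda ~ Exp(mean theta_anc L).
between_pmf_oracle <- function(k, L, theta_anc, tau) {
  mean_lam <- theta_anc * L
  vapply(k, function(kk) {
    stats::integrate(function(lam) {
      stats::dpois(kk, 2 * tau * L + lam) * stats::dexp(lam, 1 / mean_lam)
    }, 0, Inf, rel.tol = 1e-10)$value
  }, 0)
}

# Log marginal likelihood oracle for the one-parameter lump model:
# log integral of L(theta) * dexp(theta, 1/mean) over theta.
lump_lnml_oracle <- function(diffs, prior_mean) {
  f <- function(theta) {
    vapply(theta, function(th) {
      exp(pairdiff_loglik(diffs, list(theta_lump = th), "lump")) *
        stats::dexp(th, 1 / prior_mean)
    }, 0)
  }
  log(stats::integrate(f, 0, Inf, rel.tol = 1e-10)$value)
}

# Independent quartet tally: for each 4-subset, derive the gene-tree split
# by pruning with ape and comparing newick shapes, then count agreement
# with the candidate topology.
quartet_score_oracle <- function(gene_trees, topology, taxa) {
  taxa <- sort(taxa)
  quartets <- utils::combn(taxa, 4)
  total <- 0L
  # node-path edge counts, computed from scratch with ape::nodepath
  split_of <- function(tree, q) {
    sub <- ape::keep.tip(tree, q)
    tip <- match(q, sub$tip.label)
    d <- function(i, j) length(ape::nodepath(sub, tip[i], tip[j])) - 1L
    sums <- c(d(1, 2) + d(3, 4), d(1, 3) + d(2, 4), d(1, 4) + d(2, 3))
    lo <- which(sums == min(sums))
    if (length(lo) == 1L) lo else 0L
  }
  for (j in seq_len(ncol(quartets))) {
    q <- quartets[, j]
    ref <- split_of(topology, q)
    for (gt in gene_trees) {
      if (!all(q %in% gt$tip.label)) next
      s <- split_of(gt, q)
      if (s != 0L && s == ref) total <- total + 1L
    }
  }
  total
}
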