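#' Multilocus alignment datasets
#'
#' A `mlbc_dataset` holds one aligned nucleotide matrix per locus over a
#' shared set of labelled individuals (`species|individual`), together with a
#' presence mask recording which individuals were sequenced at which loci.
#' It is the reference "database" against which queries are identified.
#'
#' @name mlbc_dataset
#' @keywords internal
NULL

new_locus <- function(locus_id, codes, seqs = NULL) {
  stopifnot(is.matrix(codes), !is.null(rownames(codes)), nzchar(locus_id))
  structure(
    list(locus_id = locus_id, codes = codes, seqs = seqs),
    class = "mlbc_locus"
  )
}

#' @export
print.mlbc_locus <- function(x, ...) {
  cat("<locus ", x$locus_id, "> ", nrow(x$codes), " sequences x ",
      ncol(x$codes), " sites\n", sep = "")
  invisible(x)
}

#' Assemble a multilocus dataset from per-locus alignments
#'
#' Takes a list of loci (as returned by [read_locus_fasta()] or produced by
#' the simulator) and builds the dataset: the union of individuals across
#' loci and a presence mask with one flag per (locus, individual).
#'
#' @param loci List of `mlbc_locus` objects with unique locus ids.
#' @return A `mlbc_dataset`.
#' @export
as_dataset <- function(loci) {
  if (length(loci) == 0L) stop("no loci supplied")
  ids <- unname(vapply(loci, function(l) l$locus_id, ""))
  if (anyDuplicated(ids)) {
    stop("duplicate locus id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(loci) <- ids
  keys <- sort(unique(unlist(lapply(loci, function(l) rownames(l$codes)))))
  present <- matrix(FALSE, nrow = length(loci), ncol = length(keys),
                    dimnames = list(ids, keys))
  for (id in ids) present[id, rownames(loci[[id]]$codes)] <- TRUE
  structure(
    list(loci = loci, individuals = split_key(keys), present = present),
    class = "mlbc_dataset"
  )
}

#' @export
print.mlbc_dataset <- function(x, ...) {
  sp <- unique(x$individuals$species)
  cat("<multilocus dataset> ", length(x$loci), " loci, ",
      nrow(x$individuals), " individuals, ", length(sp), " species\n",
      sep = "")
  cat("  completeness: ", round(100 * mean(x$present), 1), "% of (locus x individual) cells\n",
      sep = "")
  invisible(x)
}

#' @export
summary.mlbc_dataset <- function(object, ...) {
  tibble::tibble(
    locus_id = rownames(object$present),
    length = vapply(object$loci, function(l) ncol(l$codes), 0L),
    n_present = rowSums(object$present),
    n_missing = ncol(object$present) - rowSums(object$present)
  )
}

locus_ids <- function(ds) rownames(ds$present)

#' Read one locus alignment from FASTA
#'
#' Headers must be of the form `species|individual`. All records must have
#' the same aligned length. Characters outside `A`, `C`, `G`, `T` (e.g. `N`,
#' `-`) are kept but treated as missing in distance computations (pairwise
#' deletion).
#'
#' @param path Path to a FASTA file.
#' @param locus_id Locus identifier; defaults to the file name without
#'   extension.
#' @return A `mlbc_locus`.
#' @export
read_locus_fasta <- function(path, locus_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  locus_id <- locus_id %||% sub("\\.(fa|fasta|fas)$", "", basename(path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA: ", path)
  widths <- Biostrings::width(set)
  if (length(unique(widths)) != 1L) {
    stop("ragged alignment in ", path, ": lengths ",
         paste(unique(widths), collapse = ", "))
  }
  headers <- names(set)
  bad <- !grepl("|", headers, fixed = TRUE)
  if (any(bad)) {
    stop("malformed header (expected 'species|individual') in record(s): ",
         paste(headers[bad], collapse = ", "))
  }
  seqs <- as.character(set)
  names(seqs) <- headers
  if (anyDuplicated(headers)) {
    stop("duplicate individual header(s) in ", path, ": ",
         paste(unique(headers[duplicated(headers)]), collapse = ", "))
  }
  codes <- do.call(rbind, lapply(seqs, encode_seq))
  rownames(codes) <- headers
  new_locus(locus_id, codes, seqs = seqs)
}

#' Load a directory of per-locus FASTA files as a dataset
#'
#' @param dir Directory containing `<locus_id>.fasta` files.
#' @param pattern Filename pattern for locus files.
#' @return A `mlbc_dataset` whose individuals are the union across loci,
#'   with the missing mask set where an individual is absent from a locus.
#' @export
load_dataset <- function(dir, pattern = "\\.(fa|fasta|fas)$") {
  files <- list.files(dir, pattern = pattern, full.names = TRUE)
  if (length(files) == 0L) stop("no FASTA files found in ", dir)
  as_dataset(lapply(files, read_locus_fasta))
}

#' Write a dataset as per-locus FASTA files
#'
#' Inverse of [load_dataset()]; emits one `<locus_id>.fasta` per locus with
#' `species|individual` headers, plus a YAML manifest recording provenance.
#'
#' @param ds A `mlbc_dataset`.
#' @param dir Output directory (created if absent).
#' @param manifest Optional named list stored alongside as `manifest.yml`.
#' @return `dir`, invisibly.
#' @export
write_dataset_fasta <- function(ds, dir, manifest = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (l in ds$loci) {
    seqs <- l$seqs %||% vapply(seq_len(nrow(l$codes)),
                               function(i) decode_codes(l$codes[i, ]), "")
    names(seqs) <- rownames(l$codes)
    Biostrings::writeXStringSet(Biostrings::BStringSet(seqs),
                                file.path(dir, paste0(l$locus_id, ".fasta")))
  }
  if (!is.null(manifest)) {
    yaml::write_yaml(manifest, file.path(dir, "manifest.yml"))
  }
  invisible(dir)
}

#' Uncorrected p-distance between two aligned sequences
#'
#' The proportion of mismatching sites among valid sites, where a site is
#' valid iff both characters are one of `A`, `C`, `G`, `T` (pairwise
#' deletion of gaps, `N` and ambiguity codes). Symmetric in its arguments.
#'
#' @param a,b Aligned nucleotide strings of equal length.
#' @return A list of class `pdist` with elements `value` (fraction in
#'   \[0, 1\]) and `valid_sites` (number of columns compared).
#' @examples
#' p_distance("ACGT", "ACGA")  # 0.25 over 4 sites
#' p_distance("AC-T", "ACGT")  # 0 over 3 sites: the gap column is dropped
#' @export
p_distance <- function(a, b) {
  if (nchar(a) != nchar(b)) {
    stop("sequences differ in length (", nchar(a), " vs ", nchar(b), ")")
  }
  pdist_from_codes(encode_seq(a), encode_seq(b))
}

pdist_from_codes <- function(xa, xb) {
  valid <- !is.na(xa) & !is.na(xb)
  n <- sum(valid)
  if (n == 0L) stop("undefined p-distance: no valid (A/C/G/T vs A/C/G/T) sites")
  mism <- sum(xa[valid] != xb[valid])
  structure(list(value = mism / n, valid_sites = n), class = "pdist")
}

#' @export
print.pdist <- function(x, ...) {
  cat("p-distance ", format(x$value, digits = 4), " over ", x$valid_sites,
      " valid sites\n", sep = "")
  invisible(x)
}

# Per-locus (mismatch, valid) tally for one pair of row indices.
locus_pair_tally <- function(codes, i, j) {
  xa <- codes[i, ]
  xb <- codes[j, ]
  valid <- !is.na(xa) & !is.na(xb)
  c(mism = sum(xa[valid] != xb[valid]), valid = sum(valid))
}

#' Concatenated p-distance across loci
#'
#' Equivalent to [p_distance()] on the physical concatenation of the listed
#' loci: total mismatches over total valid sites, restricted to loci where
#' both individuals are present.
#'
#' @param ds A `mlbc_dataset`.
#' @param loci Character vector of locus ids.
#' @param a,b Individual keys (`"species|individual"`).
#' @return A `pdist`.
#' @export
concat_distance <- function(ds, loci, a, b) {
  missing_loci <- setdiff(loci, locus_ids(ds))
  if (length(missing_loci)) {
    stop("unknown locus id(s): ", paste(missing_loci, collapse = ", "))
  }
  mism <- 0L
  valid <- 0L
  shared <- FALSE
  for (id in loci) {
    if (!ds$present[id, a] || !ds$present[id, b]) next
    shared <- TRUE
    t <- locus_pair_tally(ds$loci[[id]]$codes, a, b)
    mism <- mism + t[["mism"]]
    valid <- valid + t[["valid"]]
  }
  if (!shared) stop("individuals ", a, " and ", b, " share no listed locus")
  if (valid == 0L) stop("undefined p-distance: no valid sites across loci")
  structure(list(value = mism / valid, valid_sites = valid), class = "pdist")
}

#' Keep only loci complete for a set of individuals
#'
#' Retains exactly the loci at which every listed individual is present;
#' used to build a no-missing-data locus set before ranking and resampling.
#'
#' @param ds A `mlbc_dataset`.
#' @param individuals Character vector of individual keys (non-empty).
#' @return A `mlbc_dataset` restricted to the complete loci.
#' @export
filter_by_missing <- function(ds, individuals) {
  stopifnot(length(individuals) > 0L)
  unknown <- setdiff(individuals, ds$individuals$key)
  if (length(unknown)) stop("unknown individual(s): ", paste(unknown, collapse = ", "))
  keep <- rownames(ds$present)[rowSums(!ds$present[, individuals, drop = FALSE]) == 0L]
  if (length(keep) == 0L) {
    warning("no locus is complete for all listed individuals; empty dataset returned")
    out <- ds
    out$loci <- ds$loci[character(0)]
    out$present <- ds$present[character(0), , drop = FALSE]
    return(out)
  }
  out <- ds
  out$loci <- ds$loci[keep]
  out$present <- ds$present[keep, , drop = FALSE]
  out
}

# Mean p-distance over all present pairs at each locus (NA if < 2 present).
locus_mean_pdist <- function(ds) {
  vapply(locus_ids(ds), function(id) {
    codes <- ds$loci[[id]]$codes
    n <- nrow(codes)
    if (n < 2L) return(NA_real_)
    d <- numeric(0)
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        t <- locus_pair_tally(codes, i, j)
        if (t[["valid"]] > 0L) d <- c(d, t[["mism"]] / t[["valid"]])
      }
    }
    if (length(d) == 0L) NA_real_ else mean(d)
  }, 0)
}

#' Rank loci by average p-distance
#'
#' Sorts loci by their mean pairwise p-distance over all present individual
#' pairs, most divergent first — the screen used to spot outlier loci and to
#' pick informative markers. Ties break by locus id so the ranking is
#' reproducible regardless of input order.
#'
#' @param ds A `mlbc_dataset`.
#' @return A tibble `locus_id`, `mean_p_distance`, `n_missing`, sorted
#'   descending by divergence. Loci with fewer than two present individuals
#'   are excluded with a warning.
#' @export
rank_loci_by_divergence <- function(ds) {
  md <- locus_mean_pdist(ds)
  excl <- names(md)[is.na(md)]
  if (length(excl)) {
    warning("excluding ", length(excl),
            " locus/loci with <2 present individuals or no valid pairs")
  }
  tibble::tibble(
    locus_id = unname(locus_ids(ds)),
    mean_p_distance = unname(md),
    n_missing = unname(ncol(ds$present) - rowSums(ds$present))
  ) |>
    dplyr::filter(!is.na(.data$mean_p_distance)) |>
    dplyr::arrange(dplyr::desc(.data$mean_p_distance), .data$locus_id)
}

#' Select a barcoding marker panel
#'
#' Two-stage selection: first keep the `n_low_missing` loci with the fewest
#' missing individuals (ties: higher mean p-distance, then locus id), then
#' keep the `n_panel` of those with the largest mean p-distance (ties:
#' locus id).
#'
#' @param ds A `mlbc_dataset` with at least `n_panel` rankable loci.
#' @param n_low_missing Size of the low-missing-data pool (default 750).
#' @param n_panel Final panel size (default 500).
#' @return Character vector of `n_panel` locus ids.
#' @export
select_panel <- function(ds, n_low_missing = 750, n_panel = 500) {
  if (n_panel > n_low_missing) stop("n_panel (", n_panel,
                                    ") exceeds n_low_missing (", n_low_missing, ")")
  rk <- suppressWarnings(rank_loci_by_divergence(ds))
  if (nrow(rk) < n_panel) {
    stop("dataset has ", nrow(rk), " rankable loci; ", n_panel, " requested")
  }
  pool <- rk |>
    dplyr::arrange(.data$n_missing, dplyr::desc(.data$mean_p_distance),
                   .data$locus_id) |>
    dplyr::slice_head(n = n_low_missing)
  pool |>
    dplyr::arrange(dplyr::desc(.data$mean_p_distance), .data$locus_id) |>
    dplyr::slice_head(n = n_panel) |>
    dplyr::pull("locus_id")
}

#' Randomly sample locus ids
#'
#' Uniform sampling without replacement, reproducible under `seed`.
#'
#' @param ds A `mlbc_dataset`.
#' @param n Number of loci to draw.
#' @param seed Integer seed (NULL uses the current RNG stream).
#' @return Character vector of locus ids.
#' @export
sample_loci <- function(ds, n, seed = NULL) {
  ids <- locus_ids(ds)
  if (n > length(ids)) {
    stop("cannot sample ", n, " loci from ", length(ids))
  }
  with_seed_(seed, sample(ids, n))
}

# ---- internal tally arrays used by the resampling machinery ----

# All unordered pairs among `keys` (defaults to all individuals), with
# per-locus mismatch and valid-site counts as (n_loci x n_pairs) matrices.
# Absent (locus, individual) combinations contribute (0, 0) so that column
# sums over sampled loci give concatenated tallies directly.
dataset_tallies <- function(ds, keys = NULL) {
  keys <- keys %||% ds$individuals$key
  info <- split_key(keys)
  n <- length(keys)
  if (n < 2L) stop("need at least two individuals")
  pr <- utils::combn(n, 2L)
  npair <- ncol(pr)
  ids <- locus_ids(ds)
  mism <- matrix(0, nrow = length(ids), ncol = npair, dimnames = list(ids, NULL))
  valid <- matrix(0, nrow = length(ids), ncol = npair, dimnames = list(ids, NULL))
  pair_idx <- cbind(pr[1L, ], pr[2L, ])
  for (id in ids) {
    codes <- ds$loci[[id]]$codes
    # rows in `keys` order; indexing with NA (absent individual) gives an
    # all-NA row, which contributes (0, 0) tallies
    C <- codes[match(keys, rownames(codes)), , drop = FALSE]
    P <- !is.na(C)
    V <- tcrossprod(P)
    M <- matrix(0, n, n)
    for (b in 1:4) {
      A <- C == b
      A[is.na(A)] <- FALSE
      M <- M + tcrossprod(A)
    }
    valid[id, ] <- V[pair_idx]
    mism[id, ] <- V[pair_idx] - M[pair_idx]
  }
  pairs <- tibble::tibble(
    i = pr[1L, ], j = pr[2L, ],
    key_a = keys[pr[1L, ]], key_b = keys[pr[2L, ]],
    species_a = info$species[pr[1L, ]], species_b = info$species[pr[2L, ]],
    intra = info$species[pr[1L, ]] == info$species[pr[2L, ]]
  )
  list(mism = mism, valid = valid, pairs = pairs, keys = keys)
}

# Concatenated pairwise distances for a set of locus ids, from tallies.
tally_distances <- function(tal, loci) {
  m <- colSums(tal$mism[loci, , drop = FALSE])
  v <- colSums(tal$valid[loci, , drop = FALSE])
  ifelse(v > 0L, m / v, NA_real_)
}

#' Remove individuals from a dataset
#'
#' Drops the listed individuals from every locus and from the presence mask
#' — e.g. to exclude a query's conspecifics from the reference database.
#'
#' @param ds A `mlbc_dataset`.
#' @param keys Individual keys to remove.
#' @return A `mlbc_dataset`.
#' @export
drop_individuals <- function(ds, keys) {
  keep <- setdiff(ds$individuals$key, keys)
  if (length(keep) == 0L) stop("cannot remove every individual")
  out <- ds
  out$individuals <- ds$individuals[ds$individuals$key %in% keep, ]
  out$present <- ds$present[, keep, drop = FALSE]
  out$loci <- lapply(ds$loci, function(l) {
    rows <- intersect(rownames(l$codes), keep)
    l$codes <- l$codes[rows, , drop = FALSE]
    if (!is.null(l$seqs)) l$seqs <- l$seqs[rows]
    l
  })
  out
}

#' Mask loci of one individual as missing
#'
#' Removes the individual's sequence at the listed loci (the individual
#' itself stays in the dataset) — the missing-data treatment used to test
#' robustness of identification when a query lacks part of the panel.
#'
#' @param ds A `mlbc_dataset`.
#' @param individual Individual key.
#' @param loci Locus ids to blank out.
#' @return A `mlbc_dataset`.
#' @export
mask_individual_loci <- function(ds, individual, loci) {
  stopifnot(individual %in% ds$individuals$key)
  out <- ds
  out$present[loci, individual] <- FALSE
  out$loci[loci] <- lapply(out$loci[loci], function(l) {
    rows <- setdiff(rownames(l$codes), individual)
    l$codes <- l$codes[rows, , drop = FALSE]
    if (!is.null(l$seqs)) l$seqs <- l$seqs[rows]
    l
  })
  out
}
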