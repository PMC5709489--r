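#' Rank reference individuals by distance to a query
#'
#' Computes the concatenated p-distance from the query to every other
#' individual over the listed loci and sorts ascending. Exact distance ties
#' are broken conservatively: a heterospecific reference ranks before a
#' conspecific one at the same distance (then by key), which biases against
#' spurious "correct" identifications. References sharing no listed locus
#' with the query are dropped with a warning.
#'
#' @param ds A `mlbc_dataset` (query included).
#' @param query Individual key of the query.
#' @param loci Locus ids to use (default: all).
#' @return A tibble `individual`, `species`, `distance`, `valid_sites`,
#'   ascending, with the query excluded.
#' @export
rank_neighbors <- function(ds, query, loci = locus_ids(ds)) {
  refs <- setdiff(ds$individuals$key, query)
  if (length(refs) == 0L) stop("empty reference set")
  if (!query %in% ds$individuals$key) stop("unknown query: ", query)
  q_species <- split_key(query)$species
  rows <- purrr::map(refs, function(r) {
    d <- tryCatch(concat_distance(ds, loci, query, r), error = function(e) NULL)
    if (is.null(d)) return(NULL)
    info <- split_key(r)
    tibble::tibble(individual = r, species = info$species,
                   distance = d$value, valid_sites = d$valid_sites)
  })
  dropped <- refs[vapply(rows, is.null, TRUE)]
  if (length(dropped)) {
    warning("dropping reference(s) sharing no valid sites with the query: ",
            paste(dropped, collapse = ", "))
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) stop("no reference shares a locus with the query")
  out |>
    dplyr::arrange(.data$distance, .data$species == q_species, .data$individual)
}

#' All-species-barcodes identification
#'
#' The strictest distance criterion: the query is `correct` iff every one of
#' its conspecifics ranks closer than every heterospecific; an exact
#' distance tie between the farthest conspecific and the nearest
#' heterospecific counts as `incorrect` (conservative tie-break). With no
#' conspecific in the references the verdict is `no_id`.
#'
#' @inheritParams rank_neighbors
#' @return A one-row tibble `criterion`, `verdict`, `max_intra`,
#'   `min_inter`.
#' @export
all_species_barcodes <- function(ds, query, loci = locus_ids(ds)) {
  rk <- rank_neighbors(ds, query, loci)
  q_species <- split_key(query)$species
  intra <- rk$distance[rk$species == q_species]
  inter <- rk$distance[rk$species != q_species]
  verdict <- if (length(intra) == 0L) {
    "no_id"
  } else if (length(inter) == 0L || max(intra) < min(inter)) {
    "correct"
  } else {
    "incorrect"
  }
  tibble::tibble(
    criterion = "all_species_barcodes", verdict = verdict,
    max_intra = if (length(intra)) max(intra) else NA_real_,
    min_inter = if (length(inter)) min(inter) else NA_real_
  )
}

# Fraction of individuals correctly identified under all-species-barcodes,
# from a vector of pairwise distances (dataset_tallies() pair order).
# Queries without conspecifics are excluded from the denominator.
asb_success_fraction <- function(dist, pairs) {
  keys <- unique(c(pairs$key_a, pairs$key_b))
  ok <- vapply(keys, function(q) {
    sel <- pairs$key_a == q | pairs$key_b == q
    intra <- dist[sel & pairs$intra]
    inter <- dist[sel & !pairs$intra]
    if (length(intra) == 0L) return(NA)
    if (length(inter) == 0L) return(TRUE)
    if (anyNA(intra) || anyNA(inter)) return(NA)
    max(intra) < min(inter)
  }, NA)
  mean(ok, na.rm = TRUE)
}

#' Identification success rate under locus resampling
#'
#' For each replicate, draws `n_loci` loci without replacement, then treats
#' every individual in turn as a query against all remaining individuals
#' (leave-one-out) under the all-species-barcodes criterion. The rate pools
#' over (individual x replicate).
#'
#' @param ds A `mlbc_dataset`.
#' @param n_loci Loci per replicate.
#' @param n_reps Replicates (default 200).
#' @param species Optional pair of species labels to restrict to.
#' @param seed Integer seed.
#' @return A tibble `n_loci`, `success_rate`, `mc_se`, `n_reps`.
#' @export
success_rate <- function(ds, n_loci, n_reps = 200, species = NULL, seed = NULL) {
  keys <- ds$individuals$key
  if (!is.null(species)) {
    keys <- keys[ds$individuals$species %in% species]
    if (length(keys) < 2L) stop("fewer than two individuals in the selected species")
  }
  tal <- dataset_tallies(ds, keys)
  ids <- locus_ids(ds)
  if (n_loci > length(ids)) stop("n_loci exceeds available loci")
  with_seed_(seed, {
    succ <- vapply(seq_len(n_reps), function(r) {
      idx <- sample.int(length(ids), n_loci)
      asb_success_fraction(tally_distances(tal, idx), tal$pairs)
    }, 0)
    tibble::tibble(n_loci = as.integer(n_loci), success_rate = mean(succ),
                   mc_se = stats::sd(succ) / sqrt(n_reps), n_reps = n_reps)
  })
}

#' Optimize a barcoding distance threshold
#'
#' Scans candidate thresholds (zero plus all midpoints between consecutive
#' sorted observed distances) and returns the one minimizing the cumulative
#' identification error: the number of intraspecific distances above the
#' threshold plus the number of interspecific distances at or below it.
#' Ties go to the smallest threshold.
#'
#' @param intra,inter Numeric vectors of intra- and interspecific distances.
#' @return A one-row tibble `threshold`, `cumulative_error`,
#'   `false_negative` (intra > T), `false_positive` (inter <= T).
#' @export
optimize_threshold <- function(intra, inter) {
  if (length(intra) == 0L || length(inter) == 0L) {
    stop("both intra- and interspecific distances are required")
  }
  obs <- sort(unique(c(intra, inter)))
  cand <- c(0, if (length(obs) > 1L) (obs[-1L] + obs[-length(obs)]) / 2)
  err <- vapply(cand, function(T) sum(intra > T) + sum(inter <= T), 0)
  best <- which.min(err)  # which.min takes the first, i.e. smallest threshold
  T <- cand[best]
  tibble::tibble(threshold = T, cumulative_error = err[best],
                 false_negative = sum(intra > T),
                 false_positive = sum(inter <= T))
}

#' Best-close-match identification
#'
#' References within the distance threshold vote: none in range gives
#' `no_id`; all conspecific, `correct`; all heterospecific, `incorrect`; a
#' mixture, `ambiguous`.
#'
#' @inheritParams rank_neighbors
#' @param threshold Distance threshold (inclusive), e.g. from
#'   [optimize_threshold()].
#' @return A one-row tibble `criterion`, `verdict`, `n_within`,
#'   `nearest_distance`.
#' @export
best_close_match <- function(ds, query, loci = locus_ids(ds), threshold) {
  rk <- rank_neighbors(ds, query, loci)
  q_species <- split_key(query)$species
  close <- rk[rk$distance <= threshold, ]
  verdict <- if (nrow(close) == 0L) {
    "no_id"
  } else if (all(close$species == q_species)) {
    "correct"
  } else if (all(close$species != q_species)) {
    "incorrect"
  } else {
    "ambiguous"
  }
  tibble::tibble(criterion = "best_close_match", verdict = verdict,
                 n_within = nrow(close), nearest_distance = rk$distance[1L])
}
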