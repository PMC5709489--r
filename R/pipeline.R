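#' Screen the database for candidate species
#'
#' Step one of the barcoding pipeline: the query's concatenated p-distance
#' to every database individual is computed, species are ranked by their
#' minimum individual distance to the query, and up to `k` nearest species
#' are kept — a fast screen that retrieves potential conspecifics and sister
#' species before tree building.
#'
#' @param ds A `mlbc_dataset` containing the query.
#' @param query Individual key of the query.
#' @param k Maximum species kept (default 4).
#' @param loci Locus ids (default all).
#' @return A tibble `species`, `distance` (minimum individual distance),
#'   ascending, at most `k` rows.
#' @export
screen_candidates <- function(ds, query, k = 4, loci = locus_ids(ds)) {
  rk <- rank_neighbors(ds, query, loci)
  rk |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(distance = min(.data$distance), .groups = "drop") |>
    dplyr::arrange(.data$distance, .data$species) |>
    dplyr::slice_head(n = k)
}

# One representative individual per species: the most complete one.
species_representatives <- function(ds, species, exclude = character(0)) {
  vapply(species, function(sp) {
    keys <- setdiff(ds$individuals$key[ds$individuals$species == sp], exclude)
    if (length(keys) == 0L) return(NA_character_)
    keys[which.max(colSums(ds$present[, keys, drop = FALSE]))]
  }, "")
}

#' Run the three-step multilocus barcoding pipeline
#'
#' 1. *Screen*: rank species by p-distance to the query and keep the `k`
#'    nearest ([screen_candidates()]).
#' 2. *Species tree*: build neighbor-joining gene trees over the query plus
#'    one representative per candidate species, amalgamate them into an
#'    exact maximum-quartet-support species tree, root it with the farthest
#'    candidate as outgroup, and read off the query's sister species.
#' 3. *Delimit*: Bayes-factor test of lumping versus splitting the query
#'    with the sister species ([delimit()]); splitting supported at 2lnBF
#'    >= 2 flags a putative new species, otherwise the query is assigned to
#'    the sister species.
#'
#' With fewer than three species in the database the tree step is skipped
#' (flagged in the result) and the nearest screened species is taken as the
#' sister.
#'
#' @param ds A `mlbc_dataset` containing the query and the reference
#'   database.
#' @param query Individual key of the query.
#' @param k Candidate species kept in the screen (default 4).
#' @param loci Locus ids to use (default all).
#' @param max_tree_loci Cap on gene trees built (default 200).
#' @param priors,mode,n_steps,chain_length,pre_burnin Passed to [delimit()].
#' @param seed Integer seed fanned out to the stochastic steps.
#' @return A `mlbc_assignment`: list with `query`, `candidates`,
#'   `species_tree` (or NULL), `sister`, `outgroup`, `delimitation`,
#'   `assigned_species` (NA for a new species), `verdict`, `tree_skipped`.
#' @export
run_pipeline <- function(ds, query, k = 4, loci = locus_ids(ds),
                         max_tree_loci = 200, priors = NULL,
                         mode = "all_pairs", n_steps = 12,
                         chain_length = 2500, pre_burnin = 250, seed = NULL) {
  db_keys <- setdiff(ds$individuals$key, query)
  db_species <- unique(ds$individuals$species[ds$individuals$key %in% db_keys])
  if (length(db_species) < 1L) stop("empty reference database")
  candidates <- screen_candidates(ds, query, k = k, loci = loci)

  tree_skipped <- length(db_species) < 3L || nrow(candidates) < 3L
  species_tree <- NULL
  gene_trees <- list()
  if (!tree_skipped) {
    reps <- species_representatives(ds, candidates$species, exclude = query)
    reps <- reps[!is.na(reps)]
    taxa <- c(stats::setNames(query, "query"), reps)
    usable <- loci[vapply(loci, function(id) all(ds$present[id, taxa]), TRUE)]
    if (length(usable) > max_tree_loci) {
      usable <- with_seed_(if (is.null(seed)) NULL else derive_seed(seed, 11L),
                           sample(usable, max_tree_loci))
    }
    gene_trees <- purrr::map(usable, function(id) {
      suppressWarnings(nj_gene_tree(ds, id, taxa))
    })
    gene_trees <- Filter(Negate(is.null), gene_trees)
    if (length(gene_trees) >= 1L) {
      species_tree <- quartet_species_tree(gene_trees, taxa = names(taxa))
    } else {
      tree_skipped <- TRUE
    }
  }

  outgroup <- candidates$species[nrow(candidates)]
  sister <- if (!is.null(species_tree)) {
    sister_species_of_query(species_tree$best_topology, "query", outgroup,
                            candidates)
  } else {
    candidates$species[1L]
  }

  sister_keys <- setdiff(ds$individuals$key[ds$individuals$species == sister],
                         query)
  dl <- delimit(ds, query_group = query, candidate_group = sister_keys,
                loci = loci, priors = priors, mode = mode, n_steps = n_steps,
                chain_length = chain_length, pre_burnin = pre_burnin,
                seed = if (is.null(seed)) NULL else derive_seed(seed, 13L))

  structure(
    list(query = query, candidates = candidates, species_tree = species_tree,
         n_gene_trees = length(gene_trees), sister = sister,
         outgroup = if (tree_skipped) NA_character_ else outgroup,
         delimitation = dl,
         assigned_species = if (dl$verdict == "assign_to_species") sister
                            else NA_character_,
         verdict = if (dl$verdict == "assign_to_species") "assigned"
                   else "new_species",
         tree_skipped = tree_skipped),
    class = "mlbc_assignment"
  )
}

# Sister species of the query tip on the rooted species tree: the species
# in the query's smallest enclosing clade, nearest by screen distance when
# several qualify.
sister_species_of_query <- function(topology, query_tip, outgroup, candidates) {
  tr <- tryCatch(ape::root(topology, outgroup = outgroup, resolve.root = TRUE),
                 error = function(e) topology)
  tip <- which(tr$tip.label == query_tip)
  parent <- tr$edge[tr$edge[, 2L] == tip, 1L]
  sibs <- setdiff(tr$tip.label[phangorn::Descendants(tr, parent, "tips")[[1L]]],
                  query_tip)
  if (length(sibs) == 0L) sibs <- setdiff(tr$tip.label, query_tip)
  hit <- candidates[candidates$species %in% sibs, ]
  if (nrow(hit) == 0L) candidates$species[1L] else hit$species[1L]
}

#' @export
print.mlbc_assignment <- function(x, ...) {
  cat("<barcoding pipeline result> query: ", x$query, "\n", sep = "")
  cat("  candidates: ", paste(x$candidates$species, collapse = ", "), "\n",
      sep = "")
  if (x$tree_skipped) {
    cat("  species-tree step skipped (fewer than three species)\n")
  } else {
    cat("  species tree: ", ape::write.tree(x$species_tree$best_topology),
        "\n", sep = "")
  }
  cat("  sister: ", x$sister, "; 2lnBF = ",
      format(x$delimitation$two_ln_bf, digits = 4), " (",
      x$delimitation$category, ", favours ", x$delimitation$favored, ")\n",
      sep = "")
  cat("  verdict: ",
      if (x$verdict == "assigned") paste0("assigned to ", x$assigned_species)
      else "putative new species", "\n", sep = "")
  invisible(x)
}

#' @export
tidy.mlbc_assignment <- function(x, ...) {
  x$candidates |>
    dplyr::mutate(query = x$query,
                  role = dplyr::case_when(
                    .data$species == x$sister ~ "sister",
                    .data$species == x$outgroup ~ "outgroup",
                    TRUE ~ "candidate"
                  ))
}

#' @export
glance.mlbc_assignment <- function(x, ...) {
  tibble::tibble(
    query = x$query, sister = x$sister,
    two_ln_bf = x$delimitation$two_ln_bf,
    category = x$delimitation$category,
    verdict = x$verdict, assigned_species = x$assigned_species,
    n_gene_trees = x$n_gene_trees, tree_skipped = x$tree_skipped
  )
}
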