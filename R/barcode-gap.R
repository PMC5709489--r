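#' Intra-/interspecific distance profile versus number of loci
#'
#' For each level (number of loci) and replicate, samples that many loci
#' without replacement, concatenates them, and records every pairwise
#' p-distance among the individuals of the two species, classed as
#' intraspecific (same species) or interspecific. This is the raw material
#' of a barcoding-gap plot: as independent loci accumulate, both
#' distributions tighten and, for good species, separate.
#'
#' @param ds A `mlbc_dataset`.
#' @param species_pair Character vector of two species labels.
#' @param levels Strictly increasing locus counts (each <= available loci).
#' @param n_reps Replicates per level (default 200).
#' @param seed Integer seed.
#' @return A tibble of class `mlbc_profile` with columns `level`,
#'   `replicate`, `class` (`"intra"`/`"inter"`), `distance`.
#' @export
distance_profile <- function(ds, species_pair, levels, n_reps = 200,
                             seed = NULL) {
  stopifnot(length(species_pair) == 2L, n_reps >= 1)
  levels <- as.integer(levels)
  if (is.unsorted(levels, strictly = TRUE)) stop("levels must be strictly increasing")
  ids <- locus_ids(ds)
  if (max(levels) > length(ids)) {
    stop("level ", max(levels), " exceeds available loci (", length(ids), ")")
  }
  keys <- ds$individuals$key[ds$individuals$species %in% species_pair]
  counts <- table(ds$individuals$species[ds$individuals$key %in% keys])
  if (length(counts) < 2L || any(counts < 2L)) {
    stop("each species needs at least two individuals")
  }
  tal <- dataset_tallies(ds, keys)
  cls <- ifelse(tal$pairs$intra, "intra", "inter")
  out <- with_seed_(seed, {
    purrr::map_dfr(levels, function(lev) {
      purrr::map_dfr(seq_len(n_reps), function(r) {
        idx <- sample.int(length(ids), lev)
        tibble::tibble(level = lev, replicate = r, class = cls,
                       distance = tally_distances(tal, idx))
      })
    })
  })
  class(out) <- c("mlbc_profile", class(out))
  attr(out, "species_pair") <- species_pair
  attr(out, "seed") <- seed
  out
}

#' Barcoding-gap summary per level
#'
#' Pools distances across replicates at each level and reports the gap
#' `min(inter) - max(intra)` — positive iff the two distributions are
#' disjoint — together with the pooled variances of each class.
#'
#' @param profile A `mlbc_profile` from [distance_profile()].
#' @return A tibble `level`, `max_intra`, `min_inter`, `gap`, `intra_var`,
#'   `inter_var`.
#' @export
gap_summary <- function(profile) {
  stopifnot(nrow(profile) > 0L)
  chk <- profile |>
    dplyr::count(.data$level, .data$class) |>
    tidyr::pivot_wider(names_from = "class", values_from = "n", values_fill = 0L)
  if (!all(c("intra", "inter") %in% names(chk)) ||
      any(chk$intra == 0L) || any(chk$inter == 0L)) {
    stop("a level has an empty intra or inter distance set")
  }
  profile |>
    dplyr::group_by(.data$level) |>
    dplyr::summarise(
      max_intra = max(.data$distance[.data$class == "intra"]),
      min_inter = min(.data$distance[.data$class == "inter"]),
      gap = .data$min_inter - .data$max_intra,
      intra_var = stats::var(.data$distance[.data$class == "intra"]),
      inter_var = stats::var(.data$distance[.data$class == "inter"]),
      .groups = "drop"
    )
}

#' Plot a distance profile
#'
#' Replicate-pooled intra- (red) and interspecific (blue) p-distances
#' against the number of loci used, the classic barcoding-gap display.
#'
#' @param object A `mlbc_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mlbc_profile <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = factor(.data$level), y = .data$distance,
                               colour = .data$class)) +
    ggplot2::geom_jitter(width = 0.25, alpha = 0.4, size = 0.6) +
    ggplot2::scale_colour_manual(values = c(intra = "#d62728", inter = "#1f77b4")) +
    ggplot2::labs(x = "number of loci", y = "p-distance", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Export a distance profile as TSV
#'
#' @param profile A `mlbc_profile`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
export_profile_tsv <- function(profile, path) {
  utils::write.table(profile, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
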