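#' Two-population isolation-with-migration model
#'
#' Parameters of the structured-coalescent simulator: two descendant
#' populations that split from a common ancestor `t_split` generations ago
#' and exchange migrants at fixed per-lineage per-generation probabilities.
#' Population sizes are in gene copies (haploid counts), so a pair of
#' lineages in population *i* coalesces at rate `1/N_i` per generation.
#'
#' @param N1,N2,N_anc Effective sizes (gene copies) of the two descendant
#'   populations and the ancestor. Default 20000.
#' @param t_split Split time in generations (0 = panmixia).
#' @param m12,m21 Per-lineage per-generation migration probabilities
#'   (backward in time: a lineage sampled in population 1 traces to
#'   population 2 at rate `m12`).
#' @param mu Mutation rate, substitutions/site/generation. Default 2e-8.
#' @param locus_length Locus length in bp. Default 300.
#' @return An `im_model`.
#' @examples
#' im_model(t_split = 7e5)
#' @export
im_model <- function(N1 = 20000, N2 = 20000, N_anc = 20000, t_split = 0,
                     m12 = 0, m21 = 0, mu = 2e-8, locus_length = 300) {
  stopifnot(N1 > 0, N2 > 0, N_anc > 0, t_split >= 0,
            m12 >= 0, m12 < 1, m21 >= 0, m21 < 1,
            mu > 0, locus_length >= 1)
  structure(
    list(N1 = N1, N2 = N2, N_anc = N_anc, t_split = t_split,
         m12 = m12, m21 = m21, mu = mu, locus_length = as.integer(locus_length)),
    class = "im_model"
  )
}

#' @export
print.im_model <- function(x, ...) {
  cat("<IM model> N1=", x$N1, " N2=", x$N2, " N_anc=", x$N_anc,
      " t_split=", x$t_split, " m12=", x$m12, " m21=", x$m21,
      " mu=", x$mu, " L=", x$locus_length, "\n", sep = "")
  invisible(x)
}

#' Simulate one gene genealogy under the IM model
#'
#' Backward-in-time structured coalescent (continuous-time exponential-rates
#' approximation). Before `t_split`, pairs within population *i* coalesce at
#' rate `1/N_i` and each lineage in *i* migrates at rate `m_ij`; at
#' `t_split` all surviving lineages merge into the ancestral population of
#' size `N_anc` and coalesce to a single root.
#'
#' @param model An [im_model()].
#' @param n1,n2 Lineages sampled from populations 1 and 2 (`n1 + n2 >= 2`).
#' @return A `genealogy`: parent pointers and node times (generations) over
#'   `n1 + n2` tips (labelled `speciesA|A*`, `speciesB|B*`) and `n1 + n2 - 1`
#'   internal nodes; tip demes recorded.
#' @export
simulate_genealogy <- function(model, n1, n2) {
  stopifnot(inherits(model, "im_model"), n1 >= 0, n2 >= 0, n1 + n2 >= 2)
  n <- n1 + n2
  n_nodes <- 2L * n - 1L
  parent <- integer(n_nodes)            # 0 = root
  time <- numeric(n_nodes)
  active <- seq_len(n)                  # node ids of live lineages
  deme <- c(rep(1L, n1), rep(2L, n2))   # deme of each live lineage
  nxt <- n + 1L
  t <- 0
  Ns <- c(model$N1, model$N2)
  ms <- c(model$m12, model$m21)

  coalesce_pair <- function(idx_pair) {
    a <- active[idx_pair[1L]]; b <- active[idx_pair[2L]]
    parent[a] <<- nxt; parent[b] <<- nxt
    time[nxt] <<- t
    active <<- c(active[-idx_pair], nxt)
    nxt <<- nxt + 1L
  }

  # Island phase: two demes until t_split.
  while (length(active) > 1L && t < model$t_split) {
    k1 <- sum(deme == 1L); k2 <- sum(deme == 2L)
    rate_c <- c(choose(k1, 2) / Ns[1L], choose(k2, 2) / Ns[2L])
    rate_m <- c(k1 * ms[1L], k2 * ms[2L])
    total <- sum(rate_c, rate_m)
    if (total == 0) { t <- model$t_split; break }
    dt <- stats::rexp(1L, total)
    if (t + dt >= model$t_split) { t <- model$t_split; break }
    t <- t + dt
    ev <- sample.int(4L, 1L, prob = c(rate_c, rate_m))
    if (ev <= 2L) {
      in_deme <- which(deme == ev)
      idx <- in_deme[sample.int(length(in_deme), 2L)]
      deme <- c(deme[-idx], ev)
      coalesce_pair(idx)
    } else {
      from <- ev - 2L
      in_deme <- which(deme == from)
      idx <- in_deme[sample.int(length(in_deme), 1L)]
      deme[idx] <- 3L - from
    }
  }

  # Ancestral phase: single panmictic deme of size N_anc.
  while (length(active) > 1L) {
    k <- length(active)
    t <- t + stats::rexp(1L, choose(k, 2) / model$N_anc)
    idx <- sample.int(k, 2L)
    deme <- deme[-idx[2L]]
    coalesce_pair(idx)
  }

  labels <- c(if (n1 > 0) ind_key("speciesA", paste0("A", seq_len(n1))),
              if (n2 > 0) ind_key("speciesB", paste0("B", seq_len(n2))))
  structure(
    list(parent = parent, time = time, n_tips = n,
         tip_labels = labels, tip_deme = c(rep(1L, n1), rep(2L, n2))),
    class = "genealogy"
  )
}

#' @export
print.genealogy <- function(x, ...) {
  cat("<genealogy> ", x$n_tips, " tips, TMRCA ",
      format(max(x$time), big.mark = ","), " generations\n", sep = "")
  invisible(x)
}

# Time to most recent common ancestor of two tips.
tmrca_pair <- function(g, a, b) {
  anc_a <- a
  node <- a
  while (g$parent[node] != 0L) { node <- g$parent[node]; anc_a <- c(anc_a, node) }
  node <- b
  while (!(node %in% anc_a)) node <- g$parent[node]
  g$time[node]
}

#' Drop Jukes-Cantor mutations on a genealogy
#'
#' Finite-sites mutation: the number of mutations on each branch is Poisson
#' with mean `mu * locus_length * branch_length`; each mutation hits a
#' uniformly chosen site and changes the base to one of the three others
#' uniformly (so multiple hits and back-mutations occur). The root sequence
#' is uniform random.
#'
#' @param g A `genealogy`.
#' @param mu Mutation rate per site per generation.
#' @param locus_length Sites.
#' @param locus_id Identifier for the returned alignment.
#' @return A `mlbc_locus` with one sequence per tip.
#' @export
drop_mutations <- function(g, mu, locus_length, locus_id = "locus") {
  L <- as.integer(locus_length)
  n_nodes <- 2L * g$n_tips - 1L
  children <- vector("list", n_nodes)
  root <- which(g$parent == 0L)
  for (v in seq_len(n_nodes)) {
    p <- g$parent[v]
    if (p != 0L) children[[p]] <- c(children[[p]], v)
  }
  codes <- matrix(0L, nrow = g$n_tips, ncol = L,
                  dimnames = list(g$tip_labels, NULL))
  seq_at <- vector("list", n_nodes)
  seq_at[[root]] <- sample.int(4L, L, replace = TRUE)
  stack <- root
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    s <- seq_at[[v]]
    for (ch in children[[v]]) {
      blen <- g$time[v] - g$time[ch]
      nmut <- stats::rpois(1L, mu * L * blen)
      s_ch <- s
      if (nmut > 0L) {
        sites <- sample.int(L, nmut, replace = TRUE)
        draws <- sample.int(3L, nmut, replace = TRUE)
        for (m in seq_len(nmut)) {
          old <- s_ch[sites[m]]
          s_ch[sites[m]] <- draws[m] + (draws[m] >= old)  # uniform over the 3 other bases
        }
      }
      seq_at[[ch]] <- s_ch
      if (ch <= g$n_tips) codes[ch, ] <- s_ch else stack <- c(stack, ch)
    }
    seq_at[v] <- list(NULL)  # free, without shifting list indices
  }
  new_locus(locus_id, codes)
}

#' Simulate a pool of independent loci
#'
#' Free recombination between loci (one independent genealogy per locus),
#' none within. Deterministic under `seed`.
#'
#' @param model An [im_model()].
#' @param n1,n2 Sequences sampled per species (default 5 + 5).
#' @param n_loci Number of loci (>= 1).
#' @param seed Integer seed.
#' @return A `mlbc_dataset` of `n_loci` simulated alignments with
#'   individuals labelled `speciesA|A1..` and `speciesB|B1..`.
#' @export
simulate_pool <- function(model, n1 = 5, n2 = 5, n_loci, seed = NULL) {
  if (n_loci < 1L) stop("n_loci must be >= 1")
  width <- max(5L, nchar(as.character(n_loci)))
  with_seed_(seed, {
    loci <- lapply(seq_len(n_loci), function(i) {
      g <- simulate_genealogy(model, n1, n2)
      drop_mutations(g, model$mu, model$locus_length,
                     locus_id = sprintf("locus%0*d", width, i))
    })
    as_dataset(loci)
  })
}

#' Identification success versus number of loci (power curve)
#'
#' Simulates one pool of `pool_size` loci under `model`, then for each level
#' and replicate draws that many loci without replacement, concatenates, and
#' scores every individual as a query against all others under the
#' all-species-barcodes criterion. The success rate pools over
#' (individual x replicate).
#'
#' @param model An [im_model()].
#' @param levels Integer vector of locus counts.
#' @param pool_size Loci in the simulated pool (default 20000; scaled-down
#'   runs of at least 2000 remain informative with wider Monte-Carlo spread).
#' @param n_reps Resampling replicates per level (default 200).
#' @param n1,n2 Sequences per species (default 5 + 5).
#' @param seed Integer seed.
#' @return Tibble `level`, `success_rate`, `mc_se`, `n_reps`.
#' @export
success_vs_loci <- function(model, levels, pool_size = 20000, n_reps = 200,
                            n1 = 5, n2 = 5, seed = NULL) {
  if (any(levels > pool_size)) stop("level exceeds pool_size")
  with_seed_(seed, {
    ds <- simulate_pool(model, n1 = n1, n2 = n2, n_loci = pool_size)
    tal <- dataset_tallies(ds)
    purrr::map_dfr(sort(unique(as.integer(levels))), function(lev) {
      succ <- vapply(seq_len(n_reps), function(r) {
        idx <- sample.int(pool_size, lev)
        d <- tally_distances(tal, idx)
        asb_success_fraction(d, tal$pairs)
      }, 0)
      tibble::tibble(level = lev, success_rate = mean(succ),
                     mc_se = stats::sd(succ) / sqrt(n_reps), n_reps = n_reps)
    })
  })
}

#' One long locus versus many short loci
#'
#' For each total length `L`, contrasts identification success from a single
#' simulated locus of length `L` (one genealogy per replicate) with success
#' from `L/300` independent 300-bp loci drawn from a simulated pool — same
#' total sequence, different numbers of independent genealogies.
#'
#' @param model An [im_model()]; `locus_length` is taken as the unit length
#'   (300 bp by default) that `total_lengths` must be multiples of.
#' @param total_lengths Integer vector of total lengths in bp.
#' @param n_reps Replicates (default 200).
#' @param pool_size Pool size for the multilocus arm (default 2000).
#' @param seed Integer seed.
#' @return Tibble `total_length`, `n_loci`, `success_single`,
#'   `success_multi`, with Monte-Carlo standard errors.
#' @export
single_vs_multi <- function(model, total_lengths, n_reps = 200,
                            pool_size = 2000, seed = NULL) {
  unit <- model$locus_length
  if (any(total_lengths %% unit != 0)) {
    stop("total_lengths must be multiples of the unit locus length (", unit, ")")
  }
  with_seed_(seed, {
    ds <- simulate_pool(model, n_loci = pool_size)
    tal <- dataset_tallies(ds)
    purrr::map_dfr(sort(unique(as.integer(total_lengths))), function(L) {
      k <- L %/% unit
      if (k > pool_size) stop("total length ", L, " needs ", k,
                              " unit loci; pool has ", pool_size)
      single <- vapply(seq_len(n_reps), function(r) {
        g <- simulate_genealogy(model, 5, 5)
        loc <- drop_mutations(g, model$mu, L, locus_id = "long")
        d1 <- as_dataset(list(loc))
        t1 <- dataset_tallies(d1)
        asb_success_fraction(tally_distances(t1, 1L), t1$pairs)
      }, 0)
      multi <- vapply(seq_len(n_reps), function(r) {
        idx <- sample.int(pool_size, k)
        asb_success_fraction(tally_distances(tal, idx), tal$pairs)
      }, 0)
      tibble::tibble(
        total_length = L, n_loci = k,
        success_single = mean(single), se_single = stats::sd(single) / sqrt(n_reps),
        success_multi = mean(multi), se_multi = stats::sd(multi) / sqrt(n_reps),
        n_reps = n_reps
      )
    })
  })
}

#' Generate a named synthetic fixture dataset
#'
#' Canned simulation scenarios used throughout the examples and tests:
#' `deep_split` (700,000-generation split, no migration), `shallow_split`
#' (10,000 generations, migration 1e-5), `panmictic` (split time 0), and
#' `sinipercid_like` (seven nominal species on a ladder species tree whose
#' shallowest split — the sister pair — is 700,000 generations, five
#' individuals each, for pipeline tests).
#'
#' @param kind One of `"deep_split"`, `"shallow_split"`, `"panmictic"`,
#'   `"sinipercid_like"`.
#' @param n_loci Loci to simulate (default 100).
#' @param seed Integer seed.
#' @return A `mlbc_dataset`.
#' @export
make_fixture <- function(kind = c("deep_split", "shallow_split", "panmictic",
                                  "sinipercid_like"),
                         n_loci = 100, seed = NULL) {
  kind <- match.arg(kind)
  if (kind == "sinipercid_like") {
    return(simulate_species_ladder(n_species = 7, first_split = 7e5,
                                   step = 1.5e6, N = 20000, n_per_species = 5,
                                   n_loci = n_loci, seed = seed))
  }
  model <- switch(kind,
    deep_split = im_model(t_split = 7e5),
    shallow_split = im_model(t_split = 1e4, m12 = 1e-5, m21 = 1e-5),
    panmictic = im_model(t_split = 0)
  )
  simulate_pool(model, n_loci = n_loci, seed = seed)
}

# Multi-species pure-divergence (no migration) coalescent on a ladder tree:
# species S1..Sk; S1 and S2 split at `first_split`; S_{j} (j >= 3) joins at
# first_split + (j - 2) * step. All populations size N gene copies.
simulate_species_ladder <- function(n_species, first_split, step, N,
                                    n_per_species, n_loci, seed = NULL) {
  merge_times <- first_split + step * (seq_len(n_species - 1L) - 1L)
  with_seed_(seed, {
    width <- max(5L, nchar(as.character(n_loci)))
    loci <- lapply(seq_len(n_loci), function(li) {
      n <- n_species * n_per_species
      n_nodes <- 2L * n - 1L
      parent <- integer(n_nodes)
      time <- numeric(n_nodes)
      active <- seq_len(n)
      deme <- rep(seq_len(n_species), each = n_per_species)
      nxt <- n + 1L
      t <- 0
      events <- c(merge_times, Inf)
      live_demes <- seq_len(n_species)
      for (ph in seq_along(events)) {
        t_end <- events[ph]
        repeat {
          ks <- tabulate(deme, nbins = n_species)
          rate <- sum(choose(ks[live_demes], 2)) / N
          if (rate == 0) { t <- t_end; break }
          dt <- stats::rexp(1L, rate)
          if (t + dt >= t_end) { t <- t_end; break }
          t <- t + dt
          dm <- live_demes[sample.int(length(live_demes), 1L,
                                      prob = choose(ks[live_demes], 2))]
          in_deme <- which(deme == dm)
          idx <- in_deme[sample.int(length(in_deme), 2L)]
          a <- active[idx[1L]]; b <- active[idx[2L]]
          parent[a] <- nxt; parent[b] <- nxt
          time[nxt] <- t
          active <- c(active[-idx], nxt)
          deme <- c(deme[-idx], dm)
          nxt <- nxt + 1L
        }
        if (is.finite(t_end)) {
          # ladder: deme (ph + 1) merges into the ancestral pool, tracked as deme 1
          deme[deme == (ph + 1L)] <- 1L
          live_demes <- setdiff(live_demes, ph + 1L)
        }
        if (length(active) == 1L) break
      }
      g <- structure(
        list(parent = parent, time = time, n_tips = n,
             tip_labels = ind_key(rep(sprintf("species%d", seq_len(n_species)),
                                      each = n_per_species),
                                  paste0(rep(sprintf("S%d_", seq_len(n_species)),
                                             each = n_per_species),
                                         rep(seq_len(n_per_species), n_species))),
             tip_deme = rep(seq_len(n_species), each = n_per_species)),
        class = "genealogy"
      )
      drop_mutations(g, 2e-8, 300, locus_id = sprintf("locus%0*d", width, li))
    })
    as_dataset(loci)
  })
}
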