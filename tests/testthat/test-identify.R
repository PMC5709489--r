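test_that("rank_neighbors orders by distance with the conservative tie-break", {
  ds <- toy_dataset(list(
    l1 = c("spA|q" = "AAAAAAAAAA",
           "spA|a1" = "AAAAAAAAAT",   # 0.1
           "spA|a2" = "AAAAAAAATT",   # 0.2
           "spB|b1" = "AAAAAAAAAT",   # 0.1, ties a1
           "spB|b2" = "AAAAATTTTT")   # 0.5
  ))
  rk <- rank_neighbors(ds, "spA|q")
  expect_equal(rk$individual,
               c("spB|b1", "spA|a1", "spA|a2", "spB|b2"))  # heterospecific wins the tie
  expect_equal(rk$distance, c(0.1, 0.1, 0.2, 0.5))
  # permuting locus/individual input order does not change the ranking
  ds2 <- toy_dataset(list(l1 = ds$loci$l1$seqs[c(3, 5, 1, 4, 2)]))
  expect_equal(rank_neighbors(ds2, "spA|q"), rk)
  expect_error(rank_neighbors(ds, "spX|nope"), "unknown query")
})

test_that("all_species_barcodes follows the criterion including shared haplotypes", {
  ok <- toy_dataset(list(
    l1 = c("spA|q" = "AAAAAAAAAA", "spA|a1" = "AAAAAAAAAT",
           "spA|a2" = "AAAAAAAATT", "spB|b1" = "AAAAATTTTT")
  ))
  expect_equal(all_species_barcodes(ok, "spA|q")$verdict, "correct")

  shared <- toy_dataset(list(
    l1 = c("spA|q" = "AAAAAAAAAA", "spA|a1" = "AAAAAAAAAT",
           "spB|b1" = "AAAAAAAAAA")  # heterospecific shares the query haplotype
  ))
  expect_equal(all_species_barcodes(shared, "spA|q")$verdict, "incorrect")

  alone <- toy_dataset(list(
    l1 = c("spA|q" = "AAAAAAAAAA", "spB|b1" = "AAAAATTTTT")
  ))
  expect_equal(all_species_barcodes(alone, "spA|q")$verdict, "no_id")
})

test_that("all_species_barcodes agrees with an exhaustive pairwise oracle", {
  withr::local_seed(91)
  for (rep in 1:25) {
    n <- 6
    sp <- sample(c("spA", "spB"), n, replace = TRUE)
    keys <- paste0(sp, "|i", 1:n)
    loci <- list(x = stats::setNames(replicate(n, random_seq(30)), keys))
    ds <- toy_dataset(loci)
    q <- keys[1]
    got <- tryCatch(all_species_barcodes(ds, q)$verdict, error = function(e) NA)
    # oracle: compare every conspecific distance against every heterospecific one
    dist_to <- vapply(keys[-1], function(r) {
      tryCatch(p_distance(loci$x[[q]], loci$x[[r]])$value, error = function(e) NA)
    }, 0)
    cons <- dist_to[sp[-1] == sp[1]]
    hets <- dist_to[sp[-1] != sp[1]]
    want <- if (length(cons) == 0) "no_id"
            else if (length(hets) == 0 || max(cons) < min(hets)) "correct"
            else "incorrect"
    expect_equal(got, want)
  }
})

test_that("success rate is 1 with diagnostic loci and ~0 for identical populations", {
  ds <- diagnostic_dataset(n_loci = 6, n_per_species = 3)
  r <- success_rate(ds, n_loci = 3, n_reps = 20, seed = 92)
  expect_equal(r$success_rate, 1)
  # same seed, same answer
  r2 <- success_rate(ds, n_loci = 3, n_reps = 20, seed = 92)
  expect_identical(r, r2)

  pan <- make_fixture("panmictic", n_loci = 150, seed = 93)
  rp <- success_rate(pan, n_loci = 100, n_reps = 50, seed = 94)
  expect_lt(rp$success_rate, 0.15)
  expect_gte(rp$success_rate, 0)
})

test_that("optimize_threshold minimizes cumulative error, smallest threshold on ties", {
  t1 <- optimize_threshold(intra = 0.01, inter = 0.10)
  expect_equal(t1$cumulative_error, 0)
  expect_equal(t1$threshold, (0.01 + 0.10) / 2)  # smallest candidate achieving 0

  # interleaved distributions: verify against an exhaustive threshold scan
  withr::local_seed(95)
  intra <- runif(40, 0, 0.2)
  inter <- runif(40, 0.05, 0.25)
  got <- optimize_threshold(intra, inter)
  cand <- sort(unique(c(0, intra, inter, (sort(c(intra, inter)) + 1e-9))))
  errs <- vapply(cand, function(T) sum(intra > T) + sum(inter <= T), 0)
  expect_equal(got$cumulative_error, min(errs))
  expect_gt(got$cumulative_error, 0)

  # duplicating an observation cannot increase the minimal error by more than 1
  dup <- optimize_threshold(c(intra, intra[1]), inter)
  expect_lte(dup$cumulative_error, got$cumulative_error + 1)
  expect_error(optimize_threshold(numeric(0), inter), "required")
})

test_that("best_close_match votes within the threshold", {
  ds <- toy_dataset(list(
    l1 = c("spA|q" = "AAAAAAAAAA", "spA|a1" = "AAAAAAAAAT",
           "spB|b1" = "AAAAATTTTT", "spB|b2" = "TTTTTTTTTT")
  ))
  expect_equal(best_close_match(ds, "spA|q", threshold = 0.2)$verdict, "correct")
  expect_equal(best_close_match(ds, "spA|q", threshold = 0.05)$verdict, "no_id")
  expect_equal(best_close_match(ds, "spA|q", threshold = 0.5)$verdict, "ambiguous")
  hetonly <- toy_dataset(list(
    l1 = c("spA|q" = "AAAAAAAAAA", "spB|b1" = "AAAAAAAAAT")
  ))
  expect_equal(best_close_match(hetonly, "spA|q", threshold = 0.2)$verdict,
               "incorrect")
})

test_that("success under the criterion rises with splitting time at fixed loci", {
  shallow <- success_vs_loci(im_model(t_split = 1e3), levels = 30,
                             pool_size = 300, n_reps = 60, seed = 96)
  deep <- success_vs_loci(im_model(t_split = 7e5), levels = 30,
                          pool_size = 300, n_reps = 60, seed = 97)
  expect_gt(deep$success_rate,
            shallow$success_rate + 2 * sqrt(deep$mc_se^2 + shallow$mc_se^2))
})
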