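test_that("pairdiff_loglik matches closed-form plug-ins", {
  d0 <- tibble::tibble(locus_id = "l", class = "within_a", k = 0L, L = 100L)
  # theta * L = 1 -> P(K = 0) = 1/2
  expect_equal(pairdiff_loglik(d0, list(theta_lump = 0.01), "lump"), log(0.5))

  # between pair with tau = 0 degenerates to the lump geometric form
  db <- tibble::tibble(locus_id = "l", class = "between", k = 3L, L = 200L)
  split0 <- pairdiff_loglik(db, list(theta1 = 1, theta2 = 1,
                                     theta_anc = 0.004, tau = 0), "split")
  lump <- pairdiff_loglik(dplyr::mutate(db, class = "within_a"),
                          list(theta_lump = 0.004), "lump")
  expect_equal(split0, lump)
  expect_error(pairdiff_loglik(dplyr::mutate(db, k = -1L), list(theta_lump = 1)),
               "negative")
})

test_that("the between-pair pmf matches 1-D quadrature over coalescence time", {
  ks <- 0:30
  for (pars in list(c(th = 0.002, tau = 0.005), c(th = 0.01, tau = 0.001))) {
    want <- between_pmf_oracle(ks, L = 300, theta_anc = pars[["th"]],
                               tau = pars[["tau"]])
    got <- vapply(ks, function(k) {
      d <- tibble::tibble(locus_id = "l", class = "between", k = k, L = 300L)
      exp(pairdiff_loglik(d, list(theta1 = 1, theta2 = 1,
                                  theta_anc = pars[["th"]],
                                  tau = pars[["tau"]]), "split"))
    }, 0)
    expect_equal(got, want, tolerance = 1e-8)
    expect_lt(abs(sum(want) - 1), 0.01)  # pmf sanity: mass captured by k <= 12
  }
})

test_that("path sampling recovers lnML = 0 on empty data and quadrature on toys", {
  empty <- tibble::tibble(locus_id = character(), class = character(),
                          k = integer(), L = integer())
  lnml0 <- path_sampling_lnML(empty, "lump", priors = list(theta_lump = 1e-3),
                              n_steps = 8, chain_length = 2000,
                              pre_burnin = 200, seed = 1)
  expect_lt(abs(as.numeric(lnml0)), 0.05)

  # 1-parameter toy: three loci of within-pair counts
  toy <- tibble::tibble(locus_id = c("a", "b", "c"), class = "within_a",
                        k = c(1L, 0L, 2L), L = 300L)
  want <- lump_lnml_oracle(toy, prior_mean = 0.004)
  got <- path_sampling_lnML(toy, "lump", priors = list(theta_lump = 0.004),
                            n_steps = 24, chain_length = 8000,
                            pre_burnin = 1000, seed = 2)
  expect_lt(abs(as.numeric(got) - want), 0.2)

  # stochastic reproducibility: two seeds agree closely on the same toy
  got2 <- path_sampling_lnML(toy, "lump", priors = list(theta_lump = 0.004),
                             n_steps = 24, chain_length = 8000,
                             pre_burnin = 1000, seed = 3)
  expect_lt(abs(as.numeric(got) - as.numeric(got2)), 0.2)
  expect_identical(
    as.numeric(path_sampling_lnML(toy, "lump", priors = list(theta_lump = 0.004),
                                  n_steps = 8, chain_length = 1000, seed = 4)),
    as.numeric(path_sampling_lnML(toy, "lump", priors = list(theta_lump = 0.004),
                                  n_steps = 8, chain_length = 1000, seed = 4)))
})

test_that("2lnBF arithmetic and Kass-Raftery bands are exact", {
  bf1 <- bf_from_marginals(-1575.80, -1586.11)
  expect_equal(as.numeric(bf1), 20.62)
  expect_equal(attr(bf1, "favored"), "a")
  bf2 <- bf_from_marginals(-2350.77, -1222.90)
  expect_equal(as.numeric(bf2), 2255.74)
  expect_equal(attr(bf2, "favored"), "b")
  expect_equal(as.numeric(bf_from_marginals(-5, -5)), 0)

  expect_equal(as.character(interpret_bf(2255.7)), "decisive")
  expect_equal(as.character(interpret_bf(20.62)), "decisive")
  expect_equal(as.character(interpret_bf(1.0)), "bare mention")
  expect_equal(as.character(interpret_bf(7.5)), "strong")
  expect_equal(as.character(interpret_bf(c(0, 2, 6, 10))),
               c("bare mention", "positive", "strong", "decisive"))
  neg <- interpret_bf(-7.5)
  expect_equal(as.character(neg), "strong")
  expect_equal(attr(neg, "direction"), -1)
})

test_that("delimit lumps a panmictic sample and splits deep divergences", {
  # two arbitrary groups from one panmictic population: no divergence signal
  pan <- make_fixture("panmictic", n_loci = 60, seed = 111)
  pa <- pan$individuals$key[pan$individuals$species == "speciesA"]
  pb <- pan$individuals$key[pan$individuals$species == "speciesB"]
  res_pan <- delimit(pan, pa, pb, seed = 5)
  expect_false(res_pan$favored == "split" && res_pan$two_ln_bf >= 2)
  expect_equal(res_pan$verdict, "assign_to_species")

  # groups simulated at t = 700,000, m = 0: decisive split
  deep <- make_fixture("deep_split", n_loci = 60, seed = 112)
  a_keys <- deep$individuals$key[deep$individuals$species == "speciesA"]
  b_keys <- deep$individuals$key[deep$individuals$species == "speciesB"]
  res_deep <- delimit(deep, a_keys, b_keys, seed = 6)
  expect_equal(res_deep$favored, "split")
  expect_equal(res_deep$verdict, "new_species")
  expect_equal(res_deep$category, "decisive")

  g <- glance(res_deep)
  expect_equal(g$verdict, "new_species")
  td <- tidy(res_deep)
  expect_equal(td$hypothesis, c("lump", "split"))
  expect_error(delimit(deep, character(0), b_keys), "non-empty")
})

test_that("one-pair-per-locus mode thins the composite likelihood", {
  deep <- make_fixture("deep_split", n_loci = 20, seed = 113)
  a_keys <- deep$individuals$key[deep$individuals$species == "speciesA"]
  b_keys <- deep$individuals$key[deep$individuals$species == "speciesB"]
  d_all <- pair_diffs(deep, a_keys, b_keys)
  d_one <- pair_diffs(deep, a_keys, b_keys, mode = "one_per_locus", seed = 7)
  expect_equal(nrow(d_all), 20 * choose(10, 2))
  expect_equal(nrow(d_one), 20 * 3)  # one pair per (locus, class)
})
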