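test_that("FASTA parsing enforces the alignment and header contracts", {
  dir <- withr::local_tempdir()
  writeLines(c(">spA|a1", "ACGTACGT", ">spA|a2", "ACGTACGA"),
             file.path(dir, "loc1.fasta"))
  loc <- read_locus_fasta(file.path(dir, "loc1.fasta"))
  expect_s3_class(loc, "mlbc_locus")
  expect_equal(loc$locus_id, "loc1")
  expect_equal(nrow(loc$codes), 2L)

  writeLines(c(">spA|a1", "ACGTACGT", ">spA|a2", "ACGTACG"),
             file.path(dir, "ragged.fasta"))
  expect_error(read_locus_fasta(file.path(dir, "ragged.fasta")), "ragged")

  writeLines(c(">spA_a1", "ACGT"), file.path(dir, "badhdr.fasta"))
  expect_error(read_locus_fasta(file.path(dir, "badhdr.fasta")),
               "malformed header.*spA_a1")
})

test_that("load_dataset unions individuals and fills the missing mask", {
  dir <- withr::local_tempdir()
  writeLines(c(">spA|a1", "ACGT", ">spA|a2", "ACGA", ">spB|b1", "TTGT"),
             file.path(dir, "locA.fasta"))
  writeLines(c(">spA|a1", "CCGT", ">spB|b1", "TAGT"),
             file.path(dir, "locB.fasta"))
  ds <- load_dataset(dir)
  expect_equal(nrow(ds$individuals), 3L)
  expect_true(ds$present["locA", "spA|a2"])
  expect_false(ds$present["locB", "spA|a2"])

  expect_error(load_dataset(withr::local_tempdir()), "no FASTA")
  file.copy(file.path(dir, "locA.fasta"), file.path(dir, "locA2.fasta"))
  expect_error(as_dataset(list(read_locus_fasta(file.path(dir, "locA.fasta"), "x"),
                               read_locus_fasta(file.path(dir, "locA2.fasta"), "x"))),
               "duplicate locus")
})

test_that("p_distance matches the stated examples and handles errors", {
  d <- p_distance("ACGT", "ACGA")
  expect_equal(d$value, 0.25)
  expect_equal(d$valid_sites, 4L)

  d2 <- p_distance("AC-T", "ACGT")
  expect_equal(d2$value, 0)
  expect_equal(d2$valid_sites, 3L)

  expect_error(p_distance("ACG", "ACGT"), "length")
  expect_error(p_distance("NNNN", "ACGT"), "undefined")
})

test_that("p_distance equals the per-site brute-force oracle and is symmetric", {
  withr::local_seed(42)
  for (i in 1:200) {
    a <- random_seq(300)
    b <- random_seq(300)
    want <- pdist_oracle(a, b)
    if (want$valid_sites == 0L) next
    got <- p_distance(a, b)
    rev <- p_distance(b, a)
    expect_equal(got$value, want$value)
    expect_equal(got$valid_sites, want$valid_sites)
    expect_equal(got$value, rev$value)
  }
})

test_that("concat_distance is additive and equals the string-concatenation oracle", {
  ds <- toy_dataset(list(
    l1 = c("spA|a" = "ACGTACGTAC", "spB|b" = "ACGAACGTAC"),
    l2 = c("spA|a" = "TTTTTTTTTT", "spB|b" = "TTTATTTATT")
  ))
  d <- concat_distance(ds, c("l1", "l2"), "spA|a", "spB|b")
  expect_equal(d$value, 3 / 20)
  one <- concat_distance(ds, "l1", "spA|a", "spB|b")
  expect_equal(one$value, p_distance("ACGTACGTAC", "ACGAACGTAC")$value)

  # random 10-locus dataset: compare against p_distance on literal concatenation
  withr::local_seed(7)
  loci <- lapply(1:10, function(i) {
    c("spA|a" = random_seq(50), "spB|b" = random_seq(50))
  })
  names(loci) <- sprintf("r%02d", 1:10)
  rds <- toy_dataset(loci)
  cat_a <- paste(vapply(loci, `[[`, "", "spA|a"), collapse = "")
  cat_b <- paste(vapply(loci, `[[`, "", "spB|b"), collapse = "")
  got <- concat_distance(rds, names(loci), "spA|a", "spB|b")
  want <- p_distance(cat_a, cat_b)
  expect_equal(got$value, want$value)
  expect_equal(got$valid_sites, want$valid_sites)
})

test_that("filter_by_missing keeps exactly the complete loci", {
  loci <- list(
    l1 = c("spA|a" = "ACGT", "spA|b" = "ACGT", "spB|c" = "ACGT"),
    l2 = c("spA|a" = "ACGT", "spB|c" = "ACGT"),
    l3 = c("spA|a" = "ACGT", "spA|b" = "ACGT", "spB|c" = "ACGT")
  )
  ds <- toy_dataset(loci)
  kept <- filter_by_missing(ds, c("spA|a", "spA|b", "spB|c"))
  expect_setequal(rownames(kept$present), c("l1", "l3"))
  # brute-force mask scan over a random mask
  withr::local_seed(11)
  inds <- paste0("sp", rep(c("A", "B"), each = 3), "|", letters[1:6])
  rloci <- lapply(1:12, function(i) {
    who <- inds[runif(6) > 0.3]
    if (length(who) < 2) who <- inds[1:2]
    stats::setNames(replicate(length(who), random_seq(20)), who)
  })
  names(rloci) <- sprintf("m%02d", 1:12)
  rds <- toy_dataset(rloci)
  sub <- inds[1:4]
  got <- rownames(filter_by_missing(rds, sub)$present)
  want <- names(rloci)[vapply(rloci, function(l) all(sub %in% names(l)), TRUE)]
  expect_setequal(got, want)
  # no complete locus -> empty dataset with warning
  ds2 <- toy_dataset(list(p1 = c("spA|a" = "ACGT", "spB|c" = "ACGT"),
                          p2 = c("spA|b" = "ACGT", "spB|c" = "ACGT")))
  expect_warning(out <- filter_by_missing(ds2, c("spA|a", "spA|b")), "no locus")
  expect_length(out$loci, 0L)
})

test_that("locus ranking is by mean p-distance with deterministic ties", {
  loci <- list(
    hi = c("spA|a" = "AAAA", "spA|b" = "TTTT"),       # mean 1
    mid = c("spA|a" = "AAAA", "spA|b" = "AATT"),      # mean 0.5
    zero = c("spA|a" = "AAAA", "spA|b" = "AAAA")      # mean 0
  )
  rk <- rank_loci_by_divergence(toy_dataset(loci))
  expect_equal(unname(rk$locus_id), c("hi", "mid", "zero"))
  expect_equal(rk$mean_p_distance, c(1, 0.5, 0))
  # permuting input order leaves the ranking unchanged
  rk2 <- rank_loci_by_divergence(toy_dataset(loci[c(3, 1, 2)]))
  expect_equal(rk2, rk)
  # a locus with a single present individual is excluded with a warning
  loci$single <- c("spA|a" = "AAAA")
  expect_warning(rk3 <- rank_loci_by_divergence(toy_dataset(loci)), "excluding")
  expect_false("single" %in% rk3$locus_id)
})

test_that("select_panel applies the two-stage rule and matches a brute-force sort", {
  withr::local_seed(5)
  inds <- c("spA|a", "spA|b", "spB|c", "spB|d")
  loci <- lapply(1:10, function(i) {
    who <- if (i %% 3 == 0) inds[1:3] else inds   # every third locus misses one
    stats::setNames(replicate(length(who), random_seq(40)), who)
  })
  names(loci) <- sprintf("s%02d", 1:10)
  ds <- toy_dataset(loci)
  got <- select_panel(ds, n_low_missing = 6, n_panel = 3)

  rk <- suppressWarnings(rank_loci_by_divergence(ds))
  ord1 <- rk[order(rk$n_missing, -rk$mean_p_distance, rk$locus_id), ]
  pool <- ord1$locus_id[1:6]
  keep <- rk[rk$locus_id %in% pool, ]
  want <- keep$locus_id[order(-keep$mean_p_distance, keep$locus_id)][1:3]
  expect_equal(got, want)

  expect_error(select_panel(ds, n_low_missing = 50, n_panel = 50), "requested")
  expect_error(select_panel(ds, n_low_missing = 3, n_panel = 5), "exceeds")
})

test_that("sample_loci is seeded, uniform and bounded", {
  ds <- diagnostic_dataset(n_loci = 8)
  expect_setequal(sample_loci(ds, 8, seed = 1), rownames(ds$present))
  expect_identical(sample_loci(ds, 3, seed = 9), sample_loci(ds, 3, seed = 9))
  expect_error(sample_loci(ds, 9), "cannot sample")
  # frequency of n=1 draws is approximately uniform
  withr::local_seed(2)
  draws <- table(replicate(8000, sample_loci(ds, 1)))
  expect_gt(stats::chisq.test(draws)$p.value, 0.001)
})
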