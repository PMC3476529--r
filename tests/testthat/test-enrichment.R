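test_that("profiles rank descending with lexicographic tie-breaking", {
  m <- tiny_matrix()              # s1 values: gA=5, gB=1, gC=9
  r <- rank_profile(m, "s1")
  expect_equal(r$genes, c("gC", "gA", "gB"))
  expect_equal(r$n, 3)
  # all-equal values -> pure lexicographic order
  m$values[, 1] <- 7
  expect_equal(rank_profile(m, "s1")$genes, c("gA", "gB", "gC"))
  # reversing values reverses the ranking (no ties here)
  m2 <- tiny_matrix()
  m2$values[, 1] <- -m2$values[, 1]
  expect_equal(rank_profile(m2, "s1")$genes, rev(rank_profile(tiny_matrix(), "s1")$genes))
  expect_error(rank_profile(m, "nope"), "no such sample")
})

test_that("hand-derived KS values for a 10-gene universe are exact", {
  r <- ranked_from_ids(sprintf("g%02d", 1:10))
  expect_identical(ks_statistic(c("g01", "g02"), r), 0.8)
  expect_identical(ks_statistic(c("g09", "g10"), r), -0.9)
})

test_that("KS statistic equals the exhaustive running-sum oracle on every placement, n <= 12", {
  impl <- c(); orac <- c()
  for (n in 2:12) {
    r <- ranked_from_ids(sprintf("g%02d", seq_len(n)))
    for (t in seq_len(n - 1)) {
      placements <- utils::combn(n, t)
      for (k in seq_len(ncol(placements))) {
        pos <- placements[, k]
        impl <- c(impl, ks_statistic(r$genes[pos], r))
        orac <- c(orac, ks_oracle(pos, n))
      }
    }
  }
  expect_gt(length(impl), 8000)
  expect_identical(impl, orac)
})

test_that("KS statistic matches the oracle on random instances up to n = 50", {
  set.seed(99)
  res <- t(vapply(1:400, function(i) {
    n <- sample(3:50, 1)
    t <- sample(seq_len(n - 1), 1)
    pos <- sample.int(n, t)
    r <- ranked_from_ids(sprintf("g%02d", seq_len(n)))
    c(ks_statistic(r$genes[pos], r), ks_oracle(pos, n))
  }, numeric(2)))
  expect_identical(res[, 1], res[, 2])
})

test_that("KS statistic validates its inputs", {
  r <- ranked_from_ids(c("a", "b", "c"))
  expect_error(ks_statistic(character(0), r), "empty")
  expect_error(ks_statistic(c("a", "zz"), r), "zz")
  expect_error(ks_statistic(c("a", "b", "c"), r), "strict subset")
})

test_that("connectivity score zeroes same-sign pairs and is antisymmetric", {
  r <- ranked_from_ids(sprintf("g%02d", 1:20))
  up_top <- c("g01", "g02", "g03")
  dn_bot <- c("g18", "g19", "g20")
  sig <- gene_signature("q", up_top, dn_bot)
  expect_gt(connectivity_score(sig, r), 0)
  # both sets at the top -> same sign -> 0
  both_top <- gene_signature("q2", c("g01", "g02"), c("g03", "g04"))
  expect_identical(connectivity_score(both_top, r), 0)
  # antisymmetry on random instances
  set.seed(7)
  for (i in 1:200) {
    n <- sample(10:40, 1)
    rr <- ranked_from_ids(sprintf("g%02d", seq_len(n)))
    picks <- sample(rr$genes, 6)
    s1 <- gene_signature("a", picks[1:3], picks[4:6])
    s2 <- gene_signature("b", picks[4:6], picks[1:3])
    expect_identical(connectivity_score(s1, rr), -connectivity_score(s2, rr))
  }
})

test_that("score scaling maps into [-1, 1], preserves order and sign, and is idempotent", {
  expect_equal(scale_scores(c(2, 1, -0.5)), c(1, 0.5, -1))
  expect_equal(scale_scores(c(0, 0)), c(0, 0))
  set.seed(11)
  for (i in 1:50) {
    x <- round(rnorm(sample(2:20, 1)), 2)
    s <- scale_scores(x)
    expect_true(all(s >= -1 & s <= 1))
    expect_equal(sign(s), sign(x))
    expect_equal(order(s), order(x))
    expect_equal(scale_scores(s), s)
  }
})

test_that("permutation p-values hit their boundaries", {
  r <- ranked_from_ids(sprintf("g%03d", 1:100))
  # observed score 0: every |null| >= 0, so p = 1
  same_sign <- gene_signature("z", c("g001", "g002"), c("g003", "g004"))
  expect_identical(connectivity_score(same_sign, r), 0)
  expect_equal(permutation_test(same_sign, r, B = 200, seed = 1)$p.value, 1)
  # perfectly separated signature attains the add-one minimum 1/(B+1)
  extreme <- gene_signature("e", sprintf("g%03d", 1:10), sprintf("g%03d", 91:100))
  pt <- permutation_test(extreme, r, B = 1000, seed = 2)
  expect_equal(pt$p.value, 1 / 1001)
  expect_error(permutation_test(
    gene_signature("w", sprintf("g%03d", 1:60), sprintf("g%03d", 61:100)),
    ranked_from_ids(c("a", "b")), B = 10), "smaller")
})

test_that("permutation test is deterministic given a seed and restores RNG state", {
  r <- ranked_from_ids(sprintf("g%03d", 1:60))
  sig <- gene_signature("q", sprintf("g%03d", 1:5), sprintf("g%03d", 30:34))
  set.seed(123); before <- runif(1)
  set.seed(123)
  p1 <- permutation_test(sig, r, B = 199, seed = 5)$p.value
  after <- runif(1)
  expect_equal(after, before)
  p2 <- permutation_test(sig, r, B = 199, seed = 5)$p.value
  expect_identical(p1, p2)
})

test_that("enrichment table recovers the query subset and inverse relationships", {
  g <- generate_cohort(default_cohort_design(seed = 41))
  m <- center_samples(g$expression$human)
  f <- remove_genes(m, tissue_specific_genes(m, "blood", "skin"))
  sig <- derive_signature(f, "CD141_DC")
  et <- enrichment_table(sig, f, B = 200, seed = 3)
  expect_true(all(et$scores$scaled_score >= -1 & et$scores$scaled_score <= 1))
  expect_true(all(et$scores$p_value >= 1 / 201 & et$scores$p_value <= 1))
  # self subset on top, monocyte references inverse
  expect_equal(et$by_subset$subset[1], "CD141_DC")
  expect_lt(et$by_subset$mean_scaled[et$by_subset$subset == "CD14_mono"], 0)
  expect_lt(et$by_subset$mean_scaled[et$by_subset$subset == "CD16_mono"], 0)
})

test_that("per-sample and subset-mean scoring agree on subset rank order", {
  g <- generate_cohort(default_cohort_design(seed = 43))
  m <- center_samples(g$expression$human)
  f <- remove_genes(m, tissue_specific_genes(m, "blood", "skin"))
  sig <- derive_signature(f, "CD141_DC")
  per_sample <- enrichment_table(sig, f, per_sample = TRUE, B = 50, seed = 1)
  per_mean <- enrichment_table(sig, f, per_sample = FALSE, B = 50, seed = 1)
  expect_equal(per_mean$by_subset$subset, per_sample$by_subset$subset)
})

test_that("signature genes absent from the references follow the intersection policy", {
  m <- noise_matrix(n_genes = 60, seed = 61)
  sig <- derive_signature(m, "A", size = 10)
  # a few genes missing: dropped with a warning, scores still computed
  small <- remove_genes(m, sig$up[1:2])
  expect_warning(et <- enrichment_table(sig, small, B = 20, seed = 1), "dropping")
  expect_equal(nrow(et$scores), ncol(m$values))
  # more than half missing: error
  tiny <- remove_genes(m, c(sig$up, sig$down[1:3]))
  expect_error(suppressWarnings(enrichment_table(sig, tiny, B = 20, seed = 1)),
               "50%")
})
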