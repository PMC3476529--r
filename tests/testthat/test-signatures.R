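test_that("vectorized Welch t matches stats::t.test gene by gene", {
  set.seed(21)
  x <- matrix(rnorm(20 * 6), 20)
  y <- matrix(rnorm(20 * 4, 0.5), 20)
  res <- dcmap:::welch_rows(x, y)
  for (i in seq_len(20)) {
    ref <- stats::t.test(x[i, ], y[i, ])
    expect_equal(res$statistic[i], unname(ref$statistic))
    expect_equal(res$df[i], unname(ref$parameter))
    expect_equal(res$p.value[i], ref$p.value)
  }
})

test_that("tissue filter recovers planted tissue genes and stays near-empty without signal", {
  g <- generate_cohort(human_cohort_design(seed = 31))
  m <- center_samples(g$expression$human)
  tg <- tissue_specific_genes(m, "blood", "skin")
  planted <- unlist(g$truth$tissue_genes$human)
  expect_gt(mean(planted %in% tg), 0.9)
  expect_lt(sum(!tg %in% planted) / max(length(tg), 1), 0.1)

  g0 <- generate_cohort(human_cohort_design(seed = 31, tissue_effect = 0))
  tg0 <- tissue_specific_genes(center_samples(g0$expression$human), "blood", "skin")
  expect_lt(length(tg0), 20)   # false positives only

  # per-subset union variant runs and is FDR-controlled too
  tg_ps <- tissue_specific_genes(m, "blood", "skin", method = "per_subset")
  expect_lt(sum(!tg_ps %in% planted) / max(length(tg_ps), 1), 0.2)

  # no subset shared between tissues -> filter undefined
  m2 <- m
  m2$samples$subset[m2$samples$tissue == "skin"] <-
    paste0(m2$samples$subset[m2$samples$tissue == "skin"], "_sk")
  expect_error(tissue_specific_genes(m2, "blood", "skin"), "both tissues")
})

test_that("remove_genes is an identity on the empty set, idempotent, and guarded", {
  m <- noise_matrix(n_genes = 20)
  expect_equal(remove_genes(m, character(0)), m)
  f <- remove_genes(m, c("g001", "g002"))
  expect_equal(nrow(f$values), 18)
  expect_equal(remove_genes(f, c("g001", "g002")), f)
  expect_equal(rownames(f$values), setdiff(rownames(m$values), c("g001", "g002")))
  expect_error(remove_genes(m, rownames(m$values)), "every gene")
})

test_that("removing planted tissue genes eliminates the tissue contribution", {
  d <- human_cohort_design(seed = 7, noise_sd = 0, donor_sd = 0)
  g <- generate_cohort(d)
  f <- remove_genes(g$expression$human, unlist(g$truth$tissue_genes$human))
  # remaining genes: CD1c skin vs blood profiles differ only through markers,
  # which are equal across tissues -> identical
  a <- f$values[, f$samples$subset == "CD1c_DC" & f$samples$tissue == "blood"][, 1]
  b <- f$values[, f$samples$subset == "CD1c_DC" & f$samples$tissue == "skin"][, 1]
  expect_equal(a, b)
})

test_that("SNR ranking matches a direct per-gene formula loop", {
  m <- noise_matrix(n_genes = 40, seed = 13)
  tgt <- m$samples$subset == "A"
  s <- snr_statistic(m, tgt)
  for (i in seq_len(40)) {
    x <- m$values[i, tgt]; y <- m$values[i, !tgt]
    st <- max(sd(x), 0.2 * abs(mean(x)), 0.2)
    sr <- max(sd(y), 0.2 * abs(mean(y)), 0.2)
    expect_equal(unname(s[i]), (mean(x) - mean(y)) / (st + sr))
  }
})

test_that("derived signatures recover planted markers and obey their invariants", {
  g <- generate_cohort(default_cohort_design(seed = 17))
  m <- center_samples(g$expression$human)
  f <- remove_genes(m, tissue_specific_genes(m, "blood", "skin"))
  sig <- derive_signature(f, "CD141_DC")
  expect_s3_class(sig, "GeneSignature")
  expect_length(sig$up, 150)
  expect_length(sig$down, 150)
  expect_length(intersect(sig$up, sig$down), 0)
  expect_gt(mean(g$truth$marker_genes$human$cd141_like %in% sig$up), 0.9)
  # monocyte markers dominate the down set (elevated in the largest rest block)
  expect_gt(mean(sig$down %in% g$truth$marker_genes$human$monocyte_like), 0.5)
})

test_that("signature derivation is invariant to column order and per-gene shifts", {
  m <- noise_matrix(n_genes = 50, seed = 77)
  s1 <- derive_signature(m, "A", size = 10)
  perm <- sample(ncol(m$values))
  mp <- expression_matrix(m$values[, perm], m$samples[perm, ])
  s2 <- derive_signature(mp, "A", size = 10)
  expect_equal(s2$up, s1$up)
  expect_equal(s2$down, s1$down)
  # a constant per-gene shift cancels in the SNR numerator; as long as the
  # mean-proportional variance floor stays non-binding the ranking is identical
  m0 <- m
  m0$values <- m0$values - 8 + rnorm(nrow(m0$values)) * 0   # centered copy
  s0 <- derive_signature(m0, "A", size = 10)
  ms <- m0
  ms$values <- ms$values + runif(nrow(ms$values), -1, 1)
  s3 <- derive_signature(ms, "A", size = 10)
  expect_equal(s3$up, s0$up)
  expect_equal(s3$down, s0$down)
})

test_that("tissue-gene removal increases marker purity of every subset's up-set", {
  g <- generate_cohort(human_cohort_design(seed = 23))
  m <- center_samples(g$expression$human)
  f <- remove_genes(m, unlist(g$truth$tissue_genes$human))
  lin <- c(CD141_DC = "cd141_like", CD1c_DC = "cd1c_like",
           CD14_mono = "monocyte_like", pDC = "pdc_like")
  for (s in names(lin)) {
    mk <- g$truth$marker_genes$human[[lin[[s]]]]
    before <- mean(derive_signature(m, s)$up %in% mk)
    after <- mean(derive_signature(f, s)$up %in% mk)
    expect_gte(after, before)
  }
})

test_that("pooling a subset with itself reproduces the unpooled ranking", {
  m <- noise_matrix(n_genes = 50, seed = 31)
  s1 <- derive_signature(m, "B", size = 10)
  s2 <- pool_signature(list(m, m), "B", size = 10)
  expect_equal(s2$up, s1$up)
  expect_equal(s2$down, s1$down)
})

test_that("pooled lineage signatures resemble their lineage more than another", {
  g <- generate_cohort(default_cohort_design(seed = 29))
  m <- center_samples(g$expression$human)
  f <- remove_genes(m, tissue_specific_genes(m, "blood", "skin"))
  pooled <- pool_signature(f, "CD141_DC")
  single_blood <- derive_signature(
    expression_matrix(f$values[, f$samples$tissue == "blood"],
                      f$samples[f$samples$tissue == "blood", ]), "CD141_DC")
  other <- derive_signature(f, "CD1c_DC")
  jac <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  expect_gt(jac(pooled$up, single_blood$up), jac(pooled$up, other$up))
  expect_length(intersect(pooled$up, pooled$down), 0)
})

test_that("gene-space mismatch in pooling is reported with the symmetric difference", {
  m1 <- noise_matrix(n_genes = 30, seed = 1)
  m2 <- noise_matrix(n_genes = 28, seed = 1)
  expect_error(pool_signature(list(m1, m2), "A"), "symmetric difference: 2")
})

test_that("signatures round-trip through GMT with directions preserved", {
  m <- noise_matrix(n_genes = 40, seed = 51)
  sigs <- list(A = derive_signature(m, "A", size = 8),
               B = derive_signature(m, "B", size = 8))
  dir <- withr::local_tempdir()
  p <- file.path(dir, "sigs.gmt")
  write_signature(sigs, p)
  back <- read_signature(p)
  expect_equal(back$A$up, sigs$A$up)
  expect_equal(back$A$down, sigs$A$down)
  expect_equal(back$B$source_subsets, "B")
})
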