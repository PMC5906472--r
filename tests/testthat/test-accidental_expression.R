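test_that("a promoter-free coding sequence scores zero with no hits", {
  s <- strrep("C", 600)
  sc <- score_gene(s, test_model)
  expect_equal(sc$total_per_kb, 0)
  expect_equal(sc$sense_per_kb, 0)
  expect_equal(sc$antisense_per_kb, 0)
  expect_equal(nrow(sc$hits), 0L)
  expect_error(score_gene(s, default_promoter_model(calibrate = FALSE)),
               "calibrated")
})

test_that("a single planted sense promoter gives the closed-form score", {
  m <- test_model
  cds <- embed_consensus(strrep("C", 1000), at = 400, spacer = 17)
  sc <- score_gene(cds, m)
  expect_equal(nrow(sc$hits), 1L)
  h <- sc$hits
  expect_equal(h$strand, "+")
  expect_equal(h$pos35, 400L)
  # contribution = (s35 + s10) * (1 + total - threshold), normalized per kb
  expect_equal(sc$sense_per_kb,
               (h$s35 + h$s10) * (1 + h$total - m$threshold) * 1000 / 1000)
  expect_equal(sc$antisense_per_kb, 0)
  expect_equal(sc$total_per_kb, sc$sense_per_kb)
})

test_that("well-separated promoters contribute additively", {
  m <- test_model
  bg <- strrep("C", 1000)
  one_a <- score_gene(embed_consensus(bg, 100), m)$total_per_kb
  one_b <- score_gene(embed_consensus(bg, 700), m)$total_per_kb
  both <- score_gene(embed_consensus(embed_consensus(bg, 100), 700),
                     m)$total_per_kb
  expect_equal(both, one_a + one_b)
})

test_that("sense and antisense swap under reverse complement", {
  m <- test_model
  for (s in random_dna(10, 400, seed = 3)) {
    a <- score_gene(s, m)
    b <- score_gene(revcomp(s), m)
    expect_equal(a$sense_per_kb, b$antisense_per_kb)
    expect_equal(a$antisense_per_kb, b$sense_per_kb)
    expect_equal(a$total_per_kb, b$total_per_kb)
  }
})

test_that("overlapping placements are suppressed to one local maximum", {
  m <- test_model
  # one strong site: suppression must leave a single hit within 10 nt
  cds <- embed_consensus(strrep("C", 500), at = 200, spacer = 17)
  h <- score_gene(cds, m)$hits
  h_sense <- h[h$strand == "+", ]
  if (nrow(h_sense) > 1L) {
    d <- diff(sort(h_sense$pos10))
    expect_true(all(d >= 10))
  } else expect_equal(nrow(h_sense), 1L)
})

test_that("mid-rank percentiles and deciles follow the tie rules", {
  r <- rank_gene(rep(1, 1000), 0)          # wt below all nulls
  expect_equal(r$percentile, 0)
  expect_equal(r$decile, 1L)
  r <- rank_gene(rep(1, 1000), 2)          # wt above all nulls
  expect_equal(r$percentile, 1)
  expect_equal(r$decile, 10L)
  r <- rank_gene(rep(0, 1000), 0)          # all tied at zero
  expect_equal(r$percentile, 0.5)
  expect_equal(r$decile, 6L)
  r <- rank_gene(c(1, 2, 3), 2.5)          # small ensemble: no decile
  expect_true(is.na(r$decile))
  expect_equal(r$percentile, 2 / 3)
})

test_that("percentiles are invariant under joint monotone transforms", {
  set.seed(9)
  nulls <- rnorm(200)
  wt <- nulls[17]
  p1 <- rank_gene(nulls, wt)$percentile
  f <- function(x) exp(3 * x) + 1
  p2 <- rank_gene(f(nulls), f(wt))$percentile
  expect_equal(p1, p2)
})

test_that("decile histograms are percentages and respect subsets", {
  ranks <- data.frame(gene_id = paste0("g", 1:100),
                      decile = rep(1:10, each = 10))
  h <- decile_histogram(ranks)
  expect_equal(h$percent, rep(10, 10))
  expect_equal(sum(h$percent), 100)
  h1 <- decile_histogram(data.frame(gene_id = "a", decile = 1L))
  expect_equal(h1$percent[1], 100)
  hs <- decile_histogram(ranks, subset = paste0("g", 1:10))
  expect_equal(hs$percent[1], 100)
  expect_error(decile_histogram(ranks, subset = "nope", "toxins"), "toxins")
})

test_that("KS contrasts match a brute-force ECDF-gap oracle", {
  expect_equal(group_ks(c(1, 2, 3), c(1, 2, 3))$D, 0)
  expect_equal(group_ks(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_equal(group_ks(c(1, 2, 3), c(10, 11, 12))$D, 1)
  set.seed(13)
  for (i in 1:5) {
    a <- rnorm(20); b <- rnorm(20, mean = runif(1, 0, 2))
    expect_equal(group_ks(a, b)$D, oracle_ks_D(a, b))
  }
  expect_error(group_ks(1, c(1, 2)), "at least 2")
})

test_that("the paired sign test is the exact two-sided binomial", {
  expect_equal(paired_sign_test(c(2, 2, 2, 2, 2), rep(1, 5))$p_value, 0.0625)
  expect_equal(paired_sign_test(c(2, 2, 1, 1), c(1, 1, 2, 2))$p_value, 1)
  # ties dropped before counting
  r <- paired_sign_test(c(5, 5, 2, 2, 2), c(5, 1, 1, 1, 1))
  expect_equal(r$n, 4L)
  expect_equal(r$k, 4L)
  # k = 16, n = 20 against exhaustive enumeration
  a <- c(rep(2, 16), rep(0, 4)); b <- rep(1, 20)
  expect_equal(paired_sign_test(a, b)$p_value, oracle_sign_p(16, 20))
  expect_error(paired_sign_test(c(1, 1), c(1, 1)), "tied")
})

test_that("null_ensemble couples wild type and nulls consistently", {
  cds <- random_cds(150, seed = 77)
  ens <- null_ensemble(cds, test_model, mode = "usage", n = 15,
                       usage = test_usage, seed = 4, gene_id = "gE")
  expect_s3_class(ens, "null_ensemble")
  expect_length(ens$null_scores, 15L)
  expect_equal(ens$wt_score, score_gene(cds, test_model)$total_per_kb)
  expect_equal(ens$wt_score, ens$wt_sense + ens$wt_antisense)
  rk <- rank_gene(ens)
  expect_equal(rk$gene_id, "gE")
  expect_gte(rk$percentile, 0)
  expect_lte(rk$percentile, 1)
})
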