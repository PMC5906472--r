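test_that("tilted usage tables hit their GC target", {
  u <- synth_usage_table(0.508)
  # independent expectation oracle: mean per-codon GC under uniform AAs
  gc <- Biostrings::GENETIC_CODE
  gc_count <- vapply(names(gc), function(cod)
    sum(strsplit(cod, "")[[1]] %in% c("G", "C")), numeric(1))
  implied <- mean(vapply(setdiff(unique(gc), "*"), function(a) {
    f <- u[u$aa == a, ]
    sum(f$prob * gc_count[f$codon] / 3)
  }, numeric(1)))
  expect_lt(abs(implied - 0.508), 0.01)
  expect_error(synth_usage_table(0), "in \\(0, 1\\)")
  expect_error(synth_usage_table(0.05), "achievable")
})

test_that("synthetic genomes are deterministic and structurally valid", {
  spec <- synth_genome_spec(n_genes = 12, seed = 8, usage = test_usage)
  a <- synth_genome(spec)
  b <- synth_genome(spec)
  expect_identical(a$genes$cds, b$genes$cds)
  expect_equal(nrow(a$genes), 12L)
  expect_true(all(nchar(a$genes$cds) %% 3 == 0))
  expect_true(all(nchar(a$genes$cds) >= 150 * 3))
  # valid CDS structure in neutral mode
  for (cds in a$genes$cds) {
    aa <- translate_cds(cds)
    expect_equal(aa[1], "M")
    expect_equal(aa[length(aa)], "*")
    expect_false(any(aa[-length(aa)] == "*"))
  }
  expect_equal(sum(a$truth$group == "essential"), 1L)
  expect_equal(a$genes$essential, a$truth$group == "essential")
})

test_that("avoid mode removes core-motif hits from generated genes", {
  spec_n <- synth_genome_spec(n_genes = 15, seed = 5, usage = test_usage)
  spec_a <- synth_genome_spec(n_genes = 15, seed = 5, usage = test_usage,
                              avoidance = "avoid")
  neutral <- synth_genome(spec_n)
  avoided <- synth_genome(spec_a)
  n_hits <- function(g) vapply(g$genes$cds, function(s)
    nrow(core_motif_hits(s, strands = c("+", "-"))), numeric(1))
  h_avoid <- n_hits(avoided)
  expect_lt(mean(h_avoid), mean(n_hits(neutral)))
  # genes not flagged partial carry no hits at all
  clean <- !avoided$truth$partial
  expect_true(all(h_avoid[clean] == 0))
  # translation preserved relative to codon-level validity
  for (cds in avoided$genes$cds) {
    aa <- translate_cds(cds)
    expect_false(any(aa[-length(aa)] == "*"))
  }
})

test_that("enrich mode plants recoverable promoter sites", {
  spec <- synth_genome_spec(n_genes = 15, seed = 6, usage = test_usage,
                            avoidance = "enrich", enrich_per_kb = 1)
  sg <- synth_genome(spec)
  expect_true(all(sg$truth$planted_sense >= 1))
  # recall: every planted gene yields at least one sense hit above threshold,
  # and nearly all planted sites are individually recovered
  planted_total <- sum(sg$truth$planted_sense)
  recovered <- 0
  for (i in seq_len(nrow(sg$genes))) {
    h <- score_gene(sg$genes$cds[i], test_model)$hits
    expect_gte(nrow(h[h$strand == "+", ]), 1)
    recovered <- recovered + min(nrow(h[h$strand == "+", ]),
                                 sg$truth$planted_sense[i])
  }
  expect_gte(recovered / planted_total, 0.95)
})

test_that("antisense planting biases toxin genes to the antisense strand", {
  spec <- synth_genome_spec(
    n_genes = 10, seed = 7, usage = test_usage,
    group_fractions = c(toxin = 0.5, antitoxin = 0.5, essential = 0, none = 0),
    antisense_bias_for_toxins = TRUE)
  sg <- synth_genome(spec)
  tox <- sg$truth$group == "toxin"
  expect_true(all(sg$truth$planted_antisense[tox] >= 1))
  expect_true(all(sg$truth$planted_antisense[!tox] == 0))
  anti <- vapply(sg$genes$cds, function(s)
    score_gene(s, test_model)$antisense_per_kb, numeric(1))
  expect_gt(mean(anti[tox]), mean(anti[!tox]))
})

test_that("synthetic promoter sets behave like a calibration set", {
  m <- test_model
  # zero noise at the optimal spacer: every sequence scores the maximum
  ps0 <- synth_promoter_set(n = 10, noise_per_position = 0, seed = 1,
                            spacer_lengths = 17, spacer_probs = 1)
  max_attainable <- sum(apply(m$w35, 1, max)) + sum(apply(m$w10, 1, max)) +
    max(m$spacer_weight)
  for (s in as.character(ps0))
    expect_equal(best_window_score(m, s)$score, max_attainable)

  expect_error(synth_promoter_set(n = 1), "at least 2")
  expect_error(synth_promoter_set(n = 5, noise_per_position = 1), "noise")

  # noisy promoters still score above the random-sequence median
  ps <- synth_promoter_set(n = 200, noise_per_position = 0.15, seed = 2)
  prom_scores <- vapply(as.character(ps), function(s)
    best_window_score(m, s)$score, numeric(1))
  rand_scores <- vapply(
    as.character(generate_random_sequences(200, seed = 3)),
    function(s) best_window_score(m, s)$score, numeric(1))
  expect_gt(median(prom_scores), median(rand_scores))
  expect_gt(unname(quantile(prom_scores, 0.1)), median(rand_scores))

  # a threshold calibrated on noisy promoters accepts consensus promoters
  m15 <- calibrate_threshold(m, synth_promoter_set(n = 200,
                                                   noise_per_position = 0.15,
                                                   seed = 4))
  held_out <- as.character(synth_promoter_set(n = 100,
                                              noise_per_position = 0,
                                              seed = 5))
  pass <- mean(vapply(held_out, function(s)
    best_window_score(m15, s)$score >= m15$threshold, logical(1)))
  expect_gte(pass, 0.9)
})
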