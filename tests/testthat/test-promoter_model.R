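test_that("build_pwm recovers the consensus and validates its input", {
  w <- data.frame(minus35 = rep("TTGACA", 10), spacer = rep(17L, 10),
                  minus10 = rep("TATAAT", 10))
  m <- build_pwm(w)
  expect_equal(paste(c("A", "C", "G", "T")[apply(m$w35, 1, which.max)],
                     collapse = ""), "TTGACA")
  expect_equal(paste(c("A", "C", "G", "T")[apply(m$w10, 1, which.max)],
                     collapse = ""), "TATAAT")
  expect_equal(unname(which.max(m$spacer_weight)), 3L)  # 17 nt

  expect_error(build_pwm(w[1, ]), "at least 2")
  w_bad <- w; w_bad$spacer[1] <- 25L
  expect_error(build_pwm(w_bad), "spacer")
})

test_that("log-odds weights equal an independent recomputation", {
  set.seed(7)
  w <- data.frame(
    minus35 = random_dna(10, 6),
    spacer = sample(15:19, 10, replace = TRUE),
    minus10 = random_dna(10, 6))
  # random spacers need not peak at 17 nt; that warning is expected here
  m <- suppressWarnings(build_pwm(w, pseudocount = 0.5))
  # spreadsheet-style: tabulate characters per column, apply the formula
  for (j in 1:6) {
    col <- substr(w$minus35, j, j)
    for (b in c("A", "C", "G", "T")) {
      cnt <- sum(col == b)
      expect_equal(unname(m$w35[j, b]), log2((cnt + 0.5) / (10 + 2) / 0.25))
    }
  }
  sp_cnt <- table(factor(w$spacer, levels = 15:19))
  expect_equal(unname(m$spacer_weight),
               unname(log2((as.numeric(sp_cnt) + 1) / (10 + 5) * 5)))
})

test_that("threshold calibration takes the median, even sets averaged", {
  m <- test_model
  # four sequences with distinct known scores
  seqs <- random_dna(4, 60, seed = 21)
  scores <- sort(vapply(seqs, function(s) best_window_score(m, s)$score,
                        numeric(1)))
  m4 <- calibrate_threshold(m, seqs)
  expect_equal(m4$threshold, mean(scores[2:3]))
  m5 <- calibrate_threshold(m, c(seqs, embed_consensus(strrep("A", 60), 10)))
  expect_equal(m5$threshold, unname(scores[3]))   # odd set: central value
  expect_error(calibrate_threshold(m, c(ok = seqs[1], tiny = "ACGT")), "tiny")
})

test_that("best_window_score finds an embedded consensus at its offset", {
  m <- test_model
  seq <- embed_consensus(strrep("C", 103), at = 30, spacer = 17)
  bw <- best_window_score(m, seq)
  expect_equal(bw$hit$pos35, 30L)
  expect_equal(bw$hit$spacer, 17L)
  expect_equal(bw$hit$pos10, 30L + 6L + 17L)
  max_attainable <- sum(apply(m$w35, 1, max)) + sum(apply(m$w10, 1, max)) +
    max(m$spacer_weight)
  expect_equal(bw$score, max_attainable)
  expect_gte(bw$hit$margin, 0)

  # homogeneous sequence: element scores tie everywhere, so the optimal
  # spacer wins and the leftmost placement is taken
  bw_a <- best_window_score(m, strrep("A", 103))
  expect_true(is.finite(bw_a$score))
  expect_equal(bw_a$hit$pos35, 0L)
  expect_equal(bw_a$hit$spacer, 17L)
})

test_that("best placement agrees with exhaustive enumeration on short toys", {
  m <- test_model
  for (s in random_dna(25, 30, seed = 31)) {
    o <- oracle_best_window(m, s)
    bw <- best_window_score(m, s)
    expect_equal(bw$score, o$score)
    expect_equal(bw$hit$pos35, o$pos35)
    expect_equal(bw$hit$spacer, o$spacer)
  }
})

test_that("minus-strand score equals plus-strand score of the reverse complement", {
  m <- test_model
  for (s in random_dna(20, 80, seed = 41)) {
    expect_equal(best_window_score(m, s, strands = "-")$score,
                 best_window_score(m, revcomp(s), strands = "+")$score)
  }
})

test_that("moving a weighted position to consensus never decreases the score", {
  m <- test_model
  con35 <- c("A", "C", "G", "T")[apply(m$w35, 1, which.max)]
  for (s in random_dna(20, 60, seed = 51)) {
    bw <- best_window_score(m, s)
    ch <- strsplit(s, "")[[1]]
    j <- sample(1:6, 1)
    ch[bw$hit$pos35 + j] <- con35[j]
    expect_gte(best_window_score(m, paste(ch, collapse = ""))$score,
               bw$score)
  }
})

test_that("core-motif hits are exact matches with a valid spacer", {
  seq <- paste0(strrep("C", 20), "TTGAAA", strrep("C", 16), "TAGGGT",
                strrep("C", 30))
  hits <- core_motif_hits(seq)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$pos35, 20L)
  expect_equal(hits$spacer, 16L)
  expect_equal(hits$pos10, 20L + 6L + 16L)
  expect_equal(nrow(core_motif_hits(strrep("C", 103))), 0L)
})

test_that("core-hit presence agrees with a regex oracle on random sequences", {
  seqs <- as.character(generate_random_sequences(2000, seed = 61))
  got <- vapply(seqs, function(s) nrow(core_motif_hits(s)) > 0, logical(1))
  want <- vapply(seqs, oracle_has_core, logical(1))
  expect_identical(unname(got), unname(want))
})

test_that("mismatch counting agrees with a brute-force oracle", {
  expect_equal(count_mismatches_to_core(
    embed_consensus(strrep("A", 60), 10))$min_mismatch, 0L)
  corrupted <- embed_consensus(strrep("A", 60), 10, m35 = "TTCACA")
  expect_equal(count_mismatches_to_core(corrupted)$min_mismatch, 1L)
  expect_equal(count_mismatches_to_core(corrupted)$mismatches$to, "G")

  for (s in random_dna(200, 40, seed = 71)) {
    expect_equal(count_mismatches_to_core(s)$min_mismatch,
                 oracle_core_mismatches(s))
  }
})

test_that("zero-mismatch placements contain every core hit", {
  for (s in random_dna(200, 50, seed = 81)) {
    has_hit <- nrow(core_motif_hits(s)) > 0
    expect_equal(count_mismatches_to_core(s)$min_mismatch == 0L, has_hit)
  }
})

test_that("the packaged default model is canonical and calibrated", {
  m <- test_model
  expect_s3_class(m, "promoter_model")
  expect_equal(paste(c("A", "C", "G", "T")[apply(m$w35, 1, which.max)],
                     collapse = ""), "TTGACA")
  expect_equal(paste(c("A", "C", "G", "T")[apply(m$w10, 1, which.max)],
                     collapse = ""), "TATAAT")
  expect_equal(names(which.max(m$spacer_weight)), "17")
  expect_false(is.na(m$threshold))
  # reproducible given the same seed
  expect_equal(default_promoter_model(seed = 42L)$threshold, m$threshold)
})
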