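test_that("tag scores at single positions match the worked toy values", {
  toy <- toy_fixture()
  s <- toy$protein
  expect_equal(tag_score(s, 10, toy$index, L = 25)$theta, 4L) # N
  expect_equal(tag_score(s, 8, toy$index, L = 25)$theta, 3L)  # S
  expect_equal(tag_score(s, 11, toy$index, L = 25)$theta, 2L) # A
  expect_equal(tag_score(s, 4, toy$index, L = 25)$theta, 0L)  # D
  expect_error(tag_score(s, 3, toy$index), "undefined")
  expect_error(tag_score(s, 16, toy$index), "undefined")

  # contributing pairs for N-10 are the four documented k-mer pairs
  contrib <- tag_score(s, 10, toy$index, L = 25)$contributors
  expect_equal(nrow(contrib), 4)
  pairs <- sort(apply(contrib, 1, function(r)
    paste(substr(s, as.integer(r[["w1_start"]]), as.integer(r[["w1_end"]])),
          substr(s, as.integer(r[["w2_start"]]), as.integer(r[["w2_end"]])))))
  expect_equal(pairs, sort(c("DPV SMP", "PVL SMP", "ATS DPV", "ATS LSG")))
})

test_that("score_string reproduces the toy per-residue score table", {
  toy <- toy_fixture()
  sc <- score_string(toy$protein, toy$index, k = 3, L = 25, tol = 0.02)
  expect_true(sc$scorable)
  expect_equal(sc$theta[4:15], c(0, 0, 0, 2, 3, 3, 4, 2, 2, 0, 0, 0))
  expect_true(all(is.na(sc$theta[c(1:3, 16:18)])))
  expect_equal(sc$kappa,
               c(0, 0, 0, 1, 1, 1, 1, 1, 1, 0, 1, 1, 1, 1, 1, 0, 0, 0))
  expect_equal(sc$theta_sum, 16)

  # each position agrees with a standalone tag_score call
  for (g in 4:15) {
    expect_equal(sc$theta[g], tag_score(toy$protein, g, toy$index,
                                        L = 25)$theta)
  }

  # empty tag set: all theta zero, all kappa zero
  empty <- tag_index(data.frame(tag = character(), offset = numeric(),
                                spectrum_id = character()), k = 3)
  sc0 <- score_string(toy$protein, empty, k = 3)
  expect_true(all(sc0$theta[!is.na(sc0$theta)] == 0))
  expect_true(all(sc0$kappa == 0))

  # too-short and unknown-residue strings are unscorable
  expect_false(score_string("AVTDPV", toy$index)$scorable)
  expect_false(score_string("AVTDPVXSGNAT", toy$index)$scorable)
})

test_that("adding tags never decreases a tag score", {
  set.seed(73)
  for (i in 1:10) {
    idx1 <- random_tag_index(sample(5:20, 1))
    extra <- random_tag_index(sample(1:10, 1))
    idx2 <- tag_index(rbind(as.data.frame(idx1)[1:3],
                            as.data.frame(extra)[1:3]), k = 3)
    s <- random_string(9)
    sc1 <- score_string(s, idx1)
    sc2 <- score_string(s, idx2)
    ok <- !is.na(sc1$theta)
    expect_true(all(sc2$theta[ok] >= sc1$theta[ok]))
  }
})

test_that("the all-positive filter requires positive theta and full kappa coverage", {
  toy <- toy_fixture()
  # the toy protein has zero tag scores, so it fails
  sc_toy <- score_string(toy$protein, toy$index)
  expect_length(positive_score_filter(list(sc_toy)), 0)

  # a fully covered synthetic peptide passes
  sim <- simulate_dataset(synthetic_spec(seed = 5))
  idx <- generate_tags(sim$spectra)
  true_seq <- sim$truth$sequence[sim$truth$is_true][1]
  sc <- score_string(true_seq, idx)
  expect_true(all(sc$theta[!is.na(sc$theta)] > 0))
  expect_length(positive_score_filter(list(sc)), 1)

  # length 2k+1 can never qualify (middle kappa is necessarily zero)
  sc7 <- score_string(substr(true_seq, 1, 7), idx)
  expect_identical(sc7$kappa[4], 0L)
  expect_length(positive_score_filter(list(sc7)), 0)
})

test_that("Hamming elimination follows the three alignment conditions", {
  a <- fake_scored("PEPTIDER", 10)
  b <- fake_scored("PEPTIDER", 5)
  expect_equal(vapply(hamming_elimination(list(a, b)), `[[`, character(1),
                      "sequence"), "PEPTIDER")

  # three substitutions survive
  c3 <- fake_scored("PEATIQEW", 5)
  expect_length(hamming_elimination(list(a, c3)), 2)

  # a one-longer string is matched on its prefix or suffix
  longer <- fake_scored("XPEPTIDER", 5)
  expect_length(hamming_elimination(list(a, longer)), 1)
  two_longer <- fake_scored("XXPEPTIDER", 5)
  expect_length(hamming_elimination(list(a, two_longer)), 2)

  # a shorter string is matched against every substring
  sub <- fake_scored("PTIDER", 3)
  expect_length(hamming_elimination(list(a, sub)), 1)

  # the highest-scoring candidate always survives
  expect_equal(hamming_elimination(list(b, a))[[1]]$theta_sum, 10)

  set.seed(79)
  for (i in 1:20) {
    n <- sample(2:12, 1)
    base <- random_string(sample(7:9, 1))
    seqs <- unique(c(base, vapply(seq_len(n), function(j) {
      s <- strsplit(base, "")[[1]]
      pos <- sample(seq_along(s), sample(1:3, 1))
      s[pos] <- sample(c("A", "G", "S", "P", "V", "W"), length(pos), TRUE)
      paste(s, collapse = "")
    }, character(1))))
    scores <- round(runif(length(seqs), 1, 50))
    scored <- Map(fake_scored, seqs, scores)
    got <- sort(unname(vapply(hamming_elimination(scored), `[[`,
                              character(1), "sequence")))
    expect_equal(got, unname(oracle_hamming_survivors(seqs, scores)))
  }
})

test_that("the middle-score filter thresholds the single defined tag score", {
  toy <- toy_fixture()
  # length-7 window of the toy protein centred on N-10: within the window
  # only the reversed-half pair (STA, GSL) bridges N, so its middle theta is 1
  win <- substr(toy$protein, 7, 13)
  sc <- score_string(win, toy$index, L = 25)
  expect_equal(sc$theta[4], 1)
  expect_length(middle_score_filter(list(sc), h = 0), 1)
  expect_length(middle_score_filter(list(sc), h = 1), 1)
  expect_length(middle_score_filter(list(sc), h = 2), 0)

  zero <- score_string(substr(toy$protein, 1, 7), toy$index)
  expect_equal(zero$theta[4], 0)
  expect_length(middle_score_filter(list(zero), h = 1), 0)
  expect_length(middle_score_filter(list(zero), h = 0), 1)
})

test_that("validate_candidates runs the cascade with per-spectrum grouping", {
  toy <- toy_fixture()
  none <- validate_candidates(
    data.frame(spectrum_id = character(), sequence = character()),
    toy$index)
  expect_length(none$retained, 0)
  expect_equal(unname(none$summary[["final"]]), 0)

  # the toy protein itself fails the positive filter (it has zero scores)
  one <- validate_candidates(
    data.frame(spectrum_id = "toy1", sequence = toy$protein), toy$index)
  expect_length(one$retained, 0)
  expect_identical(one$results$status, "failed_positive_filter")

  sim <- simulate_dataset(synthetic_spec(seed = 42))
  idx <- generate_tags(sim$spectra)
  val <- validate_candidates(sim$candidates, idx, h = 1)
  got <- data.frame(
    spectrum_id = vapply(val$retained, `[[`, character(1), "spectrum_id"),
    sequence = vapply(val$retained, `[[`, character(1), "sequence"))
  truth <- sim$truth
  # every planted true candidate is retained, every decoy removed
  expect_equal(nrow(got), sum(truth$is_true))
  expect_setequal(paste(got$spectrum_id, got$sequence),
                  paste(truth$spectrum_id[truth$is_true],
                        truth$sequence[truth$is_true]))
  # bookkeeping is consistent
  s <- val$summary
  expect_equal(s[["all_positive"]],
               s[["align_retained"]] + s[["align_eliminated"]])
  expect_equal(s[["middle_total"]], s[["middle_pass"]] + s[["middle_fail"]])
  expect_equal(s[["final"]], s[["align_retained"]] + s[["middle_pass"]])
})
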