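test_that("PSSM scores and relative entropy match hand computation", {
  p <- toy_pssm()
  expect_equal(pssm_score("AA", p), log2(0.97 / 0.25), tolerance = 1e-9)
  expect_equal(pssm_score("CA", p), log2(0.01 / 0.25), tolerance = 1e-9)
  expect_equal(pssm_score("AA", p), 1.956, tolerance = 1e-3)
  # H = 0.97 log2(0.97/0.25) + 3 * 0.01 log2(0.01/0.25)
  h_hand <- 0.97 * log2(0.97 / 0.25) + 3 * 0.01 * log2(0.01 / 0.25)
  expect_equal(p$relative_entropy, h_hand, tolerance = 1e-9)
  expect_equal(p$relative_entropy, 1.758, tolerance = 1e-3)
  expect_error(pssm_score("AAA", p), "length")
  expect_true(is.na(pssm_score("NA", p)))
})

test_that("background-equal matrices are uninformative", {
  flat <- pssm("FLAT", matrix(0.25, 4, 3), pseudocount = 0)
  expect_equal(flat$relative_entropy, 0)
  for (s in c("ACG", "TTT", "GAT")) expect_equal(pssm_score(s, flat), 0)
})

test_that("relative entropy is invariant under column permutation", {
  m <- cbind(c(0.7, 0.1, 0.1, 0.1), c(0.1, 0.6, 0.2, 0.1),
             c(0.25, 0.25, 0.25, 0.25))
  a <- pssm("A", m, pseudocount = 0)
  b <- pssm("B", m[, c(3, 1, 2)], pseudocount = 0)
  expect_equal(a$relative_entropy, b$relative_entropy, tolerance = 1e-12)
})

test_that("PSSM validation rejects malformed matrices", {
  expect_error(pssm("BAD", matrix(1, 3, 2)), "4 rows")
  expect_error(pssm("NEG", matrix(c(-1, rep(1, 7)), 4, 2)), "negative")
})

test_that("mark scores scan windows centred on the variant, both strands", {
  p <- toy_pssm()
  # sequence with a strong 'AA' site around the centre
  seqs <- paste0(strrep("C", 20), "AA", strrep("C", 20))
  v_id <- list(position = 21L, ref = "A", alt = "A")
  ms <- mark_scores(seqs, v_id, p, window = 21)
  expect_equal(ms$delta, 0)   # identity variant
  # destroying the site lowers the mutant score
  v <- list(position = 21L, ref = "A", alt = "C")
  ms2 <- mark_scores(seqs, v, p, window = 21, both_strands = FALSE)
  expect_lt(ms2$score_mut, ms2$score_ref)
  expect_equal(ms2$score_ref, pssm_score("AA", p))
  expect_error(mark_scores("ACGT", list(position = 2, ref = "C", alt = "A"),
                           p, window = 1), "longer")
})

test_that("strand symmetry: reverse-complement scan reproduces the score", {
  set.seed(31)
  seqs <- paste(sample(c("A", "C", "G", "T"), 61, replace = TRUE),
                collapse = "")
  m <- cbind(c(0.7, 0.1, 0.1, 0.1), c(0.1, 0.1, 0.7, 0.1),
             c(0.1, 0.7, 0.1, 0.1))
  p <- pssm("P", m, pseudocount = 0)
  pos <- 31L
  refb <- substr(seqs, pos, pos)
  v <- list(position = pos, ref = refb,
            alt = setdiff(c("A", "C", "G", "T"), refb)[1])
  fwd <- mark_scores(seqs, v, p, window = 51)
  # same variant on the reverse-complemented sequence with the rc motif
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs)))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  v_rc <- list(position = nchar(seqs) - pos + 1L,
               ref = comp[[refb]], alt = comp[[v$alt]])
  rev <- mark_scores(rc, v_rc, pssm_revcomp(p), window = 51)
  expect_equal(rev$score_ref, fwd$score_ref, tolerance = 1e-12)
  expect_equal(rev$score_mut, fwd$score_mut, tolerance = 1e-12)
})

test_that("best TF selection admits by relative entropy and ranks by |delta|", {
  # two motifs over a two-base core: hand-computed deltas
  pa <- toy_pssm()                                    # favours "A" at column 1
  mb <- cbind(rep(0.25, 4), c(0.01, 0.97, 0.01, 0.01))  # favours "C" at col 2
  pb <- pssm("TOYB", mb, pseudocount = 0)
  seqs <- paste0(strrep("G", 10), "AA", strrep("G", 10))
  v <- list(position = 11L, ref = "A", alt = "C")
  res <- best_tf_change(seqs, v, list(pa, pb), window = 11,
                        both_strands = FALSE)
  expect_equal(nrow(res), 2L)
  expect_true(all(res$admitted == (pmax(res$score_ref, res$score_mut) >
                                     res$relative_entropy)))
  if (any(res$admitted)) {
    best <- res[res$best, ]
    expect_equal(best$tf,
                 res$tf[res$admitted][which.max(abs(res$delta[res$admitted]))])
  }
  # nothing admitted -> no best TF
  weak <- pssm("WEAK", matrix(c(0.4, 0.2, 0.2, 0.2), 4, 1), pseudocount = 0)
  none <- best_tf_change(strrep("G", 21), list(position = 11L, ref = "G",
                                               alt = "G"),
                         list(weak), window = 21)
  expect_true(is.na(attr(none, "best_tf")) || !any(none$admitted))

  # single admitted TF is the best TF
  single <- best_tf_change(seqs, v, list(pa), window = 11,
                           both_strands = FALSE)
  expect_equal(attr(single, "best_tf"), "TOY")
})

test_that("variant tables scan cleanly against a collection", {
  coll <- example_pssms()
  ref <- generate_reference(200, mask_flank = 10, seed = 33)
  refb <- substring(ref$sequence, 50, 50)
  vars <- tibble::tibble(position = 50L, ref = refb,
                         alt = setdiff(c("A", "C", "G", "T"), refb)[1])
  res <- scan_variants(ref, vars, coll)
  expect_equal(nrow(res), length(coll))
  expect_true(all(c("score_ref", "score_mut", "delta", "admitted", "best")
                  %in% names(res)))
  expect_lte(sum(res$best), 1L)
})
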