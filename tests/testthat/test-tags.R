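q_of <- function(phred, n = 20) strrep(rawToChar(as.raw(phred + 33)), n)

test_that("tag counting applies the prefix quality filter", {
  tagA <- strrep("ACGT", 5)
  reads <- tibble::tibble(
    replicate = 1L, aliquot = 3L,
    sequence = rep(tagA, 3),
    quality = c(q_of(30), q_of(30), q_of(10))
  )
  tc <- count_tags(reads, min_tag_quality = 20)
  expect_equal(nrow(tc), 1L)
  expect_equal(tc$count, 2L)
  expect_equal(tc$aliquot, 3L)
  expect_equal(attr(tc, "n_reads_fail"), 1L)

  # mean-based filter: 10 bases at Q30 + 10 at Q12 -> mean 21 passes at 20,
  # min-based filter rejects the same read
  mixed <- paste0(q_of(30, 10), q_of(12, 10))
  r2 <- tibble::tibble(replicate = 1L, aliquot = 1L, sequence = tagA,
                       quality = mixed)
  expect_equal(sum(count_tags(r2)$count), 1L)
  expect_equal(nrow(count_tags(r2, statistic = "min")), 0L)

  expect_warning(tc0 <- count_tags(reads[0, ]), "empty")
  expect_equal(nrow(tc0), 0L)
  expect_error(count_tags(tibble::tibble(replicate = 1, aliquot = 1,
                                         sequence = "ACGT",
                                         quality = "IIII")),
               "tag_length")
})

test_that("a mixed-quality fixture keeps exactly the passing reads", {
  set.seed(42)
  n <- 100
  tags <- replicate(n, paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE),
                             collapse = ""))
  phred <- c(rep(30, 60), rep(10, 40))[sample.int(n)]
  reads <- tibble::tibble(replicate = sample(1:2, n, TRUE),
                          aliquot = sample(1:4, n, TRUE),
                          sequence = tags,
                          quality = vapply(phred, q_of, character(1)))
  tc <- count_tags(reads, min_tag_quality = 20)
  expect_equal(sum(tc$count), 60L)  # conservation of passing reads
  expect_equal(attr(tc, "n_reads_pass"), 60L)
})

test_that("presence filter thresholds aliquot support", {
  counts <- new_counts <- tibble::tibble(
    tag = "T1", replicate = 1L, aliquot = 1:3, count = c(12L, 9L, 30L))
  counts <- structure(counts, class = c("tag_counts", class(tibble::tibble())))
  ap <- presence_filter(counts, min_reads_per_tag = 10,
                        n_replicates = 1, n_aliquots_per_replicate = 3)
  expect_equal(ap$y, 2L)
  # degenerate threshold: y = number of nonzero cells
  expect_equal(presence_filter(counts, min_reads_per_tag = 1,
                               n_replicates = 1,
                               n_aliquots_per_replicate = 3)$y, 3L)
  # total scope keeps the tag if total support passes, then counts nonzero cells
  expect_equal(presence_filter(counts, min_reads_per_tag = 40,
                               scope = "total", n_replicates = 1,
                               n_aliquots_per_replicate = 3)$y, 3L)
  expect_equal(nrow(presence_filter(counts, min_reads_per_tag = 60,
                                    scope = "total")), 0L)
})

test_that("presence filter matches a brute-force recount on random input", {
  set.seed(7)
  tags <- sprintf("TAG%02d", 1:30)
  grid <- expand.grid(tag = tags, replicate = 1:2, aliquot = 1:4,
                      stringsAsFactors = FALSE)
  grid$count <- rpois(nrow(grid), 8)
  grid <- grid[grid$count > 0, ]
  counts <- structure(tibble::as_tibble(grid),
                      class = c("tag_counts", class(tibble::tibble())))
  ap <- presence_filter(counts, min_reads_per_tag = 10,
                        n_replicates = 2, n_aliquots_per_replicate = 4)
  brute <- sapply(ap$tag, function(t) {
    sum(grid$count[grid$tag == t] >= 10)
  })
  expect_equal(ap$y, unname(brute))
  # monotonicity: a higher threshold never increases y
  ap2 <- presence_filter(counts, min_reads_per_tag = 12,
                         n_replicates = 2, n_aliquots_per_replicate = 4)
  common <- intersect(ap$tag, ap2$tag)
  expect_true(all(ap2$y[match(common, ap2$tag)] <=
                    ap$y[match(common, ap$tag)]))
})

test_that("dictionary tags are retained at y = 0 and spillover is reported", {
  counts <- structure(
    tibble::tibble(tag = c("KNOWN1", "ROGUE1"), replicate = 1L, aliquot = 1L,
                   count = c(20L, 20L)),
    class = c("tag_counts", class(tibble::tibble())))
  ap <- presence_filter(counts, min_reads_per_tag = 10,
                        haplotype_tags = c("KNOWN1", "KNOWN2"),
                        n_replicates = 1, n_aliquots_per_replicate = 1)
  expect_setequal(ap$tag, c("KNOWN1", "KNOWN2"))
  expect_equal(ap$y[ap$tag == "KNOWN2"], 0L)
  expect_equal(attr(ap, "spillover"), "ROGUE1")
})

test_that("replicate combination is additive over the tag union", {
  mk <- function(tags, y, K) {
    structure(tibble::tibble(tag = tags, y = y, y_rep1 = y),
              class = c("aliquot_presence", class(tibble::tibble())), K = K)
  }
  a <- mk(c("T1", "T2"), c(5L, 1L), 16L)
  b <- mk(c("T1", "T3"), c(7L, 2L), 16L)
  cmb <- combine_replicates(a, b)
  expect_equal(cmb$y[cmb$tag == "T1"], 12L)
  expect_equal(cmb$y[cmb$tag == "T2"], 1L)  # absent from b counts 0 there
  expect_equal(cmb$y[cmb$tag == "T3"], 2L)
  expect_equal(attr(cmb, "K"), 32L)
  expect_error(combine_replicates(a), "at least two")
})

test_that("filtering per replicate then combining equals filtering jointly", {
  set.seed(11)
  tags <- sprintf("TAG%02d", 1:25)
  grid <- expand.grid(tag = tags, replicate = 1:2, aliquot = 1:4,
                      stringsAsFactors = FALSE)
  grid$count <- rpois(nrow(grid), 9)
  counts <- structure(tibble::as_tibble(grid),
                      class = c("tag_counts", class(tibble::tibble())))
  joint <- presence_filter(counts, min_reads_per_tag = 10,
                           haplotype_tags = tags,
                           n_replicates = 2, n_aliquots_per_replicate = 4)
  per_rep <- lapply(1:2, function(r) {
    sub <- counts[counts$replicate == r, ]
    sub$replicate <- 1L
    presence_filter(structure(sub, class = class(counts)),
                    min_reads_per_tag = 10, haplotype_tags = tags,
                    n_replicates = 1, n_aliquots_per_replicate = 4)
  })
  cmb <- combine_replicates(per_rep)
  expect_equal(cmb$y[match(joint$tag, cmb$tag)], joint$y)
})
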