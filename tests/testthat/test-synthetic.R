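test_that("reference generation masks flanks and is seed-deterministic", {
  ref <- generate_reference(600, mask_flank = 20, seed = 1)
  expect_equal(sum(ref$doping_mask), 560L)
  expect_false(any(ref$doping_mask[c(1:20, 581:600)]))
  ref2 <- generate_reference(600, mask_flank = 20, seed = 1)
  expect_identical(ref$sequence, ref2$sequence)
  expect_error(generate_reference(10, mask_flank = 20), "exceed")
})

test_that("planted landscapes respect nulls, sign mixing and the mask", {
  ref <- generate_reference(200, mask_flank = 10, seed = 2)
  null <- plant_effect_landscape(ref, n_clusters = 0, seed = 3)
  expect_true(all(null$effect == 0))

  neg <- plant_effect_landscape(ref, n_clusters = 3, cluster_width = 6,
                                sign_mix = 1, seed = 4)
  expect_true(all(neg$effect <= 0))
  expect_true(any(neg$effect < 0))
  # masked positions never carry effects
  masked_pos <- which(!ref$doping_mask)
  expect_true(all(neg$effect[neg$position %in% masked_pos] == 0))
  # effects confined to the annotated clusters
  cl <- attr(neg, "clusters")
  in_cl <- unlist(Map(seq, cl$start, cl$end))
  expect_true(all(neg$position[neg$effect != 0] %in% in_cl))

  again <- plant_effect_landscape(ref, n_clusters = 3, cluster_width = 6,
                                  sign_mix = 1, seed = 4)
  expect_identical(neg$effect, again$effect)
})

test_that("doped libraries follow the designated-base retention model", {
  ref <- generate_reference(200, mask_flank = 10, seed = 5)
  wt <- simulate_doped_library(ref, 50, doping = 1, seed = 6)
  expect_true(all(wt$substitutions == ""))
  expect_false(anyDuplicated(wt$tag) > 0)
  expect_true(all(nchar(wt$tag) == 20L))

  lib <- simulate_doped_library(ref, 5000, doping = 0.9, seed = 7)
  long <- substitutions_long(lib)
  # masked positions are never mutated
  expect_true(all(ref$doping_mask[long$position]))
  # the recorded reference base matches the sequence
  expect_true(all(substring(ref$sequence, long$position, long$position) ==
                    long$ref))
  # substitutions change the base
  expect_true(all(long$ref != long$alt))
  # determinism
  lib2 <- simulate_doped_library(ref, 5000, doping = 0.9, seed = 7)
  expect_identical(lib, lib2)
})

test_that("per-position mutation frequencies match the doping ratio", {
  ref <- generate_reference(200, mask_flank = 10, seed = 8)
  n <- 5000
  doping <- 0.9
  lib <- simulate_doped_library(ref, n, doping = doping, seed = 9)
  long <- substitutions_long(lib)
  mutable <- which(ref$doping_mask)
  freq <- tabulate(long$position, nchar(ref$sequence))[mutable] / n
  se <- sqrt((1 - doping) * doping / n)
  expect_true(all(abs(freq - (1 - doping)) <= 3.9 * se))
  # each alternate base appears at (1 - doping) / 3
  alt_freq <- table(long$alt) / (n * length(mutable))
  # every base is an alternate at ~3/4 of positions; compare totals instead
  expect_equal(sum(freq) / length(mutable), 1 - doping, tolerance = 3 * se)
  # conservation: every substitution token accounted for
  expect_equal(nrow(long),
               sum(lengths(strsplit(lib$substitutions[lib$substitutions != ""],
                                    ","))))
})

test_that("aliquot readout follows the detection model", {
  ref <- generate_reference(60, mask_flank = 5, seed = 10)
  refb <- substring(ref$sequence, 1:60, 1:60)
  alt_of <- function(p) setdiff(c("A", "C", "G", "T"), refb[p])[1]
  # 200 wild-type and 200 single-mutant haplotypes at position 30
  n_half <- 200L
  haps <- tibble::tibble(
    tag = replicate(2 * n_half, paste(sample(c("A", "C", "G", "T"), 20,
                                             replace = TRUE), collapse = "")),
    substitutions = c(rep("", n_half),
                      rep(sprintf("30:%s>%s", refb[30], alt_of(30)), n_half))
  )
  landscape <- plant_effect_landscape(ref, n_clusters = 0, seed = 11)
  landscape$effect[landscape$position == 30 &
                     landscape$alt == alt_of(30)] <- 1

  design <- mpra_design(capture = 0.2)
  ro <- simulate_aliquot_counts(haps, landscape, design = design,
                                noise_sd = 0, seed = 12)
  # detection probabilities are exact in the noiseless linear regime
  expect_equal(unique(ro$p_detect[1:n_half]), 0.2)
  expect_equal(unique(ro$p_detect[(n_half + 1):(2 * n_half)]), 0.4)
  # E[y_mut] / E[y_wt] = 2^E within binomial error
  ratio <- mean(ro$y[(n_half + 1):(2 * n_half)]) / mean(ro$y[1:n_half])
  expect_equal(ratio, 2, tolerance = 0.15)
  # per-replicate counts sum to y
  expect_equal(ro$y, ro$y_rep1 + ro$y_rep2)
  expect_true(all(ro$y <= design$K))
  # read counts exist exactly for detected cells
  rc <- attr(ro, "read_counts")
  expect_equal(sum(ro$y), nrow(rc))
  expect_true(all(rc$count >= 1L))
})

test_that("a zero-activity haplotype is never observed", {
  ref <- generate_reference(60, mask_flank = 5, seed = 13)
  refb <- substring(ref$sequence, 30, 30)
  alt <- setdiff(c("A", "C", "G", "T"), refb)[1]
  haps <- tibble::tibble(tag = strrep(c("A", "C"), 20),
                         substitutions = c("", sprintf("30:%s>%s", refb, alt)))
  landscape <- plant_effect_landscape(ref, n_clusters = 0)
  landscape$effect[landscape$position == 30 & landscape$alt == alt] <- -1000
  ro <- simulate_aliquot_counts(haps, landscape, noise_sd = 0, seed = 14)
  expect_equal(ro$y[2], 0L)
})

test_that("subassembly read simulation produces exact substrings at error 0", {
  ref <- generate_reference(150, mask_flank = 10, seed = 15)
  lib <- simulate_doped_library(ref, 20, seed = 16)
  reads <- simulate_subassembly_reads(lib, ref, read_length = 50,
                                      mean_coverage = 5, error_rate = 0,
                                      seed = 17)
  seqs <- haplotype_sequences(ref, lib)
  hap_of <- match(reads$tag, lib$tag)
  expect_true(all(substr(seqs[hap_of], reads$offset + 1,
                         reads$offset + nchar(reads$sequence)) ==
                    reads$sequence))
  # requesting no coverage yields no reads
  empty <- simulate_subassembly_reads(lib, ref, mean_coverage = 0)
  expect_equal(nrow(empty), 0L)
  # determinism
  reads2 <- simulate_subassembly_reads(lib, ref, read_length = 50,
                                       mean_coverage = 5, error_rate = 0,
                                       seed = 17)
  expect_identical(reads, reads2)
})
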