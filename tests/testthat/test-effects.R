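test_that("univariate fit equals the group-means closed form", {
  # y = [4,4,6,6] against indicators [0,0,1,1]
  inp <- manual_input(
    y = c(4, 4, 6, 6),
    sub_long = tibble::tibble(hap = 3:4, position = 2L, ref = "A", alt = "G"))
  est <- fit_univariate(inp, positions = 2L)
  expect_equal(est$beta0, 4)
  expect_equal(est$beta, 2)
  expect_equal(est$effect_size, log2(6 / 4))
  expect_equal(est$n_mutant, 2L)

  # equal group means: beta = 0, effect size 0
  inp0 <- manual_input(
    y = c(5, 5, 5, 5),
    sub_long = tibble::tibble(hap = 3:4, position = 2L, ref = "A", alt = "G"))
  est0 <- fit_univariate(inp0, positions = 2L)
  expect_equal(est0$beta, 0)
  expect_equal(est0$effect_size, 0)

  # halving: beta0 = 8, beta = -4 -> effect size -1
  inph <- manual_input(
    y = c(8, 8, 4, 4),
    sub_long = tibble::tibble(hap = 3:4, position = 2L, ref = "A", alt = "G"))
  expect_equal(fit_univariate(inph, positions = 2L)$effect_size, -1)

  # no variation at a position is an error
  expect_error(fit_univariate(inp, positions = 5L), "variation")

  # mutant group mean zero: effect size undefined, p retained
  inpz <- manual_input(
    y = c(3, 5, 0, 0),
    sub_long = tibble::tibble(hap = 3:4, position = 2L, ref = "A", alt = "G"))
  estz <- fit_univariate(inpz, positions = 2L)
  expect_true(is.na(estz$effect_size))
  expect_false(is.na(estz$p_value))
})

test_that("vectorized OLS matches lm() on random fixtures", {
  set.seed(1234)
  for (rep in 1:10) {
    n <- 60
    sub_long <- tibble::tibble(
      hap = sample.int(n, 25),
      position = sample(2:9, 25, replace = TRUE))
    sub_long <- sub_long[!duplicated(sub_long[c("hap", "position")]), ]
    sub_long$ref <- "A"
    sub_long$alt <- sample(c("C", "G", "T"), nrow(sub_long), replace = TRUE)
    y <- rpois(n, 6)
    inp <- manual_input(y, sub_long)
    est <- fit_univariate(inp)
    for (i in seq_len(nrow(est))) {
      x <- integer(n)
      x[sub_long$hap[sub_long$position == est$position[i]]] <- 1L
      s <- summary(lm(y ~ x))$coefficients
      expect_equal(est$beta0[i], s[1, 1], tolerance = 1e-9)
      expect_equal(est$beta[i], s[2, 1], tolerance = 1e-9)
      expect_equal(est$p_value[i], s[2, 4], tolerance = 1e-9)
    }
    # trivariate against a 3-indicator lm at one position
    tri <- fit_trivariate(inp)
    p0 <- tri$position[1]
    sel <- sub_long[sub_long$position == p0, ]
    X <- sapply(c("C", "G", "T"), function(b) {
      x <- integer(n); x[sel$hap[sel$alt == b]] <- 1L; x
    })
    X <- X[, colSums(X) > 0, drop = FALSE]
    s <- summary(lm(y ~ X))$coefficients
    rows <- tri[tri$position == p0, ]
    expect_equal(rows$beta, unname(s[-1, 1]), tolerance = 1e-9)
    expect_equal(rows$p_value, unname(s[-1, 4]), tolerance = 1e-9)
  }
})

test_that("trivariate estimates reduce to univariate with one alternate base", {
  inp <- manual_input(
    y = c(4, 4, 7, 7, 2),
    sub_long = tibble::tibble(hap = c(3, 4, 5), position = c(2L, 2L, 6L),
                              ref = "A", alt = c("G", "G", "T")))
  uni <- fit_univariate(inp, positions = 2L)
  tri <- fit_trivariate(inp, positions = 2L)
  expect_equal(nrow(tri), 1L)  # unobserved substitutions are absent
  expect_equal(tri$alt, "G")
  expect_equal(tri$beta, uni$beta, tolerance = 1e-9)
  expect_equal(tri$p_value, uni$p_value, tolerance = 1e-9)
  expect_equal(tri$effect_size, uni$effect_size, tolerance = 1e-9)
  expect_error(fit_trivariate(inp, positions = 9L), "zero mutant")
})

test_that("profiles are deterministic and flag by the display threshold", {
  sim <- small_recovery_sim()
  prof <- effect_profile(sim$input, p_display_threshold = 0.01)
  prof2 <- effect_profile(sim$input, p_display_threshold = 0.01)
  expect_identical(prof$univariate, prof2$univariate)
  expect_identical(prof$trivariate, prof2$trivariate)
  expect_true(all(prof$univariate$p_value[prof$univariate$display] <= 0.01))
  expect_true(all(prof$trivariate$p_value[prof$trivariate$display] <= 0.01))
  expect_s3_class(tidy(prof), "tbl_df")
  expect_equal(glance(prof)$n_positions, nrow(prof$univariate))
})

test_that("planted effects are recovered by the trivariate model", {
  sim <- small_recovery_sim()
  tri <- fit_trivariate(sim$input)
  key <- paste(sim$landscape$position, sim$landscape$alt)
  tri$true <- sim$landscape$effect[match(paste(tri$position, tri$alt), key)]
  sel <- abs(tri$true) >= 0.5 & tri$n_mutant >= 30
  r <- cor(tri$true[sel], tri$effect_size[sel], use = "complete.obs")
  expect_gt(r, 0.85)
})

test_that("per-replicate fits are concordant on planted effects", {
  sim <- small_recovery_sim()
  effs <- lapply(c("y_rep1", "y_rep2"), function(col) {
    pres <- structure(
      tibble::tibble(tag = sim$readout$tag, y = sim$readout[[col]]),
      class = c("aliquot_presence", class(tibble::tibble())), K = 16L)
    inp <- effect_model_input(sim$lib, pres, sim$ref)
    fit_univariate(inp)
  })
  planted <- unique(sim$landscape$position[sim$landscape$effect != 0])
  a <- effs[[1]][effs[[1]]$position %in% planted, ]
  b <- effs[[2]][effs[[2]]$position %in% planted, ]
  shared <- intersect(a$position, b$position)
  r <- cor(a$effect_size[match(shared, a$position)],
           b$effect_size[match(shared, b$position)], use = "complete.obs")
  expect_gt(r, 0.8)
})

test_that("windowed F profile responds to planted clusters only", {
  sim <- small_recovery_sim()
  wf <- windowed_f_profile(sim$input, width = 10)
  expect_equal(nrow(wf), sim$input$length - 10 + 1)
  cl <- attr(sim$landscape, "clusters")
  in_cluster <- wf$start <= cl$end[1] & wf$end >= cl$start[1]
  expect_gt(max(wf$f_statistic[in_cluster], na.rm = TRUE),
            stats::median(wf$f_statistic, na.rm = TRUE))
  expect_error(windowed_f_profile(sim$input, width = 10000), "width")

  # constant outcome: no window is predictive
  inp0 <- manual_input(
    y = rep(4, 6),
    sub_long = tibble::tibble(hap = 1:3, position = c(2L, 3L, 4L),
                              ref = "A", alt = "G"))
  wf0 <- windowed_f_profile(inp0, width = 3)
  has_pred <- wf0$n_predictors > 0
  expect_true(all(wf0$f_statistic[has_pred] == 0))
  expect_true(all(wf0$p_value[has_pred] == 1))
  expect_true(all(is.na(wf0$f_statistic[!has_pred])))
})

test_that("fold-change classes follow the log2 thresholds", {
  est <- tibble::tibble(effect_size = c(-1, 0.2, 0, 0.3, NA),
                        position = 1:5, ref = "A", alt = "G")
  cls <- classify_fold_change(est, thresholds = c(1.2, 2))
  expect_true(cls$fc_ge_1.2[1] && cls$fc_ge_2[1])
  expect_equal(cls$direction[1], "decrease")
  # |0.2| < log2(1.2) = 0.263: in neither class
  expect_false(cls$fc_ge_1.2[2] || cls$fc_ge_2[2])
  expect_true(cls$fc_ge_1.2[4] && !cls$fc_ge_2[4])
  smry <- fold_change_summary(cls)
  expect_equal(smry$n_functional, c(2L, 1L))

  zero <- classify_fold_change(tibble::tibble(effect_size = rep(0, 5)))
  expect_true(all(fold_change_summary(zero)$fraction == 0))
})

test_that("coding consequences follow the standard genetic code", {
  ref <- structure(
    list(name = "toy",
         sequence = paste0("AAAA", "GCTGAT", "AAAA"),  # CDS at 5..10
         doping_mask = rep(TRUE, 14),
         cds_window = list(start = 5L, end = 10L, frame = 0L)),
    class = "reference_enhancer")
  subs <- tibble::tibble(position = c(7L, 6L, 2L), alt = c("C", "A", "G"))
  ann <- annotate_coding_consequence(ref, subs)
  expect_equal(ann$consequence, c("synonymous",     # GCT -> GCC
                                  "non-synonymous", # GCT -> GAT
                                  "noncoding"))
  # stop gain is non-synonymous: GAT -> TAT is Asp->Tyr (missense); use TGA
  ref$sequence <- paste0("AAAA", "TGCGAT", "AAAA")
  stopg <- annotate_coding_consequence(
    ref, tibble::tibble(position = 6L, alt = "A"))  # TGC -> TAC? no: pos6=G>A: TAC
  expect_equal(stopg$consequence, "non-synonymous")
  # codon extending past the window errors
  ref$cds_window <- list(start = 5L, end = 9L, frame = 0L)
  expect_error(
    annotate_coding_consequence(ref, tibble::tibble(position = 9L, alt = "C")),
    "codon")
})

test_that("the consequence contingency test matches enumeration", {
  mk <- function(tab) {
    syn <- rep(c("synonymous", "non-synonymous"), times = rowSums(tab))
    fun <- c(rep(c(TRUE, FALSE), times = tab[1, ]),
             rep(c(TRUE, FALSE), times = tab[2, ]))
    cls <- tibble::tibble(effect_size = ifelse(fun, -1, 0),
                          consequence = syn)
    cls <- classify_fold_change(cls, thresholds = 1.2)
    cls$consequence <- syn
    cls
  }
  even <- consequence_contingency(mk(rbind(c(5, 5), c(5, 5))), threshold = 1.2)
  expect_equal(even$p_value, 1)

  # perfectly separated 10/0 vs 0/10: compare to the hypergeometric sum
  sep <- consequence_contingency(mk(rbind(c(10, 0), c(0, 10))), threshold = 1.2)
  # two-sided Fisher p: sum over tables with probability <= observed
  probs <- stats::dhyper(0:10, 10, 10, 10)
  expected <- sum(probs[probs <= stats::dhyper(10, 10, 10, 10) * (1 + 1e-7)])
  expect_equal(sep$p_value, expected, tolerance = 1e-9)

  # empty margin: p = 1 with a warning
  cls <- mk(rbind(c(3, 2), c(4, 1)))
  cls$consequence <- "synonymous"
  expect_warning(em <- consequence_contingency(cls, threshold = 1.2), "margin")
  expect_equal(em$p_value, 1)
  expect_s3_class(glance(even), "tbl_df")
})
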