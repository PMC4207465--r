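# Effect-size regression on aliquot counts: per-position univariate and
# per-substitution trivariate linear models, the windowed F profile,
# fold-change classification and coding-consequence comparison.

#' Assemble the effect-model input
#'
#' Joins the subassembled haplotype dictionary with the aliquot-count
#' outcome: every haplotype contributes its aliquot count `y` (0 when its
#' tag was never observed) and its substitution list becomes the binary
#' mutation predictors.
#'
#' @param haplotypes Haplotype tibble (`tag`, `substitutions`); rows with a
#'   `status` column are filtered to `status == "ok"`.
#' @param presence An `aliquot_presence` tibble (`tag`, `y`).
#' @param ref A [generate_reference()] object.
#' @return An `effect_input` object.
#' @export
effect_model_input <- function(haplotypes, presence, ref) {
  if ("status" %in% names(haplotypes)) {
    haplotypes <- haplotypes[haplotypes$status == "ok", ]
  }
  if (nrow(haplotypes) == 0L) abort("no usable haplotypes")
  y <- presence$y[match(haplotypes$tag, presence$tag)]
  y[is.na(y)] <- 0L
  L <- nchar(ref$sequence)
  long <- substitutions_long(haplotypes)
  if (nrow(long) > 0L && max(long$position) > L) {
    abort("substitution position beyond the enhancer length")
  }
  K <- attr(presence, "K") %||% NA_integer_
  if (!is.na(K) && any(y > K)) abort("aliquot counts exceed K")
  structure(
    list(y = as.numeric(y),
         tags = haplotypes$tag,
         hap = match(long$tag, haplotypes$tag),
         position = long$position,
         alt = long$alt,
         n = nrow(haplotypes),
         length = L,
         mask = ref$doping_mask,
         ref_bases = ref_bases(ref),
         K = K),
    class = "effect_input"
  )
}

#' @export
print.effect_input <- function(x, ...) {
  cat(sprintf("<effect_input> %d haplotypes, %d substitutions, %d bp enhancer\n",
              x$n, length(x$position), x$length))
  invisible(x)
}

# Shared core: given group sizes/sums of y for disjoint mutant groups at one
# or more positions, return OLS coefficients and t-test p-values. For
# mutually exclusive binary indicators plus intercept, OLS equals group
# means; inference uses the usual coefficient t statistics.
ols_group_stats <- function(n, sum_y, sum_y2, n1, s1, q1, dof_q) {
  n0 <- n - n1
  m0 <- (sum_y - s1) / n0
  m1 <- s1 / n1
  beta0 <- m0
  beta <- m1 - m0
  rss <- pmax(sum_y2 - (n0 * m0^2 + q1), 0)
  sigma2 <- rss / (n - 1 - dof_q)
  se <- sqrt(sigma2 * (1 / n0 + 1 / n1))
  tstat <- beta / se
  p <- 2 * pt(-abs(tstat), df = n - 1 - dof_q)
  list(beta0 = beta0, beta = beta, se = se, t = tstat, p = p)
}

effect_size_log2 <- function(beta0, beta) {
  es <- rep(NA_real_, length(beta0))
  ok <- beta0 > 0 & (beta0 + beta) > 0
  es[ok] <- log2((beta0[ok] + beta[ok]) / beta0[ok])
  es
}

#' Per-position univariate effect model
#'
#' For each position, an ordinary least-squares regression of the aliquot
#' count `y` on a single binary predictor (1 = the haplotype is mutant at
#' the position, 0 = wild type). The coefficients satisfy the group-means
#' identity: `beta0` is the mean aliquot count of wild-type haplotypes and
#' `beta` the mutant minus wild-type mean difference. The effect size is
#' `log2((beta0 + beta) / beta0)`, the log2 fold change in model-predicted
#' activity of a mutant relative to wild type; the p-value is the two-sided
#' t test on `beta`.
#'
#' @param input An [effect_model_input()] object.
#' @param positions Positions to fit (default: every position with both
#'   mutant and wild-type haplotypes). Requesting a position without
#'   variation is an error.
#' @return Tibble with columns `position`, `ref`, `alt` (`"any"`), `beta0`,
#'   `beta`, `se`, `statistic`, `p_value`, `effect_size`, `n_mutant`.
#' @export
fit_univariate <- function(input, positions = NULL) {
  stopifnot(inherits(input, "effect_input"))
  L <- input$length
  n <- input$n
  # unique (haplotype, position) mutation indicators
  n1 <- tabulate(input$position, L)
  s1 <- sum_by_index(input$y[input$hap], input$position, L)
  varying <- which(n1 > 0L & n1 < n)
  if (is.null(positions)) {
    positions <- varying
  } else {
    bad <- setdiff(positions, varying)
    if (length(bad) > 0L) {
      abort(sprintf(
        "position %d has no variation (all wild-type or all mutant)", bad[1]))
    }
  }
  sum_y <- sum(input$y)
  sum_y2 <- sum(input$y^2)
  j <- positions
  st <- ols_group_stats(n, sum_y, sum_y2, n1[j], s1[j],
                        q1 = (s1[j]^2) / n1[j], dof_q = 1)
  tibble(
    position = as.integer(j),
    ref = input$ref_bases[j],
    alt = "any",
    beta0 = st$beta0, beta = st$beta, se = st$se,
    statistic = st$t, p_value = st$p,
    effect_size = effect_size_log2(st$beta0, st$beta),
    n_mutant = as.integer(n1[j])
  )
}

#' Per-substitution trivariate effect model
#'
#' For each position, one multiple regression of the aliquot count on three
#' binary predictors, one per possible nucleotide substitution at that
#' position. Substitutions never observed in the library get missing
#' estimates. Because the three indicators are mutually exclusive, the OLS
#' solution is the group-means fit; p-values are per-coefficient t tests
#' with the model residual degrees of freedom. The effect size of
#' substitution k is `log2((beta0 + beta_k) / beta0)`.
#'
#' @inheritParams fit_univariate
#' @param positions Positions to fit (default: all with at least one mutant
#'   haplotype). Requesting a position with zero mutants is an error.
#' @return Tibble with one row per observed substitution: `position`, `ref`,
#'   `alt`, `beta0`, `beta`, `se`, `statistic`, `p_value`, `effect_size`,
#'   `n_mutant`.
#' @export
fit_trivariate <- function(input, positions = NULL) {
  stopifnot(inherits(input, "effect_input"))
  L <- input$length
  n <- input$n
  key <- paste(input$position, input$alt)
  grp <- count_sums_by_key(key, input$y[input$hap])
  pos_k <- as.integer(sub(" .*", "", grp$key))
  alt_k <- sub(".* ", "", grp$key)
  n_pos <- tabulate(pos_k, L)   # substitution kinds per position (observed)
  n1_pos <- tabulate(input$position, L)
  if (is.null(positions)) {
    positions <- which(n1_pos > 0L & n1_pos < n)
  } else {
    bad <- setdiff(positions, which(n1_pos > 0L))
    if (length(bad) > 0L) {
      abort(sprintf("position %d has zero mutant haplotypes", bad[1]))
    }
  }
  keep <- pos_k %in% positions
  pos_k <- pos_k[keep]; alt_k <- alt_k[keep]
  nk <- grp$n[keep]; sk <- grp$s[keep]
  # per-position totals over observed substitution groups
  s1_pos <- sum_by_index(sk, pos_k, L)
  q1_pos <- sum_by_index(sk^2 / nk, pos_k, L)
  nmut_pos <- sum_by_index(nk, pos_k, L)
  sum_y <- sum(input$y)
  sum_y2 <- sum(input$y^2)
  n0 <- n - nmut_pos[pos_k]
  m0 <- (sum_y - s1_pos[pos_k]) / n0
  mk <- sk / nk
  beta0 <- m0
  beta <- mk - m0
  q <- n_pos[pos_k]  # predictors actually in the model
  rss <- pmax(sum_y2 - (n0 * m0^2 + q1_pos[pos_k]), 0)
  sigma2 <- rss / (n - 1 - q)
  se <- sqrt(sigma2 * (1 / n0 + 1 / nk))
  tstat <- beta / se
  p <- 2 * pt(-abs(tstat), df = n - 1 - q)
  out <- tibble(
    position = pos_k,
    ref = input$ref_bases[pos_k],
    alt = alt_k,
    beta0 = beta0, beta = beta, se = se,
    statistic = tstat, p_value = p,
    effect_size = effect_size_log2(beta0, beta),
    n_mutant = as.integer(nk)
  )
  arrange(out, .data$position, .data$alt)
}

count_sums_by_key <- function(key, y) {
  f <- factor(key)
  list(key = levels(f), n = tabulate(f), s = as.vector(rowsum(y, f)))
}

#' Full univariate and trivariate effect profiles
#'
#' Fits both models at every position with variation and flags estimates
#' whose p-value is at or below the display threshold (all estimates are
#' retained in the tables; the flag only drives display).
#'
#' @param input An [effect_model_input()] object.
#' @param p_display_threshold Display threshold (default 0.01).
#' @return An `mpra_profile` object: list with tibbles `univariate` and
#'   `trivariate` (each with a logical `display` column), the threshold and
#'   the enhancer length. Supports [tidy()], [glance()] and [autoplot()].
#' @export
effect_profile <- function(input, p_display_threshold = 0.01) {
  uni <- fit_univariate(input)
  tri <- fit_trivariate(input)
  uni$display <- !is.na(uni$p_value) & uni$p_value <= p_display_threshold
  tri$display <- !is.na(tri$p_value) & tri$p_value <= p_display_threshold
  structure(
    list(univariate = uni, trivariate = tri,
         p_display_threshold = p_display_threshold,
         length = input$length, n_haplotypes = input$n),
    class = "mpra_profile"
  )
}

#' @export
print.mpra_profile <- function(x, ...) {
  cat(sprintf(
    "<mpra_profile> %d bp, %d haplotypes; %d univariate / %d trivariate estimates (%d / %d flagged at p <= %g)\n",
    x$length, x$n_haplotypes, nrow(x$univariate), nrow(x$trivariate),
    sum(x$univariate$display), sum(x$trivariate$display),
    x$p_display_threshold))
  invisible(x)
}

#' Sliding-window multi-position regression profile
#'
#' Multiple linear regression of the aliquot count on the per-position
#' mutation indicators of `width` adjacent positions, slid one position at
#' a time along the enhancer. The overall model F statistic summarises how
#' predictive the window is of the outcome. Non-varying positions are
#' dropped from each window's model; a window with no varying position gets
#' a missing F.
#'
#' @param input An [effect_model_input()] object.
#' @param width Window width in positions (default 10).
#' @return Tibble `start`, `end`, `n_predictors`, `f_statistic`, `p_value`.
#' @export
windowed_f_profile <- function(input, width = 10L) {
  stopifnot(inherits(input, "effect_input"))
  width <- as.integer(width)
  L <- input$length
  n <- input$n
  if (width > L) abort("`width` must not exceed the enhancer length")
  if (width < 1L) abort("`width` must be >= 1")
  X <- matrix(FALSE, nrow = n, ncol = L)
  X[cbind(input$hap, input$position)] <- TRUE
  n1 <- colSums(X)
  varying <- n1 > 0L & n1 < n
  y <- input$y
  tss <- sum((y - mean(y))^2)
  starts <- seq_len(L - width + 1L)
  res <- lapply(starts, function(s) {
    cols <- s:(s + width - 1L)
    cols <- cols[varying[cols]]
    p <- length(cols)
    if (p == 0L) {
      return(c(p = 0, f = NA_real_, pv = NA_real_))
    }
    if (tss <= 0) {
      # constant outcome: the window explains nothing
      return(c(p = p, f = 0, pv = 1))
    }
    fit <- stats::.lm.fit(cbind(1, X[, cols, drop = FALSE] * 1), y)
    rss <- sum(fit$residuals^2)
    df2 <- n - p - 1L
    f <- ((tss - rss) / p) / (rss / df2)
    c(p = p, f = f, pv = pf(f, p, df2, lower.tail = FALSE))
  })
  m <- do.call(rbind, res)
  tibble(start = starts, end = starts + width - 1L,
         n_predictors = as.integer(m[, "p"]),
         f_statistic = m[, "f"], p_value = m[, "pv"])
}

#' Classify estimates by fold change
#'
#' A variant belongs to the `">=T-fold"` class when `|effect_size| >=
#' log2(T)`; direction records whether activity increased or decreased.
#'
#' @param estimates Tibble with an `effect_size` column (e.g.
#'   `tidy(profile, "trivariate")`).
#' @param thresholds Fold-change thresholds (default `c(1.2, 2)`).
#' @return The input with `fold_change`, `direction` and one logical
#'   `fc_ge_<T>` column per threshold; per-threshold summary fractions are
#'   available via [fold_change_summary()].
#' @export
classify_fold_change <- function(estimates, thresholds = c(1.2, 2)) {
  if (nrow(estimates) == 0L) abort("no estimates to classify")
  es <- estimates$effect_size
  out <- estimates
  out$fold_change <- 2^abs(es)
  out$direction <- dplyr::case_when(
    is.na(es) ~ NA_character_,
    es < 0 ~ "decrease",
    es > 0 ~ "increase",
    TRUE ~ "none"
  )
  for (th in thresholds) {
    out[[fc_col(th)]] <- !is.na(es) & abs(es) >= log2(th)
  }
  attr(out, "fc_thresholds") <- thresholds
  out
}

fc_col <- function(th) sprintf("fc_ge_%s", format(th))

#' @param classified Output of [classify_fold_change()].
#' @rdname classify_fold_change
#' @return `fold_change_summary()`: a tibble with one row per threshold:
#'   `threshold`, `n`, `n_functional`, `fraction`, `fraction_decrease`.
#' @export
fold_change_summary <- function(classified) {
  thresholds <- attr(classified, "fc_thresholds")
  if (is.null(thresholds)) abort("input must come from classify_fold_change()")
  rows <- lapply(thresholds, function(th) {
    hit <- classified[[fc_col(th)]]
    n_fun <- sum(hit)
    tibble(
      threshold = th,
      n = sum(!is.na(classified$effect_size)),
      n_functional = n_fun,
      fraction = n_fun / sum(!is.na(classified$effect_size)),
      fraction_decrease = if (n_fun > 0) {
        sum(hit & classified$direction == "decrease") / n_fun
      } else {
        NA_real_
      }
    )
  })
  bind_rows(rows)
}

#' Annotate the coding consequence of substitutions
#'
#' Translates the affected codon before and after each substitution using
#' the standard genetic code. Positions outside the coding window are
#' `noncoding`; stop gain or loss counts as `non-synonymous`. A substitution
#' inside the coding window whose codon extends past the window is an error.
#'
#' @param ref A [generate_reference()] object whose `cds_window` is set.
#' @param substitutions Tibble with `position` and `alt` columns (1-based).
#' @return The input tibble with a `consequence` column
#'   (`"synonymous"`, `"non-synonymous"` or `"noncoding"`).
#' @export
annotate_coding_consequence <- function(ref, substitutions) {
  cds <- ref$cds_window
  if (is.null(cds)) abort("reference has no `cds_window`")
  bases <- ref_bases(ref)
  code <- Biostrings::GENETIC_CODE
  first_codon <- cds$start + cds$frame
  consequence <- character(nrow(substitutions))
  for (i in seq_len(nrow(substitutions))) {
    p <- substitutions$position[i]
    if (p < first_codon || p > cds$end) {
      consequence[i] <- "noncoding"
      next
    }
    codon_idx <- (p - first_codon) %/% 3L
    c_start <- first_codon + 3L * codon_idx
    if (c_start + 2L > cds$end) {
      abort(sprintf(
        "substitution at position %d: codon extends past the coding window", p))
    }
    codon_ref <- paste(bases[c_start:(c_start + 2L)], collapse = "")
    mut <- bases[c_start:(c_start + 2L)]
    mut[p - c_start + 1L] <- substitutions$alt[i]
    codon_mut <- paste(mut, collapse = "")
    consequence[i] <- if (code[[codon_ref]] == code[[codon_mut]]) {
      "synonymous"
    } else {
      "non-synonymous"
    }
  }
  out <- substitutions
  out$consequence <- consequence
  out
}

#' Synonymous versus non-synonymous contingency test
#'
#' Cross-tabulates coding substitutions by consequence (synonymous /
#' non-synonymous) and by functional status at a fold-change threshold, and
#' tests for association with a two-sided Fisher exact test (hypergeometric
#' enumeration). Noncoding substitutions are excluded. An empty margin
#' yields p = 1 with a warning.
#'
#' @param classified Output of [classify_fold_change()] carrying a
#'   `consequence` column (see [annotate_coding_consequence()]).
#' @param threshold Which fold-change threshold defines "functional"
#'   (default 1.2).
#' @return An `mpra_contingency` object: list with the 2x2 `table`,
#'   `p_value`, `odds_ratio` and `threshold`. Supports [tidy()]/[glance()].
#' @export
consequence_contingency <- function(classified, threshold = 1.2) {
  if (!"consequence" %in% names(classified)) {
    abort("input must carry a `consequence` column")
  }
  col <- fc_col(threshold)
  if (!col %in% names(classified)) {
    abort(sprintf("no fold-change classification at threshold %s",
                  format(threshold)))
  }
  coding <- classified[classified$consequence %in%
                         c("synonymous", "non-synonymous"), ]
  tab <- table(
    factor(coding$consequence, levels = c("synonymous", "non-synonymous")),
    factor(ifelse(coding[[col]], "functional", "not_functional"),
           levels = c("functional", "not_functional"))
  )
  if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)) {
    warn("empty margin in the contingency table; p set to 1")
    p <- 1
    or <- NA_real_
  } else {
    ft <- fisher.test(tab, alternative = "two.sided")
    p <- ft$p.value
    or <- unname(ft$estimate)
  }
  structure(list(table = tab, p_value = p, odds_ratio = or,
                 threshold = threshold),
            class = "mpra_contingency")
}

#' @export
print.mpra_contingency <- function(x, ...) {
  cat(sprintf("<mpra_contingency> functional at >= %g-fold; Fisher p = %.4g\n",
              x$threshold, x$p_value))
  print(x$table)
  invisible(x)
}
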