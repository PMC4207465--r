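# Spatial clustering of effect sizes: lag-distance statistic and
# permutation test.

#' Lag-distance dissimilarity statistic
#'
#' `S(d)` sums the absolute difference between effect sizes at all position
#' pairs separated by exactly `d` positions; pairs with a missing endpoint
#' are excluded. Small `S(d)` relative to permutations means nearby
#' positions carry similar effect sizes.
#'
#' @param effects Numeric vector of per-position effect sizes, in position
#'   order; `NA` marks positions without an estimate.
#' @param d Lag distance, `1 <= d < length(effects)`.
#' @return The statistic `S(d)` (non-negative scalar).
#' @export
#' @examples
#' lag_statistic(c(1, 2, 4), 1)  # |1-2| + |2-4| = 3
lag_statistic <- function(effects, d) {
  n <- length(effects)
  if (d < 1L || d >= n) abort("`d` must satisfy 1 <= d < length(effects)")
  a <- effects[seq_len(n - d)]
  b <- effects[seq_len(n - d) + d]
  sum(abs(a - b), na.rm = TRUE)
}

#' Permutation test for effect-size similarity at fixed lags
#'
#' For each lag `d`, compares the observed `S(d)` with its distribution
#' under random permutation of the effect sizes. Missing positions are left
#' in place; the permutation shuffles the defined values among the defined
#' positions. By default one permutation per replicate is shared across all
#' lags, preserving cross-lag dependence. The p-value is the smoothed
#' fraction of permutations with a statistic at least as small as observed:
#' `p(d) = (1 + #{S_perm(d) <= S_obs(d)}) / (n_permutations + 1)`, so it is
#' never exactly zero.
#'
#' @param effects Numeric per-position effect sizes (`NA` = no estimate).
#' @param d_max Largest lag tested (default 30).
#' @param n_permutations Number of permutations (default 1000).
#' @param seed Integer seed.
#' @param share_permutations Share one permutation across lags per replicate
#'   (default `TRUE`); otherwise each lag gets independent permutations.
#' @return An `mpra_lagtest` tibble: `lag`, `s_obs`, `p_value`,
#'   `n_permutations`. Supports [autoplot()].
#' @export
lag_permutation_test <- function(effects, d_max = 30L, n_permutations = 1000L,
                                 seed = NULL, share_permutations = TRUE) {
  defined <- which(!is.na(effects))
  if (length(defined) < d_max + 1L) {
    abort("`effects` must have at least d_max + 1 defined entries")
  }
  lags <- seq_len(d_max)
  s_obs <- vapply(lags, function(d) lag_statistic(effects, d), numeric(1))
  vals <- effects[defined]
  count_le <- integer(d_max)
  with_seed_or_current(seed, {
    for (b in seq_len(n_permutations)) {
      if (share_permutations) {
        perm <- effects
        perm[defined] <- vals[sample.int(length(vals))]
        s_perm <- vapply(lags, function(d) lag_statistic(perm, d), numeric(1))
      } else {
        s_perm <- vapply(lags, function(d) {
          perm <- effects
          perm[defined] <- vals[sample.int(length(vals))]
          lag_statistic(perm, d)
        }, numeric(1))
      }
      count_le <- count_le + (s_perm <= s_obs)
    }
  })
  structure(
    tibble(lag = lags, s_obs = s_obs,
           p_value = (1 + count_le) / (n_permutations + 1),
           n_permutations = as.integer(n_permutations)),
    class = c("mpra_lagtest", class(tibble()))
  )
}
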