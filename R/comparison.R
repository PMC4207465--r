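# Cross-condition comparison of per-position effect-size profiles:
# standardize, difference, loess-smooth, call differential clusters.

#' Standardize an effect-size profile
#'
#' Centres and scales to mean 0, sample standard deviation 1 over the
#' defined positions; missing positions stay missing. Standardizing twice
#' equals standardizing once.
#'
#' @param effects Numeric vector (`NA` = undefined position).
#' @return Numeric vector of z-scores.
#' @export
standardize_profile <- function(effects) {
  ok <- !is.na(effects)
  if (sum(ok) < 2L) abort("need at least 2 defined values to standardize")
  s <- sd(effects[ok])
  if (s == 0) abort("zero spread: profile cannot be standardized")
  (effects - mean(effects[ok])) / s
}

#' Per-position difference of two standardized profiles
#'
#' @param z_a,z_b Numeric vectors over a common position universe (equal
#'   length). Positions missing in either profile are missing in the
#'   difference.
#' @return `z_a - z_b`, elementwise.
#' @export
profile_difference <- function(z_a, z_b) {
  if (length(z_a) != length(z_b)) {
    abort("profiles must cover the same position universe")
  }
  both <- !is.na(z_a) & !is.na(z_b)
  if (!any(both)) abort("profiles have disjoint supports")
  out <- z_a - z_b
  out[!both] <- NA_real_
  out
}

#' Loess smoothing of a positional signal
#'
#' Local linear regression (degree 1, tricube weights) over the fraction
#' `span` of nearest neighbours, evaluated at each input position. Exactly
#' linear input is reproduced exactly; missing values are dropped from the
#' fit and returned as missing.
#'
#' @param positions Numeric positions.
#' @param values Values at those positions (`NA` allowed).
#' @param span Neighbourhood fraction in (0, 1] (default 0.1).
#' @param degree Local polynomial degree (default 1).
#' @return Numeric vector of smoothed values at `positions`.
#' @export
loess_smooth <- function(positions, values, span = 0.1, degree = 1) {
  if (span <= 0 || span > 1) abort("`span` must be in (0, 1]")
  ok <- !is.na(values) & !is.na(positions)
  if (sum(ok) < 3L) abort("need at least 3 defined points")
  fit <- tryCatch(
    loess(values[ok] ~ positions[ok], span = span, degree = degree,
          family = "gaussian",
          control = stats::loess.control(surface = "direct")),
    error = function(e) abort(sprintf("loess failed: %s", conditionMessage(e)))
  )
  out <- rep(NA_real_, length(values))
  out[ok] <- as.numeric(predict(fit, newdata = positions[ok]))
  out
}

#' Call differential clusters from a smoothed difference curve
#'
#' Maximal runs of positions where `|smoothed| >= threshold`, kept when at
#' least `min_width` long. Runs separated by any sub-threshold position are
#' not merged. The sign of a cluster is the sign of its smoothed values.
#'
#' @param smoothed Numeric vector (smoothed standardized difference).
#' @param threshold Absolute threshold on the smoothed scale (default 1.5).
#' @param min_width Minimum run length in positions (default 4).
#' @return Tibble `start`, `end` (1-based inclusive), `width`, `sign`,
#'   `peak` (extreme smoothed value in the run).
#' @export
call_differential_clusters <- function(smoothed, threshold = 1.5,
                                       min_width = 4L) {
  hit <- !is.na(smoothed) & abs(smoothed) >= threshold
  if (!any(hit)) {
    return(tibble(start = integer(0), end = integer(0), width = integer(0),
                  sign = integer(0), peak = numeric(0)))
  }
  r <- rle(hit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values & r$lengths >= min_width)
  rows <- lapply(runs, function(i) {
    s <- starts[i]; e <- ends[i]
    seg <- smoothed[s:e]
    peak <- seg[which.max(abs(seg))]
    tibble(start = s, end = e, width = e - s + 1L,
           sign = as.integer(sign(peak)), peak = peak)
  })
  if (length(rows) == 0L) {
    return(tibble(start = integer(0), end = integer(0), width = integer(0),
                  sign = integer(0), peak = numeric(0)))
  }
  bind_rows(rows)
}

#' Compare two regulatory profiles
#'
#' Full cross-condition comparison: standardize each condition's
#' per-position effect profile, take per-position differences, smooth the
#' difference with loess, and call differential clusters where the smoothed
#' absolute difference exceeds a threshold.
#'
#' @param effects_a,effects_b Per-position effect sizes of the two
#'   conditions, equal length (`NA` = undefined).
#' @param span Loess span (default 0.1).
#' @param threshold Cluster threshold on the smoothed standardized scale
#'   (default 1.5).
#' @param min_width Minimum cluster width (default 4).
#' @return An `mpra_comparison` object: list with `profile` (tibble
#'   `position`, `z_a`, `z_b`, `difference`, `smoothed`) and `clusters`.
#'   Supports [tidy()], [glance()], [autoplot()].
#' @export
compare_profiles <- function(effects_a, effects_b, span = 0.1,
                             threshold = 1.5, min_width = 4L) {
  z_a <- standardize_profile(effects_a)
  z_b <- standardize_profile(effects_b)
  diff <- profile_difference(z_a, z_b)
  sm <- loess_smooth(seq_along(diff), diff, span = span)
  clusters <- call_differential_clusters(sm, threshold = threshold,
                                         min_width = min_width)
  structure(
    list(profile = tibble(position = seq_along(diff), z_a = z_a, z_b = z_b,
                          difference = diff, smoothed = sm),
         clusters = clusters, span = span, threshold = threshold,
         min_width = as.integer(min_width)),
    class = "mpra_comparison"
  )
}

#' @export
print.mpra_comparison <- function(x, ...) {
  cat(sprintf(
    "<mpra_comparison> %d positions; %d differential clusters (|smoothed z| >= %g, width >= %d)\n",
    nrow(x$profile), nrow(x$clusters), x$threshold, x$min_width))
  invisible(x)
}
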