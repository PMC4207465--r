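# broom-style tidiers for the package's fitted objects.

#' Tidy an effect profile
#'
#' @param x An `mpra_profile` from [effect_profile()].
#' @param model `"trivariate"` (default) or `"univariate"`.
#' @param ... Unused.
#' @return The requested estimate tibble.
#' @method tidy mpra_profile
#' @export
tidy.mpra_profile <- function(x, model = c("trivariate", "univariate"), ...) {
  model <- match.arg(model)
  x[[model]]
}

#' @rdname tidy.mpra_profile
#' @return `glance()`: a one-row tibble with counts of estimates and
#'   display-flagged estimates in both models.
#' @method glance mpra_profile
#' @export
glance.mpra_profile <- function(x, ...) {
  tibble(
    n_haplotypes = x$n_haplotypes,
    n_positions = nrow(x$univariate),
    n_substitutions = nrow(x$trivariate),
    n_display_univariate = sum(x$univariate$display),
    n_display_trivariate = sum(x$trivariate$display),
    p_display_threshold = x$p_display_threshold
  )
}

#' Tidy a contingency test
#'
#' @param x An `mpra_contingency` from [consequence_contingency()].
#' @param ... Unused.
#' @return One row per contingency cell with the test results repeated.
#' @method tidy mpra_contingency
#' @export
tidy.mpra_contingency <- function(x, ...) {
  df <- as.data.frame(x$table)
  names(df) <- c("consequence", "functional", "n")
  out <- as_tibble(df)
  out$threshold <- x$threshold
  out$p_value <- x$p_value
  out
}

#' @rdname tidy.mpra_contingency
#' @method glance mpra_contingency
#' @export
glance.mpra_contingency <- function(x, ...) {
  tibble(threshold = x$threshold, p_value = x$p_value,
         odds_ratio = x$odds_ratio, n = sum(x$table))
}

#' Tidy a profile comparison
#'
#' @param x An `mpra_comparison` from [compare_profiles()].
#' @param ... Unused.
#' @return The per-position comparison tibble.
#' @method tidy mpra_comparison
#' @export
tidy.mpra_comparison <- function(x, ...) x$profile

#' @rdname tidy.mpra_comparison
#' @method glance mpra_comparison
#' @export
glance.mpra_comparison <- function(x, ...) {
  tibble(n_positions = sum(!is.na(x$profile$difference)),
         n_clusters = nrow(x$clusters),
         threshold = x$threshold, min_width = x$min_width, span = x$span)
}
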