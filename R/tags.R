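# Tag processing: from raw RNA-tag reads to the per-haplotype aliquot-count
# outcome y.

#' Count quality-filtered tags per aliquot
#'
#' A read contributes to the tag count of its aliquot if and only if the
#' mean Phred score over its first `tag_length` bases (the degenerate tag)
#' is at least `min_tag_quality`; alternatively the minimum per-base score
#' can be used as the filter statistic. The 20-base prefix is taken as the
#' tag.
#'
#' @param reads Tibble with columns `replicate`, `aliquot`, `sequence`,
#'   `quality` (Phred+33). One row per read; each read must be at least
#'   `tag_length` bases long.
#' @param tag_length Tag length (default 20).
#' @param min_tag_quality Minimum quality over the tag prefix (default 20).
#' @param statistic `"mean"` (default) or `"min"` per-base Phred statistic.
#' @return A `tag_counts` tibble `tag`, `replicate`, `aliquot`, `count`;
#'   the numbers of passing and failing reads are attached as attributes.
#' @export
#' @examples
#' reads <- tibble::tibble(replicate = 1, aliquot = 3,
#'                         sequence = strrep("ACGTA", 4),
#'                         quality = strrep("I", 20))
#' count_tags(reads[c(1, 1), ])
count_tags <- function(reads, tag_length = 20L, min_tag_quality = 20,
                       statistic = c("mean", "min")) {
  statistic <- match.arg(statistic)
  need <- c("replicate", "aliquot", "sequence", "quality")
  if (!all(need %in% names(reads))) {
    abort(sprintf("`reads` must have columns: %s", paste(need, collapse = ", ")))
  }
  if (nrow(reads) == 0L) {
    warn("empty read input: returning an empty tag count matrix")
    return(new_tag_counts(
      tibble(tag = character(0), replicate = integer(0),
             aliquot = integer(0), count = integer(0)),
      n_reads_pass = 0L, n_reads_fail = 0L))
  }
  if (any(nchar(reads$sequence) < tag_length)) {
    abort(sprintf("all reads must be at least tag_length = %d bases", tag_length))
  }
  q <- if (statistic == "mean") {
    phred_prefix_mean(reads$quality, tag_length)
  } else {
    pre <- substr(reads$quality, 1L, tag_length)
    uq <- unique(pre)
    mins <- vapply(uq, function(s) min(utf8ToInt(s)) - 33, numeric(1),
                   USE.NAMES = FALSE)
    mins[match(pre, uq)]
  }
  pass <- q >= min_tag_quality
  kept <- reads[pass, ]
  out <- tibble(
    tag = toupper(substr(kept$sequence, 1L, tag_length)),
    replicate = kept$replicate,
    aliquot = kept$aliquot
  ) %>%
    count(.data$tag, .data$replicate, .data$aliquot, name = "count") %>%
    arrange(.data$tag, .data$replicate, .data$aliquot)
  new_tag_counts(out, n_reads_pass = sum(pass), n_reads_fail = sum(!pass))
}

#' Aliquot-presence filter
#'
#' Converts a tag-by-aliquot count matrix into the aliquot-count outcome.
#' With `scope = "per_aliquot"` (default) a tag is present in an aliquot if
#' and only if it is supported by at least `min_reads_per_tag` reads in that
#' aliquot. With `scope = "total"` a tag is kept if its total read support
#' across aliquots reaches the threshold, and is then present in every
#' aliquot where it has at least one read. `y` is the number of aliquots in
#' which the tag is present.
#'
#' Tags present in zero aliquots are retained (with `y = 0`) only when they
#' appear in `haplotype_tags` (the subassembled haplotype dictionary);
#' otherwise they are dropped. Observed tags that are absent from a supplied
#' dictionary are reported in the `spillover` attribute rather than silently
#' discarded.
#'
#' @param counts A `tag_counts` tibble from [count_tags()] or
#'   [read_tag_counts()].
#' @param min_reads_per_tag Read-support threshold (default 10).
#' @param scope `"per_aliquot"` (default) or `"total"`.
#' @param haplotype_tags Optional character vector of known haplotype tags.
#' @param n_replicates,n_aliquots_per_replicate Design dimensions; inferred
#'   from the data when omitted.
#' @return An `aliquot_presence` tibble `tag`, `y`, `y_rep1`, `y_rep2`, ...
#' @export
presence_filter <- function(counts, min_reads_per_tag = 10L,
                            scope = c("per_aliquot", "total"),
                            haplotype_tags = NULL,
                            n_replicates = NULL,
                            n_aliquots_per_replicate = NULL) {
  scope <- match.arg(scope)
  n_replicates <- n_replicates %||%
    (if (nrow(counts)) max(counts$replicate) else 1L)
  n_aliquots_per_replicate <- n_aliquots_per_replicate %||%
    (if (nrow(counts)) max(counts$aliquot) else 0L)
  present <- if (scope == "per_aliquot") {
    counts[counts$count >= min_reads_per_tag, ]
  } else {
    tot <- counts %>% group_by(.data$tag) %>%
      summarise(total = sum(.data$count), .groups = "drop")
    keep_tags <- tot$tag[tot$total >= min_reads_per_tag]
    counts[counts$tag %in% keep_tags & counts$count >= 1L, ]
  }
  per_rep <- present %>%
    count(.data$tag, .data$replicate, name = "y_rep") %>%
    tidyr::pivot_wider(names_from = "replicate", values_from = "y_rep",
                       names_prefix = "y_rep", values_fill = 0L)
  rep_cols <- sprintf("y_rep%d", seq_len(n_replicates))
  for (cl in setdiff(rep_cols, names(per_rep))) per_rep[[cl]] <- 0L
  per_rep <- per_rep[, c("tag", rep_cols)]
  spillover <- character(0)
  if (!is.null(haplotype_tags)) {
    spillover <- setdiff(per_rep$tag, haplotype_tags)
    per_rep <- per_rep[per_rep$tag %in% haplotype_tags, ]
    zero <- setdiff(haplotype_tags, per_rep$tag)
    if (length(zero) > 0L) {
      pad <- tibble(tag = zero)
      for (cl in rep_cols) pad[[cl]] <- 0L
      per_rep <- bind_rows(per_rep, pad)
    }
  }
  out <- per_rep %>%
    mutate(y = as.integer(rowSums(across(all_of(rep_cols))))) %>%
    select("tag", "y", all_of(rep_cols)) %>%
    arrange(.data$tag)
  structure(out,
            class = c("aliquot_presence", class(tibble())),
            K = as.integer(n_replicates * n_aliquots_per_replicate),
            scope = scope, min_reads_per_tag = min_reads_per_tag,
            spillover = spillover)
}

#' Combine aliquot-presence tables across replicates
#'
#' Sums aliquot counts over biological replicates: a tag absent from one
#' replicate contributes 0 there. Under the default design of 16 aliquots
#' and 2 replicates the combined maximum is K = 32.
#'
#' @param ... Two or more `aliquot_presence` tibbles (or a single list of
#'   them), one per replicate.
#' @return An `aliquot_presence` tibble over the union of tags, with the
#'   per-replicate counts as `y_rep1`, `y_rep2`, ... and `y` their sum.
#' @export
combine_replicates <- function(...) {
  tabs <- list(...)
  if (length(tabs) == 1L && is.list(tabs[[1]]) && !is.data.frame(tabs[[1]])) {
    tabs <- tabs[[1]]
  }
  if (length(tabs) < 2L) abort("need at least two replicate tables")
  Ks <- vapply(tabs, function(t) attr(t, "K") %||% NA_integer_, integer(1))
  tags <- sort(unique(unlist(lapply(tabs, function(t) t$tag))))
  out <- tibble(tag = tags)
  for (r in seq_along(tabs)) {
    y <- tabs[[r]]$y[match(tags, tabs[[r]]$tag)]
    out[[sprintf("y_rep%d", r)]] <- ifelse(is.na(y), 0L, y)
  }
  rep_cols <- sprintf("y_rep%d", seq_along(tabs))
  out$y <- as.integer(rowSums(out[, rep_cols]))
  out <- out[, c("tag", "y", rep_cols)]
  structure(out,
            class = c("aliquot_presence", class(tibble())),
            K = if (all(!is.na(Ks))) sum(Ks) else NA_integer_)
}
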