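# PSSM-based scoring of variant impact on transcription factor binding:
# log-likelihood-ratio mark scores over a window centred on each variant,
# a relative-entropy admission gate, and best-TF reporting.

#' Construct a position-specific scoring matrix
#'
#' Normalizes a 4 x L count (or probability) matrix per column with a
#' pseudocount, `(count + pseudocount) / (total + 4 * pseudocount)`, so
#' every probability is strictly positive, and precomputes the relative
#' entropy against the background.
#'
#' @param name Transcription factor name.
#' @param counts 4 x L numeric matrix, rows in A, C, G, T order.
#' @param background Length-4 background probabilities (A, C, G, T).
#' @param pseudocount Pseudocount per cell (default 0.25). Use 0 to take the
#'   matrix as exact probabilities.
#' @return A `pssm` object: list with `name`, `prob` (4 x L, columns sum to
#'   1), `background`, `length`, `relative_entropy` (bits).
#' @export
#' @examples
#' m <- cbind(c(97, 1, 1, 1), c(25, 25, 25, 25)) / 100
#' p <- pssm("toy", m, pseudocount = 0)
#' p$relative_entropy
pssm <- function(name, counts, background = rep(0.25, 4), pseudocount = 0.25) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) abort("PSSM matrix must have 4 rows (A, C, G, T)")
  if (any(counts < 0)) abort(sprintf("PSSM '%s' has negative entries", name))
  if (any(!is.finite(counts))) abort(sprintf("PSSM '%s' has non-finite entries", name))
  if (length(background) != 4L || abs(sum(background) - 1) > 1e-9) {
    abort("`background` must be 4 probabilities summing to 1")
  }
  tot <- colSums(counts)
  if (any(tot + 4 * pseudocount <= 0)) abort("PSSM has an empty column")
  prob <- sweep(counts + pseudocount, 2L, tot + 4 * pseudocount, "/")
  dimnames(prob) <- list(DNA_BASES, NULL)
  obj <- structure(
    list(name = name, prob = prob, background = setNames(background, DNA_BASES),
         length = ncol(prob)),
    class = "pssm"
  )
  obj$relative_entropy <- relative_entropy(obj)
  obj
}

#' @export
print.pssm <- function(x, ...) {
  cat(sprintf("<pssm> %s: length %d, relative entropy %.3f bits\n",
              x$name, x$length, x$relative_entropy))
  invisible(x)
}

#' Relative entropy of a PSSM against its background
#'
#' Kullback-Leibler divergence in bits:
#' `H = sum_j sum_i m[i, j] * log2(m[i, j] / B[i])`, with `0 * log(0) = 0`.
#' `H` is zero exactly when every column equals the background; a zero
#' background entry facing positive matrix mass gives infinite `H` (flagged
#' with a warning).
#'
#' @param x A [pssm] object.
#' @return Relative entropy in bits (scalar, `>= 0`).
#' @export
relative_entropy <- function(x) {
  stopifnot(inherits(x, "pssm"))
  m <- x$prob
  B <- x$background
  term <- m * log2(m / B)
  term[m == 0] <- 0
  if (any(B == 0 & rowSums(m) > 0)) {
    warn(sprintf("PSSM '%s': zero background entry with positive mass; relative entropy is infinite",
                 x$name))
    return(Inf)
  }
  max(sum(term), 0)
}

#' Score a subsequence against a PSSM
#'
#' Log2 likelihood ratio of the motif model against the background:
#' `sum_j log2(m[base_j, j] / B[base_j])`, in bits. The subsequence must
#' have exactly the motif length; any `N` base makes the score undefined
#' (`NA`).
#'
#' @param subsequence Character scalar of length `x$length` over A/C/G/T/N.
#' @param x A [pssm] object.
#' @return Score in bits, or `NA` if the subsequence contains `N`.
#' @export
pssm_score <- function(subsequence, x) {
  stopifnot(inherits(x, "pssm"))
  if (nchar(subsequence) != x$length) {
    abort(sprintf("subsequence length %d != motif length %d",
                  nchar(subsequence), x$length))
  }
  b <- .base_code[utf8ToInt(subsequence) + 1L] + 1L
  if (anyNA(b)) return(NA_real_)
  sum(log2(x$prob[cbind(b, seq_len(x$length))] / x$background[b]))
}

#' Reverse-complement a PSSM
#'
#' @param x A [pssm] object.
#' @return The PSSM of the reverse strand motif (columns reversed, rows
#'   swapped A<->T, C<->G); background likewise complemented.
#' @export
pssm_revcomp <- function(x) {
  stopifnot(inherits(x, "pssm"))
  prob <- x$prob[4:1, rev(seq_len(x$length)), drop = FALSE]
  dimnames(prob) <- list(DNA_BASES, NULL)
  out <- x
  out$prob <- prob
  out$background <- setNames(unname(x$background[4:1]), DNA_BASES)
  out$relative_entropy <- relative_entropy(out)
  out
}

#' Mark scores of a variant under one PSSM
#'
#' Takes the window (default 51 bp) of reference sequence centred on the
#' variant position (truncated at the sequence ends, keeping the variant as
#' central as possible), enumerates every motif-length subsequence that
#' overlaps the central position, and scores each with [pssm_score()].
#' `score_ref` is the maximum over those offsets (and over both strands by
#' default); `score_mut` is the same maximum after applying the variant.
#'
#' @param ref A [generate_reference()] object or a sequence string.
#' @param variant List or one-row data frame with `position` (1-based),
#'   `ref`, `alt`.
#' @param x A [pssm] object.
#' @param window Window width in bases (default 51).
#' @param both_strands Scan both strands (default TRUE).
#' @return Named list: `score_ref`, `score_mut`, `delta` (bits).
#' @export
mark_scores <- function(ref, variant, x, window = 51L, both_strands = TRUE) {
  seqs <- if (inherits(ref, "reference_enhancer")) ref$sequence else ref
  Lr <- nchar(seqs)
  pos <- as.integer(variant$position)
  if (pos < 1L || pos > Lr) abort("variant position outside the sequence")
  refb <- substr(seqs, pos, pos)
  if (!is.null(variant$ref) && !is.na(variant$ref) && variant$ref != refb) {
    abort(sprintf("variant reference base %s does not match sequence base %s at %d",
                  variant$ref, refb, pos))
  }
  if (x$length > window) abort("motif longer than the scan window")
  half <- (window - 1L) %/% 2L
  wstart <- max(1L, pos - half)
  wend <- min(Lr, wstart + window - 1L)
  wstart <- max(1L, wend - window + 1L)
  win_ref <- substr(seqs, wstart, wend)
  centre <- pos - wstart + 1L
  win_mut <- win_ref
  substr(win_mut, centre, centre) <- variant$alt
  L <- x$length
  # motif placements within the window whose span covers the central base
  starts <- max(1L, centre - L + 1L):min(nchar(win_ref) - L + 1L, centre)
  models <- list(x)
  if (both_strands) models <- c(models, list(pssm_revcomp(x)))
  best <- function(win) {
    scores <- unlist(lapply(models, function(m) {
      vapply(starts, function(s) {
        pssm_score(substr(win, s, s + L - 1L), m)
      }, numeric(1))
    }))
    if (all(is.na(scores))) NA_real_ else max(scores, na.rm = TRUE)
  }
  score_ref <- best(win_ref)
  score_mut <- best(win_mut)
  list(score_ref = score_ref, score_mut = score_mut,
       delta = score_mut - score_ref)
}

#' Best transcription factor change for a variant
#'
#' Computes [mark_scores()] for every PSSM in a collection, admits a TF only
#' if its reference or mutant score exceeds the TF's relative entropy, and
#' reports the admitted TF with the largest absolute score change. Ties are
#' broken deterministically by (|delta| descending, TF name ascending).
#'
#' @inheritParams mark_scores
#' @param collection List of [pssm] objects (see [read_pssm_collection()]).
#' @return Tibble with one row per TF: `tf`, `score_ref`, `score_mut`,
#'   `delta`, `relative_entropy`, `admitted`, `best` (logical; at most one
#'   TRUE). The best TF name (or `NA`) is in `attr(, "best_tf")`.
#' @export
best_tf_change <- function(ref, variant, collection, window = 51L,
                           both_strands = TRUE) {
  if (length(collection) == 0L) abort("empty PSSM collection")
  rows <- lapply(collection, function(p) {
    ms <- mark_scores(ref, variant, p, window = window,
                      both_strands = both_strands)
    tibble(tf = p$name, score_ref = ms$score_ref, score_mut = ms$score_mut,
           delta = ms$delta, relative_entropy = p$relative_entropy)
  })
  out <- bind_rows(rows)
  out$admitted <- !is.na(out$score_ref) & !is.na(out$score_mut) &
    pmax(out$score_ref, out$score_mut) > out$relative_entropy
  out$best <- FALSE
  adm <- which(out$admitted)
  if (length(adm) > 0L) {
    o <- adm[order(-abs(out$delta[adm]), out$tf[adm])]
    out$best[o[1]] <- TRUE
  }
  attr(out, "best_tf") <- if (any(out$best)) out$tf[out$best] else NA_character_
  out
}

#' Scan a variant table against a PSSM collection
#'
#' Applies [best_tf_change()] to every variant and stacks the per-TF rows.
#'
#' @param ref A [generate_reference()] object or sequence string.
#' @param variants Tibble with columns `position`, `ref`, `alt`.
#' @param collection List of [pssm] objects.
#' @inheritParams mark_scores
#' @return Tibble: `position`, `ref`, `alt`, `tf`, `score_ref`, `score_mut`,
#'   `delta`, `relative_entropy`, `admitted`, `best`.
#' @export
scan_variants <- function(ref, variants, collection, window = 51L,
                          both_strands = TRUE) {
  rows <- lapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    res <- best_tf_change(ref, v, collection, window = window,
                          both_strands = both_strands)
    res$position <- v$position
    res$ref <- v$ref
    res$alt <- v$alt
    res
  })
  bind_rows(rows) %>%
    select("position", "ref", "alt", dplyr::everything())
}

#' A small synthetic PSSM collection for examples and pipelines
#'
#' Builds a handful of synthetic liver-style motif matrices (sharp
#' consensus motifs of different lengths) in code. These are stand-ins for
#' database motifs, useful for demonstrations and end-to-end runs without
#' external matrix files.
#'
#' @param background Background base probabilities.
#' @return Named list of [pssm] objects.
#' @export
example_pssms <- function(background = rep(0.25, 4)) {
  consensus_matrix <- function(seqs, weight = 0.9) {
    L <- nchar(seqs[1])
    m <- matrix(0, nrow = 4L, ncol = L)
    for (s in seqs) {
      b <- match(split_chars(s), DNA_BASES)
      for (j in seq_len(L)) {
        m[, j] <- m[, j] + (1 - weight) / 3
        m[b[j], j] <- m[b[j], j] + weight - (1 - weight) / 3
      }
    }
    m / length(seqs)
  }
  defs <- list(
    TF_A = "TGACTCA",            # AP-1-like 7-mer
    TF_B = "CAAAGTCCA",          # nuclear-receptor-like 9-mer
    TF_C = "TTGGCA",             # NF-1-like half site
    TF_D = "GATAAG"              # GATA-like 6-mer
  )
  out <- lapply(names(defs), function(nm) {
    pssm(nm, consensus_matrix(defs[[nm]]), background = background,
         pseudocount = 0)
  })
  setNames(out, names(defs))
}
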