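#' Analysis configuration
#'
#' Bundles the fixed constants of the MPRA workflow: the tag-support filter
#' (at least ten reads per tag), the tag quality filter, the significance
#' display threshold, the sliding-window width for the windowed F profile,
#' the permutation count of the lag test, the PSSM scan window, the
#' fold-change classification thresholds, and the background base
#' distribution used for PSSM scoring.
#'
#' @param seed Integer seed that determines every stochastic step downstream.
#' @param min_reads_per_tag Minimum read support for a tag to count as
#'   present in an aliquot (default 10).
#' @param min_tag_quality Minimum mean Phred score over the 20-base tag
#'   prefix of an RNA read (default 20).
#' @param p_display_threshold Per-coefficient p-value below which an effect
#'   estimate is flagged for display (default 0.01).
#' @param window_size Width, in positions, of the sliding multi-position
#'   regression window (default 10).
#' @param n_permutations Number of permutations for the lag test
#'   (default 1000).
#' @param pssm_window Width, in bases, of the sequence window centred on a
#'   variant for PSSM scanning (default 51).
#' @param fc_thresholds Fold-change thresholds for classifying variants as
#'   functional (default `c(1.2, 2)`).
#' @param background Length-4 probability vector (A, C, G, T) used as the
#'   PSSM background model; must sum to 1 (default uniform).
#'
#' @return A list of class `mpra_config`.
#' @export
#' @examples
#' cfg <- mpra_config(seed = 7)
#' cfg$min_reads_per_tag
mpra_config <- function(seed = 1L,
                        min_reads_per_tag = 10L,
                        min_tag_quality = 20,
                        p_display_threshold = 0.01,
                        window_size = 10L,
                        n_permutations = 1000L,
                        pssm_window = 51L,
                        fc_thresholds = c(1.2, 2),
                        background = rep(0.25, 4)) {
  num <- list(min_reads_per_tag = min_reads_per_tag,
              min_tag_quality = min_tag_quality,
              p_display_threshold = p_display_threshold,
              window_size = window_size,
              n_permutations = n_permutations,
              pssm_window = pssm_window)
  for (nm in names(num)) {
    if (!is_scalar_number(num[[nm]]) || num[[nm]] <= 0) {
      abort(sprintf("`%s` must be a single strictly positive number", nm))
    }
  }
  if (length(fc_thresholds) < 1L || any(fc_thresholds <= 0)) {
    abort("`fc_thresholds` must be strictly positive fold changes")
  }
  if (length(background) != 4L || any(background < 0) ||
      abs(sum(background) - 1) > 1e-9) {
    abort("`background` must be 4 non-negative probabilities summing to 1")
  }
  structure(
    list(seed = as.integer(seed),
         min_reads_per_tag = as.integer(min_reads_per_tag),
         min_tag_quality = min_tag_quality,
         p_display_threshold = p_display_threshold,
         window_size = as.integer(window_size),
         n_permutations = as.integer(n_permutations),
         pssm_window = as.integer(pssm_window),
         fc_thresholds = sort(fc_thresholds),
         background = setNames(background, DNA_BASES)),
    class = "mpra_config"
  )
}

#' @export
print.mpra_config <- function(x, ...) {
  cat("<mpra_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-20s %s\n", nm, paste(format(x[[nm]]), collapse = " ")))
  }
  invisible(x)
}

#' Experiment design of the aliquot-presence readout
#'
#' Describes how the RNA readout is structured: the number of RT-PCR
#' aliquots per biological replicate, the number of replicates, the capture
#' efficiency linking haplotype activity to per-aliquot detection
#' probability, and the mean read count for a tag that is present in an
#' aliquot.
#'
#' @param n_aliquots_per_replicate RT-PCR aliquots per replicate (default 16).
#' @param n_replicates Biological replicates (default 2).
#' @param capture Capture efficiency `c`: a wild-type haplotype is detected
#'   in an aliquot with probability `c`; a mutant with probability
#'   `min(1, c * 2^E)` where `E` is its total log2 effect (default 0.2).
#' @param read_mean Mean (Poisson) read count for a tag present in an
#'   aliquot (default 50).
#'
#' @return A list of class `mpra_design`; `K = n_aliquots_per_replicate *
#'   n_replicates` is the maximum aliquot count.
#' @export
#' @examples
#' mpra_design()$K
mpra_design <- function(n_aliquots_per_replicate = 16L,
                        n_replicates = 2L,
                        capture = 0.2,
                        read_mean = 50) {
  if (n_aliquots_per_replicate < 1L || n_replicates < 1L) {
    abort("aliquot and replicate counts must be >= 1")
  }
  if (capture <= 0 || capture > 1) abort("`capture` must be in (0, 1]")
  if (read_mean <= 0) abort("`read_mean` must be positive")
  structure(
    list(n_aliquots_per_replicate = as.integer(n_aliquots_per_replicate),
         n_replicates = as.integer(n_replicates),
         capture = capture,
         read_mean = read_mean,
         K = as.integer(n_aliquots_per_replicate) * as.integer(n_replicates)),
    class = "mpra_design"
  )
}

#' @export
print.mpra_design <- function(x, ...) {
  cat(sprintf(
    "<mpra_design> %d aliquots x %d replicates (K = %d), capture = %g, read_mean = %g\n",
    x$n_aliquots_per_replicate, x$n_replicates, x$K, x$capture, x$read_mean))
  invisible(x)
}
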