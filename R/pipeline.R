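# End-to-end synthetic experiment: simulate -> count tags -> subassemble ->
# fit -> lag test -> TFBS scan -> cross-condition comparison.

#' Rescale planted effects inside selected clusters
#'
#' Multiplies the planted effects of the named clusters by `factor`,
#' leaving the rest of the landscape unchanged. Useful to derive a second
#' condition whose regulatory profile differs at specific clusters.
#'
#' @param landscape An [plant_effect_landscape()] tibble.
#' @param labels Cluster labels to modulate (see `attr(landscape,
#'   "clusters")`).
#' @param factor Multiplier applied to the effects in those clusters.
#' @return The modified landscape (cluster annotation preserved).
#' @export
modulate_landscape <- function(landscape, labels, factor = 0) {
  clusters <- attr(landscape, "clusters")
  sel <- clusters[clusters$label %in% labels, ]
  if (nrow(sel) == 0L) abort("no matching cluster labels")
  pos <- unlist(lapply(seq_len(nrow(sel)), function(i) sel$start[i]:sel$end[i]))
  out <- landscape
  out$effect[out$position %in% pos] <- out$effect[out$position %in% pos] * factor
  attr(out, "clusters") <- clusters
  out
}

#' Per-position effect vector from an estimate table
#'
#' @param estimates Tibble with `position` and `effect_size` columns (one
#'   row per position; use the univariate table).
#' @param length Enhancer length.
#' @param significant_only Keep only estimates flagged for display.
#' @return Numeric vector of length `length`, `NA` where no estimate.
#' @export
effects_by_position <- function(estimates, length, significant_only = FALSE) {
  if (significant_only && "display" %in% names(estimates)) {
    estimates <- estimates[estimates$display, ]
  }
  out <- rep(NA_real_, length)
  out[estimates$position] <- estimates$effect_size
  out
}

simulate_condition_readout <- function(haplotypes, landscape, design,
                                       noise_sd, min_reads_per_tag,
                                       min_tag_quality, haplotype_tags) {
  readout <- simulate_aliquot_counts(haplotypes, landscape, design = design,
                                     noise_sd = noise_sd)
  tag_reads <- simulate_tag_reads(attr(readout, "read_counts"))
  counts <- count_tags(tag_reads, min_tag_quality = min_tag_quality)
  presence_filter(counts, min_reads_per_tag = min_reads_per_tag,
                  haplotype_tags = haplotype_tags,
                  n_replicates = design$n_replicates,
                  n_aliquots_per_replicate = design$n_aliquots_per_replicate)
}

#' Run a complete synthetic MPRA experiment
#'
#' Simulates a doped haplotype library on a random reference enhancer with a
#' planted effect landscape, reconstructs the haplotypes by subassembly from
#' simulated fragment reads, simulates the RNA aliquot-presence readout in
#' two conditions (the second with selected clusters attenuated), runs the
#' tag-counting and presence-filter stages, fits the univariate and
#' trivariate effect models, the windowed F profile, the fold-change
#' classification with coding-consequence contingency, the lag permutation
#' test, a PSSM scan of the significant variants, and the standardized
#' cross-condition comparison.
#'
#' @param config An [mpra_config()]; `config$seed` determines every
#'   stochastic step.
#' @param design An [mpra_design()].
#' @param ref_length,mask_flank Reference geometry (defaults 600, 20).
#' @param n_haplotypes Library size (default 10000).
#' @param doping Designated-base retention probability (default 0.97).
#' @param n_clusters,cluster_width,sign_mix Landscape shape (defaults 5, 8,
#'   0.9).
#' @param noise_sd Activity noise, log2 units (default 0.25).
#' @param mean_coverage,error_rate Subassembly read simulation (defaults 20,
#'   0.001).
#' @param attenuate_labels Cluster labels silenced in condition B (default
#'   the first cluster).
#' @param pssm_collection PSSMs used for the variant scan (default
#'   [example_pssms()]).
#' @param max_scan_variants Cap on the number of significant variants
#'   scanned against the collection (default 50).
#' @return An `mpra_experiment` object: a list with the reference,
#'   landscapes, library, haplotype calls, per-condition presence tables and
#'   effect profiles, the windowed F profile, classification and
#'   contingency, lag test, TFBS scan, and profile comparison.
#' @export
run_mpra_experiment <- function(config = mpra_config(),
                                design = mpra_design(),
                                ref_length = 600L, mask_flank = 20L,
                                n_haplotypes = 10000L, doping = 0.97,
                                n_clusters = 5L, cluster_width = 8L,
                                sign_mix = 0.9, noise_sd = 0.25,
                                mean_coverage = 20, error_rate = 0.001,
                                attenuate_labels = "cluster_1",
                                pssm_collection = example_pssms(),
                                max_scan_variants = 50L) {
  withr::with_seed(config$seed, {
    cds_len <- 3L * ((ref_length %/% 2L) %/% 3L)
    cds_start <- mask_flank + 1L + ((ref_length - 2L * mask_flank - cds_len) %/% 2L)
    ref <- generate_reference(ref_length, mask_flank = mask_flank,
                              cds_window = list(start = cds_start,
                                                end = cds_start + cds_len - 1L,
                                                frame = 0L))
    landscape_a <- plant_effect_landscape(
      ref, n_clusters = n_clusters, cluster_width = cluster_width,
      sign_mix = sign_mix)
    landscape_b <- modulate_landscape(landscape_a, attenuate_labels, factor = 0)

    library <- simulate_doped_library(ref, n_haplotypes = n_haplotypes,
                                      doping = doping)
    sub_reads <- simulate_subassembly_reads(library, ref,
                                            mean_coverage = mean_coverage,
                                            error_rate = error_rate)
    calls <- subassemble(sub_reads, ref)
    usable <- calls[calls$status == "ok", ]

    presence <- lapply(list(a = landscape_a, b = landscape_b), function(ls) {
      simulate_condition_readout(library, ls, design, noise_sd,
                                 config$min_reads_per_tag,
                                 config$min_tag_quality, usable$tag)
    })
    inputs <- lapply(presence, function(p) effect_model_input(usable, p, ref))
    profiles <- lapply(inputs, effect_profile,
                       p_display_threshold = config$p_display_threshold)
    window_f <- windowed_f_profile(inputs$a, width = config$window_size)

    classified <- classify_fold_change(profiles$a$trivariate,
                                       thresholds = config$fc_thresholds)
    classified <- annotate_coding_consequence(ref, classified)
    contingency <- consequence_contingency(classified,
                                           threshold = config$fc_thresholds[1])

    eff_a <- effects_by_position(profiles$a$univariate, ref_length)
    eff_b <- effects_by_position(profiles$b$univariate, ref_length)
    lagtest <- lag_permutation_test(eff_a,
                                    d_max = min(30L, sum(!is.na(eff_a)) - 1L),
                                    n_permutations = config$n_permutations)

    sig <- profiles$a$trivariate[profiles$a$trivariate$display, ]
    sig <- head(arrange(sig, .data$p_value), max_scan_variants)
    tfbs <- if (nrow(sig) > 0L) {
      scan_variants(ref, sig[, c("position", "ref", "alt")], pssm_collection,
                    window = config$pssm_window)
    } else {
      NULL
    }

    # smoothing bandwidth matched to the TFBS-scale features the landscape
    # plants (~30 positions at the default geometry)
    comparison <- compare_profiles(eff_a, eff_b, span = 0.05)

    structure(
      list(config = config, design = design, reference = ref,
           landscape_a = landscape_a, landscape_b = landscape_b,
           library = library, sub_read_count = nrow(sub_reads),
           calls = calls, presence = presence, profiles = profiles,
           window_f = window_f, classified = classified,
           contingency = contingency, lagtest = lagtest, tfbs = tfbs,
           comparison = comparison),
      class = "mpra_experiment"
    )
  })
}

#' @export
print.mpra_experiment <- function(x, ...) {
  fc <- fold_change_summary(x$classified)
  cat("<mpra_experiment>\n")
  cat(sprintf("  reference: %d bp, %d mutable\n",
              nchar(x$reference$sequence), sum(x$reference$doping_mask)))
  cat(sprintf("  library: %d haplotypes; subassembly: %d/%d tags ok\n",
              nrow(x$library), sum(x$calls$status == "ok"), nrow(x$calls)))
  cat(sprintf("  condition A: %d univariate estimates, %d flagged at p <= %g\n",
              nrow(x$profiles$a$univariate),
              sum(x$profiles$a$univariate$display),
              x$config$p_display_threshold))
  for (i in seq_len(nrow(fc))) {
    cat(sprintf("  >= %g-fold: %.1f%% of substitutions (%.0f%% decrease)\n",
                fc$threshold[i], 100 * fc$fraction[i],
                100 * fc$fraction_decrease[i]))
  }
  cat(sprintf("  synonymous vs non-synonymous Fisher p = %.3g\n",
              x$contingency$p_value))
  cat(sprintf("  lag test: smallest lag with p >= 0.01: %s\n",
              {
                h <- x$lagtest$lag[x$lagtest$p_value >= 0.01]
                if (length(h)) min(h) else "none tested"
              }))
  cat(sprintf("  comparison: %d differential clusters\n",
              nrow(x$comparison$clusters)))
  invisible(x)
}

#' Write all result tables of an experiment
#'
#' Serializes the standard outputs: subassembly calls, per-condition
#' presence tables, univariate/trivariate effect tables, windowed F profile,
#' fold-change classification summary, contingency report, lag test, TFBS
#' scan, comparison profile, and BED files of landscape clusters and
#' differential clusters.
#'
#' @param x An [run_mpra_experiment()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_mpra_results <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(dir, f)
  files <- character(0)
  w <- function(tbl, f) {
    readr::write_tsv(tbl, path(f))
    files <<- c(files, path(f))
  }
  w(x$calls, "subassembly_calls.tsv")
  for (cond in names(x$presence)) {
    w(x$presence[[cond]], sprintf("presence_%s.tsv", cond))
    write_effect_table(x$profiles[[cond]]$univariate,
                       path(sprintf("effects_univariate_%s.tsv", cond)),
                       enhancer = x$reference$name)
    write_effect_table(x$profiles[[cond]]$trivariate,
                       path(sprintf("effects_trivariate_%s.tsv", cond)),
                       enhancer = x$reference$name)
    files <- c(files, path(sprintf("effects_univariate_%s.tsv", cond)),
               path(sprintf("effects_trivariate_%s.tsv", cond)))
  }
  w(x$window_f, "window_f_profile.tsv")
  w(fold_change_summary(x$classified), "fold_change_summary.tsv")
  w(tidy(x$contingency), "contingency.tsv")
  w(x$lagtest, "lag_test.tsv")
  if (!is.null(x$tfbs)) w(x$tfbs, "tfbs_scan.tsv")
  w(x$comparison$profile, "comparison_profile.tsv")
  clusters <- attr(x$landscape_a, "clusters")
  write_bed(clusters, path("planted_clusters.bed"), chrom = x$reference$name)
  files <- c(files, path("planted_clusters.bed"))
  if (nrow(x$comparison$clusters) > 0L) {
    write_bed(x$comparison$clusters, path("differential_clusters.bed"),
              chrom = x$reference$name)
    files <- c(files, path("differential_clusters.bed"))
  }
  invisible(files)
}
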