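# Shared fixtures built in code.

# Toy length-2 motif: column 1 nearly certain A, column 2 uniform.
toy_pssm <- function() {
  m <- cbind(c(0.97, 0.01, 0.01, 0.01), rep(0.25, 4))
  pssm("TOY", m, pseudocount = 0)
}

# Hand-built effect-model input: n haplotypes, given substitution long table.
manual_input <- function(y, sub_long, length = 10L, ref_seq = NULL) {
  ref_seq <- ref_seq %||% strrep("A", length)
  ref <- structure(
    list(name = "toy", sequence = ref_seq,
         doping_mask = rep(TRUE, nchar(ref_seq)), cds_window = NULL),
    class = "reference_enhancer")
  tags <- sprintf("TAG%03d", seq_along(y))
  subs <- rep("", length(y))
  if (nrow(sub_long) > 0L) {
    tok <- sprintf("%d:%s>%s", sub_long$position, sub_long$ref, sub_long$alt)
    agg <- vapply(split(tok, factor(sub_long$hap, levels = seq_along(y))),
                  paste, character(1), collapse = ",")
    subs <- unname(agg)
  }
  haps <- tibble::tibble(tag = tags, substitutions = subs)
  presence <- structure(tibble::tibble(tag = tags, y = y),
                        class = c("aliquot_presence", class(tibble::tibble())),
                        K = max(y, 1L))
  effect_model_input(haps, presence, ref)
}

# A small library + readout + fitted input used by several effect tests.
small_sim_env <- new.env(parent = emptyenv())

small_recovery_sim <- function() {
  if (!is.null(small_sim_env$sim)) return(small_sim_env$sim)
  ref <- generate_reference(300, mask_flank = 15, seed = 101)
  landscape <- plant_effect_landscape(ref, n_clusters = 3, cluster_width = 8,
                                      sign_mix = 0.9, seed = 102)
  lib <- simulate_doped_library(ref, n_haplotypes = 4000, seed = 103)
  readout <- suppressWarnings(
    simulate_aliquot_counts(lib, landscape, noise_sd = 0.25, seed = 104))
  input <- effect_model_input(lib, readout, ref)
  small_sim_env$sim <- list(ref = ref, landscape = landscape, lib = lib,
                            readout = readout, input = input)
  small_sim_env$sim
}

extdata <- function(f) system.file("extdata", f, package = "mpradisect")
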