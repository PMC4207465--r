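# Synthetic-data generators emulating the study design: a doped
# saturation-mutagenesis haplotype library read out as aliquot presence
# across replicated RT-PCR aliquots, plus subassembly fragment reads.

#' Generate a reference enhancer sequence
#'
#' Draws a uniform-random A/C/G/T sequence and masks the flanking
#' primer-landing sites, which are never mutated in a doped library.
#'
#' @param length Total sequence length in bases (default 600).
#' @param mask_flank Number of masked (immutable) positions at each end
#'   (default 20).
#' @param seed Integer seed; the same seed reproduces the same sequence.
#' @param name Sequence name.
#' @param cds_window Optional coding window `list(start, end, frame)`
#'   (1-based inclusive; `frame` = offset of the first complete codon within
#'   the window, 0..2) used for coding-consequence annotation.
#' @return A `reference_enhancer` object: list with `name`, `sequence`,
#'   `doping_mask` (logical, `TRUE` = mutable) and `cds_window`.
#' @export
#' @examples
#' ref <- generate_reference(200, mask_flank = 10, seed = 1)
#' sum(ref$doping_mask)
generate_reference <- function(length = 600L, mask_flank = 20L, seed = NULL,
                               name = "enhancer", cds_window = NULL) {
  length <- as.integer(length)
  mask_flank <- as.integer(mask_flank)
  if (length <= 2L * mask_flank) {
    abort("`length` must exceed twice `mask_flank`")
  }
  sequence <- with_seed_or_current(seed, {
    paste(sample(DNA_BASES, length, replace = TRUE), collapse = "")
  })
  mask <- rep(TRUE, length)
  if (mask_flank > 0L) {
    mask[c(seq_len(mask_flank), seq(length - mask_flank + 1L, length))] <- FALSE
  }
  if (!is.null(cds_window)) {
    cds_window <- as.list(cds_window)
    names(cds_window) <- c("start", "end", "frame")[seq_along(cds_window)]
    if (is.null(cds_window$frame)) cds_window$frame <- 0L
    if (cds_window$start < 1L || cds_window$end > length ||
        cds_window$start > cds_window$end) {
      abort("`cds_window` must lie within the sequence")
    }
  }
  structure(
    list(name = name, sequence = sequence, doping_mask = mask,
         cds_window = cds_window),
    class = "reference_enhancer"
  )
}

#' @export
print.reference_enhancer <- function(x, ...) {
  cat(sprintf("<reference_enhancer> %s: %d bp, %d mutable positions\n",
              x$name, nchar(x$sequence), sum(x$doping_mask)))
  invisible(x)
}

ref_bases <- function(ref) split_chars(ref$sequence)

#' Plant a ground-truth effect landscape
#'
#' Builds a per-(position, alternate base) table of true log2 fold-change
#' effects: zero everywhere except inside `n_clusters` non-overlapping
#' clusters of `cluster_width` adjacent mutable positions, where each
#' substitution's effect magnitude is drawn uniformly from
#' `[effect_low, effect_high]` and is negative with probability `sign_mix`.
#' This emulates enhancers whose activity-critical bases come in dispersed
#' TFBS-sized clusters and whose strong variants mostly reduce activity.
#'
#' @param ref A [generate_reference()] object.
#' @param n_clusters Number of effect clusters (default 5).
#' @param cluster_width Cluster width in positions (default 8).
#' @param effect_low,effect_high Range of |log2 fold change| inside clusters
#'   (defaults 0.5 and 2).
#' @param sign_mix Fraction of planted effects that are negative
#'   (default 0.9).
#' @param seed Integer seed.
#' @return An `effect_landscape` tibble with columns `position`, `ref`,
#'   `alt`, `effect`, covering every (position, alt != ref) pair; masked
#'   positions have effect 0. Cluster coordinates are stored in
#'   `attr(, "clusters")`.
#' @export
plant_effect_landscape <- function(ref, n_clusters = 5L, cluster_width = 8L,
                                   effect_low = 0.5, effect_high = 2,
                                   sign_mix = 0.9, seed = NULL) {
  L <- nchar(ref$sequence)
  bases <- ref_bases(ref)
  mutable <- which(ref$doping_mask)
  grid <- tibble(
    position = rep(seq_len(L), each = 3L),
    ref = rep(bases, each = 3L)
  )
  grid$alt <- unlist(lapply(bases, function(b) setdiff(DNA_BASES, b)),
                     use.names = FALSE)
  grid$effect <- 0
  clusters <- tibble(start = integer(0), end = integer(0), label = character(0))
  if (n_clusters > 0L) {
    span <- range(mutable)
    n_slots <- span[2] - cluster_width + 1L - span[1] + 1L
    if (n_slots < n_clusters * cluster_width) {
      abort("clusters do not fit inside the mutable span")
    }
    res <- with_seed_or_current(seed, {
      # rejection-sample non-overlapping cluster starts
      starts <- integer(0)
      tries <- 0L
      while (length(starts) < n_clusters) {
        cand <- sample(seq(span[1], span[2] - cluster_width + 1L), 1L)
        if (all(abs(cand - starts) >= cluster_width)) {
          starts <- c(starts, cand)
        }
        tries <- tries + 1L
        if (tries > 10000L) abort("could not place non-overlapping clusters")
      }
      starts <- sort(starts)
      in_cluster <- grid$position %in%
        unlist(lapply(starts, function(s) s:(s + cluster_width - 1L)))
      in_cluster <- in_cluster & grid$position %in% mutable
      k <- sum(in_cluster)
      mag <- runif(k, effect_low, effect_high)
      sgn <- ifelse(runif(k) < sign_mix, -1, 1)
      list(starts = starts, idx = which(in_cluster), eff = mag * sgn)
    })
    grid$effect[res$idx] <- res$eff
    clusters <- tibble(start = res$starts,
                       end = res$starts + cluster_width - 1L,
                       label = sprintf("cluster_%d", seq_along(res$starts)))
  }
  structure(grid, class = c("effect_landscape", class(tibble())),
            clusters = clusters)
}

#' Simulate a doped saturation-mutagenesis haplotype library
#'
#' Emulates doped oligonucleotide synthesis: each mutable position of each
#' haplotype independently retains the designated base with probability
#' `doping` and otherwise becomes one of the other three bases uniformly
#' (a 97:1:1:1 hand-mix at the default `doping = 0.97`). Each haplotype is
#' coupled to a unique degenerate tag.
#'
#' @param ref A [generate_reference()] object.
#' @param n_haplotypes Library size (default 10000).
#' @param doping Probability of retaining the designated base (default 0.97).
#' @param tag_length Tag length in bases (default 20).
#' @param seed Integer seed.
#' @return A haplotype tibble with columns `tag` and `substitutions`
#'   (comma-joined `"pos:ref>alt"` tokens, `""` for a wild-type haplotype).
#' @export
#' @examples
#' ref <- generate_reference(100, mask_flank = 5, seed = 1)
#' lib <- simulate_doped_library(ref, n_haplotypes = 50, seed = 2)
#' head(lib)
simulate_doped_library <- function(ref, n_haplotypes = 10000L, doping = 0.97,
                                   tag_length = 20L, seed = NULL) {
  if (doping <= 0 || doping > 1) abort("`doping` must be in (0, 1]")
  n_haplotypes <- as.integer(n_haplotypes)
  if (n_haplotypes < 1L) abort("`n_haplotypes` must be >= 1")
  bases <- ref_bases(ref)
  mutable <- which(ref$doping_mask)
  m <- length(mutable)
  with_seed_or_current(seed, {
    tags <- random_tags(n_haplotypes, tag_length)
    subs <- character(n_haplotypes)
    if (doping < 1 && m > 0L) {
      hit <- which(matrix(runif(n_haplotypes * m) > doping,
                          nrow = n_haplotypes, ncol = m),
                   arr.ind = TRUE)
      if (nrow(hit) > 0L) {
        hap <- hit[, 1L]
        pos <- mutable[hit[, 2L]]
        refb <- bases[pos]
        # uniform choice among the three non-designated bases
        off <- sample.int(3L, length(pos), replace = TRUE)
        alt <- vapply(seq_along(pos), function(i) {
          setdiff(DNA_BASES, refb[i])[off[i]]
        }, character(1))
        o <- order(hap, pos)
        tok <- sprintf("%d:%s>%s", pos[o], refb[o], alt[o])
        subs <- vapply(
          split(tok, factor(hap[o], levels = seq_len(n_haplotypes))),
          paste, character(1), collapse = ",")
      }
    }
    new_haplotype_table(tibble(tag = tags, substitutions = unname(subs)))
  })
}

new_haplotype_table <- function(x) {
  structure(x, class = c("haplotype_table", class(tibble())))
}

#' Expand a haplotype table to one row per substitution
#'
#' @param haplotypes Tibble with `tag` and comma-joined `substitutions`.
#' @return Tibble with columns `tag`, `position`, `ref`, `alt`, one row per
#'   substitution (haplotypes without substitutions contribute no rows).
#' @export
substitutions_long <- function(haplotypes) {
  nonwt <- haplotypes$substitutions != "" & !is.na(haplotypes$substitutions)
  if (!any(nonwt)) {
    return(tibble(tag = character(0), position = integer(0),
                  ref = character(0), alt = character(0)))
  }
  toks <- strsplit(haplotypes$substitutions[nonwt], ",", fixed = TRUE)
  tag <- rep(haplotypes$tag[nonwt], lengths(toks))
  tok <- unlist(toks, use.names = FALSE)
  m <- regmatches(tok, regexec("^([0-9]+):([ACGT])>([ACGT])$", tok))
  bad <- lengths(m) != 4L
  if (any(bad)) abort(sprintf("malformed substitution token '%s'", tok[bad][1]))
  mm <- matrix(unlist(m, use.names = FALSE), ncol = 4L, byrow = TRUE)
  tibble(tag = tag, position = as.integer(mm[, 2L]),
         ref = mm[, 3L], alt = mm[, 4L])
}

#' Reconstruct full haplotype sequences
#'
#' @param ref A [generate_reference()] object.
#' @param haplotypes Haplotype tibble (`tag`, `substitutions`).
#' @return Character vector of full-length sequences, one per haplotype.
#' @export
haplotype_sequences <- function(ref, haplotypes) {
  n <- nrow(haplotypes)
  L <- nchar(ref$sequence)
  m <- matrix(rep(encode_base_matrix(ref$sequence)[1L, ], each = n),
              nrow = n, ncol = L)
  long <- substitutions_long(haplotypes)
  if (nrow(long) > 0L) {
    hap_idx <- match(long$tag, haplotypes$tag)
    refb <- ref_bases(ref)
    if (any(refb[long$position] != long$ref)) {
      abort("substitution reference base does not match the reference sequence")
    }
    m[cbind(hap_idx, long$position)] <- match(long$alt, DNA_BASES) - 1L
  }
  decode_base_matrix(m)
}

#' Simulate the aliquot-presence readout
#'
#' Forward model for the assay outcome. Haplotype activity is multiplicative
#' in fold change: `A_i = 2^(sum of true effects + noise)` with
#' `noise ~ N(0, noise_sd)` in log2 units. The tag of haplotype *i* is
#' detected in each of the `K` aliquots independently with probability
#' `p_i = min(1, capture * A_i)`; the outcome `y_i` is the number of
#' aliquots in which it was detected (the aliquot count). Detected
#' (tag, aliquot) cells additionally receive a Poisson read count with mean
#' `design$read_mean`, so the tag-counting stage can be exercised end to end.
#'
#' @param haplotypes Haplotype tibble (`tag`, `substitutions`).
#' @param landscape An [plant_effect_landscape()] tibble.
#' @param design An [mpra_design()].
#' @param noise_sd Standard deviation of per-haplotype lognormal activity
#'   noise, in log2 units (default 0.25).
#' @param seed Integer seed.
#' @return A tibble with columns `tag`, `y`, `y_rep1`, ..., plus `activity`
#'   and `p_detect`; the per-aliquot read counts are attached as
#'   `attr(, "read_counts")` (tibble `tag`, `replicate`, `aliquot`, `count`).
#'   The number of probability clippings at 1 is in `attr(, "n_clipped")`.
#' @export
simulate_aliquot_counts <- function(haplotypes, landscape,
                                    design = mpra_design(),
                                    noise_sd = 0.25, seed = NULL) {
  long <- substitutions_long(haplotypes)
  n <- nrow(haplotypes)
  e_tot <- numeric(n)
  if (nrow(long) > 0L) {
    key_land <- paste(landscape$position, landscape$alt)
    idx <- match(paste(long$position, long$alt), key_land)
    if (anyNA(idx)) abort("haplotype substitution not covered by the landscape")
    e_tot <- sum_by_index(landscape$effect[idx],
                          match(long$tag, haplotypes$tag), n)
  }
  K <- design$K
  R <- design$n_replicates
  A <- design$n_aliquots_per_replicate
  with_seed_or_current(seed, {
    log2_act <- e_tot + if (noise_sd > 0) rnorm(n, 0, noise_sd) else 0
    activity <- 2^log2_act
    p_raw <- design$capture * activity
    n_clipped <- sum(p_raw > 1)
    if (n_clipped > 0L) {
      warn(sprintf(
        "%d haplotypes had detection probability clipped at 1 (out of linear regime)",
        n_clipped))
    }
    p <- pmin(1, p_raw)
    detected <- matrix(runif(n * K) < rep(p, K), nrow = n, ncol = K)
    rep_of_col <- rep(seq_len(R), each = A)
    y_rep <- vapply(seq_len(R), function(r) {
      rowSums(detected[, rep_of_col == r, drop = FALSE])
    }, numeric(n))
    out <- tibble(tag = haplotypes$tag, y = as.integer(rowSums(y_rep)))
    for (r in seq_len(R)) out[[sprintf("y_rep%d", r)]] <- as.integer(y_rep[, r])
    out$activity <- activity
    out$p_detect <- p
    cells <- which(detected, arr.ind = TRUE)
    counts <- tibble(
      tag = haplotypes$tag[cells[, 1L]],
      replicate = rep_of_col[cells[, 2L]],
      aliquot = ((cells[, 2L] - 1L) %% A) + 1L,
      count = rpois(nrow(cells), design$read_mean)
    )
    # a detected cell always yields at least one read
    counts$count[counts$count == 0L] <- 1L
    structure(out,
              class = c("aliquot_presence", class(tibble())),
              read_counts = counts, design = design, n_clipped = n_clipped,
              K = K)
  })
}

#' Expand simulated per-aliquot tag counts into RNA-tag reads
#'
#' Materializes the read-count table of [simulate_aliquot_counts()] as
#' individual tag reads with constant quality, the input expected by
#' [count_tags()].
#'
#' @param read_counts Tibble `tag`, `replicate`, `aliquot`, `count`.
#' @param quality Constant per-base Phred score (default 37).
#' @return Tibble `replicate`, `aliquot`, `sequence`, `quality`.
#' @export
simulate_tag_reads <- function(read_counts, quality = 37) {
  idx <- rep(seq_len(nrow(read_counts)), read_counts$count)
  qchar <- rawToChar(as.raw(quality + 33))
  tibble(
    replicate = read_counts$replicate[idx],
    aliquot = read_counts$aliquot[idx],
    sequence = read_counts$tag[idx],
    quality = strrep(qchar, nchar(read_counts$tag[idx]))
  )
}

#' Simulate subassembly fragment reads
#'
#' Per haplotype, draws fragment breakpoints uniformly along the cloned
#' construct until the requested mean per-position coverage is reached, and
#' emits `read_length`-bp reads starting at each breakpoint. Breakpoints may
#' fall in the cloning context flanking the tested sequence, so terminal
#' reads are clipped to the reference span and coverage is uniform across
#' the whole sequence. Sequencing substitution errors are injected per base
#' at `error_rate`; qualities are constant Q37. The paired index read
#' carries the exact 20-bp tag.
#'
#' @param haplotypes Haplotype tibble (`tag`, `substitutions`).
#' @param ref A [generate_reference()] object.
#' @param read_length Fragment read length (default 101).
#' @param mean_coverage Target mean per-position coverage per haplotype
#'   (default 20).
#' @param error_rate Per-base substitution error probability (default 0.001).
#' @param seed Integer seed.
#' @return Tibble with columns `read_id`, `tag`, `offset` (0-based start on
#'   the reference), `sequence`, `quality`. Use [write_fastq_pair()] to
#'   serialize as a FASTQ pair.
#' @export
simulate_subassembly_reads <- function(haplotypes, ref, read_length = 101L,
                                       mean_coverage = 20, error_rate = 0.001,
                                       seed = NULL) {
  L <- nchar(ref$sequence)
  read_length <- as.integer(read_length)
  if (read_length > L) abort("`read_length` must not exceed the reference length")
  if (mean_coverage <= 0) {
    return(tibble(read_id = character(0), tag = character(0),
                  offset = integer(0), sequence = character(0),
                  quality = character(0)))
  }
  n <- nrow(haplotypes)
  # breakpoints span the construct: starts in [-(read_length-1), L-1] keep
  # every position of the tested sequence equally coverable
  n_starts <- L + read_length - 1L
  reads_per_hap <- as.integer(ceiling(mean_coverage * n_starts / read_length))
  with_seed_or_current(seed, {
    seqs <- haplotype_sequences(ref, haplotypes)
    hap_idx <- rep(seq_len(n), each = reads_per_hap)
    bp <- sample.int(n_starts, n * reads_per_hap, replace = TRUE) -
      read_length  # 0-based construct start; negative = in 5' flank
    start <- pmax(bp, 0L)
    end <- pmin(bp + read_length - 1L, L - 1L)
    keep <- end >= start
    hap_idx <- hap_idx[keep]; start <- start[keep]; end <- end[keep]
    sequence <- substr(seqs[hap_idx], start + 1L, end + 1L)
    total_bases <- sum(end - start + 1L)
    if (error_rate > 0) {
      n_err <- rbinom(1L, total_bases, error_rate)
      if (n_err > 0L) {
        len <- end - start + 1L
        cum <- cumsum(len)
        flat <- sample.int(total_bases, n_err)
        rid <- findInterval(flat - 1L, cum) + 1L
        within <- flat - c(0L, cum)[rid]
        for (i in seq_len(n_err)) {
          old <- substr(sequence[rid[i]], within[i], within[i])
          substr(sequence[rid[i]], within[i], within[i]) <-
            sample(setdiff(DNA_BASES, old), 1L)
        }
      }
    }
    q <- rawToChar(as.raw(37 + 33))
    tibble(
      read_id = sprintf("read_%d", seq_along(hap_idx)),
      tag = haplotypes$tag[hap_idx],
      offset = start,
      sequence = sequence,
      quality = strrep(q, end - start + 1L)
    )
  })
}
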