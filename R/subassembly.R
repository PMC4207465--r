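# Subassembly: reconstruct the full haplotype behind each tag from
# fragment reads sharing that tag. Libraries contain substitutions only,
# so placement is ungapped and anchored on exact k-mers.

#' Group fragment reads by tag
#'
#' @param reads Tibble with columns `tag` and `sequence` (for example from
#'   [simulate_subassembly_reads()] or a FASTQ pair read with
#'   [read_fastq()]). Tags must be exact 20-base strings; grouping is by
#'   exact string match.
#' @return Tibble `tag`, `n_reads`, `reads` (list column of character
#'   vectors), one row per distinct tag.
#' @export
group_reads_by_tag <- function(reads) {
  if (nrow(reads) == 0L) {
    return(tibble(tag = character(0), n_reads = integer(0), reads = list()))
  }
  reads %>%
    group_by(.data$tag) %>%
    summarise(n_reads = n(), reads = list(.data$sequence), .groups = "drop") %>%
    arrange(.data$tag)
}

# Build the exact k-mer index of the reference: position (0-based) of each
# k-mer code; k-mers occurring more than once are ambiguous and excluded.
ref_kmer_index <- function(ref_sequence, k) {
  rm <- encode_base_matrix(ref_sequence)[1L, ]
  L <- length(rm)
  n_kmers <- L - k + 1L
  codes <- numeric(n_kmers)
  code <- 0
  for (t in seq_len(k)) code <- code * 4 + rm[t]
  codes[1L] <- code
  top <- 4^(k - 1)
  if (n_kmers > 1L) {
    for (j in 2:n_kmers) {
      code <- (code - rm[j - 1L] * top) * 4 + rm[j + k - 1L]
      codes[j] <- code
    }
  }
  dup <- codes %in% codes[duplicated(codes)]
  list(codes = codes[!dup], pos0 = which(!dup) - 1L, k = k, ref_int = rm)
}

# Rolling k-mer codes for a batch of equal-length reads: matrix
# n_reads x (len - k + 1), NA where the k-mer contains a non-ACGT base.
read_kmer_codes <- function(M, k) {
  len <- ncol(M)
  n_kmers <- len - k + 1L
  codes <- matrix(NA_real_, nrow = nrow(M), ncol = n_kmers)
  code <- numeric(nrow(M))
  code[] <- 0
  for (t in seq_len(k)) code <- code * 4 + M[, t]
  codes[, 1L] <- code
  top <- 4^(k - 1)
  if (n_kmers > 1L) {
    for (j in 2:n_kmers) {
      code <- (code - M[, j - 1L] * top) * 4 + M[, j + k - 1L]
      codes[, j] <- code
    }
  }
  codes
}

place_batch <- function(seqs, index, max_mismatch_frac) {
  n <- length(seqs)
  len <- nchar(seqs[1])
  k <- index$k
  if (len < k) return(rep(NA_integer_, n))
  M <- encode_base_matrix(seqs)
  codes <- read_kmer_codes(M, k)
  hit <- matrix(index$pos0[match(codes, index$codes)],
                nrow = n, ncol = ncol(codes))
  # candidate offset implied by anchor j: ref position minus read position
  off <- hit - matrix(rep(0:(ncol(codes) - 1L), each = n), nrow = n)
  offset <- rep(NA_integer_, n)
  cols <- lapply(seq_len(ncol(off)), function(j) off[, j])
  rng_min <- Reduce(function(a, b) pmin(a, b, na.rm = TRUE), cols)
  rng_max <- Reduce(function(a, b) pmax(a, b, na.rm = TRUE), cols)
  unanimous <- !is.na(rng_min) & rng_min == rng_max
  offset[unanimous] <- as.integer(rng_min[unanimous])
  disagree <- which(!is.na(rng_min) & !unanimous)
  for (i in disagree) {
    tab <- table(off[i, ])
    best <- max(tab)
    winners <- names(tab)[tab == best]
    if (length(winners) == 1L) offset[i] <- as.integer(winners)
  }
  # reject placements outside the reference or with too many mismatches
  L <- length(index$ref_int)
  bad <- !is.na(offset) & (offset < 0L | offset + len > L)
  offset[bad] <- NA_integer_
  ok <- which(!is.na(offset))
  if (length(ok) > 0L) {
    idx <- matrix(rep(offset[ok], len) + rep(seq_len(len), each = length(ok)),
                  nrow = length(ok))
    mm <- rowSums(M[ok, , drop = FALSE] !=
                    matrix(index$ref_int[idx], nrow = length(ok)),
                  na.rm = TRUE)
    reject <- mm > ceiling(len * max_mismatch_frac)
    offset[ok[reject]] <- NA_integer_
  }
  offset
}

#' Place fragment reads on the reference (ungapped)
#'
#' Every exact k-mer of the read is looked up in the reference k-mer index;
#' the offset consistent with the most anchors wins (ties and anchor-free
#' reads are unplaced). A placement is accepted only if the number of
#' mismatches does not exceed `ceiling(read_length * max_mismatch_frac)`.
#'
#' @param reads Character vector of read sequences (lengths may differ).
#' @param ref A [generate_reference()] object, or a reference sequence
#'   string.
#' @param k Anchor k-mer length (default 15).
#' @param max_mismatch_frac Maximum mismatch fraction (default 0.1).
#' @return Integer vector of 0-based offsets; `NA` for unplaced reads.
#' @export
#' @examples
#' ref <- generate_reference(200, mask_flank = 10, seed = 1)
#' read <- substr(ref$sequence, 101, 180)
#' place_read(read, ref)  # 100 (0-based)
place_read <- function(reads, ref, k = 15L, max_mismatch_frac = 0.1) {
  ref_seq <- if (inherits(ref, "reference_enhancer")) ref$sequence else ref
  if (k > min(c(nchar(reads), nchar(ref_seq)))) {
    abort("`k` must not exceed the read and reference lengths")
  }
  index <- ref_kmer_index(ref_seq, as.integer(k))
  offsets <- rep(NA_integer_, length(reads))
  for (len in unique(nchar(reads))) {
    sel <- nchar(reads) == len
    offsets[sel] <- place_batch(reads[sel], index, max_mismatch_frac)
  }
  offsets
}

#' Call the haplotype of one tag group
#'
#' Majority vote per covered reference position over the placed reads of a
#' tag group. A base is called where coverage is at least `min_cov` and the
#' majority fraction is at least `min_frac`; a called base differing from
#' the reference yields a substitution. A position failing `min_frac`
#' despite sufficient coverage marks the call `conflicted` (for example two
#' haplotypes sharing one tag). Positions with coverage below `min_cov` are
#' assumed wild-type when `assume_wt = TRUE` (the default); otherwise they
#' set status `low_coverage`. Masked positions never yield substitutions.
#'
#' @param group List with elements `reads` (character vector) or a character
#'   vector of read sequences.
#' @param ref A [generate_reference()] object.
#' @param min_cov Minimum coverage to call a base (default 3).
#' @param min_frac Minimum majority fraction (default 0.8).
#' @param assume_wt Assume wild type at positions with coverage below
#'   `min_cov` (default TRUE).
#' @param k,max_mismatch_frac Placement parameters, see [place_read()].
#' @return A one-row tibble `tag`, `status` (`ok`, `low_coverage` or
#'   `conflicted`), `n_reads`, `n_placed`, `substitutions`,
#'   `min_coverage`, `min_majority`.
#' @export
call_haplotype <- function(group, ref, min_cov = 3L, min_frac = 0.8,
                           assume_wt = TRUE, k = 15L,
                           max_mismatch_frac = 0.1) {
  reads <- if (is.list(group) && !is.null(group$reads)) {
    if (is.list(group$reads)) group$reads[[1]] else group$reads
  } else {
    group
  }
  tag <- if (is.list(group) && !is.null(group$tag)) group$tag[1] else NA_character_
  if (length(reads) == 0L) abort("empty read group")
  offsets <- place_read(reads, ref, k = k, max_mismatch_frac = max_mismatch_frac)
  call_from_votes(tag, reads, offsets, ref, min_cov, min_frac, assume_wt)
}

# Tally per-position base votes for one group and call substitutions.
call_from_votes <- function(tag, reads, offsets, ref, min_cov, min_frac,
                            assume_wt) {
  L <- nchar(ref$sequence)
  placed <- which(!is.na(offsets))
  if (length(placed) == 0L) {
    return(tibble(tag = tag, status = "conflicted",
                  n_reads = length(reads), n_placed = 0L,
                  substitutions = "", min_coverage = 0L, min_majority = NA_real_))
  }
  votes <- matrix(0L, nrow = 4L, ncol = L)
  for (i in placed) {
    b <- encode_base_matrix(reads[i])[1L, ]
    pos <- offsets[i] + seq_along(b)
    keep <- !is.na(b)
    idx <- cbind(b[keep] + 1L, pos[keep])
    votes[idx] <- votes[idx] + 1L
  }
  summarise_votes(tag, votes, ref, length(reads), length(placed),
                  min_cov, min_frac, assume_wt)
}

summarise_votes <- function(tag, votes, ref, n_reads, n_placed,
                            min_cov, min_frac, assume_wt) {
  L <- ncol(votes)
  coverage <- colSums(votes)
  top <- apply(votes, 2L, max)
  winner <- max.col(t(votes), ties.method = "first")
  frac <- ifelse(coverage > 0, top / coverage, NA_real_)
  refb <- ref_bases(ref)
  called <- coverage >= min_cov & !is.na(frac) & frac >= min_frac
  conflict <- coverage >= min_cov & !is.na(frac) & frac < min_frac
  lowcov <- coverage < min_cov
  status <- if (any(conflict)) {
    "conflicted"
  } else if (any(lowcov) && !assume_wt) {
    "low_coverage"
  } else if (any(coverage == 0L)) {
    "low_coverage"
  } else {
    "ok"
  }
  sub_pos <- which(called & DNA_BASES[winner] != refb & ref$doping_mask)
  subs <- if (length(sub_pos) > 0L) {
    paste(sprintf("%d:%s>%s", sub_pos, refb[sub_pos], DNA_BASES[winner][sub_pos]),
          collapse = ",")
  } else {
    ""
  }
  tibble(tag = tag, status = status, n_reads = n_reads, n_placed = n_placed,
         substitutions = subs,
         min_coverage = as.integer(min(coverage)),
         min_majority = suppressWarnings(min(frac[coverage >= min_cov])))
}

#' Subassemble a full read set into haplotype calls
#'
#' Vectorized pipeline over all tags: places every read on the reference,
#' tallies per-(tag, position) base votes, and calls one haplotype per tag
#' with [call_haplotype()] semantics.
#'
#' @param reads Tibble with columns `tag`, `sequence` (for example from
#'   [simulate_subassembly_reads()]).
#' @param ref A [generate_reference()] object.
#' @inheritParams call_haplotype
#' @param chunk_size Number of reads processed per placement chunk.
#' @return A `haplotype_table` tibble: `tag`, `status`, `n_reads`,
#'   `n_placed`, `substitutions`, `min_coverage`, `min_majority`, one row
#'   per tag, sorted by tag.
#' @export
subassemble <- function(reads, ref, min_cov = 3L, min_frac = 0.8,
                        assume_wt = TRUE, k = 15L, max_mismatch_frac = 0.1,
                        chunk_size = 200000L) {
  if (nrow(reads) == 0L) {
    return(new_haplotype_table(tibble(
      tag = character(0), status = character(0), n_reads = integer(0),
      n_placed = integer(0), substitutions = character(0),
      min_coverage = integer(0), min_majority = numeric(0))))
  }
  L <- nchar(ref$sequence)
  tags <- sort(unique(reads$tag))
  tag_id <- match(reads$tag, tags)
  n_tags <- length(tags)
  index <- ref_kmer_index(ref$sequence, as.integer(k))
  # vote tally laid out as [base(4), position(L), tag]; accumulated with
  # tabulate() over chunked flat indices to bound memory
  nbins <- 4 * L * n_tags
  tally <- numeric(nbins)
  buffer <- list()
  buffered <- 0
  flush_buffer <- function() {
    if (buffered == 0) return(invisible(NULL))
    tally <<- tally + tabulate(unlist(buffer, use.names = FALSE), nbins = nbins)
    buffer <<- list()
    buffered <<- 0
  }
  offsets_all <- rep(NA_integer_, nrow(reads))
  lens <- nchar(reads$sequence)
  for (len in unique(lens)) {
    sel <- which(lens == len)
    for (from in seq(1L, length(sel), by = chunk_size)) {
      ii <- sel[from:min(from + chunk_size - 1L, length(sel))]
      M <- encode_base_matrix(reads$sequence[ii])
      offs <- place_batch(reads$sequence[ii], index, max_mismatch_frac)
      offsets_all[ii] <- offs
      ok <- which(!is.na(offs))
      if (length(ok) == 0L) next
      nok <- length(ok)
      basec <- M[ok, , drop = FALSE]                        # 0..3
      posm <- matrix(rep(offs[ok], len) + rep(seq_len(len), each = nok),
                     nrow = nok)                            # 1..L
      tagm <- matrix(rep(tag_id[ii][ok], len), nrow = nok)
      flat <- basec + 4 * (posm - 1) + (4 * L) * (tagm - 1) + 1
      buffer[[length(buffer) + 1L]] <- flat[!is.na(flat)]
      buffered <- buffered + length(buffer[[length(buffer)]])
      if (buffered >= 3e7) flush_buffer()
    }
  }
  flush_buffer()
  dim(tally) <- c(4L, L * n_tags)
  coverage <- colSums(tally)                                 # length L*n_tags
  top <- pmax(tally[1L, ], tally[2L, ], tally[3L, ], tally[4L, ])
  winner <- rep(1L, length(top))
  cur <- tally[1L, ]
  for (b in 2:4) {
    better <- tally[b, ] > cur
    winner[better] <- b
    cur[better] <- tally[b, better]
  }
  refb <- ref_bases(ref)
  refb_code <- rep(match(refb, DNA_BASES), n_tags)
  frac <- top / coverage                                     # NaN at cov 0
  called <- coverage >= min_cov & !is.nan(frac) & frac >= min_frac
  conflict <- coverage >= min_cov & !is.nan(frac) & frac < min_frac
  tag_of_cell <- rep(seq_len(n_tags), each = L)
  pos_of_cell <- rep(seq_len(L), n_tags)
  mask_cell <- rep(ref$doping_mask, n_tags)

  n_reads_tag <- tabulate(tag_id, n_tags)
  n_placed_tag <- tabulate(tag_id[!is.na(offsets_all)], n_tags)
  any_conflict <- tabulate(tag_of_cell[conflict], n_tags) > 0L
  any_lowcov <- tabulate(tag_of_cell[coverage < min_cov], n_tags) > 0L
  any_zero <- tabulate(tag_of_cell[coverage == 0L], n_tags) > 0L
  min_cov_tag <- as.integer(
    vapply(split(coverage, tag_of_cell), min, numeric(1), USE.NAMES = FALSE))
  frac_called <- ifelse(coverage >= min_cov, frac, NA_real_)
  min_frac_tag <- suppressWarnings(
    vapply(split(frac_called, tag_of_cell), min, numeric(1),
           na.rm = TRUE, USE.NAMES = FALSE))
  min_frac_tag[!is.finite(min_frac_tag)] <- NA_real_

  status <- rep("ok", n_tags)
  status[(any_lowcov & !assume_wt) | any_zero] <- "low_coverage"
  status[any_conflict] <- "conflicted"
  status[n_placed_tag == 0L] <- "conflicted"
  min_cov_tag[n_placed_tag == 0L] <- 0L

  sub_cell <- which(called & winner != refb_code & mask_cell)
  subs <- rep("", n_tags)
  if (length(sub_cell) > 0L) {
    sp <- pos_of_cell[sub_cell]
    st <- tag_of_cell[sub_cell]
    tok <- sprintf("%d:%s>%s", sp, refb[sp], DNA_BASES[winner[sub_cell]])
    o <- order(st, sp)
    agg <- vapply(split(tok[o], factor(st[o], levels = seq_len(n_tags))),
                  paste, character(1), collapse = ",")
    subs <- unname(agg)
  }
  new_haplotype_table(tibble(
    tag = tags, status = status, n_reads = n_reads_tag,
    n_placed = n_placed_tag, substitutions = subs,
    min_coverage = min_cov_tag, min_majority = min_frac_tag))
}
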