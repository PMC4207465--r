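# Readers and writers for the standard formats the workflow touches:
# FASTA, FASTQ (Phred+33), JASPAR/TRANSFAC matrices, TSV tables, BED.

#' Read and write FASTA files
#'
#' `read_fasta()` returns one row per record with the sequence uppercased;
#' sequences are restricted to the A/C/G/T/N alphabet. `write_fasta()` is its
#' inverse; the pair round-trips exactly.
#'
#' @param path File path.
#' @return `read_fasta()`: a tibble with columns `name`, `sequence`.
#' @export
#' @examples
#' fp <- tempfile(fileext = ".fa")
#' write_fasta(tibble::tibble(name = "e", sequence = "ACGT"), fp)
#' read_fasta(fp)
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  recs <- tryCatch(
    Biostrings::readBStringSet(path, format = "fasta"),
    error = function(e) abort(sprintf("malformed FASTA '%s': %s", path,
                                      conditionMessage(e)))
  )
  if (length(recs) == 0L) abort(sprintf("empty FASTA file: %s", path))
  nm <- sub("\\s.*$", "", names(recs))
  if (anyDuplicated(nm)) {
    abort(sprintf("duplicate record name '%s' in %s", nm[duplicated(nm)][1], path))
  }
  seqs <- toupper(as.character(recs))
  check_alphabet(seqs, nm, allow_n = TRUE)
  tibble(name = unname(nm), sequence = unname(seqs))
}

#' @param records Data frame with columns `name`, `sequence`.
#' @rdname read_fasta
#' @export
write_fasta <- function(records, path) {
  stopifnot(all(c("name", "sequence") %in% names(records)))
  x <- Biostrings::BStringSet(setNames(records$sequence, records$name))
  Biostrings::writeXStringSet(x, path, format = "fasta")
  invisible(path)
}

#' Read and write FASTQ files
#'
#' Four-line FASTQ records with Phred+33 qualities. `read_fastq()` validates
#' that sequence and quality lengths agree per record.
#'
#' @param path File path.
#' @return `read_fastq()`: a tibble with columns `name`, `sequence`,
#'   `quality`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) abort(sprintf("empty FASTQ file: %s", path))
  if (length(lines) %% 4L != 0L) {
    abort(sprintf("truncated FASTQ record %d in %s",
                  length(lines) %/% 4L + 1L, path))
  }
  hdr <- lines[seq(1L, length(lines), by = 4L)]
  seqs <- toupper(lines[seq(2L, length(lines), by = 4L)])
  plus <- lines[seq(3L, length(lines), by = 4L)]
  qual <- lines[seq(4L, length(lines), by = 4L)]
  bad <- which(!startsWith(hdr, "@") | !startsWith(plus, "+"))
  if (length(bad) > 0L) {
    abort(sprintf("malformed FASTQ record %d in %s", bad[1], path))
  }
  bad <- which(nchar(seqs) != nchar(qual))
  if (length(bad) > 0L) {
    abort(sprintf("FASTQ record %d: sequence and quality lengths differ", bad[1]))
  }
  tibble(name = sub("\\s.*$", "", substring(hdr, 2L)),
         sequence = seqs, quality = qual)
}

#' @param records Data frame with columns `name`, `sequence`, `quality`.
#' @rdname read_fastq
#' @export
write_fastq <- function(records, path) {
  stopifnot(all(c("name", "sequence", "quality") %in% names(records)))
  if (any(nchar(records$sequence) != nchar(records$quality))) {
    abort("sequence and quality lengths differ")
  }
  x <- Biostrings::BStringSet(setNames(records$sequence, records$name))
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(records$quality))
  invisible(path)
}

#' Write a subassembly read pair as two FASTQ files
#'
#' Writes the genomic fragment reads (read 1) and the 20-bp tag index reads
#' to a matched pair of FASTQ files, in the same record order.
#'
#' @param reads Tibble from [simulate_subassembly_reads()], with columns
#'   `read_id`, `sequence`, `quality`, `tag`.
#' @param genomic_path,tag_path Output FASTQ paths.
#' @export
write_fastq_pair <- function(reads, genomic_path, tag_path) {
  write_fastq(tibble(name = reads$read_id, sequence = reads$sequence,
                     quality = reads$quality), genomic_path)
  tagq <- strrep(rawToChar(as.raw(37 + 33)), nchar(reads$tag))
  write_fastq(tibble(name = reads$read_id, sequence = reads$tag,
                     quality = tagq), tag_path)
  invisible(c(genomic_path, tag_path))
}

#' Read a PSSM collection in JASPAR or TRANSFAC text format
#'
#' Count matrices are converted per column to probabilities with a
#' pseudocount: `(count + pseudocount) / (total + 4 * pseudocount)`, so no
#' cell is exactly zero. The relative entropy of each matrix against the
#' background is precomputed.
#'
#' JASPAR dialect: `>` header lines followed by four base rows
#' (`A [ 4 19 0 ]` or unbracketed). TRANSFAC dialect: blocks with `ID`/`NA`
#' names, a `P0 A C G T` header, numbered matrix rows, terminated by
#' `XX`/`//`.
#'
#' @param path File path.
#' @param dialect `"jaspar"` or `"transfac"`.
#' @param background Length-4 background probability vector (A, C, G, T).
#' @param pseudocount Pseudocount added to every cell (default 0.25).
#' @return A named list of [pssm] objects.
#' @export
read_pssm_collection <- function(path, dialect = c("jaspar", "transfac"),
                                 background = rep(0.25, 4),
                                 pseudocount = 0.25) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  mats <- switch(dialect,
                 jaspar = parse_jaspar(lines),
                 transfac = parse_transfac(lines))
  if (length(mats) == 0L) abort(sprintf("no matrices found in %s", path))
  out <- lapply(names(mats), function(nm) {
    pssm(nm, mats[[nm]], background = background, pseudocount = pseudocount)
  })
  setNames(out, names(mats))
}

extract_numbers <- function(line) {
  m <- regmatches(line, gregexpr("[-+]?[0-9]*\\.?[0-9]+([eE][-+]?[0-9]+)?", line))[[1]]
  as.numeric(m)
}

parse_jaspar <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) abort("JASPAR input has no '>' header lines")
  mats <- list()
  for (i in seq_along(hdr)) {
    from <- hdr[i] + 1L
    to <- if (i < length(hdr)) hdr[i + 1L] - 1L else length(lines)
    body <- lines[from:to]
    if (length(body) != 4L) {
      abort(sprintf("JASPAR block '%s': expected 4 base rows, got %d",
                    lines[hdr[i]], length(body)))
    }
    rows <- lapply(body, extract_numbers)
    lens <- lengths(rows)
    if (length(unique(lens)) != 1L) {
      abort(sprintf("JASPAR block '%s': ragged matrix rows", lines[hdr[i]]))
    }
    lab <- toupper(substr(trimws(body), 1L, 1L))
    m <- do.call(rbind, rows)
    if (all(lab %in% DNA_BASES) && !anyDuplicated(lab)) {
      m <- m[match(DNA_BASES, lab), , drop = FALSE]
    }
    rownames(m) <- DNA_BASES
    nm <- trimws(sub("^>\\s*", "", lines[hdr[i]]))
    nm <- sub("\\s+", " ", nm)
    mats[[nm]] <- m
  }
  mats
}

parse_transfac <- function(lines) {
  mats <- list()
  cur_name <- NULL
  cur_rows <- list()
  flush <- function() {
    if (length(cur_rows) == 0L) return(NULL)
    lens <- lengths(cur_rows)
    if (any(lens != 4L)) abort("TRANSFAC block: matrix rows must have 4 values")
    m <- t(do.call(rbind, cur_rows))
    rownames(m) <- DNA_BASES
    nm <- cur_name %||% sprintf("matrix_%d", length(mats) + 1L)
    mats[[nm]] <<- m
  }
  for (line in lines) {
    line <- trimws(line)
    if (grepl("^(ID|NA)\\s+", line)) {
      if (is.null(cur_name)) cur_name <- sub("^(ID|NA)\\s+", "", line)
    } else if (grepl("^AC\\s+", line) && is.null(cur_name)) {
      cur_name <- sub("^AC\\s+", "", line)
    } else if (grepl("^[0-9]{2,}\\s", line)) {
      vals <- extract_numbers(line)
      # first number is the row index; the next four are A C G T counts
      cur_rows[[length(cur_rows) + 1L]] <- vals[2:5]
    } else if (grepl("^(//|XX)$", line) && length(cur_rows) > 0L) {
      flush()
      cur_name <- NULL
      cur_rows <- list()
    }
  }
  flush()
  mats
}

#' Write and read per-substitution effect tables
#'
#' Serializes effect estimates as TSV with 1-based positions. Columns:
#' `enhancer`, `position`, `ref`, `alt`, `beta0`, `beta`,
#' `effect_size_log2`, `p_value`, `n_mutant`.
#'
#' @param estimates Tibble of effect estimates (for example
#'   `tidy(profile, "trivariate")`).
#' @param path Output path.
#' @param enhancer Enhancer name written in the first column.
#' @export
write_effect_table <- function(estimates, path, enhancer = "enhancer") {
  if (nrow(estimates) == 0L) abort("no estimates to write")
  out <- tibble(
    enhancer = enhancer,
    position = estimates$position,
    ref = estimates$ref,
    alt = estimates$alt,
    beta0 = estimates$beta0,
    beta = estimates$beta,
    effect_size_log2 = estimates$effect_size,
    p_value = estimates$p_value,
    n_mutant = estimates$n_mutant
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_effect_table
#' @export
read_effect_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE) %>%
    dplyr::rename(effect_size = "effect_size_log2")
}

#' Write intervals as BED
#'
#' Positions in the package are 1-based along the tested sequence; BED
#' output is 0-based half-open, so a width-1 cluster at position 1 becomes
#' `enh 0 1`.
#'
#' @param clusters Data frame with 1-based inclusive `start`, `end` columns
#'   and optionally `label` and `sign`.
#' @param path Output path.
#' @param chrom Sequence name for the first BED column.
#' @export
write_bed <- function(clusters, path, chrom = "enhancer") {
  stopifnot(all(c("start", "end") %in% names(clusters)))
  n <- nrow(clusters)
  bed <- data.frame(
    chrom = rep(chrom, length.out = n),
    start = as.integer(clusters$start) - 1L,
    end = as.integer(clusters$end),
    name = if ("label" %in% names(clusters)) clusters$label
           else sprintf("cluster_%d", seq_len(n)),
    score = 0L,
    strand = if ("sign" %in% names(clusters))
               ifelse(clusters$sign >= 0, "+", "-") else rep(".", n)
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Read a pre-counted tag-by-aliquot table
#'
#' Accepts the TSV alternative to raw RNA-tag FASTQ input: one row per
#' (tag, replicate, aliquot) with a read count.
#'
#' @param path TSV with columns `tag`, `replicate`, `aliquot`, `count`.
#' @return A `tag_counts` tibble.
#' @export
read_tag_counts <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("tag", "replicate", "aliquot", "count")
  if (!all(need %in% names(x))) {
    abort(sprintf("tag count table must have columns: %s",
                  paste(need, collapse = ", ")))
  }
  if (any(x$count < 0) || any(x$count != round(x$count))) {
    abort("tag counts must be non-negative integers")
  }
  new_tag_counts(as_tibble(x[need]))
}

new_tag_counts <- function(x, n_reads_pass = NA_integer_,
                           n_reads_fail = NA_integer_) {
  structure(x,
            class = c("tag_counts", class(tibble())),
            n_reads_pass = n_reads_pass,
            n_reads_fail = n_reads_fail)
}
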