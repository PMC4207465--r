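# Internal helpers: base encoding, reverse complement, seeded evaluation.

DNA_BASES <- c("A", "C", "G", "T")

# Map A/C/G/T -> 0..3; anything else -> NA. Built once at load.
.base_code <- local({
  v <- rep(NA_integer_, 256L)
  v[utf8ToInt("A") + 1L] <- 0L
  v[utf8ToInt("C") + 1L] <- 1L
  v[utf8ToInt("G") + 1L] <- 2L
  v[utf8ToInt("T") + 1L] <- 3L
  v
})

# Encode equal-length strings as an integer matrix (one row per string,
# values 0..3, NA for non-ACGT). Fast path for bulk sequence work.
encode_base_matrix <- function(x, width = NULL) {
  if (length(x) == 0L) {
    return(matrix(integer(0), nrow = 0L, ncol = width %||% 0L))
  }
  nc <- unique(nchar(x))
  if (length(nc) != 1L) {
    abort("encode_base_matrix() requires equal-length strings.")
  }
  if (!is.null(width) && nc != width) {
    abort(sprintf("expected strings of width %d, got %d", width, nc))
  }
  ints <- utf8ToInt(paste(x, collapse = ""))
  matrix(.base_code[ints + 1L], nrow = length(x), ncol = nc, byrow = TRUE)
}

decode_base_matrix <- function(m) {
  if (nrow(m) == 0L) return(character(0))
  ints <- c(65L, 67L, 71L, 84L)[m + 1L]
  dim(ints) <- dim(m)
  vapply(seq_len(nrow(ints)), function(i) intToUtf8(ints[i, ]), character(1))
}

split_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG
# state; with seed = NULL the current RNG stream is used.
with_seed_or_current <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(as.integer(seed), expr)
}

# Mean Phred score (offset 33) over the first `k` characters of each quality
# string. Deduplicates before decoding so constant-quality bulk input is cheap.
phred_prefix_mean <- function(quality, k) {
  pre <- substr(quality, 1L, k)
  uq <- unique(pre)
  means <- vapply(uq, function(s) mean(utf8ToInt(s)) - 33, numeric(1),
                  USE.NAMES = FALSE)
  means[match(pre, uq)]
}

check_alphabet <- function(sequence, name, allow_n = TRUE) {
  pattern <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  bad <- !grepl(pattern, sequence)
  if (any(bad)) {
    abort(sprintf(
      "record '%s' contains characters outside {A,C,G,T%s}",
      name[bad][1], if (allow_n) ",N" else ""
    ))
  }
  invisible(TRUE)
}

# Sum x within integer groups idx (1..n), returning a dense length-n vector
# (groups with no members sum to 0).
sum_by_index <- function(x, idx, n) {
  out <- numeric(n)
  if (length(x) > 0L) {
    t <- rowsum(as.numeric(x), idx)
    out[as.integer(rownames(t))] <- t[, 1L]
  }
  out
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

random_tags <- function(n, tag_length = 20L) {
  m <- matrix(sample(DNA_BASES, n * tag_length, replace = TRUE),
              nrow = n, ncol = tag_length)
  tags <- do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
  # re-draw collisions so tags identify haplotypes uniquely
  while (anyDuplicated(tags)) {
    dup <- which(duplicated(tags))
    m2 <- matrix(sample(DNA_BASES, length(dup) * tag_length, replace = TRUE),
                 nrow = length(dup))
    tags[dup] <- do.call(paste0, as.data.frame(m2, stringsAsFactors = FALSE))
  }
  tags
}
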