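# Internal helpers shared across modules.

# C-locale, byte-wise sort: deterministic lexicographic tie-breaking for
# reference IDs regardless of the session locale.
lex_sort <- function(x) sort(x, method = "radix")

lex_min <- function(x) if (length(x) == 0L) NA_character_ else lex_sort(x)[1L]

#' Generate random DNA strings
#'
#' Uniform random sequences over A/C/G/T, driven by R's RNG (so reproducible
#' under `set.seed()`).
#'
#' @param n Number of strings.
#' @param width Width of each string (scalar or vector of length `n`).
#' @return Character vector of length `n`.
#' @keywords internal
#' @noRd
rand_dna <- function(n, width) {
  if (n == 0L) return(character())
  if (length(width) == 1L) {
    stri_rand_strings(n, width, pattern = "[ACGT]")
  } else {
    stopifnot(length(width) == n)
    out <- stri_rand_strings(n, max(width), pattern = "[ACGT]")
    stri_sub(out, 1L, width)
  }
}

# Apply substitution errors at a fixed per-base rate to a character vector of
# sequences. Substitutions always change the base. Uses R's RNG.
mutate_seqs <- function(seq, rate) {
  if (rate <= 0) return(seq)
  len <- stri_length(seq)
  n_err <- rbinom(length(seq), size = len, prob = rate)
  hit <- which(n_err > 0L)
  for (i in hit) {
    pos <- sample.int(len[i], n_err[i])
    for (p in pos) {
      old <- stri_sub(seq[i], p, p)
      stri_sub(seq[i], p, p) <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
    }
  }
  seq
}

# Substitute exactly n_err[i] random positions of seq[i] (always to a
# different base). Uses R's RNG.
mutate_positions <- function(seq, n_err) {
  len <- stri_length(seq)
  for (i in seq_along(seq)) {
    if (n_err[i] == 0L) next
    pos <- sample.int(len[i], min(n_err[i], len[i]))
    for (p in pos) {
      old <- stri_sub(seq[i], p, p)
      stri_sub(seq[i], p, p) <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
    }
  }
  seq
}

# Hamming distance between each element of `x` and a single string `b`.
# Strings of differing length get distance Inf. NA in x -> Inf.
hamming_to <- function(x, b) {
  nb <- stri_length(b)
  d <- rep(Inf, length(x))
  ok <- !is.na(x) & stri_length(x) == nb
  if (any(ok)) {
    dd <- integer(sum(ok))
    xs <- x[ok]
    for (p in seq_len(nb)) {
      dd <- dd + (stri_sub(xs, p, p) != stri_sub(b, p, p))
    }
    d[ok] <- dd
  }
  d
}

# All k-mers (substrings of width k) of one sequence; character(0) if shorter.
kmers_of <- function(seq, k) {
  n <- stri_length(seq)
  if (is.na(n) || n < k) return(character())
  starts <- seq_len(n - k + 1L)
  stri_sub(seq, starts, starts + k - 1L)
}

# Tab-separated writer used for all tables (plain text, no quoting).
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  as_tibble(read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                       check.names = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
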