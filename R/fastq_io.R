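#' Read a FASTQ file into a tibble of reads
#'
#' Reads plain or gzip-compressed 4-line FASTQ. Sequences are uppercased;
#' qualities are kept as the raw ASCII string (decode with [decode_quals()]).
#' A sequencer-assigned sample index is parsed from CASAVA-style headers
#' (`@id 1:N:0:ACGTAC`, the field after the last `:`), or taken from a
#' parallel index FASTQ whose records pair with the main file by position.
#'
#' @param path Path to a FASTQ file (`.gz` handled transparently).
#' @param phred_offset ASCII offset of the quality encoding, 33 (modern
#'   Illumina, default) or 64.
#' @param index_path Optional path to a separate index-read FASTQ; its
#'   sequences become `seq_index`, overriding any header-derived index.
#' @return A tibble with columns `read_id` (full header minus `@`), `seq`,
#'   `qual` (ASCII quality string) and `seq_index` (`NA` when absent), with
#'   attribute `phred_offset`.
#' @examples
#' fq <- tempfile(fileext = ".fastq")
#' writeLines(c("@r1", "acgt", "+", "IIII"), fq)
#' reads <- read_fastq(fq)
#' decode_quals(reads$qual)[[1]]  # 40 40 40 40
#' @export
read_fastq <- function(path, phred_offset = 33, index_path = NULL) {
  stopifnot(phred_offset %in% c(33, 64))
  lines <- read_text_lines(path)
  if (length(lines) %% 4L != 0L) {
    stop("malformed FASTQ '", path, "': number of lines (", length(lines),
         ") is not a multiple of 4")
  }
  n <- length(lines) %/% 4L
  if (n == 0L) {
    out <- tibble(read_id = character(), seq = character(),
                  qual = character(), seq_index = character())
    attr(out, "phred_offset") <- phred_offset
    return(out)
  }
  hdr <- lines[seq(1L, by = 4L, length.out = n)]
  seq <- stri_trans_toupper(lines[seq(2L, by = 4L, length.out = n)])
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  qual <- lines[seq(4L, by = 4L, length.out = n)]
  bad_hdr <- which(!startsWith(hdr, "@"))
  if (length(bad_hdr)) {
    stop("malformed FASTQ '", path, "': record ", bad_hdr[1L],
         " does not start with '@'")
  }
  bad_plus <- which(!startsWith(plus, "+"))
  if (length(bad_plus)) {
    stop("malformed FASTQ '", path, "': record ", bad_plus[1L],
         " lacks the '+' separator line")
  }
  bad_len <- which(stri_length(seq) != stri_length(qual))
  if (length(bad_len)) {
    stop("malformed FASTQ '", path, "': record ", bad_len[1L],
         " has sequence and quality strings of different length")
  }
  read_id <- stri_sub(hdr, 2L)
  seq_index <- parse_header_index(read_id)
  if (!is.null(index_path)) {
    idx <- read_fastq(index_path, phred_offset = phred_offset)
    if (nrow(idx) != n) {
      stop("index FASTQ '", index_path, "' has ", nrow(idx),
           " records but main FASTQ has ", n)
    }
    seq_index <- idx$seq
  }
  out <- tibble(read_id = read_id, seq = seq, qual = qual,
                seq_index = seq_index)
  attr(out, "phred_offset") <- phred_offset
  out
}

# Read all lines of a possibly gzip-compressed text file. gzfile() sniffs the
# magic bytes, so plain files pass through unchanged.
read_text_lines <- function(path) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  con <- gzfile(path, open = "rt")
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

# CASAVA-style headers carry the sample index after the last ':' of the
# description, e.g. "r1 1:N:0:ACGTAC". Only plausible index strings (ACGTN,
# length >= 4) are accepted; anything else yields NA.
parse_header_index <- function(read_id) {
  parts <- stri_split_fixed(read_id, " ", n = 2L, simplify = TRUE)
  desc <- parts[, 2L]
  tail_tok <- vapply(stri_split_fixed(desc, ":"), function(x) x[length(x)],
                     character(1))
  tail_tok <- stri_trans_toupper(tail_tok)
  ok <- !is.na(tail_tok) & stri_detect_regex(tail_tok, "^[ACGTN]{4,}$")
  ifelse(ok, tail_tok, NA_character_)
}

#' Write reads to a FASTQ file
#'
#' Inverse of [read_fastq()]. When `embed_index = TRUE`, a non-`NA`
#' `seq_index` is written into the header as a CASAVA-style description
#' (`1:N:0:<index>`) so that [read_fastq()] recovers it.
#'
#' @param reads Tibble with columns `read_id`, `seq`, `qual`, and optionally
#'   `seq_index`.
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @param embed_index Write `seq_index` into the header? Default `TRUE`.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, embed_index = TRUE) {
  stopifnot(all(c("read_id", "seq", "qual") %in% names(reads)))
  hdr <- reads$read_id
  if (embed_index && "seq_index" %in% names(reads)) {
    has_idx <- !is.na(reads$seq_index) &
      !stri_detect_fixed(hdr, " ")  # don't double-annotate
    hdr[has_idx] <- paste0(hdr[has_idx], " 1:N:0:", reads$seq_index[has_idx])
  }
  lines <- as.vector(rbind(paste0("@", hdr), reads$seq, "+", reads$qual))
  con <- if (endsWith(path, ".gz")) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Decode ASCII quality strings to PHRED integer vectors
#'
#' @param qual Character vector of ASCII quality strings.
#' @param phred_offset Encoding offset (33 or 64).
#' @return List of integer vectors, one per input string.
#' @export
decode_quals <- function(qual, phred_offset = 33) {
  lapply(stri_enc_toutf32(qual), function(v) as.integer(v - phred_offset))
}
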