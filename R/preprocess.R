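#' Sample configuration
#'
#' Describes one sequencing library: its 3' adapter, library protocol,
#' species code, optional UMI prefix, expected sample index, and quality
#' encoding. The adapter-search primitive is the adapter's first 8-mer, so
#' adapter-based protocols require an adapter of at least 8 nt.
#'
#' @param sample_id Sample identifier.
#' @param adapter 3' adapter sequence (e.g. the Illumina TruSeq small-RNA
#'   adapter `TGGAATTCTCGGGTGCCAAGG`). Required (>= 8 nt) for the
#'   `truseq_qiaseq` and `nextflex` protocols; ignored by `cats`, which trims
#'   a poly-A tail instead.
#' @param protocol Library protocol: `"truseq_qiaseq"` (default),
#'   `"nextflex"` (4 random nt flanking the insert on both sides), or
#'   `"cats"` (3 leading nt, poly-A tail).
#' @param species Species code (miRBase-style three-letter prefix); used for
#'   bookkeeping and QC flag denominators.
#' @param umi_prefix_len Number of leading UMI bases to strip before any
#'   other processing (default 0; single-cell protocols often use 10).
#' @param index Expected sample index for demultiplexing (optional).
#' @param expected_clade Clade this sample is expected to trace to
#'   (optional; enables the contamination report).
#' @param phred_offset Quality encoding offset, 33 (default) or 64.
#' @return An object of class `sample_config`.
#' @export
sample_config <- function(sample_id, adapter = NULL,
                          protocol = c("truseq_qiaseq", "nextflex", "cats"),
                          species = NA_character_, umi_prefix_len = 0L,
                          index = NULL, expected_clade = NULL,
                          phred_offset = 33) {
  protocol <- match.arg(protocol)
  if (protocol %in% c("truseq_qiaseq", "nextflex")) {
    if (is.null(adapter) || !nzchar(adapter)) {
      stop("protocol '", protocol, "' requires a 3' adapter sequence")
    }
    if (stri_length(adapter) < 8L) {
      stop("adapter must be at least 8 nt (the first 8-mer is the search key)")
    }
  }
  stopifnot(umi_prefix_len >= 0L, phred_offset %in% c(33, 64))
  structure(
    list(sample_id = sample_id,
         adapter = if (is.null(adapter)) NA_character_ else
           stri_trans_toupper(adapter),
         protocol = protocol, species = species,
         umi_prefix_len = as.integer(umi_prefix_len),
         index = if (is.null(index)) NA_character_ else
           stri_trans_toupper(index),
         expected_clade = if (is.null(expected_clade)) NA_character_ else
           expected_clade,
         phred_offset = phred_offset),
    class = "sample_config"
  )
}

#' Truncate reads to a maximum length
#'
#' Sequencing beyond the first `max_len` nucleotides is discarded; shorter
#' reads pass unchanged. Applied before any other filter so that all
#' downstream lengths are bounded.
#'
#' @param seq Character vector of read sequences.
#' @param qual Optional parallel vector of quality strings.
#' @param max_len Length cap (default 50).
#' @return If `qual` is `NULL`, the truncated sequences; otherwise a list
#'   with elements `seq` and `qual`.
#' @export
truncate_read <- function(seq, qual = NULL, max_len = 50L) {
  s <- stri_sub(seq, 1L, max_len)
  if (is.null(qual)) return(s)
  list(seq = s, qual = stri_sub(qual, 1L, max_len))
}

#' Per-read quality filter
#'
#' A read fails when *more than* `max_frac` of its bases have a PHRED score
#' below `min_q`; exactly half low-quality bases still passes. Zero-length
#' reads fail.
#'
#' @param qual Character vector of ASCII quality strings.
#' @param phred_offset Encoding offset (33 or 64).
#' @param min_q Minimum acceptable PHRED score (default 20).
#' @param max_frac Maximum tolerated fraction of bases below `min_q`
#'   (default 0.5, strict inequality).
#' @return Logical vector, `TRUE` for reads that pass.
#' @export
passes_quality <- function(qual, phred_offset = 33, min_q = 20,
                           max_frac = 0.5) {
  n <- stri_length(qual)
  cls <- sprintf("[\\u%04X-\\u%04X]", phred_offset,
                 phred_offset + min_q - 1L)
  low <- stri_count_charclass(qual, cls)
  n > 0L & (low / pmax(n, 1L)) <= max_frac
}

#' Trim the 3' adapter, TruSeq/QiaSeq style
#'
#' The read is searched for the first 8-mer of the adapter. If present, the
#' *last* occurrence and everything after it are removed and the adapter is
#' counted as found. Otherwise the longest read suffix equal to a prefix of
#' the adapter (length 7 down to 1) is removed; such reads are counted as
#' adapter-unrecognized because the full 8-mer was never seen.
#'
#' @param seq Character vector of read sequences.
#' @param adapter Adapter sequence (>= 8 nt).
#' @return A list with elements `insert` (character) and `adapter_found`
#'   (logical).
#' @export
trim_adapter_truseq <- function(seq, adapter) {
  if (is.na(adapter) || stri_length(adapter) < 8L) {
    stop("adapter must be at least 8 nt")
  }
  k8 <- stri_sub(adapter, 1L, 8L)
  pos <- stri_locate_last_fixed(seq, k8)[, 1L]
  found <- !is.na(pos)
  insert <- seq
  if (any(found)) {
    insert[found] <- stri_sub(seq[found], 1L, pos[found] - 1L)
  }
  nf <- which(!found)
  if (length(nf)) {
    rem <- seq[nf]
    cut <- integer(length(nf))
    for (k in 7:1) {
      cand <- which(cut == 0L & stri_length(rem) >= k)
      if (length(cand)) {
        hit <- stri_sub(rem[cand], -k) == stri_sub(adapter, 1L, k)
        cut[cand[hit]] <- k
      }
    }
    insert[nf] <- stri_sub(rem, 1L, stri_length(rem) - cut)
  }
  list(insert = insert, adapter_found = found)
}

#' Trim adapters, NEXTflex style
#'
#' NEXTflex libraries carry 4 randomized bases on each side of the insert.
#' The 4 leading bases are removed, the adapter is trimmed as in
#' [trim_adapter_truseq()], and when the adapter was found the last 4 bases
#' of the remaining insert are removed as well.
#'
#' @inheritParams trim_adapter_truseq
#' @return A list with elements `insert` and `adapter_found`.
#' @export
trim_adapter_nextflex <- function(seq, adapter) {
  core <- stri_sub(seq, 5L)
  r <- trim_adapter_truseq(core, adapter)
  ins <- r$insert
  f <- r$adapter_found
  if (any(f)) {
    ins[f] <- stri_sub(ins[f], 1L, pmax(stri_length(ins[f]) - 4L, 0L))
  }
  list(insert = ins, adapter_found = f)
}

#' Trim adapters, CATS style
#'
#' CATS libraries start with 3 template-switch bases and end in a poly-A
#' tail. The 3 leading bases are removed; if a poly-A 8-mer occurs, the read
#' is cut at its left-most occurrence (adapter found). Otherwise shorter
#' trailing poly-A runs (7 down to a single A) are trimmed from the 3' end.
#'
#' @param seq Character vector of read sequences.
#' @return A list with elements `insert` and `adapter_found`.
#' @export
trim_adapter_cats <- function(seq) {
  core <- stri_sub(seq, 4L)
  pos <- stri_locate_first_fixed(core, "AAAAAAAA")[, 1L]
  found <- !is.na(pos)
  insert <- core
  if (any(found)) {
    insert[found] <- stri_sub(core[found], 1L, pos[found] - 1L)
  }
  if (any(!found)) {
    # a trailing run of >= 8 A's would contain the 8-mer, so this strips <= 7
    insert[!found] <- stri_replace_first_regex(core[!found], "A+$", "")
  }
  list(insert = insert, adapter_found = found)
}

#' Tandem-repeat low-complexity test
#'
#' An insert is low-complexity when it is a tandem repetition (allowing a
#' truncated final unit) of a single motif of length 1, 2, or 3, with the
#' motif repeated at least twice. Highly repeated nucleotides carry no
#' taxonomic signal and are removed during pre-processing.
#'
#' @param insert Character vector of insert sequences.
#' @param max_motif Largest motif length considered (default 3).
#' @return Logical vector.
#' @export
is_low_complexity <- function(insert, max_motif = 3L) {
  n <- stri_length(insert)
  res <- rep(FALSE, length(insert))
  for (m in seq_len(max_motif)) {
    cand <- which(!res & n >= 2L * m)
    if (!length(cand)) next
    motif <- stri_sub(insert[cand], 1L, m)
    rep_full <- strrep(motif, ceiling(n[cand] / m))
    res[cand] <- stri_sub(rep_full, 1L, n[cand]) == insert[cand]
  }
  res
}

#' Pre-process raw reads into QC-passed inserts
#'
#' Applies, in order: UMI prefix trimming, truncation to 50 nt, the PHRED
#' quality filter (discard reason `low_quality`), protocol-specific adapter
#' trimming, then the insert filters: any non-ACGT symbol (`ambiguous_nt`),
#' tandem-repeat low complexity (`low_complexity`), and length < 18 nt
#' (`too_short`). Surviving reads are "QC-passed": status
#' `qc_passed_adapter_found` when the adapter 8-mer was located, else
#' `qc_passed_adapter_unrecognized` (no adapter seen; the untrimmed insert
#' is kept, so lengths above 50 never occur and lengths of exactly the read
#' cap hint at unrecognized adapters).
#'
#' @param reads Tibble from [read_fastq()] (columns `read_id`, `seq`,
#'   `qual`).
#' @param cfg A [sample_config()].
#' @param max_len Read truncation cap (default 50).
#' @param min_insert Minimum QC-passed insert length (default 18).
#' @return A tibble with one row per input read, in order: `read_id`,
#'   `insert` (`NA` for quality-discarded reads), `insert_len`, `status`,
#'   `discard_reason` (`"none"` unless discarded), `adapter_found`,
#'   `pre_trim_len` (length entering adapter trimming, <= `max_len`).
#' @export
preprocess_reads <- function(reads, cfg, max_len = 50L, min_insert = 18L) {
  stopifnot(inherits(cfg, "sample_config"))
  n <- nrow(reads)
  seq <- reads$seq
  qual <- reads$qual
  if (cfg$umi_prefix_len > 0L) {
    seq <- stri_sub(seq, cfg$umi_prefix_len + 1L)
    qual <- stri_sub(qual, cfg$umi_prefix_len + 1L)
  }
  tr <- truncate_read(seq, qual, max_len = max_len)
  seq <- tr$seq
  qual <- tr$qual
  pre_trim_len <- stri_length(seq)

  ok_q <- passes_quality(qual, phred_offset = cfg$phred_offset)
  insert <- rep(NA_character_, n)
  adapter_found <- rep(FALSE, n)
  status <- rep("discarded", n)
  reason <- rep("low_quality", n)

  live <- which(ok_q)
  if (length(live)) {
    trm <- switch(cfg$protocol,
      truseq_qiaseq = trim_adapter_truseq(seq[live], cfg$adapter),
      nextflex = trim_adapter_nextflex(seq[live], cfg$adapter),
      cats = trim_adapter_cats(seq[live])
    )
    ins <- trm$insert
    fnd <- trm$adapter_found
    insert[live] <- ins
    adapter_found[live] <- fnd

    amb <- stri_detect_regex(ins, "[^ACGT]")
    lowc <- !amb & is_low_complexity(ins)
    short <- !amb & !lowc & stri_length(ins) < min_insert
    pass <- !amb & !lowc & !short

    reason[live[amb]] <- "ambiguous_nt"
    reason[live[lowc]] <- "low_complexity"
    reason[live[short]] <- "too_short"
    reason[live[pass]] <- "none"
    status[live[pass]] <- ifelse(fnd[pass], "qc_passed_adapter_found",
                                 "qc_passed_adapter_unrecognized")
  }

  tibble(
    read_id = reads$read_id,
    insert = insert,
    insert_len = ifelse(is.na(insert), NA_integer_, stri_length(insert)),
    status = status,
    discard_reason = reason,
    adapter_found = adapter_found,
    pre_trim_len = pre_trim_len
  )
}
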