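#' Extract the inline (second-read) sample index
#'
#' When a short insert is sequenced, the main read extends through the 3'
#' adapter into the adjacent sample index, so the index is read a second
#' time. With a 75-nt read, a ~22-nt miRNA plus a 33-nt adapter leaves the
#' 6-nt index fully readable. The adapter is located by the last occurrence
#' of its first 8-mer, and the *entire* adapter must follow at that position
#' before the next `index_len` bases are trusted as the inline index (this
#' avoids reading insert bases as index). If the adapter or the full index
#' is not contained in the read, the inline index is unreadable (`NA`).
#'
#' @param seq Character vector of raw (untruncated) read sequences.
#' @param adapter Full 3' adapter sequence (>= 8 nt).
#' @param index_len Index length in bases (>= 1).
#' @return Character vector of inline indices, `NA` where unreadable.
#' @export
extract_inline_index <- function(seq, adapter, index_len) {
  if (index_len < 1L) stop("index_len must be >= 1")
  if (is.na(adapter) || stri_length(adapter) < 8L) {
    stop("adapter must be at least 8 nt")
  }
  k8 <- stri_sub(adapter, 1L, 8L)
  alen <- stri_length(adapter)
  pos <- stri_locate_last_fixed(seq, k8)[, 1L]
  out <- rep(NA_character_, length(seq))
  cand <- which(!is.na(pos))
  if (length(cand)) {
    full <- stri_sub(seq[cand], pos[cand], pos[cand] + alen - 1L) == adapter
    cand <- cand[full]
    if (length(cand)) {
      start <- pos[cand] + alen
      idx <- stri_sub(seq[cand], start, start + index_len - 1L)
      ok <- stri_length(idx) == index_len
      out[cand[ok]] <- idx[ok]
    }
  }
  out
}

# Normalize `samples` (list of sample_config or a tibble/data.frame with
# columns sample_id, index, adapter) into a sample sheet tibble.
as_sample_sheet <- function(samples) {
  if (is.data.frame(samples)) {
    stopifnot(all(c("sample_id", "index") %in% names(samples)))
    sheet <- as_tibble(samples)
    if (!"adapter" %in% names(sheet)) sheet$adapter <- NA_character_
  } else {
    stopifnot(is.list(samples), length(samples) > 0L)
    sheet <- tibble(
      sample_id = vapply(samples, function(s) s$sample_id, character(1)),
      index = vapply(samples, function(s) s$index, character(1)),
      adapter = vapply(samples, function(s) s$adapter, character(1))
    )
  }
  if (anyNA(sheet$index)) stop("every sample needs an index for demultiplexing")
  if (anyDuplicated(sheet$index)) stop("sample indices must be distinct")
  sheet
}

#' Demultiplex reads by sample index
#'
#' Three regimes of increasing stringency:
#' * `mismatch1` — assign when exactly one sample index is within Hamming
#'   distance 1 of the sequencer-reported index (the common demultiplexer
#'   default; requires sample indices to be pairwise >= 3 apart, which is
#'   checked with a warning).
#' * `strict` — require a perfect index match.
#' * `strict_consistent` — as `strict`, and additionally read the inline
#'   index from the read itself ([extract_inline_index()]); when it is
#'   readable and differs from the sequencer index the read is a mis-pairing
#'   event and is rejected (`rejected_inconsistent`). An unreadable inline
#'   index gives `assigned_unverifiable`.
#'
#' In modes that never compute the inline index, assigned reads get verdict
#' `assigned_unverifiable` (assignment made, consistency not verified).
#' Reads with no sequencer index, or whose index matches no sample under the
#' mode's rule, are `rejected_index_mismatch`.
#'
#' @param reads Tibble from [read_fastq()] with a `seq_index` column.
#' @param samples Sample sheet: list of [sample_config()]s (with `index`
#'   set) or a data frame with columns `sample_id`, `index`, `adapter`.
#' @param mode `"mismatch1"`, `"strict"`, or `"strict_consistent"`.
#' @param index_len Index length; defaults to the (uniform) length of the
#'   sample indices.
#' @return A tibble with one row per read: `read_id`, `assigned_sample`
#'   (`NA` unless the verdict is an assignment), `candidate_sample` (the
#'   strict-matching sample, also set for `rejected_inconsistent`),
#'   `inline_index`, `verdict`.
#' @export
demultiplex <- function(reads, samples,
                        mode = c("mismatch1", "strict", "strict_consistent"),
                        index_len = NULL) {
  mode <- match.arg(mode)
  sheet <- as_sample_sheet(samples)
  ilen <- unique(stri_length(sheet$index))
  if (length(ilen) != 1L) stop("sample indices must share one length")
  index_len <- as.integer(index_len %||% ilen)

  if (mode == "mismatch1") {
    dmat <- outer(seq_len(nrow(sheet)), seq_len(nrow(sheet)),
                  Vectorize(function(i, j)
                    sum(hamming_to(sheet$index[i], sheet$index[j]))))
    if (any(dmat[upper.tri(dmat)] < 3)) {
      warning("some sample indices are within Hamming distance 2 of each ",
              "other; one-mismatch demultiplexing may assign ambiguously")
    }
  }

  n <- nrow(reads)
  idx <- reads$seq_index
  dist <- vapply(sheet$index, function(b) hamming_to(idx, b), numeric(n))
  dist <- matrix(dist, nrow = n)

  tol <- if (mode == "mismatch1") 1 else 0
  within <- dist <= tol
  nhit <- rowSums(within)
  sample_i <- ifelse(nhit == 1L, max.col(within, ties.method = "first"),
                     NA_integer_)
  assigned <- !is.na(sample_i)

  candidate <- rep(NA_character_, n)
  candidate[assigned] <- sheet$sample_id[sample_i[assigned]]
  verdict <- ifelse(assigned, "assigned_unverifiable",
                    "rejected_index_mismatch")
  inline <- rep(NA_character_, n)

  if (mode == "strict_consistent" && any(assigned)) {
    for (si in unique(sample_i[assigned])) {
      rows <- which(!is.na(sample_i) & sample_i == si)
      inline[rows] <- extract_inline_index(reads$seq[rows],
                                           sheet$adapter[si], index_len)
    }
    readable <- assigned & !is.na(inline)
    # N in the inline index counts as a mismatch, never as a confirmation
    consistent <- readable & inline == idx &
      !stri_detect_fixed(inline, "N")
    verdict[readable & !consistent] <- "rejected_inconsistent"
    verdict[consistent] <- "assigned_consistent"
  }

  assigned_sample <- ifelse(startsWith(verdict, "assigned"), candidate,
                            NA_character_)
  tibble(read_id = reads$read_id,
         assigned_sample = assigned_sample,
         candidate_sample = candidate,
         inline_index = inline,
         verdict = verdict)
}

#' Clean a multiplexed run and write per-sample FASTQ files
#'
#' Demultiplexes a multiplexed FASTQ (index in the header or in a parallel
#' index file) under the chosen regime and writes one output FASTQ per
#' sample containing the retained raw reads, untouched. Reads with verdict
#' `assigned_consistent` are always kept; `assigned_unverifiable` reads
#' (inline index unreadable) are kept by default — rejecting them would
#' discard genuine long-insert reads — unless `drop_unverifiable = TRUE`.
#'
#' @param input Path to the multiplexed FASTQ, or a reads tibble from
#'   [read_fastq()].
#' @param samples Sample sheet (see [demultiplex()]).
#' @param mode Demultiplexing regime (default `"strict_consistent"`).
#' @param out_dir Output directory for per-sample FASTQ files (created).
#' @param drop_unverifiable Also drop reads whose inline index could not be
#'   read? Default `FALSE`.
#' @param index_path Optional parallel index FASTQ (when `input` is a path).
#' @param gzip Compress outputs (default `TRUE`).
#' @return A list with `report` (tibble: sample x verdict counts; the
#'   `(unassigned)` row collects reads rejected before any sample could be
#'   determined), `decisions` (per-read tibble from [demultiplex()]), and
#'   `files` (named vector of written paths).
#' @export
clean_run <- function(input, samples,
                      mode = c("strict_consistent", "strict", "mismatch1"),
                      out_dir, drop_unverifiable = FALSE, index_path = NULL,
                      gzip = TRUE) {
  mode <- match.arg(mode)
  reads <- if (is.character(input)) {
    read_fastq(input, index_path = index_path)
  } else {
    input
  }
  sheet <- as_sample_sheet(samples)
  dec <- demultiplex(reads, sheet, mode = mode)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory '", out_dir, "'")

  keep_verdicts <- if (drop_unverifiable) "assigned_consistent" else
    c("assigned_consistent", "assigned_unverifiable")
  files <- character(0)
  for (sid in sheet$sample_id) {
    rows <- which(dec$assigned_sample == sid & dec$verdict %in% keep_verdicts)
    path <- file.path(out_dir, paste0(sid, if (gzip) ".fastq.gz" else ".fastq"))
    write_fastq(reads[rows, , drop = FALSE], path)
    files[sid] <- path
  }

  verd_lev <- c("assigned_consistent", "assigned_unverifiable",
                "rejected_index_mismatch", "rejected_inconsistent")
  grp <- ifelse(is.na(dec$candidate_sample), "(unassigned)",
                dec$candidate_sample)
  tab <- table(factor(grp, levels = c(sheet$sample_id, "(unassigned)")),
               factor(dec$verdict, levels = verd_lev))
  report <- as_tibble(cbind(sample = rownames(tab),
                            as.data.frame.matrix(tab)))
  for (v in verd_lev) report[[v]] <- as.integer(report[[v]])

  list(report = report, decisions = dec, files = files)
}
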