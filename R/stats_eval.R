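#' Expected number of spurious marker matches
#'
#' Under a uniform-random read model, a read's leading 20-mer hits a marker
#' index of `W` distinct 20-mer keys with probability `1 - (1 - 4^-L)^W`.
#' The expected number of spurious clade assignments among `N` random reads
#' is `N` times that probability — for a catalog of ~30,000 indexed windows
#' and ten million reads, well below one, which is what makes exact 20-mer
#' matching so specific.
#'
#' @param W Number of distinct indexed 20-mer keys (e.g.
#'   `nrow(catalog$index)`).
#' @param N Number of reads.
#' @param kmer_len Marker k-mer length (default 20).
#' @return Expected spurious match count (real, `<= N`).
#' @examples
#' expected_spurious_matches(30000, 1e7)  # ~0.27
#' @export
expected_spurious_matches <- function(W, N, kmer_len = 20L) {
  stopifnot(W >= 0, N >= 0)
  # -expm1(W * log1p(-p)) keeps precision at p = 4^-20 ~ 9e-13
  N * -expm1(W * log1p(-4^-kmer_len))
}

# Exact 2-bit encoding of 20-mers into doubles (4^20 = 2^40 < 2^53).
encode_kmer20 <- function(kmers) {
  lut <- rep(NA_real_, 128L)
  lut[c(65L, 67L, 71L, 84L) + 1L] <- 0:3  # A C G T
  pows <- 4^(19:0)
  vapply(stri_enc_toutf32(kmers),
         function(v) sum(lut[v + 1L] * pows), numeric(1))
}

#' Monte-Carlo estimate of spurious marker matches
#'
#' Draws `n_reads` uniform-random 20-mers and counts how many hit the
#' catalog's index — the empirical counterpart of
#' [expected_spurious_matches()]. Random 20-mers are drawn as uniform 40-bit
#' integers under an exact 2-bit sequence encoding, which is equivalent to
#' drawing random A/C/G/T strings and fast enough for 10^7 draws.
#'
#' @param catalog A `clade_catalog`, or a character vector of 20-mer keys.
#' @param n_reads Number of random reads to draw.
#' @param seed RNG seed (applied locally).
#' @return Integer count of spurious hits.
#' @export
simulate_spurious_matches <- function(catalog, n_reads, seed = 1L) {
  kmers <- if (inherits(catalog, "clade_catalog")) catalog$index$kmer else
    catalog
  if (length(kmers) == 0L || n_reads == 0L) return(0L)
  keys <- encode_kmer20(kmers)
  withr::with_seed(seed, {
    hi <- sample.int(1048576L, n_reads, replace = TRUE) - 1L
    lo <- sample.int(1048576L, n_reads, replace = TRUE) - 1L
    draws <- hi * 1048576 + lo
    sum(!is.na(match(draws, keys)))
  })
}

#' Quality-control flags for a sample summary
#'
#' Reproduces the three report flags:
#' * `length_flag` — fewer than 25% of the (adapter-trimmed) sequences are
#'   between 20 and 25 nt long, the length band where mature miRNAs live.
#' * `mirna_content_flag` — less than 10% of QC-passed reads annotate as
#'   miRNA.
#' * `complexity_flag` — the sample reveals less than 10% of all known
#'   miRNA precursors for the studied species.
#'
#' All inequalities are strict.
#'
#' @param summary A `sample_summary` from [run_qc()] (or any list with
#'   `length_histogram`, `rna_type_counts`, `n_qc_passed`,
#'   `distinct_precursors`).
#' @param n_reference_precursors Number of known precursors for the species
#'   (the complexity denominator); taken from
#'   `summary$n_reference_precursors` when missing.
#' @return Character vector of raised flag labels (possibly empty).
#' @export
qc_flags <- function(summary, n_reference_precursors = NULL) {
  n_ref <- n_reference_precursors %||% summary$n_reference_precursors
  flags <- character(0)
  lh <- summary$length_histogram
  tot_len <- sum(lh$reads)
  if (tot_len > 0L) {
    in_band <- sum(lh$reads[lh$length >= 20L & lh$length <= 25L])
    if (in_band / tot_len < 0.25) flags <- c(flags, "length_flag")
  }
  if (summary$n_qc_passed > 0L) {
    rt <- summary$rna_type_counts
    mir <- rt$reads[rt$rna_type == "mirna"]
    if (mir / summary$n_qc_passed < 0.10) {
      flags <- c(flags, "mirna_content_flag")
    }
  }
  if (!is.null(n_ref) && n_ref > 0L) {
    if (summary$distinct_precursors / n_ref < 0.10) {
      flags <- c(flags, "complexity_flag")
    }
  }
  flags
}

#' Reads-per-million normalization
#'
#' @param counts Named numeric vector of raw counts (total must be > 0).
#' @return Named numeric vector of RPM values; sums to 10^6.
#' @export
rpm_normalize <- function(counts) {
  total <- sum(counts)
  if (total <= 0) stop("rpm_normalize: total count must be positive")
  counts / total * 1e6
}

#' Call differentially expressed miRNAs between two RPM profiles
#'
#' An ID is differentially expressed when it is present in both profiles
#' with at least 10 RPM in one of them and *more than* 2-fold change in
#' either direction, or present in exactly one profile with at least 10 RPM.
#' Presence means membership in the named vector; a fold change of exactly
#' 2 is not called.
#'
#' @param rpm_a,rpm_b Named numeric vectors of RPM values.
#' @param min_rpm Expression threshold (default 10).
#' @param min_fold Fold-change threshold, strict (default 2).
#' @return Character vector of DE IDs (sorted).
#' @export
call_de <- function(rpm_a, rpm_b, min_rpm = 10, min_fold = 2) {
  ids_a <- names(rpm_a)
  ids_b <- names(rpm_b)
  both <- intersect(ids_a, ids_b)
  only_a <- setdiff(ids_a, ids_b)
  only_b <- setdiff(ids_b, ids_a)

  de_both <- character(0)
  if (length(both)) {
    a <- rpm_a[both]
    b <- rpm_b[both]
    hi <- pmax(a, b)
    lo <- pmin(a, b)
    fold <- ifelse(lo == 0, Inf, hi / lo)
    de_both <- both[hi >= min_rpm & fold > min_fold]
  }
  de_single <- c(only_a[rpm_a[only_a] >= min_rpm],
                 only_b[rpm_b[only_b] >= min_rpm])
  lex_sort(unique(c(de_both, de_single)))
}

#' Sensitivity, specificity, and accuracy from confusion counts
#'
#' TPR = TP/(TP+FN), SPC = TN/(TN+FP), ACC = (TP+TN)/(TP+FP+FN+TN).
#' A ratio whose denominator is zero is undefined and reported as `NA`.
#'
#' @param TP,FP,TN,FN Non-negative integer counts.
#' @return Named numeric vector `c(TPR=, SPC=, ACC=)`.
#' @export
confusion_metrics <- function(TP, FP, TN, FN) {
  stopifnot(TP >= 0, FP >= 0, TN >= 0, FN >= 0)
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  c(TPR = safe(TP, TP + FN),
    SPC = safe(TN, TN + FP),
    ACC = safe(TP + TN, TP + FP + FN + TN))
}
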