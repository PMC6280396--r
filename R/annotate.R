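#' Classify inserts by RNA type
#'
#' Each QC-passed insert is assigned the type of the first reference
#' collection it aligns to, as an ungapped substring. Pass 1 tries miRNA
#' precursors, then tRNA, then rRNA with 0 mismatches; the first collection
#' with a hit wins. Pass 2 repeats the cascade with 1 mismatch for reads
#' still unassigned. Reads still unmatched are checked against the artifact
#' sequences, which match when read and artifact share at least one 18-nt
#' stretch of identity. Everything else is `unknown`.
#'
#' Ties within a collection resolve to the lexicographically smallest
#' reference ID; classification depends only on the insert and the database,
#' never on stream order.
#'
#' @param insert Character vector of insert sequences (classification is
#'   computed once per distinct insert).
#' @param db An [build_rnatype_db()] database.
#' @return A tibble with one row per input insert, columns `insert`,
#'   `rna_type` (`mirna`/`trna`/`rrna`/`artifact`/`unknown`),
#'   `matched_reference_id` (`NA` for `unknown`), `mismatches_used`
#'   (0, 1, or `NA` for artifact/unknown).
#' @export
classify_rna_type <- function(insert, db) {
  stopifnot(inherits(db, "rnatype_db"))
  u <- unique(insert)
  type <- rep("unknown", length(u))
  ref <- rep(NA_character_, length(u))
  mm_used <- rep(NA_integer_, length(u))

  type_of <- c(precursor_mirna = "mirna", trna = "trna", rrna = "rrna")
  for (mm in 0:1) {
    for (coll in names(type_of)) {
      open <- which(type == "unknown")
      if (!length(open)) break
      for (i in open) {
        hits <- match_collection(u[i], db, coll, max_mismatch = mm)
        if (length(hits)) {
          type[i] <- type_of[[coll]]
          ref[i] <- hits[1L]
          mm_used[i] <- mm
        }
      }
    }
  }

  open <- which(type == "unknown")
  if (length(open) && nrow(db$artifact_index)) {
    for (i in open) {
      wins <- kmers_of(u[i], 18L)
      m <- match(wins, db$artifact_index$kmer)
      m <- m[!is.na(m)]
      if (length(m)) {
        type[i] <- "artifact"
        ref[i] <- lex_min(db$artifact_index$ref_id[m])
      }
    }
  }

  j <- match(insert, u)
  tibble(insert = insert, rna_type = type[j],
         matched_reference_id = ref[j], mismatches_used = mm_used[j])
}

#' Cumulative miRNA complexity curve
#'
#' Tracks the cumulative number of distinct miRNA precursors identified as a
#' function of sequencing depth, where depth is counted in processed *raw*
#' reads (discarded and non-miRNA reads advance depth without adding
#' precursors). Checkpoints are taken every `checkpoint_step` raw reads and
#' at end of stream.
#'
#' @param precursor_ids Character vector, one element per raw read in input
#'   order: the matched precursor ID for miRNA-annotated reads, `NA`
#'   otherwise.
#' @param checkpoint_step Reads between checkpoints (default 10000).
#' @return A tibble with columns `depth` (strictly increasing) and
#'   `distinct_precursors` (non-decreasing); zero rows for an empty stream.
#' @export
complexity_curve <- function(precursor_ids, checkpoint_step = 10000L) {
  if (checkpoint_step < 1L) stop("checkpoint_step must be >= 1")
  n <- length(precursor_ids)
  if (n == 0L) {
    return(tibble(depth = integer(), distinct_precursors = integer()))
  }
  new <- !is.na(precursor_ids) & !duplicated(precursor_ids)
  cum <- cumsum(new)
  depth <- unique(c(seq.int(checkpoint_step, n, by = checkpoint_step), n))
  tibble(depth = as.integer(depth), distinct_precursors = cum[depth])
}

#' Tabulate RNA-type counts
#'
#' @param rna_type Character vector of per-read RNA types.
#' @return A tibble with columns `rna_type` and `reads`, covering all five
#'   categories (zero-filled).
#' @export
rna_type_counts <- function(rna_type) {
  lev <- c("mirna", "rrna", "trna", "artifact", "unknown")
  tab <- table(factor(rna_type, levels = lev))
  tibble(rna_type = lev, reads = as.integer(tab))
}
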