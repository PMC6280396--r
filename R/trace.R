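#' Assign reads to clades by exact 20-mer matching
#'
#' A read is identified as clade-specific miRNA when its first 20 nt exactly
#' match an indexed marker 20-mer. In clade mode the index covers every
#' 20-nt window of the admitted reference sequences; in species mode only
#' reference prefixes are indexed, making the comparison strictly
#' prefix-to-prefix. Matching is strand-specific. Inserts shorter than 20 nt
#' cannot form a query and stay unassigned.
#'
#' @param insert Character vector of QC-passed insert sequences.
#' @param catalog A [build_clade_catalog()] marker catalog.
#' @return Character vector of clade labels, `NA` for unassigned reads.
#' @export
assign_clade <- function(insert, catalog) {
  stopifnot(inherits(catalog, "clade_catalog"))
  k <- catalog$kmer_len
  out <- rep(NA_character_, length(insert))
  ok <- !is.na(insert) & stri_length(insert) >= k
  if (any(ok)) {
    m <- match(stri_sub(insert[ok], 1L, k), catalog$index$kmer)
    out[ok] <- catalog$index$clade[m]
  }
  out
}

#' Assign reads to species (species-mode catalog)
#'
#' Identical lookup to [assign_clade()] but requires a species-mode catalog,
#' in which only the first 20 nt of each reference are indexed, so the match
#' is first-20-nt to first-20-nt.
#'
#' @inheritParams assign_clade
#' @return Character vector of species labels, `NA` for unassigned reads.
#' @export
assign_species <- function(insert, catalog) {
  stopifnot(inherits(catalog, "clade_catalog"))
  if (catalog$mode != "species") {
    stop("assign_species() requires a catalog built in species mode")
  }
  assign_clade(insert, catalog)
}

#' Build the clade composition profile of a sample
#'
#' Counts clade-specific reads and distinct clade-specific insert sequences
#' per clade. Composition percentages use clade-specific reads as the
#' denominator (reads that match no marker do not dilute the composition).
#'
#' @param insert Character vector of QC-passed inserts.
#' @param catalog A [build_clade_catalog()] catalog.
#' @return An object of class `clade_profile`: list with `read_counts` and
#'   `unique_sequence_counts` (named integer vectors over all catalog
#'   clades), `total_clade_specific_reads`, `unassigned_reads`, and
#'   `composition` (fractions of clade-specific reads; `NaN`-free, all zero
#'   when nothing matched).
#' @export
build_clade_profile <- function(insert, catalog) {
  cl <- assign_clade(insert, catalog)
  clades <- catalog$clades
  assigned <- !is.na(cl)
  rc <- table(factor(cl[assigned], levels = clades))
  read_counts <- setNames(as.integer(rc), clades)
  uniq <- integer(length(clades))
  names(uniq) <- clades
  if (any(assigned)) {
    u <- unique(tibble(clade = cl[assigned], insert = insert[assigned]))
    ut <- table(factor(u$clade, levels = clades))
    uniq <- setNames(as.integer(ut), clades)
  }
  total <- sum(read_counts)
  comp <- if (total > 0L) read_counts / total else
    setNames(numeric(length(clades)), clades)
  structure(
    list(read_counts = read_counts,
         unique_sequence_counts = uniq,
         total_clade_specific_reads = total,
         unassigned_reads = sum(!assigned),
         composition = comp),
    class = "clade_profile"
  )
}

#' @export
print.clade_profile <- function(x, ...) {
  cat("<clade_profile> clade-specific reads:", x$total_clade_specific_reads,
      " unassigned:", x$unassigned_reads, "\n")
  nz <- x$read_counts[x$read_counts > 0L]
  if (length(nz)) {
    for (cl in names(nz)) {
      cat(sprintf("  %-18s %8d reads (%6.2f%%), %d distinct sequences\n",
                  cl, nz[[cl]], 100 * x$composition[[cl]],
                  x$unique_sequence_counts[[cl]]))
    }
  } else {
    cat("  no clade-specific reads\n")
  }
  invisible(x)
}

#' Report foreign clades in a profile
#'
#' Lists every clade other than the expected one with at least `min_reads`
#' clade-specific reads, with its fraction of clade-specific reads. The
#' default threshold of a single read reflects that even single-digit marker
#' counts are meaningful evidence of foreign material.
#'
#' @param profile A [build_clade_profile()] result.
#' @param expected_clade The clade the sample is expected to trace to.
#' @param min_reads Minimum read count to report a foreign clade (default 1).
#' @return A tibble with columns `clade`, `reads`, `fraction`, sorted by
#'   decreasing reads. When the profile has zero clade-specific reads the
#'   tibble is empty and carries attribute `no_evidence = TRUE`.
#' @export
detect_contamination <- function(profile, expected_clade, min_reads = 1L) {
  stopifnot(inherits(profile, "clade_profile"))
  if (!expected_clade %in% names(profile$read_counts)) {
    stop("expected_clade '", expected_clade, "' is not a catalog clade")
  }
  total <- profile$total_clade_specific_reads
  if (total == 0L) {
    out <- tibble(clade = character(), reads = integer(), fraction = numeric())
    attr(out, "no_evidence") <- TRUE
    return(out)
  }
  rc <- profile$read_counts
  foreign <- names(rc)[names(rc) != expected_clade & rc >= min_reads]
  out <- tibble(clade = foreign,
                reads = unname(rc[foreign]),
                fraction = unname(rc[foreign]) / total)
  out[order(-out$reads, out$clade), , drop = FALSE]
}
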