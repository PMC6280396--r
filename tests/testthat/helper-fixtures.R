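# Shared fixtures, built in code. Bundles are cached per options() key so
# repeated tests don't regenerate them.

tiny_bundle <- local({
  cache <- new.env(parent = emptyenv())
  function(seed = 42, n_clades = 3, families_per_clade = 3,
           species_per_family = 2) {
    key <- paste(seed, n_clades, families_per_clade, species_per_family,
                 sep = "_")
    if (is.null(cache[[key]])) {
      cache[[key]] <- generate_reference_bundle(
        n_clades = n_clades, families_per_clade = families_per_clade,
        species_per_family = species_per_family, seed = seed,
        n_trna = 5, n_rrna = 3, n_artifacts = 2
      )
    }
    cache[[key]]
  }
})

default_bundle <- local({
  cache <- new.env(parent = emptyenv())
  function(seed = 7) {
    key <- as.character(seed)
    if (is.null(cache[[key]])) {
      cache[[key]] <- generate_reference_bundle(seed = seed)
    }
    cache[[key]]
  }
})

bundle_catalog <- function(bundle, mode = "clade") {
  cat_tab <- tibble::tibble(
    family_key = paste0("miR-", bundle$catalog$family_number),
    clade = bundle$catalog$clade
  )
  build_clade_catalog(cat_tab, bundle$mature, mode = mode)
}

bundle_db <- function(bundle) {
  build_rnatype_db(bundle$precursor, bundle$trna, bundle$rrna,
                   bundle$artifacts)
}

make_reads <- function(seq, qual = NULL, read_id = NULL, seq_index = NULL) {
  n <- length(seq)
  if (is.null(qual)) qual <- strrep("I", nchar(seq))
  if (is.null(read_id)) read_id <- sprintf("r%03d", seq_len(n))
  if (is.null(seq_index)) seq_index <- rep(NA_character_, n)
  tibble::tibble(read_id = read_id, seq = seq, qual = qual,
                 seq_index = seq_index)
}

write_tmp_fastq <- function(reads, gz = FALSE, ...) {
  path <- tempfile(fileext = if (gz) ".fastq.gz" else ".fastq")
  write_fastq(reads, path, ...)
  path
}

# Quality string with `n_low` characters below Q20 (Q10) and the rest Q30,
# offset 33: Q10 = '+', Q30 = '?'.
qual_mix <- function(n_total, n_low) {
  paste0(strrep("+", n_low), strrep("?", n_total - n_low))
}

# Independent brute-force ungapped matcher: does `query` occur as a
# substring of `ref` with <= k substitutions? Implemented by position-wise
# masked string comparison (a different algorithm from the package's
# Biostrings-based matcher).
oracle_substring_match <- function(query, ref, k = 0) {
  nq <- nchar(query)
  nr <- nchar(ref)
  if (nq > nr) return(FALSE)
  for (s in 1:(nr - nq + 1)) {
    win <- substr(ref, s, s + nq - 1)
    if (k == 0) {
      if (win == query) return(TRUE)
    } else {
      d <- sum(strsplit(win, "")[[1]] != strsplit(query, "")[[1]])
      if (d <= k) return(TRUE)
    }
  }
  FALSE
}

# Bulk oracle for equal-width queries: masked-hash substring matching (an
# independent algorithm from the package's Biostrings-based matcher). For
# 1-mismatch hits, query and window match iff they are equal after masking
# the same single position.
oracle_windows <- function(seqs, w) {
  unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < w) return(character(0))
    substring(s, 1:(n - w + 1), w:n)
  }), use.names = FALSE)
}

oracle_hits_bulk <- function(queries, refs, k, w) {
  wins <- oracle_windows(refs, w)
  if (!length(wins)) return(rep(FALSE, length(queries)))
  hit <- queries %in% wins
  if (k >= 1) {
    for (p in seq_len(w)) {
      mq <- queries; substr(mq, p, p) <- "."
      mw <- wins; substr(mw, p, p) <- "."
      hit <- hit | (mq %in% mw)
    }
  }
  hit
}

# Bulk oracle classifier for equal-width inserts, implementing the same
# cascade contract (precursor -> tRNA -> rRNA at 0 mm, again at 1 mm, then
# artifacts by shared 18-mer) on top of the masked-hash matcher.
oracle_classify_bulk <- function(inserts, bundle, w) {
  type <- rep("unknown", length(inserts))
  colls <- list(mirna = bundle$precursor$seq, trna = bundle$trna$seq,
                rrna = bundle$rrna$seq)
  for (k in 0:1) {
    for (ty in names(colls)) {
      open <- type == "unknown"
      if (!any(open)) break
      hit <- oracle_hits_bulk(inserts[open], colls[[ty]], k, w)
      type[open][hit] <- ty
    }
  }
  open <- which(type == "unknown")
  if (length(open)) {
    art18 <- oracle_windows(bundle$artifacts$seq, 18)
    for (o in seq_len(w - 17)) {
      sub <- substr(inserts[open], o, o + 17)
      type[open][sub %in% art18] <- "artifact"
    }
  }
  type
}

# Oracle RNA-type classifier: same cascade contract, independent matcher.
oracle_classify <- function(insert, bundle) {
  colls <- list(mirna = bundle$precursor, trna = bundle$trna,
                rrna = bundle$rrna)
  for (k in 0:1) {
    for (ty in names(colls)) {
      refs <- colls[[ty]]
      for (j in seq_len(nrow(refs))) {
        if (oracle_substring_match(insert, refs$seq[j], k)) return(ty)
      }
    }
  }
  for (j in seq_len(nrow(bundle$artifacts))) {
    art <- bundle$artifacts$seq[j]
    wins <- substring(insert, 1:(nchar(insert) - 17),
                      18:nchar(insert))
    arts <- substring(art, 1:(nchar(art) - 17), 18:nchar(art))
    if (any(wins %in% arts)) return("artifact")
  }
  "unknown"
}
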