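#' Parse miRNA family keys from miRBase-style mature IDs
#'
#' miRBase mature IDs follow `<species>-<stem><family>[suffix]`, e.g.
#' `hsa-miR-580-5p` or `dme-let-7`. The family key is the stem namespace
#' (`miR` or `let`) plus the leading integer of the family token; suffix
#' letters and the `-5p`/`-3p` arm are ignored. `let` families are kept
#' distinct from `miR` families with the same number.
#'
#' @param ids Character vector of mature miRNA IDs.
#' @return Character vector of family keys (`miR-580`, `let-7`, ...) with
#'   `NA` for IDs that carry no recognizable family token.
#' @examples
#' parse_family_key(c("hsa-miR-580-5p", "dme-let-7", "mml-miR-580"))
#' @export
parse_family_key <- function(ids) {
  m <- stri_match_first_regex(ids, "(?i)\\b(let|mir)-?(\\d+)")
  ns <- ifelse(stri_trans_toupper(m[, 2L]) == "LET", "let", "miR")
  ifelse(is.na(m[, 1L]), NA_character_, paste0(ns, "-", m[, 3L]))
}

#' Build a clade (or species) marker catalog from mature miRNA sequences
#'
#' A mature sequence is admitted if and only if its parsed family key is in
#' the catalog. For each admitted sequence, every 20-nt window (clade mode)
#' or only the first 20 nt (species mode) is indexed under the sequence's
#' clade label. A 20-mer observed under two different clades would break the
#' "present in exactly one clade" marker logic: such k-mers are excluded
#' from the index and listed in the ambiguity report so the catalog can be
#' re-curated. Matching is strand-specific; no reverse complements are
#' indexed.
#'
#' @param catalog Tibble mapping `family_key` to `clade` (see
#'   [parse_clade_catalog()]).
#' @param mature Tibble of mature sequences with columns `id` and `seq`
#'   (miRBase-style IDs).
#' @param mode `"clade"` (index all 20-nt windows) or `"species"` (index the
#'   first 20 nt only, for species-specific custom databases).
#' @return An object of class `clade_catalog`: a list with `kmer_len`,
#'   `mode`, `index` (tibble `kmer`/`clade`/`ref_id`), `ambiguous` (tibble
#'   `kmer`/`clades`), `n_references` (admitted), `total_reference_nt`, and
#'   `skipped` (IDs skipped as unparseable or shorter than 20 nt).
#' @export
build_clade_catalog <- function(catalog, mature, mode = c("clade", "species")) {
  mode <- match.arg(mode)
  k <- 20L
  fam <- parse_family_key(mature$id)
  unparseable <- mature$id[is.na(fam)]
  if (length(unparseable)) {
    warning("skipping ", length(unparseable),
            " mature ID(s) without a parseable family number, e.g. ",
            head(unparseable, 1L))
  }
  clade_of <- setNames(catalog$clade, catalog$family_key)
  admit <- !is.na(fam) & fam %in% names(clade_of)
  adm <- mature[admit, , drop = FALSE]
  adm_clade <- unname(clade_of[fam[admit]])
  short <- stri_length(adm$seq) < k
  if (any(short)) {
    warning("excluding ", sum(short), " admitted sequence(s) shorter than ",
            k, " nt, e.g. ", adm$id[which(short)[1L]])
  }
  skipped <- c(unparseable, adm$id[short])
  adm_clade <- adm_clade[!short]
  adm <- adm[!short, , drop = FALSE]

  if (nrow(adm) == 0L) {
    idx <- tibble(kmer = character(), clade = character(), ref_id = character())
    amb <- tibble(kmer = character(), clades = character())
  } else {
    win <- if (mode == "species") {
      lapply(adm$seq, function(s) stri_sub(s, 1L, k))
    } else {
      lapply(adm$seq, kmers_of, k = k)
    }
    nwin <- lengths(win)
    long <- tibble(
      kmer = unlist(win, use.names = FALSE),
      clade = rep(adm_clade, nwin),
      ref_id = rep(adm$id, nwin)
    )
    # collapse duplicate (kmer, clade) pairs keeping the lexicographically
    # smallest reference id for deterministic, order-independent output
    key <- paste(long$kmer, long$clade, sep = "\r")
    ord <- order(key, long$ref_id, method = "radix")
    long <- long[ord, , drop = FALSE]
    long <- long[!duplicated(key[ord]), , drop = FALSE]
    nclades <- table(long$kmer)
    amb_kmers <- names(nclades)[nclades > 1L]
    if (length(amb_kmers)) {
      amb_rows <- long[long$kmer %in% amb_kmers, , drop = FALSE]
      amb <- tibble(
        kmer = lex_sort(unique(amb_rows$kmer)),
        clades = unname(vapply(
          lex_sort(unique(amb_rows$kmer)),
          function(km) paste(lex_sort(unique(amb_rows$clade[amb_rows$kmer == km])),
                             collapse = ","),
          character(1)
        ))
      )
      long <- long[!(long$kmer %in% amb_kmers), , drop = FALSE]
    } else {
      amb <- tibble(kmer = character(), clades = character())
    }
    ord2 <- order(long$kmer, method = "radix")
    idx <- as_tibble(long[ord2, , drop = FALSE])
  }

  structure(
    list(
      kmer_len = k,
      mode = mode,
      index = idx,
      ambiguous = amb,
      n_references = nrow(adm),
      total_reference_nt = sum(stri_length(adm$seq)),
      clades = lex_sort(unique(catalog$clade)),
      skipped = skipped
    ),
    class = "clade_catalog"
  )
}

#' Build a species-mode catalog directly from labelled references
#'
#' Convenience wrapper for custom species-specific databases (e.g. one
#' mature-miRNA FASTA per species): each reference is labelled with its
#' species and only its first 20 nt are indexed.
#'
#' @param mature Tibble with columns `id` and `seq`.
#' @param labels Character vector of species labels, one per reference. By
#'   default the species prefix of the ID (the token before the first `-`).
#' @return A `clade_catalog` in species mode.
#' @export
build_species_catalog <- function(mature,
                                  labels = sub("-.*$", "", mature$id)) {
  stopifnot(length(labels) == nrow(mature))
  # route through the family machinery by giving every reference its own
  # family via the catalog; simpler to index directly
  k <- 20L
  keep <- stri_length(mature$seq) >= k
  if (any(!keep)) {
    warning("excluding ", sum(!keep), " reference(s) shorter than ", k, " nt")
  }
  adm <- mature[keep, , drop = FALSE]
  lab <- labels[keep]
  long <- tibble(kmer = stri_sub(adm$seq, 1L, k), clade = lab,
                 ref_id = adm$id)
  key <- paste(long$kmer, long$clade, sep = "\r")
  ord <- order(key, long$ref_id, method = "radix")
  long <- long[ord, , drop = FALSE]
  long <- long[!duplicated(key[ord]), , drop = FALSE]
  nclades <- table(long$kmer)
  amb_kmers <- names(nclades)[nclades > 1L]
  amb <- tibble(kmer = character(), clades = character())
  if (length(amb_kmers)) {
    amb_rows <- long[long$kmer %in% amb_kmers, , drop = FALSE]
    amb <- tibble(
      kmer = lex_sort(unique(amb_rows$kmer)),
      clades = unname(vapply(
        lex_sort(unique(amb_rows$kmer)),
        function(km) paste(lex_sort(unique(amb_rows$clade[amb_rows$kmer == km])),
                           collapse = ","),
        character(1)
      ))
    )
    long <- long[!(long$kmer %in% amb_kmers), , drop = FALSE]
  }
  structure(
    list(
      kmer_len = k, mode = "species",
      index = as_tibble(long[order(long$kmer, method = "radix"), ,
                             drop = FALSE]),
      ambiguous = amb,
      n_references = nrow(adm),
      total_reference_nt = sum(stri_length(adm$seq)),
      clades = lex_sort(unique(lab)),
      skipped = mature$id[!keep]
    ),
    class = "clade_catalog"
  )
}

#' @export
print.clade_catalog <- function(x, ...) {
  cat("<clade_catalog> mode:", x$mode, "\n",
      " references admitted:", x$n_references,
      " (", x$total_reference_nt, "nt )\n",
      " indexed 20-mers:", nrow(x$index),
      " ambiguous excluded:", nrow(x$ambiguous), "\n")
  invisible(x)
}

#' Build the RNA-type annotation database
#'
#' Holds the ordered reference collections used by the annotation cascade:
#' miRNA precursors first, then tRNA, then rRNA (fixed priority), plus
#' sequencing-artifact sequences indexed by their 18-mers (a read is an
#' artifact when it shares at least one 18-nt stretch of identity with an
#' artifact sequence).
#'
#' @param precursors,trnas,rrnas,artifacts Tibbles with columns `id`/`seq`
#'   (any may be empty: empty collections simply never match).
#' @return An object of class `rnatype_db`.
#' @export
build_rnatype_db <- function(precursors = NULL, trnas = NULL, rrnas = NULL,
                             artifacts = NULL) {
  empty <- tibble(id = character(), seq = character())
  as_coll <- function(x) {
    if (is.null(x) || nrow(x) == 0L) return(list(tab = empty, set = NULL))
    list(tab = as_tibble(x[, c("id", "seq")]),
         set = Biostrings::DNAStringSet(setNames(x$seq, x$id)))
  }
  arts <- if (is.null(artifacts)) empty else as_tibble(artifacts[, c("id", "seq")])
  if (nrow(arts)) {
    win <- lapply(arts$seq, kmers_of, k = 18L)
    art_idx <- tibble(kmer = unlist(win, use.names = FALSE),
                      ref_id = rep(arts$id, lengths(win)))
    ord <- order(art_idx$kmer, art_idx$ref_id, method = "radix")
    art_idx <- art_idx[ord, , drop = FALSE]
    art_idx <- art_idx[!duplicated(art_idx$kmer), , drop = FALSE]
  } else {
    art_idx <- tibble(kmer = character(), ref_id = character())
  }
  structure(
    list(
      collections = list(
        precursor_mirna = as_coll(precursors),
        trna = as_coll(trnas),
        rrna = as_coll(rrnas)
      ),
      artifacts = arts,
      artifact_index = art_idx
    ),
    class = "rnatype_db"
  )
}

#' @export
print.rnatype_db <- function(x, ...) {
  n <- vapply(x$collections, function(cc) nrow(cc$tab), integer(1))
  cat("<rnatype_db> precursors:", n[["precursor_mirna"]],
      " tRNA:", n[["trna"]], " rRNA:", n[["rrna"]],
      " artifacts:", nrow(x$artifacts), "\n")
  invisible(x)
}

#' Query a reference collection for ungapped substring hits
#'
#' Is `query` a contiguous substring of any member of `collection`, allowing
#' up to `max_mismatch` substitutions (no indels)? Used by the annotation
#' cascade; exposed for testing against independent oracles.
#'
#' @param query Single query sequence.
#' @param db An `rnatype_db`.
#' @param collection One of `"precursor_mirna"`, `"trna"`, `"rrna"`.
#' @param max_mismatch 0 or 1.
#' @return Character vector of matching reference IDs (possibly empty),
#'   lexicographically sorted.
#' @export
match_collection <- function(query, db, collection, max_mismatch = 0) {
  cc <- db$collections[[collection]]
  if (is.null(cc$set) || stri_length(query) == 0L) return(character())
  hits <- Biostrings::vcountPattern(query, cc$set,
                                    max.mismatch = max_mismatch,
                                    with.indels = FALSE) > 0L
  lex_sort(cc$tab$id[hits])
}

#' Write a reference bundle to a directory
#'
#' Serializes the standard reference layout: `clade_catalog.tsv`,
#' `mature.fa`, `precursor.fa`, `trna.fa`, `rrna.fa`, `artifacts.fa`.
#'
#' @param bundle A `reference_bundle` (see [generate_reference_bundle()]) or
#'   a list with elements `catalog`, `mature`, `precursor`, `trna`, `rrna`,
#'   `artifacts`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_reference_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_clade_catalog(bundle$catalog, file.path(dir, "clade_catalog.tsv"))
  write_fasta(bundle$mature, file.path(dir, "mature.fa"))
  write_fasta(bundle$precursor, file.path(dir, "precursor.fa"))
  write_fasta(bundle$trna, file.path(dir, "trna.fa"))
  write_fasta(bundle$rrna, file.path(dir, "rrna.fa"))
  write_fasta(bundle$artifacts, file.path(dir, "artifacts.fa"))
  invisible(dir)
}

#' Load a reference bundle from a directory
#'
#' @param dir Directory produced by [write_reference_bundle()].
#' @return A `reference_bundle` list.
#' @export
load_reference_bundle <- function(dir) {
  structure(
    list(
      catalog = parse_clade_catalog(file.path(dir, "clade_catalog.tsv")),
      mature = read_fasta(file.path(dir, "mature.fa")),
      precursor = read_fasta(file.path(dir, "precursor.fa")),
      trna = read_fasta(file.path(dir, "trna.fa")),
      rrna = read_fasta(file.path(dir, "rrna.fa")),
      artifacts = read_fasta(file.path(dir, "artifacts.fa"))
    ),
    class = "reference_bundle"
  )
}
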