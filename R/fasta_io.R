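#' Read a FASTA file
#'
#' Parses plain or gzipped FASTA via Biostrings, concatenating wrapped
#' sequence lines, uppercasing, and converting RNA `U` to DNA `T`. The record
#' ID is the first whitespace-delimited token of the header.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` and `seq`, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  set <- Biostrings::readBStringSet(path)
  ids <- stri_split_fixed(names(set), " ", n = 2L, simplify = TRUE)[, 1L]
  seqs <- chartr("Uu", "Tt", as.character(set))
  seqs <- stri_trans_toupper(seqs)
  empty <- which(stri_length(seqs) == 0L)
  if (length(empty)) {
    stop("FASTA '", path, "': record '", ids[empty[1L]],
         "' has an empty sequence")
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    warning("FASTA '", path, "': duplicate IDs kept as-is: ",
            paste(head(dup, 5L), collapse = ", "))
  }
  tibble(id = unname(ids), seq = unname(seqs))
}

#' Write sequences to a FASTA file
#'
#' @param records Tibble with columns `id` and `seq`.
#' @param path Output path; `.gz` triggers compression.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(all(c("id", "seq") %in% names(records)))
  lines <- as.vector(rbind(paste0(">", records$id), records$seq))
  con <- if (endsWith(path, ".gz")) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Parse a clade catalog TSV
#'
#' The catalog maps curated clade-specific miRNA family numbers to clade
#' labels. The file is tab-separated with a header line naming the columns
#' `family_number` and `clade`. Family numbers are plain integers for the
#' `miR` namespace; `let` families are written `let-7` style. Each family
#' must map to exactly one clade (markers are exclusive by construction).
#'
#' @param path Path to the TSV catalog.
#' @return A tibble with columns `family_key` (normalized, e.g. `miR-580`,
#'   `let-7`) and `clade`.
#' @export
parse_clade_catalog <- function(path) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  raw <- tryCatch(
    read.delim(path, sep = "\t", stringsAsFactors = FALSE),
    error = function(e) NULL
  )
  if (is.null(raw) || nrow(raw) == 0L) {
    return(tibble(family_key = character(), clade = character()))
  }
  if (!all(c("family_number", "clade") %in% names(raw))) {
    stop("clade catalog '", path,
         "' must have columns 'family_number' and 'clade'")
  }
  key <- normalize_family_key(as.character(raw$family_number))
  clade <- as.character(raw$clade)
  tab <- unique(tibble(family_key = key, clade = clade))
  conflict <- unique(tab$family_key[duplicated(tab$family_key)])
  if (length(conflict)) {
    stop("clade catalog '", path, "': family listed under multiple clades: ",
         paste(head(conflict, 5L), collapse = ", "))
  }
  tab
}

#' Write a clade catalog TSV
#'
#' @param catalog Tibble with columns `family_key` and `clade` (as produced
#'   by [parse_clade_catalog()]) or `family_number` and `clade`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clade_catalog <- function(catalog, path) {
  fam <- if ("family_number" %in% names(catalog)) {
    as.character(catalog$family_number)
  } else {
    # strip the default miR namespace back to a bare number; keep let-N
    sub("^miR-", "", catalog$family_key)
  }
  write_tsv(tibble(family_number = fam, clade = catalog$clade), path)
}

# Normalize a family token to a namespaced key: "580" -> "miR-580",
# "miR-580" -> "miR-580", "let-7" -> "let-7". miRBase convention keeps the
# let-7 family in a namespace of its own, distinct from miR-7.
normalize_family_key <- function(x) {
  x <- trimws(x)
  bare <- stri_detect_regex(x, "^\\d+$")
  out <- character(length(x))
  out[bare] <- paste0("miR-", x[bare])
  rest <- x[!bare]
  m <- stri_match_first_regex(rest, "(?i)^(let|mir)-?(\\d+)")
  bad <- is.na(m[, 1L])
  if (any(bad)) {
    stop("unparseable family number(s): ",
         paste(head(rest[bad], 5L), collapse = ", "))
  }
  ns <- ifelse(stri_trans_toupper(m[, 2L]) == "LET", "let", "miR")
  out[!bare] <- paste0(ns, "-", m[, 3L])
  out
}
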