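#' Standard Illumina TruSeq small-RNA 3' adapter (33 nt)
#'
#' The full-length 3' adapter sequenced through when a short insert is read
#' on a 75-cycle kit: insert (~22 nt) + adapter (33 nt) + index (6 nt) fits
#' in 75 cycles, which is what makes the inline index readable.
#' @export
TRUSEQ_ADAPTER <- "TGGAATTCTCGGGTGCCAAGGAACTCCAGTCAC"

# The 14 animal and plant clades used by the default marker catalog.
DEFAULT_CLADES <- c(
  "primate", "rodent", "laurasiatheria", "marsupial", "bird", "reptile",
  "fish", "lophotrochozoa", "nematode", "hexapoda", "echinoderm",
  "land_plant", "monocot", "eudicot"
)

#' Specification for synthetic read generation
#'
#' Collects every knob of the read simulator: library size, read and insert
#' geometry, protocol decorations, per-base substitution error rate,
#' quality model, and (for multiplexed runs) the sample index and index
#' corruption rates. All generation is a pure function of the spec and its
#' seed.
#'
#' @param n_reads Number of reads.
#' @param seed RNG seed.
#' @param read_length Instrument read length (default 75, long enough for
#'   insert + 33-nt adapter + 6-nt index).
#' @param adapter 3' adapter used to decorate reads (default
#'   [TRUSEQ_ADAPTER]).
#' @param protocol Library protocol (`"truseq_qiaseq"`, `"nextflex"`,
#'   `"cats"`).
#' @param per_base_error_rate Substitution error probability per base
#'   (default 0; substitution-only, matching the pipeline's ungapped model).
#' @param quality_mean,quality_sd Per-base PHRED model (Gaussian, clipped to
#'   \[2, 41\]).
#' @param insert_length_distribution Optional named numeric vector of
#'   probabilities by insert length; inserts are 3'-truncated marker
#'   sequences. `NULL` (default) uses each marker's full length (~22 nt).
#' @param index Sample index to embed after the adapter (optional).
#' @param umi_prefix_len Leading random UMI bases (default 0).
#' @param index_misread_rate,mispair_rate Index corruption rates used by
#'   [generate_multiplexed_run()].
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(n_reads, seed = 1L, read_length = 75L,
                       adapter = TRUSEQ_ADAPTER,
                       protocol = c("truseq_qiaseq", "nextflex", "cats"),
                       per_base_error_rate = 0,
                       quality_mean = 35, quality_sd = 3,
                       insert_length_distribution = NULL,
                       index = NULL, umi_prefix_len = 0L,
                       index_misread_rate = 0, mispair_rate = 0) {
  protocol <- match.arg(protocol)
  probs <- c(per_base_error_rate, index_misread_rate, mispair_rate)
  stopifnot(all(probs >= 0 & probs <= 1), n_reads >= 0, read_length >= 1)
  if (!is.null(insert_length_distribution)) {
    stopifnot(abs(sum(insert_length_distribution) - 1) < 1e-8)
  }
  structure(
    list(n_reads = as.integer(n_reads), seed = as.integer(seed),
         read_length = as.integer(read_length), adapter = adapter,
         protocol = protocol, per_base_error_rate = per_base_error_rate,
         quality_mean = quality_mean, quality_sd = quality_sd,
         insert_length_distribution = insert_length_distribution,
         index = if (is.null(index)) NA_character_ else index,
         umi_prefix_len = as.integer(umi_prefix_len),
         index_misread_rate = index_misread_rate,
         mispair_rate = mispair_rate),
    class = "synth_spec"
  )
}

#' Generate a synthetic reference bundle
#'
#' Emits a complete, self-consistent reference set standing in for the
#' curated marker catalog plus the annotation databases: a clade catalog
#' (family number to clade), mature marker sequences with miRBase-style IDs
#' realizing those families, precursors that embed each mature in random
#' flanks, tRNA and rRNA decoys, and artifact sequences containing the
#' standard sequencing adapter. Mature sequences are resampled until no
#' 20-mer is shared between any two sequences, so catalog construction has
#' zero ambiguity exclusions and clade assignment of error-free reads is
#' exact by construction.
#'
#' The defaults (14 clades x 24 families x 4 species variants, ~22 nt each)
#' give a marker set of roughly 30,000 nucleotides, the size of the real
#' curated catalog.
#'
#' @param n_clades Number of clades (default 14; the first 14 use the
#'   standard clade labels).
#' @param families_per_clade Marker families per clade (default 24).
#' @param species_per_family Species variants per family (default 4).
#' @param seed RNG seed; generation is byte-reproducible.
#' @param n_trna,n_rrna,n_artifacts Decoy collection sizes.
#' @param adapter Adapter embedded in the artifact sequences.
#' @return An object of class `reference_bundle` with elements `catalog`,
#'   `mature`, `precursor`, `trna`, `rrna`, `artifacts`, `clades`.
#' @export
generate_reference_bundle <- function(n_clades = 14L,
                                      families_per_clade = 24L,
                                      species_per_family = 4L,
                                      seed = 1L,
                                      n_trna = 20L, n_rrna = 8L,
                                      n_artifacts = 6L,
                                      adapter = TRUSEQ_ADAPTER) {
  stopifnot(n_clades >= 1L, families_per_clade >= 1L,
            species_per_family >= 1L)
  clades <- if (n_clades <= length(DEFAULT_CLADES)) {
    DEFAULT_CLADES[seq_len(n_clades)]
  } else {
    c(DEFAULT_CLADES,
      sprintf("clade_%02d", seq.int(length(DEFAULT_CLADES) + 1L, n_clades)))
  }
  withr::with_seed(seed, {
    n_fam <- n_clades * families_per_clade
    fam_numbers <- seq.int(100L, length.out = n_fam)
    fam_clade <- rep(clades, each = families_per_clade)
    catalog <- tibble(family_number = fam_numbers, clade = fam_clade)

    n_mat <- n_fam * species_per_family
    sp_codes <- sprintf("s%02d%s",
                        rep(seq_len(n_clades), each = families_per_clade *
                              species_per_family),
                        rep(letters[seq_len(species_per_family)],
                            times = n_fam))
    mat_fam <- rep(fam_numbers, each = species_per_family)
    mat_clade <- rep(fam_clade, each = species_per_family)
    mat_id <- paste0(sp_codes, "-miR-", mat_fam)
    mat_len <- sample(c(21L, 22L, 23L), n_mat, replace = TRUE,
                      prob = c(0.25, 0.5, 0.25))
    mat_seq <- rand_dna(n_mat, mat_len)

    # resample until no 20-mer is shared between two mature sequences
    for (iter in seq_len(50L)) {
      win <- lapply(mat_seq, kmers_of, k = 20L)
      all_win <- unlist(win, use.names = FALSE)
      dup <- unique(all_win[duplicated(all_win)])
      if (!length(dup)) break
      owner <- rep(seq_len(n_mat), lengths(win))
      redo <- unique(owner[all_win %in% dup])
      redo <- redo[-1L]  # keep the first owner of each clash where possible
      if (!length(redo)) redo <- unique(owner[all_win %in% dup])[1L]
      mat_seq[redo] <- rand_dna(length(redo), mat_len[redo])
    }
    win <- lapply(mat_seq, kmers_of, k = 20L)
    all_win <- unlist(win, use.names = FALSE)
    if (anyDuplicated(all_win)) {
      stop("could not generate a collision-free marker set; ",
           "reduce the requested sequence volume")
    }

    mature <- tibble(id = mat_id, seq = mat_seq)
    precursor <- tibble(
      id = paste0(sp_codes, "-mir-", mat_fam),
      seq = paste0(rand_dna(n_mat, 25L), mat_seq, rand_dna(n_mat, 25L))
    )
    trna <- tibble(id = sprintf("trna_%03d", seq_len(n_trna)),
                   seq = rand_dna(n_trna, sample(72:85, n_trna,
                                                 replace = TRUE)))
    rrna <- tibble(id = sprintf("rrna_%03d", seq_len(n_rrna)),
                   seq = rand_dna(n_rrna, sample(110:130, n_rrna,
                                                 replace = TRUE)))
    artifacts <- tibble(
      id = sprintf("illumina_artifact_%02d", seq_len(n_artifacts)),
      seq = paste0(rand_dna(n_artifacts, 10L), adapter,
                   rand_dna(n_artifacts, 20L))
    )
    structure(
      list(catalog = catalog, mature = mature, precursor = precursor,
           trna = trna, rrna = rrna, artifacts = artifacts,
           clades = clades, mature_clade = mat_clade),
      class = "reference_bundle"
    )
  })
}

#' @export
print.reference_bundle <- function(x, ...) {
  cat("<reference_bundle>", length(x$clades), "clades,",
      nrow(x$catalog), "families,", nrow(x$mature), "mature markers (",
      sum(stri_length(x$mature$seq)), "nt )\n")
  invisible(x)
}

# Draw a pool of quality strings (one per pool slot) under the Gaussian
# PHRED model, then sample reads from the pool. Statistically equivalent to
# fresh per-base draws for histogram purposes at a fraction of the cost.
qual_pool_sample <- function(n, width, mean, sd, offset = 33L,
                             pool_size = 256L) {
  pool_size <- min(pool_size, max(n, 1L))
  q <- matrix(as.integer(pmin(pmax(round(rnorm(pool_size * width, mean, sd)),
                                   2L), 41L)),
              nrow = pool_size)
  pool <- apply(q + offset, 1L, intToUtf8)
  pool[sample.int(pool_size, n, replace = TRUE)]
}

#' Generate a synthetic sample from one clade's markers
#'
#' Each read is built as (optional UMI) + insert + protocol decorations +
#' optional sample index + random filler, truncated to the read length,
#' where the insert is a mature marker sequence of the requested clade.
#' Substitution errors and Gaussian qualities are applied per the spec.
#' Ground truth records the originating reference, clade, insert, and index
#' of every read, sufficient to score trimming, classification, and
#' demultiplexing without re-deriving labels.
#'
#' @param spec A [synth_spec()].
#' @param bundle A [generate_reference_bundle()] bundle.
#' @param clade Clade whose markers seed the inserts.
#' @param sample_id Prefix for read IDs (default the clade label).
#' @return A list with `reads` (tibble ready for [write_fastq()]) and
#'   `truth` (tibble `read_id`, `ref_id`, `clade`, `insert`, `index`).
#' @export
generate_sample <- function(spec, bundle, clade, sample_id = clade) {
  stopifnot(inherits(spec, "synth_spec"),
            inherits(bundle, "reference_bundle"))
  if (!clade %in% bundle$clades) stop("clade '", clade, "' not in bundle")
  pool_rows <- which(bundle$mature_clade == clade)
  if (!length(pool_rows)) stop("bundle has no markers for clade '", clade, "'")
  n <- spec$n_reads
  withr::with_seed(spec$seed, {
    pick <- pool_rows[sample.int(length(pool_rows), n, replace = TRUE)]
    insert <- bundle$mature$seq[pick]
    if (!is.null(spec$insert_length_distribution)) {
      d <- spec$insert_length_distribution
      want <- as.integer(sample(names(d), n, replace = TRUE, prob = d))
      insert <- stri_sub(insert, 1L, pmin(want, stri_length(insert)))
    }
    umi <- if (spec$umi_prefix_len > 0L) {
      rand_dna(n, spec$umi_prefix_len)
    } else ""
    idx_part <- if (!is.na(spec$index)) spec$index else ""
    core <- switch(spec$protocol,
      truseq_qiaseq = paste0(umi, insert, spec$adapter, idx_part),
      nextflex = paste0(umi, rand_dna(n, 4L), insert, rand_dna(n, 4L),
                        spec$adapter, idx_part),
      cats = paste0(umi, rand_dna(n, 3L), insert)
    )
    need <- pmax(spec$read_length - stri_length(core), 0L)
    fill <- if (spec$protocol == "cats") strrep("A", need) else
      rand_dna(n, need)
    seq <- stri_sub(paste0(core, fill), 1L, spec$read_length)
    seq <- mutate_seqs(seq, spec$per_base_error_rate)
    qual <- qual_pool_sample(n, spec$read_length, spec$quality_mean,
                             spec$quality_sd)
    read_id <- sprintf("%s_%07d", sample_id, seq_len(n))
    reads <- tibble(read_id = read_id, seq = seq, qual = qual,
                    seq_index = if (!is.na(spec$index))
                      rep(spec$index, n) else rep(NA_character_, n))
    truth <- tibble(read_id = read_id, ref_id = bundle$mature$id[pick],
                    clade = clade, insert = insert,
                    index = reads$seq_index)
    list(reads = reads, truth = truth)
  })
}

#' Mix contaminant reads into a host sample
#'
#' Draws `round(fraction * total_n)` reads from the contaminant sample and
#' the remainder from the host, without replacement, and shuffles the
#' result. Note the rounding: a fraction of 0.0001% of 10^6 reads is a
#' single read, so sensitivity experiments should pick `total_n`
#' accordingly. Provenance is recorded per read.
#'
#' @param host,contaminant Lists with `reads`/`truth` (from
#'   [generate_sample()]), or bare read tibbles.
#' @param fraction Contaminant fraction in \[0, 1\].
#' @param total_n Total reads in the mixture.
#' @param seed RNG seed for the subsampling and shuffle.
#' @return A list with `reads` and `truth` (with an `origin` column,
#'   `"host"` or `"contaminant"`).
#' @export
spike_mix <- function(host, contaminant, fraction, total_n, seed = 1L) {
  stopifnot(fraction >= 0, fraction <= 1, total_n >= 0)
  as_pair <- function(x) {
    if (is_tibble(x)) list(reads = x, truth = NULL) else x
  }
  host <- as_pair(host)
  contaminant <- as_pair(contaminant)
  n_cont <- as.integer(round(fraction * total_n))
  n_host <- as.integer(total_n) - n_cont
  if (n_host > nrow(host$reads)) {
    stop("host sample has only ", nrow(host$reads), " reads; need ", n_host)
  }
  if (n_cont > nrow(contaminant$reads)) {
    stop("contaminant sample has only ", nrow(contaminant$reads),
         " reads; need ", n_cont)
  }
  withr::with_seed(seed, {
    hi <- sample.int(nrow(host$reads), n_host)
    ci <- sample.int(nrow(contaminant$reads), n_cont)
    reads <- rbind(host$reads[hi, , drop = FALSE],
                   contaminant$reads[ci, , drop = FALSE])
    origin <- c(rep("host", n_host), rep("contaminant", n_cont))
    truth <- if (!is.null(host$truth) && !is.null(contaminant$truth)) {
      tr <- rbind(host$truth[hi, , drop = FALSE],
                  contaminant$truth[ci, , drop = FALSE])
      tr$origin <- origin
      tr
    } else {
      tibble(read_id = reads$read_id, origin = origin)
    }
    ord <- sample.int(nrow(reads))
    list(reads = as_tibble(reads[ord, , drop = FALSE]),
         truth = as_tibble(truth[ord, , drop = FALSE]))
  })
}

#' Generate a multiplexed run with controlled index corruption
#'
#' Emulates a pooled sequencing run: each sample's reads carry their true
#' index both inline (after the adapter, read by the main reaction) and as
#' the sequencer-reported index. Two corruption channels are then applied to
#' the reported index only: per-base misreads at `index_misread_rate`
#' (sequencing errors in the index read), and mis-pairing at `mispair_rate`
#' (the instrument pairs a correctly read index of a *different* sample
#' with this read; the inline index stays true). Ground truth records the
#' event applied to every read.
#'
#' @param specs Named list of [synth_spec()]s, one per sample, each with its
#'   `index` set (indices must be distinct).
#' @param bundle A reference bundle.
#' @param clades Character vector: generating clade per sample (recycled).
#' @param index_misread_rate,mispair_rate Corruption probabilities.
#' @param seed RNG seed governing corruption (sample generation uses each
#'   spec's own seed).
#' @return A list with `reads` (pooled, shuffled), `truth` (with columns
#'   `sample_id`, `true_index`, `observed_index`, `event` in
#'   none/misread/mispair), and `samples` (the sample sheet tibble).
#' @export
generate_multiplexed_run <- function(specs, bundle, clades,
                                     index_misread_rate = 0,
                                     mispair_rate = 0, seed = 1L) {
  stopifnot(length(specs) >= 1L)
  ids <- names(specs) %||% sprintf("sample_%02d", seq_along(specs))
  clades <- rep_len(clades, length(specs))
  indices <- vapply(specs, function(s) s$index, character(1))
  if (anyNA(indices)) stop("every spec needs an index")
  if (anyDuplicated(indices)) stop("sample indices must be distinct")

  parts <- lapply(seq_along(specs), function(i) {
    smp <- generate_sample(specs[[i]], bundle, clades[i], sample_id = ids[i])
    smp$truth$sample_id <- ids[i]
    smp
  })
  reads <- do.call(rbind, lapply(parts, `[[`, "reads"))
  truth <- do.call(rbind, lapply(parts, `[[`, "truth"))
  names(truth)[names(truth) == "index"] <- "true_index"

  withr::with_seed(seed, {
    n <- nrow(reads)
    ilen <- unique(stri_length(indices))
    stopifnot(length(ilen) == 1L)
    event <- rep("none", n)
    mis <- which(stats::runif(n) < mispair_rate)
    if (length(mis)) {
      event[mis] <- "mispair"
      own <- match(truth$true_index[mis], indices)
      other <- vapply(own, function(o)
        sample(indices[-o], 1L), character(1))
      reads$seq_index[mis] <- other
    }
    rest <- setdiff(seq_len(n), mis)
    if (index_misread_rate > 0 && length(rest)) {
      nerr <- rbinom(length(rest), ilen, index_misread_rate)
      hit <- nerr > 0L
      if (any(hit)) {
        event[rest[hit]] <- "misread"
        reads$seq_index[rest[hit]] <-
          mutate_positions(reads$seq_index[rest[hit]], nerr[hit])
      }
    }
    truth$observed_index <- reads$seq_index
    truth$event <- event
    ord <- sample.int(n)
    list(reads = as_tibble(reads[ord, , drop = FALSE]),
         truth = as_tibble(truth[ord, , drop = FALSE]),
         samples = tibble(sample_id = ids, index = indices,
                          adapter = vapply(specs, function(s) s$adapter,
                                           character(1))))
  })
}
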