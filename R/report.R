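#' Summarize one sample through the full QC pipeline
#'
#' Runs preprocess, RNA-type annotation, complexity accumulation, and clade
#' tracing for one sample and collects every per-sample accumulator: the
#' per-read mean PHRED histogram, the insert-length histogram (over all
#' adapter-trimmed reads, so zero lengths flag adapter dimers and lengths at
#' the read cap flag unrecognized adapters), QC category counts, RNA-type
#' counts, the miRNA complexity curve, the clade profile, and QC flags.
#'
#' @param reads Tibble from [read_fastq()].
#' @param cfg A [sample_config()].
#' @param db An [build_rnatype_db()] database.
#' @param catalog A [build_clade_catalog()] marker catalog.
#' @param checkpoint_step Complexity-curve checkpoint interval.
#' @param min_reads Foreign-clade detection threshold.
#' @return An object of class `sample_summary`.
#' @export
summarize_sample <- function(reads, cfg, db, catalog,
                             checkpoint_step = 10000L, min_reads = 1L) {
  pre <- preprocess_reads(reads, cfg)
  n_input <- nrow(pre)
  qc_pass <- startsWith(pre$status, "qc_passed")

  mean_q <- vapply(decode_quals(reads$qual, cfg$phred_offset),
                   function(v) if (length(v)) mean(v) else 0, numeric(1))
  phred_tab <- table(factor(pmin(pmax(floor(mean_q), 0L), 41L),
                            levels = 0:41))
  phred_histogram <- tibble(phred = 0:41, reads = as.integer(phred_tab))

  trimmed <- !is.na(pre$insert_len)
  max_len <- 50L
  len_tab <- table(factor(pmin(pre$insert_len[trimmed], max_len),
                          levels = 0:max_len))
  length_histogram <- tibble(length = 0:max_len, reads = as.integer(len_tab))

  cat_key <- ifelse(pre$status == "discarded",
                    paste0("discarded_", pre$discard_reason), pre$status)
  cat_lev <- c("qc_passed_adapter_found", "qc_passed_adapter_unrecognized",
               "discarded_low_quality", "discarded_ambiguous_nt",
               "discarded_low_complexity", "discarded_too_short")
  qc_counts <- tibble(category = cat_lev,
                      reads = as.integer(table(factor(cat_key,
                                                      levels = cat_lev))))

  ann <- classify_rna_type(pre$insert[qc_pass], db)
  rt_counts <- rna_type_counts(ann$rna_type)

  prec_ids <- rep(NA_character_, n_input)
  prec_ids[which(qc_pass)[ann$rna_type == "mirna"]] <-
    ann$matched_reference_id[ann$rna_type == "mirna"]
  curve <- complexity_curve(prec_ids, checkpoint_step = checkpoint_step)
  distinct_precursors <- if (nrow(curve))
    curve$distinct_precursors[nrow(curve)] else 0L

  profile <- build_clade_profile(pre$insert[qc_pass], catalog)
  contamination <- if (!is.na(cfg$expected_clade)) {
    detect_contamination(profile, cfg$expected_clade, min_reads = min_reads)
  } else NULL

  out <- structure(
    list(sample_id = cfg$sample_id,
         species = cfg$species,
         n_input = n_input,
         n_qc_passed = sum(qc_pass),
         phred_histogram = phred_histogram,
         length_histogram = length_histogram,
         qc_category_counts = qc_counts,
         rna_type_counts = rt_counts,
         complexity_curve = curve,
         distinct_precursors = distinct_precursors,
         n_reference_precursors = nrow(db$collections$precursor_mirna$tab),
         clade_profile = profile,
         contamination = contamination,
         flags = character(0)),
    class = "sample_summary"
  )
  out$flags <- qc_flags(out)
  out
}

#' @export
print.sample_summary <- function(x, ...) {
  cat("<sample_summary>", x$sample_id, "-", x$n_input, "reads,",
      x$n_qc_passed, "QC-passed,", x$distinct_precursors,
      "distinct precursors\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

# Resolve a sample entry (list with config plus either reads or path) into
# a reads tibble.
resolve_sample_reads <- function(entry) {
  if (!is.null(entry$reads)) return(entry$reads)
  if (!is.null(entry$path)) {
    return(read_fastq(entry$path,
                      phred_offset = entry$config$phred_offset))
  }
  stop("sample entry needs either 'reads' or 'path'")
}

#' Run the full quality-control pipeline over a set of samples
#'
#' For every sample: pre-processing, RNA-type annotation, complexity
#' accumulation, clade tracing, and flagging; optionally serializes the six
#' report panels (PHRED score distribution, read length distribution, QC
#' statistics, RNA type, miRNA complexity, contamination) as TSV tables, a
#' JSON summary, per-panel figures, and one self-contained HTML report.
#' Every number rendered in a figure also appears in a TSV/JSON output.
#'
#' @param samples List of sample entries: each a list with `config` (a
#'   [sample_config()]) and either `reads` (tibble) or `path` (FASTQ path).
#' @param db An `rnatype_db`.
#' @param catalog A `clade_catalog`.
#' @param output_dir Directory for report files, or `NULL` (default) to
#'   skip serialization.
#' @param checkpoint_step Complexity checkpoint interval (default 10000).
#' @param min_reads Foreign-clade detection threshold (default 1).
#' @return Named list of `sample_summary` objects, invisibly when writing
#'   reports.
#' @export
run_qc <- function(samples, db, catalog, output_dir = NULL,
                   checkpoint_step = 10000L, min_reads = 1L) {
  stopifnot(length(samples) >= 1L)
  summaries <- list()
  for (entry in samples) {
    cfg <- entry$config
    reads <- resolve_sample_reads(entry)
    summaries[[cfg$sample_id]] <- summarize_sample(
      reads, cfg, db, catalog,
      checkpoint_step = checkpoint_step, min_reads = min_reads
    )
  }
  if (!is.null(output_dir)) {
    write_qc_report(summaries, output_dir)
    return(invisible(summaries))
  }
  summaries
}

#' Run trace-only analysis over a set of samples
#'
#' The lightweight path: pre-processing plus clade (or species, with a
#' species-mode catalog) composition, without RNA-type annotation. Emits
#' the clade read-count and unique-sequence tables and a stacked-bar
#' composition figure when `output_dir` is given.
#'
#' @inheritParams run_qc
#' @return Named list of `clade_profile` objects (one per sample).
#' @export
run_trace <- function(samples, catalog, output_dir = NULL, min_reads = 1L) {
  stopifnot(length(samples) >= 1L)
  profiles <- list()
  for (entry in samples) {
    cfg <- entry$config
    reads <- resolve_sample_reads(entry)
    pre <- preprocess_reads(reads, cfg)
    qc <- startsWith(pre$status, "qc_passed")
    profiles[[cfg$sample_id]] <- build_clade_profile(pre$insert[qc], catalog)
  }
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(profile_table(profiles, "read_counts"),
              file.path(output_dir, "clade_read_counts.tsv"))
    write_tsv(profile_table(profiles, "unique_sequence_counts"),
              file.path(output_dir, "clade_unique_sequence_counts.tsv"))
    p <- plot_clade_composition(profiles)
    ggplot2::ggsave(file.path(output_dir, "clade_composition.png"), p,
                    width = 7, height = 4.5, dpi = 120)
    return(invisible(profiles))
  }
  profiles
}

# Long-format clade count table across samples.
profile_table <- function(profiles, field = "read_counts") {
  do.call(rbind, lapply(names(profiles), function(sid) {
    v <- profiles[[sid]][[field]]
    tibble(sample = sid, clade = names(v), reads = as.integer(v))
  }))
}

#' Stacked-bar clade composition figure
#'
#' One bar per sample, stratified by clade with a fixed 14-clade palette;
#' bar heights are fractions of clade-specific reads. Samples with no
#' clade-specific reads render as an empty bar.
#'
#' @param profiles Named list of `clade_profile`s.
#' @return A ggplot object.
#' @export
plot_clade_composition <- function(profiles) {
  tab <- profile_table(profiles, "read_counts")
  tab <- tab[tab$reads > 0L, , drop = FALSE]
  totals <- vapply(profiles, function(p)
    max(p$total_clade_specific_reads, 1L), numeric(1))
  tab$fraction <- tab$reads / totals[tab$sample]
  pal <- clade_palette(unique(profile_table(profiles)$clade))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$sample, y = .data$fraction,
                                    fill = .data$clade)) +
    ggplot2::geom_col(width = 0.7) +
    ggplot2::scale_fill_manual(values = pal, drop = FALSE) +
    ggplot2::labs(x = NULL, y = "fraction of clade-specific reads",
                  fill = "clade") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

# Fixed, order-stable palette: one colour per clade label.
clade_palette <- function(clades) {
  base <- c(
    "#E41A1C", "#377EB8", "#4DAF4A", "#984EA3", "#FF7F00", "#FFFF33",
    "#A65628", "#F781BF", "#999999", "#66C2A5", "#FC8D62", "#8DA0CB",
    "#E78AC3", "#A6D854"
  )
  clades <- lex_sort(unique(clades))
  setNames(rep_len(base, length(clades)), clades)
}

#' Write the QC report bundle
#'
#' Serializes per-panel TSV tables, `summary.json`, per-panel PNG figures,
#' and a single self-contained `report.html` with the figures inlined as
#' base64 images. Re-running on identical inputs yields identical JSON.
#'
#' @param summaries Named list of `sample_summary` objects.
#' @param output_dir Output directory (created).
#' @return `output_dir`, invisibly.
#' @export
write_qc_report <- function(summaries, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  long <- function(field, id_cols) {
    do.call(rbind, lapply(summaries, function(s) {
      df <- s[[field]]
      cbind(tibble(sample = s$sample_id), df)
    }))
  }
  write_tsv(long("phred_histogram"), file.path(output_dir, "phred.tsv"))
  write_tsv(long("length_histogram"),
            file.path(output_dir, "length_distribution.tsv"))
  write_tsv(long("qc_category_counts"), file.path(output_dir, "qc_stats.tsv"))
  write_tsv(long("rna_type_counts"), file.path(output_dir, "rna_types.tsv"))
  write_tsv(long("complexity_curve"), file.path(output_dir, "complexity.tsv"))
  profiles <- lapply(summaries, `[[`, "clade_profile")
  write_tsv(profile_table(profiles, "read_counts"),
            file.path(output_dir, "clade_read_counts.tsv"))
  write_tsv(profile_table(profiles, "unique_sequence_counts"),
            file.path(output_dir, "clade_unique_sequence_counts.tsv"))

  js <- lapply(summaries, function(s) {
    list(sample_id = s$sample_id, species = s$species,
         n_input = s$n_input, n_qc_passed = s$n_qc_passed,
         qc_category_counts = setNames(as.list(s$qc_category_counts$reads),
                                       s$qc_category_counts$category),
         rna_type_counts = setNames(as.list(s$rna_type_counts$reads),
                                    s$rna_type_counts$rna_type),
         distinct_precursors = s$distinct_precursors,
         clade_read_counts = as.list(s$clade_profile$read_counts),
         total_clade_specific_reads =
           s$clade_profile$total_clade_specific_reads,
         flags = s$flags)
  })
  jsonlite::write_json(js, file.path(output_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  figs <- qc_figures(summaries)
  fig_paths <- character(0)
  for (nm in names(figs)) {
    p <- file.path(output_dir, paste0(nm, ".png"))
    ggplot2::ggsave(p, figs[[nm]], width = 7, height = 4.5, dpi = 120)
    fig_paths[nm] <- p
  }
  write_html_report(summaries, fig_paths,
                    file.path(output_dir, "report.html"))
  invisible(output_dir)
}

# The six report panels as ggplot objects.
qc_figures <- function(summaries) {
  phred <- do.call(rbind, lapply(summaries, function(s)
    cbind(tibble(sample = s$sample_id), s$phred_histogram)))
  len <- do.call(rbind, lapply(summaries, function(s)
    cbind(tibble(sample = s$sample_id), s$length_histogram)))
  qcs <- do.call(rbind, lapply(summaries, function(s)
    cbind(tibble(sample = s$sample_id), s$qc_category_counts)))
  rna <- do.call(rbind, lapply(summaries, function(s)
    cbind(tibble(sample = s$sample_id), s$rna_type_counts)))
  cpx <- do.call(rbind, lapply(summaries, function(s)
    cbind(tibble(sample = s$sample_id), s$complexity_curve)))
  profiles <- lapply(summaries, `[[`, "clade_profile")

  list(
    phred_score_distribution =
      ggplot2::ggplot(phred, ggplot2::aes(.data$phred, .data$reads)) +
      ggplot2::geom_col(fill = "#377EB8") +
      ggplot2::facet_wrap(~sample) +
      ggplot2::labs(x = "mean PHRED score", y = "reads") +
      ggplot2::theme_minimal(),
    read_length_distribution =
      ggplot2::ggplot(len, ggplot2::aes(.data$length, .data$reads)) +
      ggplot2::geom_col(fill = "#4DAF4A") +
      ggplot2::facet_wrap(~sample) +
      ggplot2::labs(x = "insert length (nt)", y = "reads") +
      ggplot2::theme_minimal(),
    qc_statistics =
      ggplot2::ggplot(qcs, ggplot2::aes(.data$sample, .data$reads,
                                        fill = .data$category)) +
      ggplot2::geom_col(position = "stack") +
      ggplot2::labs(x = NULL, y = "reads") +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                         hjust = 1)),
    rna_type =
      ggplot2::ggplot(rna, ggplot2::aes(.data$sample, .data$reads,
                                        fill = .data$rna_type)) +
      ggplot2::geom_col(position = "fill") +
      ggplot2::labs(x = NULL, y = "fraction of QC-passed reads") +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                         hjust = 1)),
    mirna_complexity =
      ggplot2::ggplot(cpx, ggplot2::aes(.data$depth,
                                        .data$distinct_precursors,
                                        colour = .data$sample)) +
      ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
      ggplot2::labs(x = "raw read depth", y = "distinct miRNA precursors") +
      ggplot2::theme_minimal(),
    contamination = plot_clade_composition(profiles)
  )
}

# Minimal self-contained HTML: summary table + base64-inlined figures.
write_html_report <- function(summaries, fig_paths, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  rows <- vapply(summaries, function(s) {
    sprintf("<tr><td>%s</td><td>%d</td><td>%d</td><td>%d</td><td>%s</td></tr>",
            esc(s$sample_id), s$n_input, s$n_qc_passed,
            s$distinct_precursors,
            esc(paste(s$flags, collapse = ", ")))
  }, character(1))
  imgs <- vapply(names(fig_paths), function(nm) {
    b64 <- jsonlite::base64_enc(readBin(fig_paths[[nm]], "raw",
                                        file.size(fig_paths[[nm]])))
    sprintf("<h2>%s</h2><img src=\"data:image/png;base64,%s\" width=\"840\"/>",
            esc(gsub("_", " ", nm)), gsub("\n", "", b64))
  }, character(1))
  html <- c(
    "<!DOCTYPE html><html><head><meta charset=\"utf-8\">",
    "<title>small RNA-seq QC report</title>",
    "<style>body{font-family:sans-serif;margin:2em}table{border-collapse:collapse}",
    "td,th{border:1px solid #ccc;padding:4px 8px}</style></head><body>",
    "<h1>small RNA-seq quality control report</h1>",
    "<table><tr><th>sample</th><th>input reads</th><th>QC-passed</th>",
    "<th>distinct precursors</th><th>flags</th></tr>",
    rows, "</table>", imgs, "</body></html>"
  )
  writeLines(html, path)
  invisible(path)
}
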