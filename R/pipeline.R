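# End-to-end per-genome scan and cohort aggregation.

#' Scan one genome for tail-associated lysins
#'
#' Runs the full per-genome pipeline: module partition, tail-module
#' location between the head and lysis modules, TMP-Dit-Tal resolution,
#' motif scanning and lysin classification of every tail-module
#' translation, temperate detection and arrangement classification.
#'
#' @param g a \code{GenomeRecord}.
#' @param library motif library (default \code{\link{tal_motif_library}()}).
#' @param vocabulary module keyword vocabulary.
#' @return list of class \code{GenomeScan}: \code{genome_id},
#'   \code{segments}, \code{layout} (\code{NULL} when not located),
#'   \code{calls} (lysin-call table), \code{hits} (all domain hits with
#'   gene_id), \code{temperate}, \code{arrangement}, \code{stats}.
#' @export
scan_genome <- function(g, library = tal_motif_library(),
                        vocabulary = module_vocabulary()) {
  segments <- partition_modules(g, vocabulary)
  layout <- locate_tail_module(segments)
  calls <- NULL
  hits_all <- list()
  if (!is.null(layout)) {
    layout <- resolve_tmp_dit_tal(layout, g)
    feats <- g$features
    call_rows <- list()
    for (gid in layout$tail_gene_ids) {
      gene <- feats[feats$gene_id == gid, ]
      if (gene$kind != "CDS" || nchar(gene$translation) < 30) next
      hits <- scan_domains(gene$translation, library)
      if (nrow(hits)) {
        hits$gene_id <- gid
        hits_all[[length(hits_all) + 1L]] <- hits
      }
      call_rows[[length(call_rows) + 1L]] <-
        classify_lysin(gene, layout, hits)
    }
    calls <- if (length(call_rows)) do.call(rbind, call_rows) else NULL
  }
  arrangement <- classify_arrangement(
    if (is.null(calls)) data.frame() else calls, layout)
  structure(list(genome_id = g$genome_id,
                 segments = segments,
                 layout = layout,
                 calls = calls,
                 hits = if (length(hits_all)) do.call(rbind, hits_all)
                        else NULL,
                 temperate = detect_temperate(g),
                 arrangement = arrangement,
                 stats = genome_stats(g)),
            class = "GenomeScan")
}

#' @export
print.GenomeScan <- function(x, ...) {
  ncall <- if (is.null(x$calls)) 0L else sum(x$calls$tal_class != "none")
  cat(sprintf("GenomeScan %s: %d segments, arrangement %s, %d lysin call(s)%s\n",
              x$genome_id, nrow(x$segments), x$arrangement, ncall,
              if (x$temperate$is_temperate) ", temperate" else ""))
  invisible(x)
}

#' Scan a cohort of genomes and aggregate landscape tables
#'
#' @param genomes list of \code{GenomeRecord}.
#' @param library motif library.
#' @param vocabulary module keyword vocabulary.
#' @param morphology_hints optional named vector genome_id -> morphology
#'   hint for size grouping.
#' @return list of class \code{CohortScan}: \code{scans} (per-genome
#'   \code{GenomeScan}), \code{calls} (all lysin calls with genome_id),
#'   \code{genome_table} (per-genome layout / arrangement / temperate /
#'   size-group summary), \code{census}, \code{arrangement_tally},
#'   \code{stats} (per-genome statistics).
#' @export
scan_cohort <- function(genomes, library = tal_motif_library(),
                        vocabulary = module_vocabulary(),
                        morphology_hints = NULL) {
  scans <- lapply(genomes, scan_genome, library = library,
                  vocabulary = vocabulary)
  names(scans) <- vapply(scans, `[[`, "", "genome_id")
  calls <- do.call(rbind, Filter(Negate(is.null), lapply(scans, function(s) {
    if (is.null(s$calls)) return(NULL)
    cbind(genome_id = s$genome_id, s$calls, stringsAsFactors = FALSE)
  })))
  rownames(calls) <- NULL
  stats <- do.call(rbind, lapply(scans, `[[`, "stats"))
  rownames(stats) <- NULL
  genome_table <- do.call(rbind, lapply(scans, function(s) {
    lay <- s$layout
    hint <- if (!is.null(morphology_hints) &&
                s$genome_id %in% names(morphology_hints))
      morphology_hints[[s$genome_id]] else "unknown"
    sg <- assign_size_group(s$stats$length_kb, hint)
    data.frame(genome_id = s$genome_id,
               module_order = paste(s$segments$category, collapse = ","),
               tail_located = !is.null(lay),
               tmp_id = if (!is.null(lay)) lay$tmp_id %||% NA_character_
                        else NA_character_,
               dit_id = if (!is.null(lay)) lay$dit_id %||% NA_character_
                        else NA_character_,
               tal_id = if (!is.null(lay)) lay$tal_id %||% NA_character_
                        else NA_character_,
               conforms_tmp_dit_tal = !is.null(lay) &&
                 isTRUE(lay$conforms_tmp_dit_tal),
               estimated_tail_length_nm = if (!is.null(lay))
                 lay$estimated_tail_length_nm %||% NA_real_ else NA_real_,
               arrangement = s$arrangement,
               is_temperate = s$temperate$is_temperate,
               size_group = sg$value,
               stringsAsFactors = FALSE)
  }))
  rownames(genome_table) <- NULL
  arr <- table(factor(genome_table$arrangement,
                      levels = c("taep_in_tal_only", "tmplt_only",
                                 "tmplt_and_taep", "no_tal")))
  with_tal <- sum(arr[c("taep_in_tal_only", "tmplt_only", "tmplt_and_taep")])
  arrangement_tally <- data.frame(
    pattern = names(arr), count = as.integer(arr),
    percent_of_all = round(100 * as.integer(arr) / max(1, sum(arr)), 1),
    percent_of_with_tal = ifelse(
      names(arr) == "no_tal", NA_real_,
      round(100 * as.integer(arr) / max(1, with_tal), 1)),
    stringsAsFactors = FALSE)
  structure(list(scans = scans, calls = calls, genome_table = genome_table,
                 census = census(calls = calls),
                 arrangement_tally = arrangement_tally, stats = stats),
            class = "CohortScan")
}

#' Write cohort scan tables as TSV
#'
#' Emits the module-assignment, layout, lysin-call, census, DA sub-census,
#' arrangement and per-genome statistics tables into a directory.
#'
#' @param cohort_scan result of \code{\link{scan_cohort}}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_scan_tables <- function(cohort_scan, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  modules <- do.call(rbind, lapply(cohort_scan$scans, function(s) {
    seg <- s$segments
    do.call(rbind, lapply(seq_len(nrow(seg)), function(k)
      data.frame(genome_id = s$genome_id,
                 gene_id = unlist(seg$gene_ids[k]),
                 category = seg$category[k],
                 segment_index = seg$segment_index[k],
                 stringsAsFactors = FALSE)))
  }))
  write_tsv(modules, file.path(dir, "module_assignments.tsv"))
  write_tsv(cohort_scan$genome_table, file.path(dir, "genome_table.tsv"))
  if (!is.null(cohort_scan$calls))
    write_tsv(cohort_scan$calls, file.path(dir, "lysin_calls.tsv"))
  write_tsv(cohort_scan$census$table, file.path(dir, "census.tsv"))
  if (!is.null(cohort_scan$census$da_table))
    write_tsv(cohort_scan$census$da_table, file.path(dir, "da_census.tsv"))
  write_tsv(cohort_scan$arrangement_tally,
            file.path(dir, "arrangements.tsv"))
  write_tsv(cohort_scan$stats, file.path(dir, "genome_stats.tsv"))
  invisible(dir)
}
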