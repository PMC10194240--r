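# Ground-truth recovery rates for a simulated cohort: fraction of genomes
# (or planted lysin genes) on which the pipeline output agrees with the
# generator's ground truth, per aspect.
recovery_rates <- function(cohort) {
  scans <- lapply(cohort$genomes, function(g)
    suppressMessages(scan_genome(g)))
  names(scans) <- vapply(scans, `[[`, "", "genome_id")
  tg <- cohort$truth_genomes
  ok_order <- ok_tmp <- ok_dit <- ok_tal <- ok_arr <- ok_temp <-
    logical(nrow(tg))
  for (i in seq_len(nrow(tg))) {
    s <- scans[[tg$genome_id[i]]]
    lay <- s$layout
    ok_order[i] <- identical(paste(s$segments$category, collapse = ","),
                             tg$module_order[i])
    get_id <- function(x) if (is.null(lay) || is.null(lay[[x]]))
      NA_character_ else lay[[x]]
    ok_tmp[i] <- identical(get_id("tmp_id"), tg$tmp_id[i])
    ok_dit[i] <- identical(get_id("dit_id"), tg$dit_id[i])
    ok_tal[i] <- identical(get_id("tal_id"), tg$tal_id[i])
    ok_arr[i] <- identical(s$arrangement, tg$arrangement[i])
    ok_temp[i] <- identical(s$temperate$is_temperate, tg$is_temperate[i]) &&
      identical(s$temperate$has_integrase, tg$has_integrase[i]) &&
      identical(s$temperate$has_repressor, tg$has_repressor[i])
  }
  # per-planted-gene class / DA / LT-family agreement
  tge <- cohort$truth_genes[cohort$truth_genes$tal_class != "none", ,
                            drop = FALSE]
  ok_class <- ok_da <- ok_fam <- logical(nrow(tge))
  for (j in seq_len(nrow(tge))) {
    s <- scans[[tge$genome_id[j]]]
    cl <- if (is.null(s$calls)) NULL
          else s$calls[s$calls$gene_id == tge$gene_id[j], , drop = FALSE]
    if (is.null(cl) || nrow(cl) != 1) next
    ok_class[j] <- identical(cl$tal_class, tge$tal_class[j])
    ok_da[j] <- identical(cl$da_group, tge$da_group[j])
    ok_fam[j] <- identical(cl$lt_family, tge$lt_family[j])
  }
  list(module_order = mean(ok_order),
       tmp = mean(ok_tmp), dit = mean(ok_dit), tal = mean(ok_tal),
       arrangement = mean(ok_arr), temperate = mean(ok_temp),
       tal_class = mean(ok_class), da_group = mean(ok_da),
       lt_family = mean(ok_fam),
       scans = scans)
}
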