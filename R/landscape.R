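# Cohort-level landscape summaries.

#' Assign a genome-size group
#'
#' Size groups follow the observed genome-size/morphotype correlation:
#' genomes under 30.5 kb are podovirus-sized; 31-43 kb is siphovirus
#' group 1; 55-86 kb is siphovirus group 2; 130 kb and above is
#' myovirus-sized. The gaps between the ranges (30.5-31, 43-55, 86-130 kb)
#' are left unclassified rather than snapped to the nearest group. A known
#' morphology hint dominates the size rules, which handles documented
#' exceptions such as a 16.9 kb siphovirus: with a siphovirus hint, genomes
#' up to 49 kb go to group 1 and larger ones to group 2.
#'
#' @param length_kb genome length in kb (> 0).
#' @param morphology_hint one of \code{"podovirus", "siphovirus",
#'   "myovirus", "unknown"}.
#' @return list with \code{value} (one of \code{podo_small, sipho_group1,
#'   sipho_group2, myo_large, unclassified}) and \code{morphology_hint}.
#' @export
assign_size_group <- function(length_kb, morphology_hint = "unknown") {
  stopifnot(length_kb > 0,
            morphology_hint %in% c("podovirus", "siphovirus", "myovirus",
                                   "unknown"))
  value <- if (morphology_hint == "podovirus") "podo_small"
  else if (morphology_hint == "myovirus") "myo_large"
  else if (morphology_hint == "siphovirus") {
    if (length_kb <= 49) "sipho_group1" else "sipho_group2"
  } else {
    if (length_kb < 30.5) "podo_small"
    else if (length_kb >= 31 && length_kb <= 43) "sipho_group1"
    else if (length_kb >= 55 && length_kb <= 86) "sipho_group2"
    else if (length_kb >= 130) "myo_large"
    else "unclassified"
  }
  list(value = value, morphology_hint = morphology_hint)
}

#' Classify the lysin arrangement pattern of one genome
#'
#' \code{tmplt_and_taep} when both a TMP-LT call and a TAEP call exist;
#' \code{taep_in_tal_only} for TAEP without TMP-LT; \code{tmplt_only} for
#' TMP-LT without TAEP; otherwise \code{no_tal}.
#'
#' @param calls \code{data.frame} of lysin calls for one genome.
#' @param layout the genome's \code{TailModuleLayout} (may be \code{NULL};
#'   a genome without a located tail module is \code{no_tal}).
#' @return pattern string.
#' @export
classify_arrangement <- function(calls, layout = NULL) {
  if (is.null(layout) || is.null(calls) || nrow(calls) == 0) return("no_tal")
  has_taep <- any(calls$tal_class == "TAEP")
  has_lt <- any(calls$tal_class == "TMP_LT")
  if (has_taep && has_lt) "tmplt_and_taep"
  else if (has_taep) "taep_in_tal_only"
  else if (has_lt) "tmplt_only"
  else "no_tal"
}

#' Lysin class census with printed-precision percentages
#'
#' One row per lysin class with count and percentage of the classified
#' total. Percentages are printed at one decimal using round-half-even,
#' which reproduces published census tables of this kind (e.g. 34/544 =
#' 6.25\% prints as 6.2). Accepts either per-gene calls or precomputed
#' class counts.
#'
#' @param calls \code{data.frame} of lysin calls (rows with
#'   \code{tal_class == "none"} are ignored), or \code{NULL}.
#' @param counts named numeric vector of per-class counts, used instead of
#'   \code{calls} when supplied.
#' @return list of class \code{LandscapeCensus}: \code{table} (class,
#'   count, percent), \code{total_sequences}, \code{da_table} (DA-group
#'   sub-tallies, when calls are supplied).
#' @export
census <- function(calls = NULL, counts = NULL) {
  da_table <- NULL
  if (is.null(counts)) {
    if (is.null(calls))
      calls <- data.frame(tal_class = character(), da_group = character())
    cl <- calls[calls$tal_class %in% TAL_CLASSES, , drop = FALSE]
    counts <- table(factor(cl$tal_class, levels = TAL_CLASSES))
    counts <- setNames(as.numeric(counts), names(counts))
    counts <- counts[counts > 0]
    if (nrow(cl)) {
      da <- table(cl$tal_class, cl$da_group)
      da_table <- as.data.frame(da, stringsAsFactors = FALSE)
      names(da_table) <- c("tal_class", "da_group", "count")
      da_table <- da_table[da_table$count > 0, , drop = FALSE]
      rownames(da_table) <- NULL
    }
  }
  total <- sum(counts)
  tab <- data.frame(tal_class = names(counts),
                    count = as.numeric(counts),
                    percent = if (total > 0)
                      round(100 * as.numeric(counts) / total, 1)
                    else rep(NA_real_, length(counts)),
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(table = tab, total_sequences = total, da_table = da_table),
            class = "LandscapeCensus")
}

#' @export
print.LandscapeCensus <- function(x, ...) {
  cat(sprintf("Lysin census: %d classified sequences\n", x$total_sequences))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Cohort bookkeeping totals
#'
#' Sums per-source genome counts into prophage and overall totals, e.g.
#' 93 + 313 prophages from two host species = 406, plus 100 phage genomes
#' = 506 genomes examined.
#'
#' @param n_phage number of phage genomes.
#' @param n_prophage numeric vector of prophage counts (e.g. per host
#'   species).
#' @return list with \code{prophage_total} and \code{genomes_examined}.
#' @export
cohort_totals <- function(n_phage, n_prophage) {
  list(prophage_total = sum(n_prophage),
       genomes_examined = n_phage + sum(n_prophage))
}

#' Spearman correlations among per-genome statistics
#'
#' Rank correlation of genome size against ORF count, tRNA count and GC
#' percent, each with a seeded two-sided permutation p-value. A constant
#' variable yields an undefined coefficient with the reason recorded.
#'
#' @param stats \code{data.frame} with columns \code{length_kb, orf_count,
#'   trna_count, gc_percent} (>= 3 rows).
#' @param n_perm number of permutations (default 10000).
#' @param seed RNG seed for the permutation null.
#' @return \code{data.frame}: \code{pair, rho, p_value, n, note}.
#' @export
correlate_genome_stats <- function(stats, n_perm = 10000, seed = 1) {
  if (nrow(stats) < 3) stop("need at least 3 genomes")
  pairs <- list(c("length_kb", "orf_count"),
                c("length_kb", "trna_count"),
                c("length_kb", "gc_percent"))
  rows <- lapply(pairs, function(pr) {
    x <- stats[[pr[1]]]; y <- stats[[pr[2]]]
    keep <- !is.na(x) & !is.na(y)
    x <- x[keep]; y <- y[keep]
    nm <- paste(pr, collapse = "~")
    if (length(x) < 3 || length(unique(x)) == 1 || length(unique(y)) == 1) {
      return(data.frame(pair = nm, rho = NA_real_, p_value = NA_real_,
                        n = length(x), note = "undefined: constant variable",
                        stringsAsFactors = FALSE))
    }
    rho <- cor(x, y, method = "spearman")
    perm <- with_seed(seed, vapply(seq_len(n_perm), function(i)
      cor(x, sample(y), method = "spearman"), numeric(1)))
    p <- (1 + sum(abs(perm) >= abs(rho) - 1e-12)) / (n_perm + 1)
    data.frame(pair = nm, rho = rho, p_value = p, n = length(x), note = "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
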