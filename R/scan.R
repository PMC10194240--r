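# Motif scanning.

# score every window of `protein` against one motif: fraction of positions
# whose residue is in the allowed set. Vectorised over window starts.
window_scores <- function(protein, motif) {
  p <- chars(protein)
  L <- length(motif$pattern)
  n <- length(p) - L + 1L
  if (n < 1L) return(numeric(0))
  hitsum <- numeric(n)
  for (i in seq_len(L)) {
    hitsum <- hitsum + (p[i:(i + n - 1L)] %in% motif$pattern[[i]])
  }
  hitsum / L
}

#' Scan a protein against a motif library
#'
#' Every window whose match score reaches the motif's \code{min_score}
#' yields a hit; overlapping hits of the same motif are merged, keeping the
#' best-scoring window (ties go to the leftmost). \code{region_ok} is
#' \code{TRUE} when the hit midpoint falls in the motif's declared region of
#' the protein: first third for \code{N_terminal}, middle third for
#' \code{central}, last third for \code{C_terminal}; \code{any} always
#' passes. Coordinates are 0-based half-open in amino acids.
#'
#' @param protein amino-acid string (length >= 30).
#' @param library list of \code{MotifDefinition}
#'   (default \code{\link{tal_motif_library}()}).
#' @return \code{data.frame}: \code{motif_name, start_aa, end_aa, score,
#'   region_ok}, ordered by \code{start_aa}.
#' @export
scan_domains <- function(protein, library = tal_motif_library()) {
  if (length(library) == 0) stop("empty motif library")
  if (nchar(protein) < 30) stop("protein shorter than 30 aa")
  plen <- nchar(protein)
  out <- list()
  for (motif in library) {
    s <- window_scores(protein, motif)
    ok <- which(s >= motif$min_score)
    if (!length(ok)) next
    L <- length(motif$pattern)
    # merge runs of overlapping windows, keep the best (leftmost on ties)
    grp <- cumsum(c(TRUE, diff(ok) >= L))
    for (g in split(ok, grp)) {
      best <- g[which(s[g] == max(s[g]))[1]]
      start_aa <- best - 1L
      end_aa <- start_aa + L
      mid <- (start_aa + end_aa) / 2
      region_ok <- switch(motif$region,
        any = TRUE,
        N_terminal = mid <= plen / 3,
        central = mid > plen / 3 && mid <= 2 * plen / 3,
        C_terminal = mid > 2 * plen / 3)
      out[[length(out) + 1L]] <- data.frame(
        motif_name = motif$name, start_aa = start_aa, end_aa = end_aa,
        score = s[best], region_ok = region_ok, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(motif_name = character(), start_aa = integer(),
                      end_aa = integer(), score = numeric(),
                      region_ok = logical(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$start_aa, res$motif_name), , drop = FALSE]
}

#' Read an externally computed domain-hit table
#'
#' Documented TSV hook that bypasses the packaged scanner: columns
#' \code{gene_id, motif_name, start_aa, end_aa, score} (0-based half-open
#' amino-acid coordinates). Region checks are re-derived from the packaged
#' motif regions and the supplied protein lengths.
#'
#' @param path TSV path.
#' @param protein_lengths named integer vector (gene_id -> protein length)
#'   used to recompute \code{region_ok}; hits for unknown genes keep
#'   \code{region_ok = NA}.
#' @param library motif library supplying region declarations.
#' @return \code{data.frame} with the \code{scan_domains} columns plus
#'   \code{gene_id}.
#' @export
read_domain_hits <- function(path, protein_lengths = NULL,
                             library = tal_motif_library()) {
  tab <- read_tsv(path)
  need <- c("gene_id", "motif_name", "start_aa", "end_aa", "score")
  if (!all(need %in% names(tab)))
    stop("domain-hit table must have columns: ", paste(need, collapse = ", "))
  regions <- vapply(library, function(m) m$region, "")
  names(regions) <- vapply(library, function(m) m$name, "")
  tab$region_ok <- NA
  if (!is.null(protein_lengths)) {
    plen <- protein_lengths[tab$gene_id]
    mid <- (tab$start_aa + tab$end_aa) / 2
    reg <- regions[tab$motif_name]
    tab$region_ok <- ifelse(is.na(plen) | is.na(reg), NA,
      ifelse(reg == "any", TRUE,
      ifelse(reg == "N_terminal", mid <= plen / 3,
      ifelse(reg == "central", mid > plen / 3 & mid <= 2 * plen / 3,
             mid > 2 * plen / 3))))
  }
  tab
}
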