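# Consensus profiles and per-column information content.

#' Build a consensus profile from aligned sequences
#'
#' Per-column residue frequencies are computed over the 20 amino acids plus
#' the gap symbol (frequencies sum to 1). Information content per column is
#' \code{log2(20)} minus the Shannon entropy of the gap-excluded residue
#' distribution (uniform background, as in standard sequence logos), so it
#' is bounded by [0, log2(20)]. Conserved positions are columns whose
#' gap-excluded majority residue reaches \code{threshold}; gap-majority
#' columns (> 50\% gaps) are excluded to avoid ragged-end artefacts.
#'
#' @param aligned_sequences character vector (>= 2) of equal-length gapped
#'   amino-acid strings.
#' @param class_name label stored on the profile.
#' @param threshold conservation threshold (default 0.9).
#' @return object of class \code{ConsensusProfile}: \code{class_name},
#'   \code{columns} (21 x L frequency matrix, rows AA20 + "-"),
#'   \code{info_bits}, \code{consensus} (argmax residue per column, ties
#'   lexicographic, "-" for all-gap columns), \code{conserved_positions}
#'   (data.frame: column, residue, frequency), \code{n_sequences}.
#' @export
build_profile <- function(aligned_sequences, class_name = "",
                          threshold = 0.9) {
  if (length(aligned_sequences) < 2) stop("need at least 2 sequences")
  L <- unique(nchar(aligned_sequences))
  if (length(L) != 1) stop("aligned sequences must have equal length")
  mat <- do.call(rbind, lapply(aligned_sequences, chars))
  symbols <- c(AA20, "-")
  freq <- matrix(0, length(symbols), L, dimnames = list(symbols, NULL))
  info <- numeric(L)
  consensus <- character(L)
  cons_rows <- list()
  for (j in seq_len(L)) {
    col <- mat[, j]
    tab <- table(factor(col, levels = symbols))
    freq[, j] <- tab / length(col)
    res <- tab[AA20]
    nres <- sum(res)
    if (nres == 0) {
      info[j] <- 0
      consensus[j] <- "-"
      next
    }
    p <- res[res > 0] / nres
    info[j] <- log2(20) + sum(p * log2(p))
    best <- AA20[which(res == max(res))]  # ties -> lexicographic (AA20 sorted)
    consensus[j] <- best[1]
    maxfreq <- max(res) / nres
    gapfrac <- freq["-", j]
    if (maxfreq >= threshold && gapfrac <= 0.5)
      cons_rows[[length(cons_rows) + 1L]] <-
        data.frame(column = j, residue = best[1], frequency = maxfreq)
  }
  conserved <- if (length(cons_rows)) do.call(rbind, cons_rows)
               else data.frame(column = integer(), residue = character(),
                               frequency = numeric())
  structure(list(class_name = class_name, columns = freq,
                 info_bits = info, consensus = paste(consensus, collapse = ""),
                 conserved_positions = conserved,
                 n_sequences = length(aligned_sequences)),
            class = "ConsensusProfile")
}

#' @export
print.ConsensusProfile <- function(x, ...) {
  cat(sprintf("ConsensusProfile '%s': %d columns, %d sequences, %d conserved positions\n",
              x$class_name, ncol(x$columns), x$n_sequences,
              nrow(x$conserved_positions)))
  invisible(x)
}

#' Write a consensus profile as TSV
#' @param profile a \code{ConsensusProfile}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  tab <- as.data.frame(t(profile$columns))
  names(tab) <- c(AA20, "gap")
  tab <- cbind(column = seq_len(nrow(tab)), tab,
               bits = profile$info_bits,
               consensus = chars(profile$consensus))
  write_tsv(tab, path)
}

#' Locate the four lytic-transglycosylase family motifs in a consensus
#'
#' Scans a GH23-class consensus N-to-C for: motif I, the catalytic E-S
#' dipeptide; motif II, the GxxQ core (G-l-M-Q preferred); motif III,
#' A/G-Y-N; motif IV, a conserved Y flanked by a hydrophobic residue. Each
#' motif is searched downstream of the previous one.
#'
#' @param profile a \code{ConsensusProfile} built from >= 2 GH23 members.
#' @return \code{data.frame}: \code{motif} (I-IV), \code{start, end}
#'   (1-based columns, NA when unmatched), \code{matched}.
#' @export
locate_family_motifs <- function(profile) {
  cons <- chars(profile$consensus)
  L <- length(cons)
  res <- data.frame(motif = c("I", "II", "III", "IV"),
                    start = NA_integer_, end = NA_integer_,
                    matched = FALSE, stringsAsFactors = FALSE)
  pos <- 0L
  # motif I: E-S
  i <- find_first(seq_len(L - 1), function(k)
    cons[k] == "E" && cons[k + 1] == "S", after = pos)
  if (!is.na(i)) { res[1, 2:4] <- list(i, i + 1L, TRUE); pos <- i + 1L }
  # motif II: G..Q
  i <- find_first(seq_len(L - 3), function(k)
    cons[k] == "G" && cons[k + 3] == "Q", after = pos)
  if (!is.na(i)) { res[2, 2:4] <- list(i, i + 3L, TRUE); pos <- i + 3L }
  # motif III: [AG]YN
  i <- find_first(seq_len(L - 2), function(k)
    cons[k] %in% c("A", "G") && cons[k + 1] == "Y" && cons[k + 2] == "N",
    after = pos)
  if (!is.na(i)) { res[3, 2:4] <- list(i, i + 2L, TRUE); pos <- i + 2L }
  # motif IV: Y flanked by a hydrophobic residue
  i <- find_first(2:(L - 1), function(k)
    cons[k] == "Y" && (cons[k - 1] %in% HYDROPHOBIC ||
                       cons[k + 1] %in% HYDROPHOBIC), after = pos)
  if (!is.na(i)) res[4, 2:4] <- list(i - 1L, i + 1L, TRUE)
  res
}

find_first <- function(candidates, pred, after = 0L) {
  for (k in candidates) if (k > after && pred(k)) return(k)
  NA_integer_
}

# ---- packaged reference members and profiles ---------------------------

#' Packaged reference members of a lysin class
#'
#' Deterministic synthetic member sets for the packaged classes: the class
#' consensus plus variants carrying fixed substitutions away from the
#' functional columns. These stand in for curated member alignments (which
#' would require external database access) and are labelled synthetic.
#'
#' @param class_name \code{"TMP_LT"}, \code{"TMP_LT_1A"} or \code{"GDPD"}.
#' @param n number of members.
#' @return named character vector of equal-length sequences (gap-free, so
#'   already aligned).
#' @export
reference_members <- function(class_name = c("TMP_LT", "TMP_LT_1A", "GDPD"),
                              n = 8) {
  class_name <- match.arg(class_name)
  cons <- switch(class_name,
                 TMP_LT = GH23_1P_CONSENSUS,
                 TMP_LT_1A = GH23_1A_CONSENSUS,
                 GDPD = GDPD_CONSENSUS)
  protected <- switch(class_name,
    TMP_LT = , TMP_LT_1A = unique(unlist(lapply(GH23_COLUMNS, function(x) {
      if (length(x) == 2 && x[2] > x[1]) seq(x[1], x[2]) else x
    }))),
    GDPD = unlist(GDPD_COLUMNS))
  with_seed(2023, {
    members <- vapply(seq_len(n), function(i) {
      s <- chars(cons)
      if (i > 1) {
        free <- setdiff(seq_along(s), protected)
        k <- sample(free, 3)
        s[k] <- vapply(s[k], function(orig)
          sample(setdiff(AA20, orig), 1), "")
      }
      paste(s, collapse = "")
    }, "")
    setNames(members, sprintf("%s_ref%02d", class_name, seq_len(n)))
  })
}

#' Packaged reference profile of a lysin class
#' @inheritParams reference_members
#' @return a \code{ConsensusProfile} over the packaged members.
#' @export
reference_profile <- function(class_name = c("TMP_LT", "TMP_LT_1A", "GDPD")) {
  class_name <- match.arg(class_name)
  build_profile(reference_members(class_name), class_name = class_name)
}
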