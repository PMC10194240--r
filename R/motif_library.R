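# Packaged motif library.
#
# Live Pfam/CDD scanning is out of scope for this package: domain detection
# runs against packaged position-constrained patterns. The GH23 lytic
# transglycosylase and GDPD patterns encode the class-level sequence
# features reported for these enzymes (catalytic E-S of motif I, the GxxQ
# core of motif II, the A/G-Y-N of motif III, the conserved flanked Y of
# motif IV, the six extra family-1P positions; and the GDPD H/H catalytic
# plus E/E/D metal-binding residues). The remaining domains have no printed
# signature and are shipped as synthetic placeholder patterns; externally
# computed domain-hit tables (e.g. from a profile-HMM scan) can be supplied
# instead via `read_domain_hits()`.

# GH23 lytic transglycosylase reference consensus, family 1P frame
# (80 columns, 1-based). Functional columns:
#   26 E, 27 S           motif I   (catalytic glutamate proton donor)
#   36 G, 37 L, 38 M, 39 Q motif II (GxxQ core)
#   49 A, 50 Y, 51 N     motif III
#   62 V, 63 Y, 64 L     motif IV  (Y flanked by hydrophobic residues)
#   46 T, 47 F, 54 G, 59 I, 67 L, 68 A  family-1P-specific positions
GH23_1P_CONSENSUS <- paste0(
  "KDNRPTHWKDNRPTHWKDNRPTHWK", "ES", "KPDTRNHW", "GLMQ", "DKPTRN",
  "TF", "K", "AYN", "DP", "G", "RTKW", "I", "DN", "VYL", "PT", "LA",
  "KDNRPTHWKDNR")

# Family 1A variant: motifs I-IV intact, 1P-specific positions absent.
GH23_1A_CONSENSUS <- local({
  s <- strsplit(GH23_1P_CONSENSUS, "", fixed = TRUE)[[1]]
  s[c(46, 47, 54, 59, 67, 68)] <- c("K", "R", "N", "T", "N", "D")
  paste(s, collapse = "")
})

GH23_COLUMNS <- list(
  catalytic = 26L,
  motif_I = c(26L, 27L), motif_II = c(36L, 39L),
  motif_III = c(49L, 51L), motif_IV = c(62L, 64L),
  family_1p = c(T = 46L, F = 47L, G = 54L, I = 59L, L = 67L, A = 68L))

# GDPD reference consensus (60 columns). Functional columns:
#   10 H, 28 H  catalytic histidines (general acid / general base)
#   17 E, 40 E, 45 D  divalent-metal-binding residues
GDPD_CONSENSUS <- paste0(
  "KNRPTWAVL", "H", "IMFCSG", "E", "QKNRPTWAVL", "H", "IMFCSGQKNRP",
  "E", "TWAV", "D", "LIMFCSGQKNRPTWA")

GDPD_COLUMNS <- list(catalytic = c(10L, 28L), metal = c(17L, 40L, 45L))

# Synthetic placeholder consensus patterns for domains without a printed
# signature (fixed arbitrary sequences, one per domain).
PLACEHOLDER_CONSENSUS <- c(
  endopeptidase           = "VILKSADTRCFLDADSCEVLAALRLWRY",
  lysozyme                = "LDNATYRWCMIYDFHGEHSIVPADNGWN",
  CHAP                    = "FRDYYLQEVRQCVVVKYNLHIFYYKIIY",
  M23_peptidase           = "DAGVMLGGKKIQEATDVTTTMEQWVFKF",
  amidase                 = "RRHGTCEAHHLPWVQKCIIMEMDFYTSK",
  endosialidase_chaperone = "IFNGDERLDWGRQGVLCQMPGKRATHYN",
  NLPC_P60                = "MCQMACEDYTSFQKEKEHRCYLASKVLK",
  membrane                = "KLYHKKCLKGCMPMPPEKLPMMKWINES",
  baseplate_upper         = "LTRLGECNQINEYMQSGNKQHLCKDRAP",
  pectinesterase          = "EWGSSIHACSCPDKQMHKAEWDPIFRGV")

#' Define one motif
#'
#' A motif is an ordered list of per-position allowed-residue sets with a
#' region constraint and a minimum window score (fraction of positions whose
#' residue is allowed).
#'
#' @param name motif name.
#' @param consensus consensus string; each position's default allowed set is
#'   its consensus residue.
#' @param region one of \code{N_terminal, C_terminal, central, any}:
#'   fractional thirds of the protein in which the hit midpoint must lie for
#'   \code{region_ok}.
#' @param min_score minimum fraction of matching positions for a hit.
#' @param allowed optional named list overriding the allowed set at given
#'   1-based positions, e.g. \code{list(`49` = c("A","G"))}.
#' @return object of class \code{MotifDefinition}.
#' @export
motif_definition <- function(name, consensus, region = "any",
                             min_score = 0.6, allowed = list()) {
  stopifnot(region %in% c("N_terminal", "C_terminal", "central", "any"),
            nchar(consensus) > 0)
  pattern <- as.list(chars(consensus))
  for (pos in names(allowed)) pattern[[as.integer(pos)]] <- allowed[[pos]]
  structure(list(name = name, consensus = consensus, pattern = pattern,
                 region = region, min_score = min_score),
            class = "MotifDefinition")
}

#' The packaged tail-associated-lysin motif library
#'
#' Twelve motifs covering the five lysin classes and their auxiliary
#' domains. Region constraints follow the reported placements: the TAEP
#' endopeptidase domain is N-terminal, the TMP lytic transglycosylase
#' C-terminal, the pectinesterase central, and the M23 peptidase, amidase
#' and baseplate-upper domains carry the placements used by the
#' domain-architecture rules. The default \code{min_score} of 0.6 was fixed
#' by a seeded shuffle-null calibration (1,000 length-matched decoys per
#' motif; see \code{\link{calibrate_min_score}}), giving a per-protein false
#' positive rate below 1\%.
#'
#' @return named list of \code{MotifDefinition}.
#' @export
tal_motif_library <- function() {
  hyd <- HYDROPHOBIC
  list(
    endopeptidase = motif_definition("endopeptidase",
      PLACEHOLDER_CONSENSUS[["endopeptidase"]], region = "N_terminal"),
    lysozyme = motif_definition("lysozyme",
      PLACEHOLDER_CONSENSUS[["lysozyme"]]),
    CHAP = motif_definition("CHAP", PLACEHOLDER_CONSENSUS[["CHAP"]]),
    M23_peptidase = motif_definition("M23_peptidase",
      PLACEHOLDER_CONSENSUS[["M23_peptidase"]], region = "C_terminal"),
    amidase = motif_definition("amidase",
      PLACEHOLDER_CONSENSUS[["amidase"]], region = "C_terminal"),
    endosialidase_chaperone = motif_definition("endosialidase_chaperone",
      PLACEHOLDER_CONSENSUS[["endosialidase_chaperone"]]),
    NLPC_P60 = motif_definition("NLPC_P60",
      PLACEHOLDER_CONSENSUS[["NLPC_P60"]]),
    GH23_LT = motif_definition("GH23_LT", GH23_1P_CONSENSUS,
      region = "C_terminal",
      allowed = list(`49` = c("A", "G"),
                     `62` = hyd, `64` = hyd)),
    GDPD = motif_definition("GDPD", GDPD_CONSENSUS),
    membrane = motif_definition("membrane",
      PLACEHOLDER_CONSENSUS[["membrane"]]),
    baseplate_upper = motif_definition("baseplate_upper",
      PLACEHOLDER_CONSENSUS[["baseplate_upper"]], region = "N_terminal"),
    pectinesterase = motif_definition("pectinesterase",
      PLACEHOLDER_CONSENSUS[["pectinesterase"]], region = "central")
  )
}

#' Class-specific conserved-residue rules
#'
#' Column indices refer to the class's packaged reference alignment frame
#' (the consensus above), not to absolute protein coordinates.
#'
#' @return named list: class -> data.frame(residue, column).
#' @export
residue_rules <- function() {
  list(
    TMP_LT = data.frame(residue = "E", column = GH23_COLUMNS$catalytic,
                        role = "catalytic proton donor",
                        stringsAsFactors = FALSE),
    GDPD = data.frame(
      residue = c("H", "H", "E", "E", "D"),
      column = c(GDPD_COLUMNS$catalytic, GDPD_COLUMNS$metal),
      role = c("catalytic", "catalytic", "metal-binding", "metal-binding",
               "metal-binding"),
      stringsAsFactors = FALSE)
  )
}

#' Calibrate a motif's score threshold on a shuffle null
#'
#' Scores \code{n_decoys} length-matched shuffled decoy proteins and returns
#' the null best-window score distribution plus the threshold at the given
#' false-positive quantile. Used to fix the packaged \code{min_score}
#' defaults; exposed so users adding motifs can recalibrate.
#'
#' @param motif a \code{MotifDefinition}.
#' @param decoy_length decoy protein length.
#' @param n_decoys number of shuffled decoys.
#' @param fpr target false-positive rate.
#' @param seed RNG seed.
#' @return list with \code{null_scores} (best window score per decoy) and
#'   \code{threshold} (the \code{1 - fpr} null quantile).
#' @export
calibrate_min_score <- function(motif, decoy_length = 500, n_decoys = 1000,
                                fpr = 0.01, seed = 1) {
  template <- chars(paste(rep(motif$consensus, ceiling(decoy_length /
                                  nchar(motif$consensus))), collapse = ""))
  template <- template[seq_len(decoy_length)]
  best <- with_seed(seed, vapply(seq_len(n_decoys), function(i) {
    decoy <- paste(sample(template), collapse = "")
    s <- window_scores(decoy, motif)
    if (length(s)) max(s) else 0
  }, numeric(1)))
  list(null_scores = best,
       threshold = as.numeric(stats::quantile(best, 1 - fpr, names = FALSE)))
}
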