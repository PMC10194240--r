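# Lysin classification: class priority, domain-architecture (DA) groups,
# catalytic-residue verification, lytic-transglycosylase families.

TAL_CLASSES <- c("TAEP", "TMP_LT", "NLPC_P60", "GDPD", "PECTINESTERASE")

# motif -> class evidence used by the class priority
CLASS_MOTIF <- c(endopeptidase = "TAEP", GH23_LT = "TMP_LT",
                 NLPC_P60 = "NLPC_P60", GDPD = "GDPD",
                 pectinesterase = "PECTINESTERASE")

#' Assign the domain-architecture group of a TAEP protein
#'
#' All TAEP architectures carry an N-terminal phage endopeptidase domain.
#' DA1 has the endopeptidase only; DA2 adds lysozyme + CHAP; DA3 adds
#' lysozyme + a C-terminal M23 peptidase; DA4 adds lysozyme + a C-terminal
#' amidase; DA5 adds an endosialidase-chaperone domain. Other accessory
#' combinations return \code{"TAEP-DA-other"}. Hits from other lysin
#' classes (e.g. a co-occurring GDPD) do not affect the TAEP architecture.
#'
#' @param hits \code{data.frame} from \code{\link{scan_domains}}.
#' @param protein_length protein length in aa (for region checks).
#' @return DA group string.
#' @export
assign_taep_da <- function(hits, protein_length) {
  if (!"endopeptidase" %in% hits$motif_name)
    stop("assign_taep_da requires an endopeptidase hit")
  acc <- sort(unique(intersect(hits$motif_name,
    c("lysozyme", "CHAP", "M23_peptidase", "amidase",
      "endosialidase_chaperone"))))
  same <- function(x, y) length(x) == length(y) && all(x == y)
  if (length(acc) == 0) return("TAEP-DA1")
  if (same(acc, c("CHAP", "lysozyme"))) return("TAEP-DA2")
  if (same(acc, c("M23_peptidase", "lysozyme")) ||
      same(acc, sort(c("M23_peptidase", "lysozyme")))) return("TAEP-DA3")
  if (same(acc, sort(c("amidase", "lysozyme")))) return("TAEP-DA4")
  if (same(acc, "endosialidase_chaperone")) return("TAEP-DA5")
  "TAEP-DA-other"
}

#' Assign the domain-architecture group of an NLPC/P60 protein
#'
#' DA5 adds an M23 peptidase domain, DA2 adds a lysozyme domain; an
#' NLPC/P60 domain alone is DA4 when it sits in the N-terminal third of the
#' protein and DA1 otherwise.
#'
#' @param hits \code{data.frame} from \code{\link{scan_domains}}.
#' @param protein_length protein length in aa.
#' @return DA group string.
#' @export
assign_nlpc_da <- function(hits, protein_length = NULL) {
  nl <- hits[hits$motif_name == "NLPC_P60", , drop = FALSE]
  if (nrow(nl) == 0) stop("assign_nlpc_da requires an NLPC_P60 hit")
  has_m23 <- "M23_peptidase" %in% hits$motif_name
  has_lyz <- "lysozyme" %in% hits$motif_name
  if (has_m23 && !has_lyz) return("NLPC-DA5")
  if (has_lyz && !has_m23) return("NLPC-DA2")
  if (!has_m23 && !has_lyz) {
    if (!is.null(protein_length)) {
      mid <- (nl$start_aa[1] + nl$end_aa[1]) / 2
      if (mid <= protein_length / 3) return("NLPC-DA4")
    }
    return("NLPC-DA1")
  }
  "NLPC-DA-other"
}

#' Assign the domain-architecture group of a GDPD protein
#'
#' DA1 is a lone GDPD domain; DA2 adds a predicted membrane domain; DA3 is
#' an N-terminal baseplate-upper protein domain with the GDPD domain at the
#' C terminus.
#'
#' @param hits \code{data.frame} from \code{\link{scan_domains}}.
#' @param protein_length protein length in aa.
#' @return DA group string.
#' @export
assign_gdpd_da <- function(hits, protein_length = NULL) {
  gd <- hits[hits$motif_name == "GDPD", , drop = FALSE]
  if (nrow(gd) == 0) stop("assign_gdpd_da requires a GDPD hit")
  has_mem <- "membrane" %in% hits$motif_name
  has_bpu <- "baseplate_upper" %in% hits$motif_name
  if (has_bpu && !has_mem) return("GDPD-DA3")
  if (has_mem && !has_bpu) return("GDPD-DA2")
  if (!has_mem && !has_bpu) return("GDPD-DA1")
  "GDPD-DA-other"
}

# ---- profile-column mapping --------------------------------------------

# Align a class reference consensus inside a protein (consensus global,
# protein local) and return the protein residue at each consensus column
# ("-" where deleted). NULL when the alignment is too poor to trust
# (less than half of the consensus columns aligned to identical residues is
# still fine -- the threshold is on coverage, not identity).
map_profile_columns <- function(protein, consensus) {
  pa <- try(Biostrings::pairwiseAlignment(
    Biostrings::AAString(consensus), Biostrings::AAString(protein),
    substitutionMatrix = blosum62(), gapOpening = GAP_OPEN,
    gapExtension = GAP_EXTEND, type = "global-local"), silent = TRUE)
  if (inherits(pa, "try-error")) return(NULL)
  ap <- chars(as.character(Biostrings::alignedPattern(pa)))
  as_ <- chars(as.character(Biostrings::alignedSubject(pa)))
  mapped <- character(nchar(consensus))
  k <- 0L
  for (i in seq_along(ap)) {
    if (ap[i] != "-") {
      k <- k + 1L
      mapped[k] <- as_[i]
    }
  }
  if (mean(mapped != "-") < 0.5) return(NULL)
  mapped
}

#' Verify class-specific conserved catalytic residues
#'
#' Aligns the protein to the class's packaged reference profile and checks
#' that every required residue is present at its mapped consensus column:
#' the GH23 lytic transglycosylase requires the catalytic glutamate (E); the
#' GDPD class requires the two catalytic histidines and the E/E/D
#' metal-binding triplet.
#'
#' @param protein amino-acid string.
#' @param call a lysin call row (needs \code{tal_class}).
#' @param rules residue rules (default \code{\link{residue_rules}()}).
#' @param class_profile \code{ConsensusProfile} for the class (default: the
#'   packaged reference profile).
#' @return \code{TRUE} iff all required residues match; \code{FALSE}
#'   (with a message) when the alignment to the profile fails.
#' @export
verify_catalytic <- function(protein, call, rules = residue_rules(),
                             class_profile = NULL) {
  cls <- call$tal_class
  if (!cls %in% names(rules))
    stop("no residue rules for class ", cls)
  if (is.null(class_profile))
    class_profile <- reference_profile(if (cls == "TMP_LT") "TMP_LT" else cls)
  cons <- class_profile$consensus
  mapped <- map_profile_columns(protein, cons)
  if (is.null(mapped) ||
      mean(mapped == chars(cons)) < 0.3) {
    message("alignment to ", cls, " profile failed; catalytic check FALSE")
    return(FALSE)
  }
  rule <- rules[[cls]]
  all(mapped[rule$column] == rule$residue)
}

#' Classify the lytic-transglycosylase family of a GH23-containing protein
#'
#' Families follow the sequence-motif system for lytic transglycosylases:
#' family 1A requires motifs I-IV (catalytic E-S; GxxQ core, G-l-M-Q
#' preferred; A/G-Y-N; conserved Y flanked by a hydrophobic residue).
#' Family 1P additionally requires the six phage-specific conserved
#' positions (T46, F47, G54, I59, L67, A68 in the packaged alignment
#' frame). Family 1E is assigned when the LT domain is N-terminal in a
#' non-TMP protein and motifs I-IV match. Anything else is
#' \code{"unassigned"}.
#'
#' @param protein amino-acid string carrying a GH23 LT hit.
#' @param profile class reference profile (default packaged TMP_LT profile).
#' @param is_tmp whether the protein is the genome's tape measure protein.
#' @return one of \code{"1A", "1P", "1E", "unassigned"}.
#' @export
classify_lt_family <- function(protein, profile = NULL, is_tmp = TRUE) {
  if (is.null(profile)) profile <- reference_profile("TMP_LT")
  lib <- tal_motif_library()["GH23_LT"]
  hits <- scan_domains(protein, lib)
  if (nrow(hits) == 0) return("unassigned")
  mapped <- map_profile_columns(protein, profile$consensus)
  if (is.null(mapped)) return("unassigned")
  cc <- GH23_COLUMNS
  m1 <- mapped[cc$motif_I[1]] == "E" && mapped[cc$motif_I[2]] == "S"
  m2 <- mapped[cc$motif_II[1]] == "G" && mapped[cc$motif_II[2]] == "Q"
  m3 <- mapped[cc$motif_III[1]] %in% c("A", "G") &&
        mapped[cc$motif_III[1] + 1] == "Y" &&
        mapped[cc$motif_III[2]] == "N"
  m4 <- mapped[cc$motif_IV[1] + 1] == "Y" &&
        (mapped[cc$motif_IV[1]] %in% HYDROPHOBIC ||
         mapped[cc$motif_IV[2]] %in% HYDROPHOBIC)
  if (!(m1 && m2 && m3 && m4)) return("unassigned")
  hit <- hits[1, ]
  n_terminal <- (hit$start_aa + hit$end_aa) / 2 <= nchar(protein) / 3
  if (!is_tmp && n_terminal) return("1E")
  extras <- cc$family_1p
  if (all(mapped[extras] == names(extras))) "1P" else "1A"
}

#' Classify one tail-module gene into a lysin class
#'
#' Class priority when several domain families hit: a TMP gene with a GH23
#' LT hit is \code{TMP_LT}; then endopeptidase -> \code{TAEP}; NLPC/P60 ->
#' \code{NLPC_P60}; GDPD -> \code{GDPD}; pectinesterase ->
#' \code{PECTINESTERASE}; otherwise \code{none}. Secondary class evidence
#' is recorded rather than dropped. The DA group comes from the matching
#' \code{assign_*} rule; catalytic residues are verified for the TMP_LT and
#' GDPD classes; the LT family is assigned whenever a GH23 hit exists.
#'
#' @param gene one feature row (needs \code{gene_id}, \code{translation}).
#' @param layout \code{TailModuleLayout} for the genome.
#' @param hits \code{data.frame} from \code{\link{scan_domains}} for this
#'   gene's translation.
#' @return one-row \code{data.frame}: \code{gene_id, tal_class, da_group,
#'   catalytic_ok, lt_family, in_tal_position, in_tmp, secondary_classes,
#'   region_violation}.
#' @export
classify_lysin <- function(gene, layout, hits) {
  gid <- gene$gene_id
  protein <- gene$translation
  is_tmp <- !is.null(layout$tmp_id) && identical(gid, layout$tmp_id)
  in_tal <- !is.null(layout$tal_id) && identical(gid, layout$tal_id)
  present <- unique(hits$motif_name)
  evidence <- unique(unname(CLASS_MOTIF[intersect(names(CLASS_MOTIF), present)]))

  tal_class <- "none"
  if (is_tmp && "GH23_LT" %in% present) tal_class <- "TMP_LT"
  else if ("endopeptidase" %in% present) tal_class <- "TAEP"
  else if ("NLPC_P60" %in% present) tal_class <- "NLPC_P60"
  else if ("GDPD" %in% present) tal_class <- "GDPD"
  else if ("pectinesterase" %in% present) tal_class <- "PECTINESTERASE"

  plen <- nchar(protein)
  da <- ""
  catalytic <- NA
  region_violation <- FALSE
  if (tal_class == "TAEP") {
    da <- assign_taep_da(hits, plen)
    region_violation <-
      !any(hits$region_ok[hits$motif_name == "endopeptidase"])
  } else if (tal_class == "NLPC_P60") {
    da <- assign_nlpc_da(hits, plen)
  } else if (tal_class == "GDPD") {
    da <- assign_gdpd_da(hits, plen)
    catalytic <- verify_catalytic(protein,
                                  list(tal_class = "GDPD"))
  } else if (tal_class == "TMP_LT") {
    da <- "TMPLT-DA1"
    catalytic <- verify_catalytic(protein,
                                  list(tal_class = "TMP_LT"))
    region_violation <-
      !any(hits$region_ok[hits$motif_name == "GH23_LT"])
  } else if (tal_class == "PECTINESTERASE") {
    da <- "PE-DA1"
  }

  lt_family <- if ("GH23_LT" %in% present)
    classify_lt_family(protein, is_tmp = is_tmp) else "not_applicable"

  secondary <- setdiff(evidence, tal_class)
  data.frame(gene_id = gid, tal_class = tal_class, da_group = da,
             catalytic_ok = catalytic, lt_family = lt_family,
             in_tal_position = in_tal, in_tmp = is_tmp,
             secondary_classes = paste(secondary, collapse = ","),
             region_violation = region_violation,
             stringsAsFactors = FALSE)
}
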