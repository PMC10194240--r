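# Functional-module assignment and tail-module resolution.

MODULE_CATEGORIES <- c("packaging", "head", "tail", "lysis",
                       "dna_metabolism", "lysogeny", "hypothetical", "other")

#' Default keyword vocabulary mapping product annotations to modules
#'
#' Matching is case-insensitive substring lookup; categories are tried in a
#' fixed priority order (lysogeny > packaging > head > tail > lysis >
#' dna_metabolism > hypothetical) so that composite annotations such as
#' "head-tail connector protein" resolve deterministically. The vocabulary
#' can be overridden by passing a modified copy to
#' \code{\link{categorize_gene}} / \code{\link{partition_modules}}, or loaded
#' from a \code{key=category} config file via
#' \code{\link{read_module_vocabulary}}.
#'
#' @return named list: category -> character vector of keywords, in priority
#'   order.
#' @export
module_vocabulary <- function() {
  list(
    lysogeny       = c("integrase", "recombinase", "repressor",
                       "excisionase", "antirepressor", "anti-repressor"),
    packaging      = c("terminase", "packaging"),
    head           = c("capsid", "portal", "scaffold", "head",
                       "prohead", "protease, hk97"),
    tail           = c("tail", "tape measure", "baseplate", "fiber",
                       "distal", "tailspike", "spike"),
    lysis          = c("holin", "endolysin", "lysin", "amidase",
                       "lysozyme", "spanin"),
    dna_metabolism = c("polymerase", "helicase", "primase", "nuclease",
                       "ligase", "methyltransferase", "thymidylate",
                       "ribonucleotide reductase", "recombination",
                       "single-strand", "replication"),
    hypothetical   = c("hypothetical protein", "hypothetical",
                       "unknown function")
  )
}

#' Read a key=category vocabulary config file
#'
#' Plain-text lines \code{keyword=category}; \code{#} comments and blank
#' lines ignored. Keywords are appended to (and take precedence within) the
#' default vocabulary of their category.
#'
#' @param path config file path.
#' @param base vocabulary to extend (default \code{module_vocabulary()}).
#' @return vocabulary list in priority order.
#' @export
read_module_vocabulary <- function(path, base = module_vocabulary()) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("bad vocabulary line: ", ln)
    cat_ <- trimws(kv[2]); key <- tolower(trimws(kv[1]))
    if (!cat_ %in% names(base)) {
      if (!cat_ %in% MODULE_CATEGORIES) stop("unknown category: ", cat_)
      base[[cat_]] <- character()
    }
    base[[cat_]] <- unique(c(key, base[[cat_]]))
  }
  base
}

#' Assign a functional-module category to one product annotation
#'
#' @param product annotation string (may be empty).
#' @param vocabulary keyword vocabulary (see \code{\link{module_vocabulary}}).
#' @return one of \code{packaging, head, tail, lysis, dna_metabolism,
#'   lysogeny, hypothetical, other}.
#' @examples
#' categorize_gene("tape measure protein")    # "tail"
#' categorize_gene("terminase large subunit") # "packaging"
#' @export
categorize_gene <- function(product, vocabulary = module_vocabulary()) {
  p <- tolower(product %||% "")
  if (!nzchar(trimws(p))) return("hypothetical")
  for (cat_ in names(vocabulary)) {
    for (kw in vocabulary[[cat_]]) {
      if (grepl(kw, p, fixed = TRUE)) return(cat_)
    }
  }
  "other"
}

#' Partition a genome's CDS genes into functional-module segments
#'
#' Greedy left-to-right segmentation over gene order: consecutive genes of
#' the same category merge into one segment; \code{hypothetical}/\code{other}
#' genes are absorbed into the enclosing segment when flanked by the same
#' category on both sides, otherwise they form their own segment. Only CDS
#' features participate (module architecture is a property of the protein
#' genes). The output covers every CDS exactly once.
#'
#' @param g a \code{GenomeRecord}.
#' @param vocabulary keyword vocabulary.
#' @return \code{data.frame} of segments: \code{segment_index, category,
#'   start_index, end_index} (gene-index half-open over the CDS-only gene
#'   order) and \code{gene_ids} (list column).
#' @export
partition_modules <- function(g, vocabulary = module_vocabulary()) {
  cds <- g$features[g$features$kind == "CDS", , drop = FALSE]
  if (nrow(cds) == 0) stop("genome ", g$genome_id, " has no CDS")
  cats <- vapply(cds$product, categorize_gene, "", vocabulary = vocabulary,
                 USE.NAMES = FALSE)
  n <- length(cats)
  filler <- cats %in% c("hypothetical", "other")
  eff <- cats
  # absorb filler runs flanked by the same real category on both sides
  i <- 1L
  while (i <= n) {
    if (filler[i]) {
      j <- i
      while (j < n && filler[j + 1L]) j <- j + 1L
      left <- if (i > 1L) eff[i - 1L] else NA_character_
      right <- if (j < n) cats[j + 1L] else NA_character_
      if (!is.na(left) && !is.na(right) && left == right &&
          !left %in% c("hypothetical", "other"))
        eff[i:j] <- left
      i <- j + 1L
    } else i <- i + 1L
  }
  runs <- rle(eff)
  endi <- cumsum(runs$lengths)
  starti <- c(0L, head(endi, -1L))
  data.frame(segment_index = seq_along(runs$values),
             category = runs$values,
             start_index = starti, end_index = endi,
             gene_ids = I(lapply(seq_along(runs$values), function(k)
               cds$gene_id[(starti[k] + 1L):endi[k]])),
             stringsAsFactors = FALSE)
}

#' Locate the tail module between the head and lysis modules
#'
#' Returns the genes of tail-category segment(s) lying strictly between the
#' last head segment and the first subsequent lysis segment. When no
#' tail-category segment lies there but uncategorized
#' (hypothetical/other) genes do, those genes become the candidate tail
#' module with \code{conforms_tmp_dit_tal = FALSE} pending
#' \code{\link{resolve_tmp_dit_tal}}. Returns \code{NULL} (with a message)
#' when the genome lacks a head or lysis module.
#'
#' @param segments segment table from \code{\link{partition_modules}}.
#' @return a \code{TailModuleLayout} list (\code{tail_gene_ids, tmp_id,
#'   dit_id, tal_id, estimated_tail_length_nm, conforms_tmp_dit_tal}) or
#'   \code{NULL}.
#' @export
locate_tail_module <- function(segments) {
  heads <- which(segments$category == "head")
  if (length(heads) == 0) {
    message("no head module; tail module not located")
    return(NULL)
  }
  h <- max(heads)
  lys <- which(segments$category == "lysis" & seq_len(nrow(segments)) > h)
  if (length(lys) == 0) {
    message("no lysis module after the head module; tail module not located")
    return(NULL)
  }
  l <- min(lys)
  between <- segments[seq_len(nrow(segments)) > h &
                      seq_len(nrow(segments)) < l, , drop = FALSE]
  tail_segs <- between[between$category == "tail", , drop = FALSE]
  if (nrow(tail_segs) > 0) {
    ids <- unlist(tail_segs$gene_ids, use.names = FALSE)
    conforms_candidate <- TRUE
  } else {
    unc <- between[between$category %in% c("hypothetical", "other"), ,
                   drop = FALSE]
    if (nrow(unc) == 0) {
      message("no tail-category or uncategorized genes between head and lysis")
      return(NULL)
    }
    ids <- unlist(unc$gene_ids, use.names = FALSE)
    conforms_candidate <- FALSE
  }
  structure(list(tail_gene_ids = ids, tmp_id = NULL, dit_id = NULL,
                 tal_id = NULL, estimated_tail_length_nm = NULL,
                 conforms_tmp_dit_tal = FALSE,
                 from_tail_annotation = conforms_candidate),
            class = "TailModuleLayout")
}

#' Resolve the TMP-Dit-Tal unit within a located tail module
#'
#' The tape measure protein (TMP) is the tail gene whose product matches a
#' tape-measure keyword, else the longest CDS in the tail module (ties go to
#' the first in genomic order). Podovirus-style modules with no keyword and
#' no gene longer than 800 aa leave the TMP unset. Dit is the gene
#' immediately after the TMP (a distal-tail keyword is preferred; otherwise
#' the adjacent gene is accepted, as Dit is typically a small, often
#' hypothetical, protein). Tal is the gene after Dit. The predicted tail
#' length is 0.15 nm per TMP amino acid.
#'
#' @param layout result of \code{\link{locate_tail_module}}.
#' @param g the \code{GenomeRecord}.
#' @return the layout with \code{tmp_id}, \code{dit_id}, \code{tal_id},
#'   \code{estimated_tail_length_nm} and \code{conforms_tmp_dit_tal} filled.
#' @export
resolve_tmp_dit_tal <- function(layout, g) {
  stopifnot(inherits(layout, "TailModuleLayout"))
  feats <- g$features
  ids <- layout$tail_gene_ids
  if (length(ids) == 0) return(layout)
  sub <- feats[match(ids, feats$gene_id), , drop = FALSE]
  aalen <- nchar(sub$translation)
  prod <- tolower(sub$product)

  tmp_i <- which(grepl("tape measure", prod, fixed = TRUE))
  if (length(tmp_i) == 0) {
    # longest-gene fallback; podovirus-style modules (nothing > 800 aa)
    # leave the TMP unset
    cand <- which(aalen > 800)
    tmp_i <- if (length(cand))
      cand[which(aalen[cand] == max(aalen[cand]))[1]] else integer()
  } else tmp_i <- tmp_i[1]

  if (length(tmp_i) == 1) {
    layout$tmp_id <- ids[tmp_i]
    layout$estimated_tail_length_nm <- 0.15 * aalen[tmp_i]
    if (tmp_i + 1L <= length(ids)) {
      nxt <- tmp_i + 1L
      dit_kw <- which(grepl("distal", prod, fixed = TRUE))
      layout$dit_id <- if (length(dit_kw) && dit_kw[1] > tmp_i)
        ids[dit_kw[1]] else ids[nxt]
      dit_i <- match(layout$dit_id, ids)
      if (dit_i + 1L <= length(ids)) layout$tal_id <- ids[dit_i + 1L]
    }
  }
  ord <- match(c(layout$tmp_id, layout$dit_id, layout$tal_id), ids)
  layout$conforms_tmp_dit_tal <- length(ord) == 3L && !anyNA(ord) &&
    all(diff(ord) > 0)
  layout
}

#' Detect temperate (lysogeny-capable) genomes
#'
#' Scans product annotations for integrase/recombinase and repressor
#' keywords; "anti-repressor"/"antirepressor" alone does not count as a
#' repressor. A genome is temperate when it has an integrase and/or a
#' repressor gene.
#'
#' @param g a \code{GenomeRecord}.
#' @return list with \code{has_integrase}, \code{has_repressor},
#'   \code{is_temperate}.
#' @export
detect_temperate <- function(g) {
  p <- tolower(g$features$product)
  has_int <- any(grepl("integrase", p) | grepl("recombinase", p))
  rep_hits <- grepl("repressor", p) &
    !grepl("anti-repressor", p) & !grepl("antirepressor", p)
  list(has_integrase = has_int,
       has_repressor = any(rep_hits),
       is_temperate = has_int || any(rep_hits))
}
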