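# Independent oracles and small builders shared across tests.

# Exhaustive alignment oracle: enumerates every monotone alignment of two
# short sequences and returns the best affine-gap score (BLOSUM62, a gap of
# length L costs open + L * extend). Exponential -- keep sequences <= 12 aa.
brute_force_align_score <- function(a, b, open = 11, ext = 1) {
  subm <- local({
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    e$BLOSUM62
  })
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  best <- -Inf
  rec <- function(i, j, sc, last) {
    if (i > n && j > m) {
      best <<- max(best, sc)
      return(invisible())
    }
    if (i <= n && j <= m) rec(i + 1, j + 1, sc + subm[A[i], B[j]], "M")
    if (i <= n) rec(i + 1, j, sc - ext - if (last == "X") 0 else open, "X")
    if (j <= m) rec(i, j + 1, sc - ext - if (last == "Y") 0 else open, "Y")
  }
  rec(1, 1, 0, "M")
  best
}

# random protein under a local seed
random_aa <- function(n, seed = NULL) {
  gen <- function() paste(sample(talscan:::AA20, n, replace = TRUE),
                          collapse = "")
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# protein of length `len` with named motifs planted at 1-based positions:
# plants = list(list(consensus, at), ...)
protein_with_motifs <- function(len, plants, seed = 1) {
  p <- random_aa(len, seed = seed)
  for (pl in plants) {
    p <- paste0(substr(p, 1, pl$at - 1), pl$consensus,
                substr(p, pl$at + nchar(pl$consensus), nchar(p)))
  }
  p
}

# a minimal annotated genome built from a vector of product strings
# (one forward CDS per product, 300 aa placeholders unless supplied)
toy_genome <- function(products, translations = NULL, id = "TOY1",
                       length_bp = NULL) {
  n <- length(products)
  if (is.null(translations))
    translations <- vapply(seq_len(n), function(i) strrep("K", 300), "")
  rows <- lapply(seq_len(n), function(i) {
    aa <- translations[i]
    start <- 100L + (i - 1L) * 2000L
    gene_feature(sprintf("%s_g%03d", id, i), start,
                 start + 3L * (nchar(aa) + 1L), product = products[i],
                 translation = aa)
  })
  feats <- do.call(rbind, rows)
  genome_record(id, feats,
                length_bp = length_bp %||% (max(feats$end) + 200L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# hand-written GenBank text (foreign formatting, 1-based inclusive
# locations) used to pin the coordinate conversion
GBK_FIXTURE_TEXT <- c(
  "LOCUS       TESTPHAGE1       1200 bp    DNA     linear   PHG 01-JAN-2020",
  "DEFINITION  hand-written test record.",
  "FEATURES             Location/Qualifiers",
  "     source          1..1200",
  "     CDS             100..399",
  '                     /locus_tag="tp1_001"',
  '                     /product="major capsid protein"',
  paste0('                     /translation="', strrep("M", 99), '"'),
  "     CDS             complement(500..799)",
  '                     /locus_tag="tp1_002"',
  '                     /product="terminase large subunit"',
  paste0('                     /translation="', strrep("K", 99), '"'),
  "     tRNA            900..975",
  '                     /locus_tag="tp1_trna1"',
  '                     /product="tRNA-Leu"',
  "//",
  "LOCUS       TESTPHAGE2       600 bp    DNA     circular PHG 01-JAN-2020",
  "DEFINITION  second hand-written record.",
  "FEATURES             Location/Qualifiers",
  "     source          1..600",
  "     CDS             10..45",
  '                     /locus_tag="tp2_001"',
  '                     /product="holin"',
  paste0('                     /translation="', strrep("A", 11), '"'),
  "//")
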