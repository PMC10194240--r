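#' Construct a gene feature
#'
#' Coordinates are 0-based half-open on the genome's forward strand; features
#' on the reverse strand keep \code{start < end} and carry the translation of
#' the reverse complement. For a circular genome a feature spanning the
#' origin is represented with \code{end > length_bp}.
#'
#' @param gene_id unique identifier within the genome.
#' @param start,end integer coordinates, 0-based half-open, \code{start < end}.
#' @param strand \code{"forward"} or \code{"reverse"}.
#' @param kind \code{"CDS"}, \code{"tRNA"} or \code{"other"}.
#' @param product free-text annotation string.
#' @param translation amino-acid string, empty for non-CDS features.
#' @return one-row \code{data.frame} with the feature fields.
#' @export
gene_feature <- function(gene_id, start, end, strand = "forward",
                         kind = "CDS", product = "", translation = "") {
  stopifnot(start < end, strand %in% c("forward", "reverse"),
            kind %in% c("CDS", "tRNA", "other"))
  if (nchar(translation) > ceiling((end - start) / 3))
    stop("translation longer than the coding span allows for ", gene_id)
  data.frame(gene_id = gene_id, start = as.integer(start),
             end = as.integer(end), strand = strand, kind = kind,
             product = product, translation = translation,
             stringsAsFactors = FALSE)
}

#' Construct an annotated genome record
#'
#' @param genome_id identifier.
#' @param features \code{data.frame} of gene features (rows as produced by
#'   \code{\link{gene_feature}}); sorted by \code{start} on construction.
#' @param sequence nucleotide string; may be empty when only a feature table
#'   is available.
#' @param length_bp genome length; required when \code{sequence} is empty.
#' @param topology \code{"linear"} or \code{"circular"}.
#' @param source_kind \code{"phage"} or \code{"prophage"}.
#' @return object of class \code{GenomeRecord}.
#' @export
genome_record <- function(genome_id, features, sequence = "",
                          length_bp = NULL, topology = "linear",
                          source_kind = "phage") {
  stopifnot_scalar_string(genome_id, "genome_id")
  stopifnot(topology %in% c("linear", "circular"),
            source_kind %in% c("phage", "prophage"))
  if (nzchar(sequence)) {
    if (!is.null(length_bp) && length_bp != nchar(sequence))
      stop("length_bp disagrees with sequence length for ", genome_id)
    length_bp <- nchar(sequence)
  }
  if (is.null(length_bp) || length_bp <= 0)
    stop("length_bp must be positive for ", genome_id)
  if (anyDuplicated(features$gene_id))
    stop("duplicate gene_id in ", genome_id)
  features <- features[order(features$start, features$end), , drop = FALSE]
  rownames(features) <- NULL
  structure(list(genome_id = genome_id,
                 sequence = sequence,
                 length_bp = as.integer(length_bp),
                 gc_fraction = gc_fraction(sequence),
                 topology = topology,
                 features = features,
                 source_kind = source_kind),
            class = "GenomeRecord")
}

#' @export
print.GenomeRecord <- function(x, ...) {
  cat(sprintf("GenomeRecord %s: %d bp (%s, %s), %d features, GC %.2f%%\n",
              x$genome_id, x$length_bp, x$topology, x$source_kind,
              nrow(x$features), 100 * (x$gc_fraction %||% NA_real_)))
  invisible(x)
}

#' GC fraction of a nucleotide string
#'
#' Ambiguity codes are excluded from the denominator: the fraction is
#' (G+C) / (A+C+G+T), case-insensitive. Returns \code{NA} for an empty
#' sequence.
#'
#' @param sequence nucleotide string.
#' @return real in [0, 1], or \code{NA_real_}.
#' @export
gc_fraction <- function(sequence) {
  if (!nzchar(sequence)) return(NA_real_)
  n <- chars(toupper(sequence))
  acgt <- sum(n %in% c("A", "C", "G", "T"))
  if (acgt == 0) return(NA_real_)
  sum(n %in% c("G", "C")) / acgt
}

# ---- GenBank flat-file I/O ---------------------------------------------

#' Read annotated genomes from a GenBank flat file
#'
#' Parses one \code{GenomeRecord} per LOCUS. CDS and tRNA features are kept
#' with their \code{/product}; CDS translations are taken from the record's
#' \code{/translation} qualifier when present, otherwise translated from the
#' coordinates with the bacterial genetic code (table 11) when sequence is
#' available. GenBank 1-based inclusive locations are converted to internal
#' 0-based half-open coordinates; \code{join(a..L,1..b)} across the origin of
#' a circular record becomes a single feature with \code{end > length_bp}.
#'
#' @param path path to a (possibly multi-record) GenBank file.
#' @param source_kind \code{"phage"} or \code{"prophage"} tag applied to all
#'   records read.
#' @return list of \code{GenomeRecord}, input order preserved.
#' @export
read_genbank <- function(path, source_kind = "phage") {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  ends <- grep("^//\\s*$", lines)
  if (length(ends) == 0) stop("not a GenBank flat file (no // terminator): ", path)
  starts <- c(1L, head(ends, -1L) + 1L)
  records <- vector("list", length(ends))
  for (k in seq_along(ends)) {
    block <- lines[starts[k]:ends[k]]
    block <- block[nzchar(trimws(block)) | seq_along(block) == length(block)]
    records[[k]] <- parse_genbank_record(block, source_kind, path)
  }
  records
}

parse_genbank_record <- function(block, source_kind, path) {
  loc <- grep("^LOCUS", block, value = TRUE)
  if (length(loc) != 1)
    stop("unparseable GenBank record (missing LOCUS) in ", path)
  toks <- strsplit(trimws(loc), "\\s+")[[1]]
  genome_id <- toks[2]
  len <- suppressWarnings(as.integer(toks[which(toks == "bp") - 1L]))
  if (length(len) != 1 || is.na(len))
    stop("unparseable LOCUS line for ", genome_id)
  topology <- if (any(grepl("circular", loc))) "circular" else "linear"

  fstart <- grep("^FEATURES", block)
  ostart <- grep("^ORIGIN", block)
  fend <- if (length(ostart)) ostart[1] - 1L else length(block)

  sequence <- ""
  if (length(ostart)) {
    seqlines <- block[(ostart[1] + 1L):length(block)]
    seqlines <- seqlines[!grepl("^//", seqlines)]
    sequence <- toupper(gsub("[^A-Za-z]", "", paste(seqlines, collapse = "")))
  }

  feats <- list()
  if (length(fstart)) {
    flines <- block[(fstart[1] + 1L):fend]
    # feature starts: 5-space indent then a key; qualifiers are indented 21
    is_new <- grepl("^ {5}\\S", flines)
    idx <- which(is_new)
    for (j in seq_along(idx)) {
      from <- idx[j]
      to <- if (j < length(idx)) idx[j + 1] - 1L else length(flines)
      feats[[length(feats) + 1L]] <-
        parse_genbank_feature(flines[from:to], len, genome_id)
    }
  }
  feats <- Filter(Negate(is.null), feats)
  counter <- 0L
  for (i in seq_along(feats)) {
    if (!nzchar(feats[[i]]$gene_id)) {
      counter <- counter + 1L
      feats[[i]]$gene_id <- sprintf("%s_f%03d", genome_id, counter)
    }
    f <- feats[[i]]
    if (f$kind == "CDS" && !nzchar(f$translation)) {
      if (nzchar(sequence)) {
        feats[[i]]$translation <-
          translate_cds(sequence, f$start, f$end, f$strand, len)
      } else {
        warning("CDS ", f$gene_id, " has no /translation and no sequence; ",
                "kept with empty translation", call. = FALSE)
      }
    }
  }
  features <- if (length(feats)) do.call(rbind, lapply(feats, as.data.frame))
              else empty_features()
  genome_record(genome_id, features, sequence = sequence,
                length_bp = len, topology = topology,
                source_kind = source_kind)
}

empty_features <- function() {
  data.frame(gene_id = character(), start = integer(), end = integer(),
             strand = character(), kind = character(), product = character(),
             translation = character(), stringsAsFactors = FALSE)
}

parse_genbank_feature <- function(flines, genome_len, genome_id) {
  keyline <- flines[1]
  key <- sub("^ {5}(\\S+).*", "\\1", keyline)
  if (key == "source") return(NULL)
  kind <- if (key == "CDS") "CDS" else if (key == "tRNA") "tRNA" else "other"
  locstr <- trimws(sub("^ {5}\\S+\\s*", "", keyline))
  strand <- if (grepl("complement", locstr)) "reverse" else "forward"
  body <- gsub("complement\\(|\\)$", "", locstr)
  coords <- NULL
  if (grepl("^join\\(", body)) {
    parts <- strsplit(gsub("join\\(|\\)", "", body), ",")[[1]]
    rng <- lapply(parts, function(p)
      as.integer(strsplit(gsub("[<>]", "", p), "\\.\\.")[[1]]))
    if (length(rng) == 2 && rng[[1]][2] == genome_len && rng[[2]][1] == 1L) {
      # origin-spanning feature on a circular genome, kept unwrapped
      coords <- c(rng[[1]][1] - 1L, genome_len + rng[[2]][2])
    } else {
      coords <- c(rng[[1]][1] - 1L, rng[[length(rng)]][2])
    }
  } else {
    ab <- suppressWarnings(
      as.integer(strsplit(gsub("[<>]", "", body), "\\.\\.")[[1]]))
    if (length(ab) == 1) ab <- c(ab, ab)
    if (any(is.na(ab)))
      stop("unparseable feature location '", locstr, "' in ", genome_id)
    coords <- c(ab[1] - 1L, ab[2])
  }
  quals <- parse_qualifiers(flines[-1])
  list(gene_id = quals[["locus_tag"]] %||% "",
       start = coords[1], end = coords[2], strand = strand, kind = kind,
       product = quals[["product"]] %||% "",
       translation = if (kind == "CDS") gsub("\\s", "", quals[["translation"]] %||% "") else "")
}

parse_qualifiers <- function(qlines) {
  txt <- paste(trimws(qlines), collapse = "\n")
  out <- list()
  # qualifiers start at line beginnings with /name=
  pieces <- strsplit(txt, "\n/", fixed = TRUE)[[1]]
  pieces[1] <- sub("^/", "", pieces[1])
  for (p in pieces) {
    if (!nzchar(p)) next
    eq <- regexpr("=", p, fixed = TRUE)
    if (eq < 0) { out[[p]] <- TRUE; next }
    nm <- substr(p, 1, eq - 1)
    val <- substr(p, eq + 1, nchar(p))
    val <- gsub('^"|"$', "", gsub("\n", " ", val))
    out[[nm]] <- val
  }
  out
}

translate_cds <- function(sequence, start, end, strand, genome_len) {
  idx_end <- end
  if (end > genome_len) { # origin-spanning: unwrap
    sequence <- paste0(sequence, substr(sequence, 1, end - genome_len))
  }
  nt <- substr(sequence, start + 1L, idx_end)
  dna <- Biostrings::DNAString(nt)
  if (strand == "reverse") dna <- Biostrings::reverseComplement(dna)
  aa <- as.character(suppressWarnings(Biostrings::translate(
    dna, genetic.code = Biostrings::getGeneticCode("11"),
    if.fuzzy.codon = "X")))
  sub("\\*$", "", aa)
}

#' Write genomes to a GenBank flat file
#'
#' Emits one LOCUS per record with CDS and tRNA features carrying
#' \code{/locus_tag}, \code{/product} and \code{/translation} qualifiers,
#' followed by ORIGIN when sequence is present. Inverse of
#' \code{\link{read_genbank}} for the feature fields it writes.
#'
#' @param genomes list of \code{GenomeRecord}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_genbank <- function(genomes, path) {
  if (inherits(genomes, "GenomeRecord")) genomes <- list(genomes)
  con <- file(path, "w")
  on.exit(close(con))
  for (g in genomes) {
    topo <- if (g$topology == "circular") "circular" else "linear"
    writeLines(sprintf("LOCUS       %-16s %d bp    DNA     %s   PHG",
                       g$genome_id, g$length_bp, topo), con)
    writeLines(sprintf("DEFINITION  %s genome %s.", g$source_kind, g$genome_id), con)
    writeLines("FEATURES             Location/Qualifiers", con)
    writeLines(sprintf("     source          1..%d", g$length_bp), con)
    for (i in seq_len(nrow(g$features))) {
      f <- g$features[i, ]
      key <- if (f$kind == "CDS") "CDS" else if (f$kind == "tRNA") "tRNA"
             else "misc_feature"
      loc <- format_genbank_location(f$start, f$end, f$strand, g$length_bp)
      writeLines(sprintf("     %-15s %s", key, loc), con)
      writeLines(sprintf('                     /locus_tag="%s"', f$gene_id), con)
      if (nzchar(f$product))
        writeLines(sprintf('                     /product="%s"', f$product), con)
      if (f$kind == "CDS" && nzchar(f$translation))
        writeLines(wrap_qualifier("translation", f$translation), con)
    }
    if (nzchar(g$sequence)) {
      writeLines("ORIGIN", con)
      s <- tolower(g$sequence)
      pos <- seq(1, nchar(s), by = 60)
      for (p in pos) {
        seg <- substr(s, p, min(p + 59, nchar(s)))
        tens <- substring(seg, seq(1, nchar(seg), 10),
                          pmin(seq(10, nchar(seg) + 9, 10), nchar(seg)))
        writeLines(sprintf("%9d %s", p, paste(tens, collapse = " ")), con)
      }
    }
    writeLines("//", con)
  }
  invisible(path)
}

format_genbank_location <- function(start, end, strand, genome_len) {
  loc <- if (end > genome_len)
    sprintf("join(%d..%d,1..%d)", start + 1L, genome_len, end - genome_len)
  else sprintf("%d..%d", start + 1L, end)
  if (strand == "reverse") loc <- sprintf("complement(%s)", loc)
  loc
}

wrap_qualifier <- function(name, value, width = 58) {
  full <- sprintf('/%s="%s"', name, value)
  starts <- seq(1, nchar(full), by = width)
  paste0(strrep(" ", 21),
         substring(full, starts, pmin(starts + width - 1, nchar(full))))
}

# ---- derived statistics and tables -------------------------------------

#' Basic statistics of a genome record
#'
#' @param g a \code{GenomeRecord}.
#' @return \code{data.frame} with \code{genome_id}, \code{length_kb},
#'   \code{orf_count} (CDS features), \code{trna_count} and
#'   \code{gc_percent} (two decimals, \code{NA} without sequence).
#' @export
genome_stats <- function(g) {
  stopifnot(inherits(g, "GenomeRecord"))
  data.frame(genome_id = g$genome_id,
             length_kb = g$length_bp / 1000,
             orf_count = sum(g$features$kind == "CDS"),
             trna_count = sum(g$features$kind == "tRNA"),
             gc_percent = if (is.na(g$gc_fraction)) NA_real_
                          else round(100 * g$gc_fraction, 2),
             stringsAsFactors = FALSE)
}

#' Write a table of flat records as TSV
#'
#' UTF-8, tab-separated, header row, stable column order. Coordinates in all
#' emitted tables are 0-based half-open (noted in a leading comment line).
#'
#' @param rows \code{data.frame} (possibly zero rows).
#' @param path output path.
#' @param coord_comment write the coordinate-convention comment line.
#' @return \code{path}, invisibly.
#' @export
write_tsv <- function(rows, path, coord_comment = FALSE) {
  con <- try(file(path, "w", encoding = "UTF-8"), silent = TRUE)
  if (inherits(con, "try-error")) stop("cannot open for writing: ", path)
  on.exit(close(con))
  if (coord_comment)
    writeLines("# coordinates are 0-based half-open", con)
  write.table(rows, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, fileEncoding = "")
  invisible(path)
}

#' Read a TSV written by \code{\link{write_tsv}}
#' @param path file path.
#' @return \code{data.frame}.
#' @export
read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, quote = "",
             comment.char = "#", stringsAsFactors = FALSE)
}
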