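test_that("GenBank 1-based inclusive locations become 0-based half-open", {
  path <- withr::local_tempfile(fileext = ".gbk")
  writeLines(GBK_FIXTURE_TEXT, path)
  recs <- read_genbank(path)

  expect_length(recs, 2)
  expect_equal(vapply(recs, function(r) r$genome_id, ""),
               c("TESTPHAGE1", "TESTPHAGE2"))

  f <- recs[[1]]$features
  expect_equal(nrow(f), 3)
  # "100..399" -> start 99, end 399 (bijective conversion)
  expect_equal(f$start[f$gene_id == "tp1_001"], 99L)
  expect_equal(f$end[f$gene_id == "tp1_001"], 399L)
  expect_equal(f$strand[f$gene_id == "tp1_002"], "reverse")
  expect_equal(f$kind[f$gene_id == "tp1_trna1"], "tRNA")
  expect_equal(recs[[2]]$topology, "circular")
  expect_true(all(diff(f$start) > 0)) # sorted by start
})

test_that("write/read round trip preserves features and sequence", {
  co <- simulate_cohort(sim_config(n_genomes = 2, seed = 3))
  path <- withr::local_tempfile(fileext = ".gbk")
  write_genbank(co$genomes, path)
  back <- read_genbank(path)
  expect_length(back, 2)
  for (k in 1:2) {
    a <- co$genomes[[k]]; b <- back[[k]]
    expect_identical(a$features$gene_id, b$features$gene_id)
    expect_identical(a$features$start, b$features$start)
    expect_identical(a$features$end, b$features$end)
    expect_identical(a$features$strand, b$features$strand)
    expect_identical(a$features$product, b$features$product)
    expect_identical(a$features$translation, b$features$translation)
    expect_identical(a$sequence, b$sequence)
    expect_equal(a$gc_fraction, b$gc_fraction)
  }
})

test_that("the packaged parser agrees with Biopython on a written genome", {
  co <- simulate_cohort(sim_config(n_genomes = 1, seed = 11,
    morphotype_mix = c(podo = 1, sipho1 = 0, sipho2 = 0, myo = 0)))
  path <- withr::local_tempfile(fileext = ".gbk")
  write_genbank(co$genomes, path)
  out <- withr::local_tempfile(fileext = ".tsv")
  script <- paste(
    "import sys",
    "from Bio import SeqIO",
    "rec = next(SeqIO.parse(sys.argv[1], 'genbank'))",
    "with open(sys.argv[2], 'w') as fh:",
    "    for f in rec.features:",
    "        if f.type not in ('CDS', 'tRNA'): continue",
    "        lt = f.qualifiers.get('locus_tag', [''])[0]",
    "        tr = f.qualifiers.get('translation', [''])[0]",
    "        strand = 'reverse' if f.location.strand == -1 else 'forward'",
    "        print(lt, int(f.location.start), int(f.location.end),",
    "              strand, tr, sep='\\t', file=fh)",
    sep = "\n")
  status <- system2("python", c("-c", shQuote(script), shQuote(path),
                                shQuote(out)))
  expect_equal(status, 0L)
  py <- read.table(out, sep = "\t", stringsAsFactors = FALSE,
                   col.names = c("gene_id", "start", "end", "strand",
                                 "translation"))
  mine <- read_genbank(path)[[1]]$features
  py <- py[match(mine$gene_id, py$gene_id), ]
  expect_equal(mine$start, py$start)
  expect_equal(mine$end, py$end)
  expect_equal(mine$strand, py$strand)
  expect_equal(mine$translation[mine$kind == "CDS"],
               py$translation[mine$kind == "CDS"])
})

test_that("CDS without /translation is translated from the sequence", {
  # 12-codon gene: ATG + 10 x GCT (Ala) + TAA stop
  nt <- paste0(strrep("t", 9), "ATG", strrep("GCT", 10), "TAA",
               strrep("a", 26))
  txt <- c(
    "LOCUS       MINI1       71 bp    DNA     linear   PHG",
    "FEATURES             Location/Qualifiers",
    "     CDS             10..45",
    '                     /locus_tag="m1"',
    '                     /product="test protein"',
    "ORIGIN",
    paste0("        1 ", tolower(nt)),
    "//")
  path <- withr::local_tempfile(fileext = ".gbk")
  writeLines(txt, path)
  g <- read_genbank(path)[[1]]
  expect_equal(g$features$translation[1], paste0("M", strrep("A", 10)))
})

test_that("genome statistics count ORFs and tRNAs and report GC", {
  g <- toy_genome(c("portal protein", "holin"))
  st <- genome_stats(g)
  expect_equal(st$orf_count, 2)
  expect_equal(st$trna_count, 0)
  expect_true(is.na(st$gc_percent)) # feature-only record

  expect_equal(gc_fraction("ATGC"), 0.5)
  expect_equal(gc_fraction("GGCC"), 1)
  # ambiguity codes excluded from the denominator
  expect_equal(gc_fraction("ATGCNNNN"), 0.5)

  co <- simulate_cohort(sim_config(n_genomes = 1, seed = 5))
  st2 <- genome_stats(co$genomes[[1]])
  expect_equal(st2$orf_count, co$truth_genomes$n_cds[1])
  expect_equal(st2$length_kb, co$genomes[[1]]$length_bp / 1000)
})

test_that("feature invariants are enforced", {
  expect_error(gene_feature("g1", 100, 100), "start < end")
  expect_error(gene_feature("g1", 0, 30, translation = strrep("A", 11)),
               "translation longer")
  f <- rbind(gene_feature("a", 0, 30), gene_feature("a", 40, 70))
  expect_error(genome_record("dup", f, length_bp = 100), "duplicate")
})

test_that("TSV output is a faithful header-stable round trip", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tsv(data.frame(x = integer(), y = character()), path)
  expect_length(readLines(path), 1) # header only

  rows <- data.frame(x = c(1L, 2L), y = c("a", "b"),
                     stringsAsFactors = FALSE)
  write_tsv(rows, path)
  expect_length(readLines(path), 3)
  expect_equal(read_tsv(path), rows)
})
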