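test_that("product keywords map to module categories with priority", {
  expect_equal(categorize_gene("tape measure protein"), "tail")
  expect_equal(categorize_gene("terminase large subunit"), "packaging")
  expect_equal(categorize_gene("hypothetical protein"), "hypothetical")
  expect_equal(categorize_gene(""), "hypothetical")
  expect_equal(categorize_gene("completely novel widget"), "other")
  # priority disambiguates composite annotations
  expect_equal(categorize_gene("head-tail connector protein"), "head")
  expect_equal(categorize_gene("anti-repressor"), "lysogeny")
  expect_equal(categorize_gene("Putative INTEGRASE"), "lysogeny")
})

test_that("vocabulary config files extend the defaults", {
  path <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# custom", "tailspike depolymerase=tail",
               "moron=other"), path)
  voc <- read_module_vocabulary(path)
  expect_equal(categorize_gene("tailspike depolymerase x", voc), "tail")
  expect_error(read_module_vocabulary({
    p2 <- withr::local_tempfile(); writeLines("x=nonsense", p2); p2
  }), "unknown category")
})

test_that("module partition absorbs flanked hypotheticals and covers all genes", {
  g <- toy_genome(c("major head protein", "minor capsid protein",
                    "hypothetical protein", "portal protein", "holin"))
  seg <- partition_modules(g)
  expect_equal(seg$category, c("head", "lysis"))
  expect_equal(seg$end_index - seg$start_index, c(4L, 1L))

  g2 <- toy_genome(c("terminase", "portal protein", "tail fiber protein",
                     "endolysin"))
  seg2 <- partition_modules(g2)
  expect_equal(seg2$category, c("packaging", "head", "tail", "lysis"))

  # cover / no-overlap invariant on simulated genomes
  co <- simulate_cohort(sim_config(n_genomes = 6, seed = 21,
                                   include_sequence = FALSE))
  for (gg in co$genomes) {
    s <- partition_modules(gg)
    expect_equal(s$start_index[1], 0L)
    expect_equal(s$end_index[nrow(s)],
                 sum(gg$features$kind == "CDS"))
    expect_true(all(s$start_index[-1] == head(s$end_index, -1)))
  }
})

test_that("tail module is located between head and lysis, with fallback", {
  g <- toy_genome(c("portal protein", "tail fiber protein", "holin"))
  lay <- locate_tail_module(partition_modules(g))
  expect_s3_class(lay, "TailModuleLayout")
  expect_equal(lay$tail_gene_ids, "TOY1_g002")

  g2 <- toy_genome(c("portal protein", "hypothetical protein",
                     "hypothetical protein", "hypothetical protein",
                     "hypothetical protein", "holin"))
  lay2 <- locate_tail_module(partition_modules(g2))
  expect_length(lay2$tail_gene_ids, 4)
  expect_false(lay2$conforms_tmp_dit_tal)

  g3 <- toy_genome(c("portal protein", "tail fiber protein",
                     "DNA polymerase"))
  expect_message(lay3 <- locate_tail_module(partition_modules(g3)),
                 "no lysis")
  expect_null(lay3)
})

test_that("TMP-Dit-Tal resolution follows keyword, length and order rules", {
  mk <- function(lens, products) {
    toy_genome(c("portal protein", products, "holin"),
               translations = c(strrep("M", 300),
                                vapply(lens, function(n) strrep("A", n), ""),
                                strrep("M", 120)))
  }
  # keyword TMP of 1000 aa: predicted tail length exactly 0.15 nm/aa
  g <- mk(c(1000, 120, 500),
          c("tape measure protein", "hypothetical protein", "tail protein"))
  lay <- resolve_tmp_dit_tal(locate_tail_module(partition_modules(g)), g)
  expect_equal(lay$estimated_tail_length_nm, 150)
  expect_equal(lay$tmp_id, "TOY1_g002")
  expect_equal(lay$dit_id, "TOY1_g003")
  expect_equal(lay$tal_id, "TOY1_g004")
  expect_true(lay$conforms_tmp_dit_tal)

  # no keyword: longest gene above 800 aa wins
  g2 <- mk(c(300, 1500, 120, 400),
           c("tail protein", "tail protein", "tail protein", "tail protein"))
  lay2 <- resolve_tmp_dit_tal(locate_tail_module(partition_modules(g2)), g2)
  expect_equal(lay2$tmp_id, "TOY1_g003")

  # tie on length: first in genomic order
  g3 <- mk(c(900, 900, 100),
           c("tail protein", "tail protein", "tail protein"))
  lay3 <- resolve_tmp_dit_tal(locate_tail_module(partition_modules(g3)), g3)
  expect_equal(lay3$tmp_id, "TOY1_g002")

  # podovirus-style: nothing above 800 aa, TMP left unset
  g4 <- mk(c(300, 200), c("tail protein", "tail protein"))
  lay4 <- resolve_tmp_dit_tal(locate_tail_module(partition_modules(g4)), g4)
  expect_null(lay4$tmp_id)
  expect_false(lay4$conforms_tmp_dit_tal)

  # fewer than 3 tail genes: partial assignment
  g5 <- mk(c(1000), "tape measure protein")
  lay5 <- resolve_tmp_dit_tal(locate_tail_module(partition_modules(g5)), g5)
  expect_equal(lay5$tmp_id, "TOY1_g002")
  expect_null(lay5$tal_id)
  expect_false(lay5$conforms_tmp_dit_tal)
})

test_that("tail-length estimate is linear with slope 0.15 nm per aa", {
  for (n in c(100, 777, 1500, 2254)) {
    g <- toy_genome(c("portal protein", "tape measure protein",
                      "hypothetical protein", "tail protein", "holin"),
                    translations = c(strrep("M", 200), strrep("A", n),
                                     strrep("A", 110), strrep("A", 400),
                                     strrep("M", 100)))
    lay <- resolve_tmp_dit_tal(locate_tail_module(partition_modules(g)), g)
    expect_equal(lay$estimated_tail_length_nm, 0.15 * n)
  }
})

test_that("temperate detection needs integrase or a true repressor", {
  g <- toy_genome(c("portal protein", "integrase", "holin"))
  tf <- detect_temperate(g)
  expect_true(tf$has_integrase)
  expect_true(tf$is_temperate)

  g2 <- toy_genome(c("portal protein", "holin"))
  expect_false(detect_temperate(g2)$is_temperate)

  # anti-repressor alone is not a repressor
  g3 <- toy_genome(c("portal protein", "anti-repressor", "holin"))
  tf3 <- detect_temperate(g3)
  expect_false(tf3$has_repressor)
  expect_false(tf3$is_temperate)

  g4 <- toy_genome(c("portal protein", "CI-like repressor protein", "holin"))
  expect_true(detect_temperate(g4)$has_repressor)
})
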