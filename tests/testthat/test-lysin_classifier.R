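lib <- tal_motif_library()
PC <- talscan:::PLACEHOLDER_CONSENSUS

hits_for <- function(p) scan_domains(p, lib)

taep_protein <- function(da, len = 600, seed = 7) {
  plants <- list(list(consensus = PC[["endopeptidase"]], at = 9))
  mid <- floor(len * 0.45)
  extra <- switch(da,
    DA1 = list(),
    DA2 = list(list(consensus = PC[["lysozyme"]], at = mid),
               list(consensus = PC[["CHAP"]], at = mid + 40)),
    DA3 = list(list(consensus = PC[["lysozyme"]], at = mid),
               list(consensus = PC[["M23_peptidase"]], at = len - 34)),
    DA4 = list(list(consensus = PC[["lysozyme"]], at = mid),
               list(consensus = PC[["amidase"]], at = len - 34)),
    DA5 = list(list(consensus = PC[["endosialidase_chaperone"]], at = mid)))
  protein_with_motifs(len, c(plants, extra), seed = seed)
}

test_that("TAEP domain architectures DA1-DA5 are assigned from hit sets", {
  for (da in paste0("DA", 1:5)) {
    p <- taep_protein(da)
    expect_equal(assign_taep_da(hits_for(p), nchar(p)),
                 paste0("TAEP-", da), info = da)
  }
  # unexpected accessory combination
  p <- protein_with_motifs(600, list(
    list(consensus = PC[["endopeptidase"]], at = 9),
    list(consensus = PC[["CHAP"]], at = 300)), seed = 9)
  expect_equal(assign_taep_da(hits_for(p), 600), "TAEP-DA-other")
  expect_error(assign_taep_da(hits_for(strrep("K", 100)), 100),
               "endopeptidase")
})

test_that("NLPC/P60 architectures distinguish position and accessories", {
  central <- protein_with_motifs(300, list(
    list(consensus = PC[["NLPC_P60"]], at = 136)), seed = 3)
  expect_equal(assign_nlpc_da(hits_for(central), 300), "NLPC-DA1")

  nterm <- protein_with_motifs(300, list(
    list(consensus = PC[["NLPC_P60"]], at = 7)), seed = 3)
  expect_equal(assign_nlpc_da(hits_for(nterm), 300), "NLPC-DA4")

  lyz <- protein_with_motifs(300, list(
    list(consensus = PC[["NLPC_P60"]], at = 136),
    list(consensus = PC[["lysozyme"]], at = 260)), seed = 3)
  expect_equal(assign_nlpc_da(hits_for(lyz), 300), "NLPC-DA2")

  m23 <- protein_with_motifs(300, list(
    list(consensus = PC[["NLPC_P60"]], at = 136),
    list(consensus = PC[["M23_peptidase"]], at = 260)), seed = 3)
  expect_equal(assign_nlpc_da(hits_for(m23), 300), "NLPC-DA5")
})

test_that("GDPD architectures DA1-DA3 are assigned from hit sets", {
  gd <- talscan:::GDPD_CONSENSUS
  alone <- protein_with_motifs(240, list(list(consensus = gd, at = 90)),
                               seed = 5)
  expect_equal(assign_gdpd_da(hits_for(alone), 240), "GDPD-DA1")

  mem <- protein_with_motifs(310, list(
    list(consensus = gd, at = 120),
    list(consensus = PC[["membrane"]], at = 276)), seed = 5)
  expect_equal(assign_gdpd_da(hits_for(mem), 310), "GDPD-DA2")

  bpu <- protein_with_motifs(460, list(
    list(consensus = PC[["baseplate_upper"]], at = 9),
    list(consensus = gd, at = 390)), seed = 5)
  expect_equal(assign_gdpd_da(hits_for(bpu), 460), "GDPD-DA3")
})

test_that("class priority yields exactly one class per protein", {
  layout <- structure(list(tail_gene_ids = c("gTMP", "gDIT", "gTAL"),
                           tmp_id = "gTMP", dit_id = "gDIT",
                           tal_id = "gTAL", conforms_tmp_dit_tal = TRUE,
                           estimated_tail_length_nm = 200),
                      class = "TailModuleLayout")
  tmp_aa <- protein_with_motifs(1500, list(
    list(consensus = talscan:::GH23_1P_CONSENSUS, at = 1411)), seed = 1)
  gene_tmp <- gene_feature("gTMP", 0, 3 * 1501, product = "tape measure protein",
                           translation = tmp_aa)
  call_tmp <- classify_lysin(gene_tmp, layout, hits_for(tmp_aa))
  expect_equal(call_tmp$tal_class, "TMP_LT")
  expect_true(call_tmp$in_tmp)
  expect_equal(call_tmp$lt_family, "1P")
  expect_true(call_tmp$catalytic_ok)

  tal_aa <- taep_protein("DA1")
  gene_tal <- gene_feature("gTAL", 10000, 10000 + 3 * 601,
                           product = "tail associated lysin",
                           translation = tal_aa)
  call_tal <- classify_lysin(gene_tal, layout, hits_for(tal_aa))
  expect_equal(call_tal$tal_class, "TAEP")
  expect_equal(call_tal$da_group, "TAEP-DA1")
  expect_true(call_tal$in_tal_position)

  # no hits -> none
  blank <- gene_feature("gDIT", 5000, 5000 + 3 * 121,
                        product = "hypothetical protein",
                        translation = random_aa(120, seed = 2))
  call_no <- classify_lysin(blank, layout,
                            hits_for(random_aa(120, seed = 2)))
  expect_equal(call_no$tal_class, "none")
  expect_equal(call_no$da_group, "")

  # two-class evidence: priority wins, secondary recorded
  both_aa <- protein_with_motifs(600, list(
    list(consensus = PC[["endopeptidase"]], at = 9),
    list(consensus = talscan:::GDPD_CONSENSUS, at = 300)), seed = 6)
  gene_both <- gene_feature("gTAL2", 20000, 20000 + 3 * 601,
                            product = "tail protein", translation = both_aa)
  layout2 <- layout; layout2$tail_gene_ids <- c(layout$tail_gene_ids, "gTAL2")
  call_both <- classify_lysin(gene_both, layout2, hits_for(both_aa))
  expect_equal(call_both$tal_class, "TAEP")
  expect_match(call_both$secondary_classes, "GDPD")
})

test_that("catalytic residues verify on intact and fail on mutated sites", {
  gd <- talscan:::GDPD_CONSENSUS
  p <- protein_with_motifs(240, list(list(consensus = gd, at = 91)), seed = 5)
  call <- list(tal_class = "GDPD")
  expect_true(verify_catalytic(p, call))

  # substitute the first catalytic histidine (profile column 10)
  cols <- talscan:::GDPD_COLUMNS
  mut <- mutate_motif(p, positions = 91 - 1 + cols$catalytic[1], rate = 1,
                      seed = 3)
  expect_false(verify_catalytic(mut$sequence, call))

  # metal-binding aspartate
  mut2 <- mutate_motif(p, positions = 91 - 1 + cols$metal[3], rate = 1,
                       seed = 4)
  expect_false(verify_catalytic(mut2$sequence, call))

  # alignment failure path: unrelated protein
  expect_message(ok <- verify_catalytic(strrep("KD", 100), call),
                 "failed")
  expect_false(ok)
})

test_that("LT families follow the motif and extra-position rules", {
  p1p <- protein_with_motifs(1500, list(
    list(consensus = talscan:::GH23_1P_CONSENSUS, at = 1411)), seed = 1)
  expect_equal(classify_lt_family(p1p, is_tmp = TRUE), "1P")

  # motifs I-IV intact but 1P-specific positions absent -> 1A
  p1a <- protein_with_motifs(1500, list(
    list(consensus = talscan:::GH23_1A_CONSENSUS, at = 1411)), seed = 1)
  expect_equal(classify_lt_family(p1a, is_tmp = TRUE), "1A")

  # catalytic E removed -> unassigned
  cols <- talscan:::GH23_COLUMNS
  noE <- mutate_motif(p1p, positions = 1411 - 1 + cols$catalytic, rate = 1,
                      seed = 9)
  expect_equal(classify_lt_family(noE$sequence, is_tmp = TRUE), "unassigned")

  # N-terminal LT in a non-TMP protein -> family 1E
  p1e <- protein_with_motifs(600, list(
    list(consensus = talscan:::GH23_1A_CONSENSUS, at = 15)), seed = 2)
  expect_equal(classify_lt_family(p1e, is_tmp = FALSE), "1E")

  # every 1P call also satisfies the 1A criteria (subset property)
  for (m in reference_members("TMP_LT", n = 6)) {
    prot <- protein_with_motifs(1300, list(list(consensus = m, at = 1211)),
                                seed = 10)
    fam <- classify_lt_family(prot, is_tmp = TRUE)
    expect_true(fam %in% c("1P", "1A"))
  }
})
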