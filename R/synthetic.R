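# Synthetic phage/prophage genome generator with planted ground truth.
#
# Genomes are emitted with the canonical module order (Packaging - Head -
# Tail - Lysis - DNA metabolism, plus a lysogeny module in temperate
# genomes), a TMP-Dit-Tal tail unit where the morphotype has one, and lysin
# genes whose translations embed the packaged class consensus patterns at
# the class's declared region. Morphotype-specific arrangements follow the
# observed patterns: group-1 siphoviruses carry both a TMP-LT and a Tal
# TAEP; group-2 siphoviruses a Tal TAEP only; myoviruses a TMP-LT plus an
# adjacent NLPC/P60 tail protein; podoviruses an NLPC/P60 protein between
# the head and lysis modules and no TMP-Dit-Tal unit.

MORPHOTYPES <- c("podo", "sipho1", "sipho2", "myo")

SIZE_RANGES_KB <- list(podo = c(17.9, 30.5), sipho1 = c(21, 43),
                       sipho2 = c(55, 86), myo = c(130.9, 156.5))

MORPH_TO_HINT <- c(podo = "podovirus", sipho1 = "siphovirus",
                   sipho2 = "siphovirus", myo = "myovirus")

MORPH_TO_SIZE_GROUP <- c(podo = "podo_small", sipho1 = "sipho_group1",
                         sipho2 = "sipho_group2", myo = "myo_large")

#' Simulation configuration
#'
#' @param n_genomes number of genomes.
#' @param morphotype_mix proportions over \code{podo, sipho1, sipho2, myo}
#'   (sum 1). The default emulates a prophage-dominated cohort in which the
#'   realized lysin-class proportions approximate \code{class_mix}.
#' @param class_mix proportions over the five lysin classes (sum 1). The
#'   TAEP / TMP_LT / NLPC_P60 shares are implied by the morphotype
#'   arrangement patterns; the GDPD and PECTINESTERASE shares control how
#'   often those extra lysins are planted in siphovirus tail modules.
#' @param noise list: \code{p_hypothetical} (per-gene probability of
#'   replacing the product with "hypothetical protein"), \code{p_shuffle}
#'   (fraction of genes whose annotation strings are permuted among
#'   themselves), \code{p_drop_dit} (per-genome probability of deleting the
#'   Dit gene).
#' @param temperate_fraction fraction of genomes given integrase (and half
#'   of those also repressor) genes.
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @param gc intergenic GC fraction.
#' @param include_sequence emit nucleotide sequence (reverse-translated
#'   CDSs plus random intergenic DNA); disable for large feature-only
#'   cohorts.
#' @return validated config list of class \code{SimConfig}.
#' @export
sim_config <- function(n_genomes = 50,
                       morphotype_mix = c(podo = 0.03, sipho1 = 0.18,
                                          sipho2 = 0.74, myo = 0.05),
                       class_mix = c(TAEP = 0.704, TMP_LT = 0.181,
                                     NLPC_P60 = 0.062, GDPD = 0.040,
                                     PECTINESTERASE = 0.013),
                       noise = list(p_hypothetical = 0, p_shuffle = 0,
                                    p_drop_dit = 0),
                       temperate_fraction = 0.16,
                       seed = 1, gc = 0.35, include_sequence = TRUE) {
  stopifnot(n_genomes >= 1,
            abs(sum(morphotype_mix) - 1) < 1e-9,
            abs(sum(class_mix) - 1) < 1e-9,
            all(names(morphotype_mix) == MORPHOTYPES),
            all(names(class_mix) == TAL_CLASSES))
  noise <- utils::modifyList(list(p_hypothetical = 0, p_shuffle = 0,
                                  p_drop_dit = 0), noise)
  if (any(unlist(noise) < 0 | unlist(noise) > 1))
    stop("noise probabilities must lie in [0, 1]")
  if (temperate_fraction < 0 || temperate_fraction > 1)
    stop("temperate_fraction must lie in [0, 1]")
  structure(list(n_genomes = n_genomes, morphotype_mix = morphotype_mix,
                 class_mix = class_mix, noise = noise,
                 temperate_fraction = temperate_fraction, seed = seed,
                 gc = gc, include_sequence = include_sequence),
            class = "SimConfig")
}

#' Expected lysin-class proportions implied by a configuration
#'
#' Base per-genome class counts follow the morphotype arrangement patterns
#' (sipho1: TAEP + TMP_LT; sipho2: TAEP; myo: TMP_LT + NLPC; podo: NLPC);
#' GDPD and pectinesterase extras are planted in siphovirus genomes at
#' rates derived from \code{class_mix}.
#'
#' @param cfg a \code{SimConfig}.
#' @return named vector of expected class proportions (sums to 1).
#' @export
expected_class_mix <- function(cfg) {
  m <- cfg$morphotype_mix
  base <- c(TAEP = unname(m["sipho1"] + m["sipho2"]),
            TMP_LT = unname(m["sipho1"] + m["myo"]),
            NLPC_P60 = unname(m["podo"] + m["myo"]),
            GDPD = 0, PECTINESTERASE = 0)
  rates <- extra_plant_rates(cfg)
  base["GDPD"] <- rates$g
  base["PECTINESTERASE"] <- rates$e
  base / sum(base)
}

# per-genome expected extra-lysin counts g (GDPD) and e (pectinesterase)
extra_plant_rates <- function(cfg) {
  m <- cfg$morphotype_mix
  B <- unname(2 * m["sipho1"] + m["sipho2"] + 2 * m["myo"] + m["podo"])
  cg <- unname(cfg$class_mix["GDPD"])
  ce <- unname(cfg$class_mix["PECTINESTERASE"])
  g <- cg * B / (1 - cg - ce)
  e <- ce * B / (1 - cg - ce)
  sipho <- unname(m["sipho1"] + m["sipho2"])
  list(g = g, e = e,
       p_gdpd = if (sipho > 0) min(1, g / sipho) else 0,
       p_pe = if (sipho > 0) min(1, e / sipho) else 0)
}

TAEP_DA_WEIGHTS <- c("TAEP-DA1" = 0.605, "TAEP-DA2" = 0.14,
                     "TAEP-DA3" = 0.12, "TAEP-DA4" = 0.10,
                     "TAEP-DA5" = 0.035)
GDPD_DA_WEIGHTS <- c("GDPD-DA1" = 0.591, "GDPD-DA2" = 0.25,
                     "GDPD-DA3" = 0.159)
NLPC_DA_WEIGHTS_PODO <- c("NLPC-DA1" = 0.55, "NLPC-DA2" = 0.08,
                          "NLPC-DA4" = 0.37)
NLPC_DA_WEIGHTS_MYO <- c("NLPC-DA1" = 0.5, "NLPC-DA5" = 0.5)

rand_protein <- function(n) paste(sample(AA20, n, replace = TRUE),
                                  collapse = "")

# overwrite `protein` with `motif` starting at 1-based position `at`
plant_motif <- function(protein, motif, at) {
  stopifnot(at >= 1, at + nchar(motif) - 1 <= nchar(protein))
  paste0(substr(protein, 1, at - 1), motif,
         substr(protein, at + nchar(motif), nchar(protein)))
}

# ---- planted lysin proteins --------------------------------------------

make_taep_protein <- function(da) {
  L <- sample(420:900, 1)
  p <- rand_protein(L)
  p <- plant_motif(p, PLACEHOLDER_CONSENSUS[["endopeptidase"]], 9)
  mid <- floor(L * 0.45)
  p <- switch(da,
    "TAEP-DA1" = p,
    "TAEP-DA2" = plant_motif(plant_motif(p,
        PLACEHOLDER_CONSENSUS[["lysozyme"]], mid),
        PLACEHOLDER_CONSENSUS[["CHAP"]], mid + 40),
    "TAEP-DA3" = plant_motif(plant_motif(p,
        PLACEHOLDER_CONSENSUS[["lysozyme"]], mid),
        PLACEHOLDER_CONSENSUS[["M23_peptidase"]], L - 34),
    "TAEP-DA4" = plant_motif(plant_motif(p,
        PLACEHOLDER_CONSENSUS[["lysozyme"]], mid),
        PLACEHOLDER_CONSENSUS[["amidase"]], L - 34),
    "TAEP-DA5" = plant_motif(p,
        PLACEHOLDER_CONSENSUS[["endosialidase_chaperone"]], mid))
  p
}

make_nlpc_protein <- function(da) {
  L <- sample(240:400, 1)
  cons <- PLACEHOLDER_CONSENSUS[["NLPC_P60"]]
  central <- floor(L / 2) - 14
  switch(da,
    "NLPC-DA1" = plant_motif(rand_protein(L), cons, central),
    "NLPC-DA2" = plant_motif(plant_motif(rand_protein(L), cons, central),
                             PLACEHOLDER_CONSENSUS[["lysozyme"]], L - 34),
    "NLPC-DA4" = plant_motif(rand_protein(L), cons, 7),
    "NLPC-DA5" = plant_motif(plant_motif(rand_protein(L), cons, central),
                             PLACEHOLDER_CONSENSUS[["M23_peptidase"]], L - 34))
}

make_gdpd_protein <- function(da) {
  cons <- GDPD_CONSENSUS
  switch(da,
    "GDPD-DA1" = {
      L <- sample(230:260, 1)
      plant_motif(rand_protein(L), cons, floor(L / 2) - 30)
    },
    "GDPD-DA2" = {
      L <- sample(290:330, 1)
      plant_motif(plant_motif(rand_protein(L), cons, floor(L / 2) - 30),
                  PLACEHOLDER_CONSENSUS[["membrane"]], L - 34)
    },
    "GDPD-DA3" = {
      L <- sample(430:480, 1)
      plant_motif(plant_motif(rand_protein(L),
                              PLACEHOLDER_CONSENSUS[["baseplate_upper"]], 9),
                  cons, L - 70)
    })
}

make_pe_protein <- function() {
  L <- sample(450:600, 1)
  plant_motif(rand_protein(L), PLACEHOLDER_CONSENSUS[["pectinesterase"]],
              floor(L / 2) - 14)
}

make_tmp_protein <- function(len_range, with_lt) {
  L <- sample(len_range[1]:len_range[2], 1)
  p <- rand_protein(L)
  if (with_lt) p <- plant_motif(p, GH23_1P_CONSENSUS, L - 89)
  p
}

# ---- genome assembly ---------------------------------------------------

new_gene <- function(product, aa, module, role = "") {
  list(product = product, aa = aa, module = module, role = role)
}

FILLERS <- list(
  packaging = list(c("DNA packaging protein", 150, 300)),
  head = list(c("minor capsid protein", 120, 300),
              c("head morphogenesis protein", 200, 350),
              c("head-tail connector protein", 150, 250)),
  tail = list(c("minor tail protein", 120, 300),
              c("tail assembly chaperone", 100, 200)),
  dna_metabolism = list(c("ATP-dependent nuclease", 250, 450),
                        c("DNA helicase", 300, 450),
                        c("replicative DNA polymerase", 400, 600))
)

simulate_genome <- function(id, morphotype, cfg, rates) {
  target_bp <- round(1000 * runif(1, SIZE_RANGES_KB[[morphotype]][1],
                                  SIZE_RANGES_KB[[morphotype]][2]))
  temperate <- runif(1) < cfg$temperate_fraction
  with_repressor <- temperate && runif(1) < 0.5
  is_sipho <- morphotype %in% c("sipho1", "sipho2")
  plant_gdpd <- is_sipho && runif(1) < rates$p_gdpd
  plant_pe <- is_sipho && runif(1) < rates$p_pe

  genes <- list()
  truth_genes <- list()
  add <- function(g) genes[[length(genes) + 1L]] <<- g
  mark <- function(role, tal_class, da = "", lt = "not_applicable") {
    truth_genes[[length(truth_genes) + 1L]] <<-
      list(index = length(genes), role = role, tal_class = tal_class,
           da_group = da, lt_family = lt)
  }

  add(new_gene("terminase small subunit", sample(140:200, 1), "packaging"))
  add(new_gene("terminase large subunit", sample(400:600, 1), "packaging"))
  add(new_gene("portal protein", sample(400:500, 1), "head"))
  add(new_gene("major capsid protein", sample(300:400, 1), "head"))
  add(new_gene("head scaffolding protein", sample(200:280, 1), "head"))

  tal_da <- NULL
  if (morphotype == "podo") {
    da <- sample(names(NLPC_DA_WEIGHTS_PODO), 1,
                 prob = NLPC_DA_WEIGHTS_PODO)
    aa <- make_nlpc_protein(da)
    add(new_gene("hypothetical protein", aa, "tail_candidate"))
    mark("nlpc", "NLPC_P60", da)
  } else {
    add(new_gene("major tail protein", sample(180:250, 1), "tail"))
    with_lt <- morphotype %in% c("sipho1", "myo")
    tmp_range <- switch(morphotype, sipho1 = c(1180, 1500),
                        sipho2 = c(1300, 1800), myo = c(1500, 2254))
    add(new_gene("tape measure protein",
                 make_tmp_protein(tmp_range, with_lt), "tail"))
    mark("tmp", if (with_lt) "TMP_LT" else "none",
         if (with_lt) "TMPLT-DA1" else "",
         if (with_lt) "1P" else "not_applicable")
    add(new_gene("hypothetical protein", sample(110:130, 1), "tail"))
    mark("dit", "none")
    if (morphotype == "myo") {
      da <- sample(names(NLPC_DA_WEIGHTS_MYO), 1,
                   prob = NLPC_DA_WEIGHTS_MYO)
      add(new_gene("tail protein", make_nlpc_protein(da), "tail"))
      mark("tal", "NLPC_P60", da)
    } else {
      tal_da <- sample(names(TAEP_DA_WEIGHTS), 1, prob = TAEP_DA_WEIGHTS)
      add(new_gene("tail associated lysin", make_taep_protein(tal_da),
                   "tail"))
      mark("tal", "TAEP", tal_da)
    }
    if (plant_pe) {
      add(new_gene("tail protein", make_pe_protein(), "tail"))
      mark("pe", "PECTINESTERASE", "PE-DA1")
    }
    if (plant_gdpd) {
      da <- sample(names(GDPD_DA_WEIGHTS), 1, prob = GDPD_DA_WEIGHTS)
      add(new_gene("tail protein", make_gdpd_protein(da), "tail"))
      mark("gdpd", "GDPD", da)
    }
    add(new_gene("tail fiber protein", sample(250:450, 1), "tail"))
  }

  add(new_gene("holin", sample(90:130, 1), "lysis"))
  add(new_gene("endolysin", sample(250:350, 1), "lysis"))
  add(new_gene("DNA polymerase", sample(500:700, 1), "dna_metabolism"))
  add(new_gene("DNA primase", sample(250:400, 1), "dna_metabolism"))
  add(new_gene("HNH endonuclease", sample(120:200, 1), "dna_metabolism"))
  if (temperate) {
    add(new_gene("integrase", sample(300:400, 1), "lysogeny"))
    if (with_repressor)
      add(new_gene("repressor protein", sample(180:230, 1), "lysogeny"))
  }

  # materialise protein strings for the non-lysin genes (lengths so far)
  genes <- lapply(genes, function(g) {
    if (is.numeric(g$aa)) g$aa <- rand_protein(g$aa)
    g
  })

  # filler genes to approach the target size
  est_bp <- function(gs) sum(vapply(gs, function(g)
    3L * (nchar(g$aa) + 1L), 0L)) + 80L * length(gs) + 200L
  fill_modules <- names(FILLERS)
  k <- 0L
  while (est_bp(genes) < target_bp - 2500) {
    k <- k + 1L
    mod <- fill_modules[1L + (k %% length(fill_modules))]
    if (mod == "tail" && morphotype == "podo") mod <- "head"
    spec <- FILLERS[[mod]][[1L + (k %% length(FILLERS[[mod]]))]]
    aa <- rand_protein(sample(as.integer(spec[2]):as.integer(spec[3]), 1))
    ins_mod <- mod
    g <- new_gene(spec[1], aa, ins_mod)
    # insert at the START of the gene's module block to keep the
    # TMP-Dit-Tal unit and planted neighbours contiguous
    first <- which(vapply(genes, function(x) x$module, "") == ins_mod)[1]
    if (is.na(first)) genes <- c(genes, list(g))
    else {
      genes <- append(genes, list(g), after = first - 1L)
      truth_genes <- lapply(truth_genes, function(t) {
        if (t$index >= first) t$index <- t$index + 1L
        t
      })
    }
  }

  # noise: drop Dit
  dropped_dit <- FALSE
  if (cfg$noise$p_drop_dit > 0 && runif(1) < cfg$noise$p_drop_dit) {
    diti <- vapply(truth_genes, function(t) t$role, "") == "dit"
    if (any(diti)) {
      di <- truth_genes[[which(diti)]]$index
      genes <- genes[-di]
      truth_genes <- lapply(truth_genes[!diti], function(t) {
        if (t$index > di) t$index <- t$index - 1L
        t
      })
      dropped_dit <- TRUE
    }
  }

  n <- length(genes)
  products <- vapply(genes, function(g) g$product, "")
  # noise: misannotation
  if (cfg$noise$p_hypothetical > 0) {
    hyp <- runif(n) < cfg$noise$p_hypothetical
    products[hyp] <- "hypothetical protein"
  }
  if (cfg$noise$p_shuffle > 0) {
    pick <- which(runif(n) < cfg$noise$p_shuffle)
    if (length(pick) > 1) products[pick] <- products[sample(pick)]
  }

  gene_ids <- sprintf("%s_g%03d", id, seq_len(n))
  # assemble coordinates (forward strand, sequential)
  rows <- vector("list", n)
  pos <- 100L
  seq_parts <- if (cfg$include_sequence) list(random_dna(100L, cfg$gc)) else NULL
  for (i in seq_len(n)) {
    aa <- genes[[i]]$aa
    nt_len <- 3L * (nchar(aa) + 1L)
    rows[[i]] <- gene_feature(gene_ids[i], pos, pos + nt_len,
                              strand = "forward", kind = "CDS",
                              product = products[i], translation = aa)
    gap <- sample(40:120, 1)
    if (cfg$include_sequence) {
      seq_parts[[length(seq_parts) + 1L]] <- reverse_translate(aa)
      seq_parts[[length(seq_parts) + 1L]] <- random_dna(gap, cfg$gc)
    }
    pos <- pos + nt_len + gap
  }
  # tRNA genes for the larger genomes
  n_trna <- switch(morphotype, sipho2 = 2L, myo = 4L, 0L)
  for (t in seq_len(n_trna)) {
    rows[[length(rows) + 1L]] <- gene_feature(
      sprintf("%s_t%02d", id, t), pos, pos + 75L, kind = "tRNA",
      product = sprintf("tRNA-%s", c("Leu", "Ser", "Arg", "Gly")[t]))
    if (cfg$include_sequence)
      seq_parts[[length(seq_parts) + 1L]] <- random_dna(115L, cfg$gc)
    pos <- pos + 115L
  }
  length_bp <- max(target_bp, pos + 100L)
  sequence <- ""
  if (cfg$include_sequence) {
    seq_parts[[length(seq_parts) + 1L]] <-
      random_dna(length_bp - pos, cfg$gc)
    sequence <- paste(unlist(seq_parts), collapse = "")
    length_bp <- nchar(sequence)
  }
  genome <- genome_record(id, do.call(rbind, rows), sequence = sequence,
                          length_bp = length_bp,
                          source_kind = if (morphotype == "sipho2" ||
                                            morphotype == "sipho1")
                            sample(c("phage", "prophage"), 1) else "phage")

  module_order <- rle(vapply(genes, function(g)
    if (g$module == "tail_candidate") "hypothetical" else g$module, ""))$values
  arrangement <- switch(morphotype, podo = "no_tal",
                        sipho1 = "tmplt_and_taep",
                        sipho2 = "taep_in_tal_only",
                        myo = "tmplt_only")
  role_id <- function(role) {
    i <- which(vapply(truth_genes, function(t) t$role, "") == role)
    if (length(i)) gene_ids[truth_genes[[i[1]]]$index] else NA_character_
  }
  truth_genome <- data.frame(
    genome_id = id, morphotype = morphotype,
    morphology_hint = unname(MORPH_TO_HINT[morphotype]),
    size_group = unname(MORPH_TO_SIZE_GROUP[morphotype]),
    length_bp = length_bp,
    module_order = paste(module_order, collapse = ","),
    tmp_id = if (morphotype == "podo") NA_character_ else role_id("tmp"),
    dit_id = if (morphotype == "podo" || dropped_dit) NA_character_
             else role_id("dit"),
    tal_id = if (morphotype == "podo") NA_character_ else role_id("tal"),
    arrangement = arrangement,
    is_temperate = temperate,
    has_integrase = temperate,
    has_repressor = with_repressor,
    n_cds = n, stringsAsFactors = FALSE)
  truth_gene_df <- do.call(rbind, lapply(truth_genes, function(t)
    data.frame(genome_id = id, gene_id = gene_ids[t$index], role = t$role,
               tal_class = t$tal_class, da_group = t$da_group,
               lt_family = t$lt_family, stringsAsFactors = FALSE)))
  list(genome = genome, truth_genome = truth_genome,
       truth_genes = truth_gene_df)
}

random_dna <- function(n, gc) {
  if (n <= 0) return("")
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

reverse_translate <- local({
  env <- new.env()
  function(aa) {
    if (is.null(env$tab)) {
      gc11 <- Biostrings::getGeneticCode("11")
      env$tab <- split(names(gc11), gc11)
    }
    tab <- env$tab
    cods <- tab[c(chars(aa), "*")]
    nl <- lengths(cods)
    idx <- floor(runif(length(cods)) * nl) + 1L
    offs <- cumsum(c(0L, head(nl, -1L)))
    paste(unlist(cods, use.names = FALSE)[offs + idx], collapse = "")
  }
})

#' Simulate a cohort of annotated genomes with ground truth
#'
#' Fully reproducible from \code{cfg$seed}: genome sizes are drawn per
#' morphotype from the canonical ranges (podo 17.9-30.5 kb, sipho1
#' 21-43 kb, sipho2 55-86 kb, myo 130.9-156.5 kb), modules are emitted in
#' Packaging-Head-Tail-Lysis-DNA order, lysins are planted per morphotype
#' pattern with the class consensus embedded at the declared region, and
#' annotation noise is applied after planting.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return list with \code{genomes} (list of \code{GenomeRecord}),
#'   \code{truth_genomes} (per-genome ground truth \code{data.frame}),
#'   \code{truth_genes} (per-planted-gene ground truth) and \code{config}.
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "SimConfig"))
  with_seed(cfg$seed, {
    morphs <- sample(MORPHOTYPES, cfg$n_genomes, replace = TRUE,
                     prob = cfg$morphotype_mix)
    rates <- extra_plant_rates(cfg)
    sims <- lapply(seq_len(cfg$n_genomes), function(i)
      simulate_genome(sprintf("SYN%04d", i), morphs[i], cfg, rates))
    list(genomes = lapply(sims, `[[`, "genome"),
         truth_genomes = do.call(rbind, lapply(sims, `[[`, "truth_genome")),
         truth_genes = do.call(rbind, lapply(sims, `[[`, "truth_genes")),
         config = cfg)
  })
}

#' Write a simulated cohort to disk
#'
#' One GenBank file per genome plus ground-truth TSVs.
#'
#' @param cohort result of \code{\link{simulate_cohort}}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (g in cohort$genomes)
    write_genbank(g, file.path(dir, paste0(g$genome_id, ".gbk")))
  write_tsv(cohort$truth_genomes, file.path(dir, "truth_genomes.tsv"))
  write_tsv(cohort$truth_genes, file.path(dir, "truth_genes.tsv"))
  invisible(dir)
}

#' Mutate selected positions of a protein
#'
#' Seeded substitutions at the given (1-based) positions, each applied with
#' probability \code{rate}; substituted residues are drawn uniformly from
#' the 19 alternatives.
#'
#' @param protein amino-acid string.
#' @param positions integer vector of 1-based positions eligible for
#'   substitution.
#' @param rate substitution probability per position, in [0, 1].
#' @param seed RNG seed.
#' @return list with \code{sequence} and \code{substitutions}
#'   (data.frame: position, from, to).
#' @export
mutate_motif <- function(protein, positions, rate, seed = 1) {
  stopifnot(rate >= 0, rate <= 1,
            all(positions >= 1), all(positions <= nchar(protein)))
  with_seed(seed, {
    s <- chars(protein)
    hit <- positions[runif(length(positions)) < rate]
    subs <- lapply(hit, function(p) {
      from <- s[p]
      to <- sample(setdiff(AA20, from), 1)
      s[p] <<- to
      data.frame(position = p, from = from, to = to,
                 stringsAsFactors = FALSE)
    })
    list(sequence = paste(s, collapse = ""),
         substitutions = if (length(subs)) do.call(rbind, subs)
                         else data.frame(position = integer(),
                                         from = character(),
                                         to = character()))
  })
}
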