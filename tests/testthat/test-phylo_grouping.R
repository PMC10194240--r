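test_that("pairwise distance is an alignment-based identity complement", {
  expect_equal(pairwise_distance("MKTAYI", "MKTAYI"), 0)
  expect_equal(pairwise_distance("AAAA", "WWWW"), 1)
  # gap-free alignment, 5/6 identity
  expect_equal(pairwise_distance("ACDEFG", "ACDEFA"), 1 / 6,
               tolerance = 1e-12)
  # symmetry
  a <- random_aa(40, seed = 1); b <- random_aa(35, seed = 2)
  expect_equal(pairwise_distance(a, b), pairwise_distance(b, a))
})

test_that("three-taxon NJ matches the closed-form branch lengths", {
  d <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(d)
  expect_equal(sort(tr$tip.label), c("a", "b", "c"))
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[["a"]], (3 + 5 - 6) / 2) # 1
  expect_equal(bl[["b"]], (3 + 6 - 5) / 2) # 2
  expect_equal(bl[["c"]], (5 + 6 - 3) / 2) # 4
})

test_that("NJ reconstructs additive trees exactly for n <= 8", {
  withr::with_seed(9, {
    for (n in 4:8) {
      tr <- ape::rtree(n, rooted = FALSE,
                       br = function(k) runif(k, 0.2, 1.5))
      dm <- ape::cophenetic.phylo(tr)
      dm <- dm[sort(rownames(dm)), sort(colnames(dm))]
      nj1 <- neighbor_joining(dm)
      expect_equal(ape::dist.topo(ape::unroot(tr), nj1), 0,
                   ignore_attr = TRUE)
      # branch lengths reproduce the generating path distances
      back <- ape::cophenetic.phylo(nj1)[rownames(dm), colnames(dm)]
      expect_equal(back, dm, tolerance = 1e-9)
    }
  })
})

test_that("NJ agrees with exhaustive topology search on additive input", {
  withr::with_seed(31, {
    for (n in 4:6) {
      tr <- ape::rtree(n, rooted = FALSE,
                       br = function(k) runif(k, 0.3, 1.2))
      dm <- ape::cophenetic.phylo(tr)
      dm <- dm[sort(rownames(dm)), sort(colnames(dm))]
      nj1 <- neighbor_joining(dm)
      allt <- phangorn::allTrees(n, rooted = FALSE,
                                 tip.label = rownames(dm))
      fits <- vapply(allt, function(t) {
        ft <- phangorn::nnls.tree(dm, t, method = "unrooted", trace = 0)
        sum((ape::cophenetic.phylo(ft)[rownames(dm), colnames(dm)] - dm)^2)
      }, numeric(1))
      # exactly one topology fits the additive matrix, and NJ finds it
      expect_equal(sum(fits < 1e-10), 1)
      expect_equal(ape::dist.topo(allt[[which.min(fits)]], nj1), 0,
                   ignore_attr = TRUE)
    }
  })
})

test_that("NJ matches the reference implementation on generic matrices", {
  withr::with_seed(13, {
    seqs <- setNames(
      vapply(1:7, function(i) random_aa(60), ""), paste0("p", 1:7))
    dm <- distance_matrix(seqs)
    expect_equal(ape::dist.topo(neighbor_joining(dm), ape::nj(dm)), 0,
                 ignore_attr = TRUE)
  })
})

test_that("degenerate and invalid matrices are handled", {
  # all equal distances: deterministic output under the lowest-index rule
  d <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(d) <- 0
  t1 <- neighbor_joining(d)
  t2 <- neighbor_joining(d)
  expect_equal(ape::write.tree(t1), ape::write.tree(t2))
  expect_equal(sort(t1$tip.label), letters[1:4])
  expect_true(all(t1$edge.length >= 0))

  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(neighbor_joining(matrix(c(0, 1, 1, 2, 0, 1, 1, 1, 0), 3, 3)),
               "symmetric")
})

test_that("Newick round trip preserves leaves and topology", {
  withr::with_seed(3, {
    tr <- ape::rtree(6, rooted = FALSE)
    dm <- ape::cophenetic.phylo(tr)
    nj1 <- neighbor_joining(dm)
    path <- withr::local_tempfile(fileext = ".nwk")
    write_newick(nj1, path)
    back <- ape::read.tree(path)
    expect_equal(sort(back$tip.label), sort(nj1$tip.label))
    expect_equal(ape::dist.topo(back, nj1), 0, ignore_attr = TRUE)
  })
})

test_that("two-group separation detects exactly matching bipartitions", {
  tr <- ape::read.tree(text = "((a1:1,a2:1):1,(b1:1,b2:1):1);")
  map <- c(a1 = "pod", a2 = "pod", b1 = "myo", b2 = "myo")
  res <- two_group_separation(tr, map)
  expect_true(res$separated)
  expect_false(two_group_separation(
    tr, c(a1 = "myo", a2 = "pod", b1 = "myo", b2 = "myo"))$separated)

  # sequences simulated from two divergent seeds separate cleanly
  withr::with_seed(77, {
    seedA <- random_aa(80)
    seedB <- random_aa(80)
    fam <- c(lapply(1:4, function(i)
               mutate_motif(seedA, 1:80, rate = 0.08, seed = i)$sequence),
             lapply(1:4, function(i)
               mutate_motif(seedB, 1:80, rate = 0.08, seed = 10 + i)$sequence))
    names(fam) <- c(paste0("podo", 1:4), paste0("myo", 1:4))
    dm <- distance_matrix(unlist(fam))
    tree <- neighbor_joining(dm)
    grp <- setNames(rep(c("g1", "g2"), each = 4), names(fam))
    expect_true(two_group_separation(tree, grp)$separated)
  })
})
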