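# Neighbor-joining grouping of lysin proteins.

#' Classical neighbor joining
#'
#' Standard NJ with Q-matrix pair selection and Studier-Keppler distance
#' updates; ties are broken by the lowest index pair, so the result is
#' deterministic. Negative branch-length estimates are clamped to zero and
#' the clamped amount reported via a message. The tree is returned unrooted
#' (trifurcating root node) as an \code{ape} \code{phylo} object.
#'
#' @param dm symmetric numeric matrix with zero diagonal and labels as
#'   dimnames (>= 3 taxa), e.g. from \code{\link{distance_matrix}}.
#' @return an \code{ape::phylo} tree.
#' @export
neighbor_joining <- function(dm) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (n < 3) stop("need at least 3 taxa")
  if (!isTRUE(all.equal(dm, t(dm), tolerance = 1e-8)))
    stop("distance matrix is not symmetric")
  labs <- rownames(dm) %||% paste0("t", seq_len(n))
  frag <- vapply(labs, quote_newick_label, "")
  D <- dm
  clamped <- 0
  clamp <- function(v) {
    if (v < 0) { clamped <<- clamped + abs(v); 0 } else v
  }
  active <- seq_len(n)
  while (length(active) > 3) {
    m <- length(active)
    Dm <- D[active, active, drop = FALSE]
    r <- rowSums(Dm)
    Q <- (m - 2) * Dm - outer(r, r, `+`)
    diag(Q) <- Inf
    # lowest-index pair on ties: scan upper triangle row-major
    best <- c(NA_integer_, NA_integer_); bestq <- Inf
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      if (Q[i, j] < bestq - 1e-12) { bestq <- Q[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    vi <- 0.5 * Dm[i, j] + (r[i] - r[j]) / (2 * (m - 2))
    vj <- Dm[i, j] - vi
    vi <- clamp(vi); vj <- clamp(vj)
    ai <- active[i]; aj <- active[j]
    newfrag <- sprintf("(%s:%.10g,%s:%.10g)", frag[ai], vi, frag[aj], vj)
    # new node reuses slot ai
    newd <- 0.5 * (D[ai, active] + D[aj, active] - D[ai, aj])
    D[ai, active] <- newd; D[active, ai] <- newd
    D[ai, ai] <- 0
    frag[ai] <- newfrag
    active <- setdiff(active, aj)
  }
  a <- active[1]; b <- active[2]; c_ <- active[3]
  va <- clamp((D[a, b] + D[a, c_] - D[b, c_]) / 2)
  vb <- clamp((D[a, b] + D[b, c_] - D[a, c_]) / 2)
  vc <- clamp((D[a, c_] + D[b, c_] - D[a, b]) / 2)
  nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 frag[a], va, frag[b], vb, frag[c_], vc)
  if (clamped > 0)
    message(sprintf("clamped %.6g of negative branch length to zero", clamped))
  ape::read.tree(text = nwk)
}

quote_newick_label <- function(lab) {
  if (grepl("[ ,():;'\\[\\]]", lab))
    paste0("'", gsub("'", "''", lab), "'")
  else lab
}

#' Test whether a tree separates two predefined groups
#'
#' \code{TRUE} iff some internal edge of the (unrooted) tree induces a
#' non-trivial bipartition of the leaves exactly matching the two groups
#' (pendant edges, which split off single leaves, do not count as group
#' structure).
#'
#' @param tree an \code{ape::phylo}.
#' @param labels_to_group named character vector mapping every leaf label to
#'   one of exactly two group labels.
#' @return list with \code{separated} (logical), \code{edge} (index into
#'   \code{tree$edge} of a splitting edge, or \code{NA}) and \code{side}
#'   (leaf labels below that edge).
#' @export
two_group_separation <- function(tree, labels_to_group) {
  tips <- tree$tip.label
  if (!all(tips %in% names(labels_to_group)))
    stop("every leaf must be mapped to a group")
  grp <- labels_to_group[tips]
  lv <- unique(grp)
  if (length(lv) != 2) stop("need exactly two groups")
  g1 <- sort(tips[grp == lv[1]])
  ntip <- length(tips)
  below <- below_tips(tree)
  for (e in seq_len(nrow(tree$edge))) {
    if (tree$edge[e, 2] <= ntip) next
    side <- sort(tips[below[[tree$edge[e, 2]]]])
    comp <- sort(setdiff(tips, side))
    if (identical(side, g1) || identical(comp, g1))
      return(list(separated = TRUE, edge = e, side = side))
  }
  list(separated = FALSE, edge = NA_integer_, side = character())
}

# tip indices below every node (tips below a tip = itself)
below_tips <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  below <- vector("list", nnode)
  for (i in seq_len(ntip)) below[[i]] <- i
  # postorder: children before parents
  ord <- ape::reorder.phylo(tree, "postorder")$edge
  for (e in seq_len(nrow(ord))) {
    par <- ord[e, 1]; child <- ord[e, 2]
    below[[par]] <- c(below[[par]], below[[child]])
  }
  below
}

#' Write a tree in Newick format
#' @param tree \code{ape::phylo}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
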