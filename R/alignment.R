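# Pairwise and progressive multiple alignment.
#
# Pairwise global alignment is Needleman-Wunsch with BLOSUM62 and affine
# gaps (open 11, extend 1; a gap of length L costs 11 + L). Progressive
# multiple alignment aligns profiles along a UPGMA guide tree built from
# pairwise identities, with deterministic tie-breaking, in the spirit of
# classical ClustalW.

blosum62 <- local({
  env <- new.env()
  function() {
    if (is.null(env$m)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      env$m <- e$BLOSUM62
    }
    env$m
  }
})

GAP_OPEN <- 11
GAP_EXTEND <- 1

#' Global pairwise alignment of two protein sequences
#'
#' @param a,b amino-acid strings (non-empty).
#' @return list with \code{aligned_a}, \code{aligned_b} (gapped strings of
#'   equal length) and \code{score}.
#' @export
pairwise_align <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = blosum62(),
    gapOpening = GAP_OPEN, gapExtension = GAP_EXTEND, type = "global")
  list(aligned_a = as.character(Biostrings::alignedPattern(pa)),
       aligned_b = as.character(Biostrings::alignedSubject(pa)),
       score = Biostrings::score(pa))
}

#' Pairwise distance between two proteins
#'
#' One minus the fraction of identical aligned positions over aligned
#' columns (dual-gap columns excluded), from a global alignment.
#'
#' @param a,b amino-acid strings.
#' @return real in [0, 1].
#' @export
pairwise_distance <- function(a, b) {
  al <- pairwise_align(a, b)
  x <- chars(al$aligned_a); y <- chars(al$aligned_b)
  keep <- !(x == "-" & y == "-")
  1 - sum(x[keep] == y[keep] & x[keep] != "-") / sum(keep)
}

#' Pairwise distance matrix for a set of labelled proteins
#'
#' @param sequences named character vector of amino-acid strings.
#' @return symmetric matrix with zero diagonal, dimnames = labels.
#' @export
distance_matrix <- function(sequences) {
  n <- length(sequences)
  labs <- names(sequences) %||% paste0("seq", seq_len(n))
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  if (n > 1) for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- pairwise_distance(sequences[[i]], sequences[[j]])
  }
  d
}

# ---- progressive multiple alignment ------------------------------------

# score between two alignment columns (character vectors with "-" gaps):
# mean BLOSUM62 over residue pairs; residue-gap pairs score -4, gap-gap 0.
profile_col_score <- function(colA, colB, subm) {
  s <- 0
  for (x in colA) for (y in colB) {
    s <- s + if (x == "-" && y == "-") 0
             else if (x == "-" || y == "-") -4
             else subm[x, y]
  }
  s / (length(colA) * length(colB))
}

# Needleman-Wunsch with affine gaps between two profiles (lists of aligned
# sequences). Deterministic tie-break: diagonal > up (gap in B) > left.
align_profiles <- function(profA, profB) {
  subm <- blosum62()
  A <- do.call(rbind, lapply(profA, chars))
  B <- do.call(rbind, lapply(profB, chars))
  n <- ncol(A); m <- ncol(B)
  # precompute column-pair scores
  S <- matrix(0, n, m)
  for (i in seq_len(n)) {
    ai <- A[, i]
    for (j in seq_len(m)) S[i, j] <- profile_col_score(ai, B[, j], subm)
  }
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -GAP_OPEN - GAP_EXTEND * (i - 1)
  for (j in 2:(m + 1)) Y[1, j] <- -GAP_OPEN - GAP_EXTEND * (j - 1)
  ptrM <- matrix(0L, n + 1, m + 1); ptrX <- ptrM; ptrY <- ptrM
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      prev <- c(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      k <- which.max(prev)
      M[i, j] <- prev[k] + S[i - 1, j - 1]; ptrM[i, j] <- k
      openx <- M[i - 1, j] - GAP_OPEN - GAP_EXTEND
      extx <- X[i - 1, j] - GAP_EXTEND
      if (openx >= extx) { X[i, j] <- openx; ptrX[i, j] <- 1L }
      else { X[i, j] <- extx; ptrX[i, j] <- 2L }
      openy <- M[i, j - 1] - GAP_OPEN - GAP_EXTEND
      exty <- Y[i, j - 1] - GAP_EXTEND
      if (openy >= exty) { Y[i, j] <- openy; ptrY[i, j] <- 1L }
      else { Y[i, j] <- exty; ptrY[i, j] <- 3L }
    }
  }
  # traceback
  i <- n + 1; j <- m + 1
  fin <- c(M[i, j], X[i, j], Y[i, j])
  state <- which.max(fin)
  pathA <- integer(0); pathB <- integer(0) # 0 = gap, else column index
  while (i > 1 || j > 1) {
    if (state == 1L) {
      nxt <- ptrM[i, j]
      pathA <- c(i - 1L, pathA); pathB <- c(j - 1L, pathB)
      i <- i - 1; j <- j - 1; state <- nxt
    } else if (state == 2L) {
      nxt <- if (i > 1) ptrX[i, j] else 3L
      pathA <- c(i - 1L, pathA); pathB <- c(0L, pathB)
      i <- i - 1; state <- if (nxt == 0L) 2L else nxt
    } else {
      nxt <- if (j > 1) ptrY[i, j] else 2L
      pathA <- c(0L, pathA); pathB <- c(j - 1L, pathB)
      j <- j - 1; state <- if (nxt == 0L) 3L else nxt
    }
    if (i == 1 && j > 1) state <- 3L
    if (j == 1 && i > 1) state <- 2L
  }
  expand <- function(mat, path) {
    out <- matrix("-", nrow(mat), length(path))
    nz <- path > 0
    out[, nz] <- mat[, path[nz], drop = FALSE]
    out
  }
  newA <- expand(A, pathA); newB <- expand(B, pathB)
  c(apply(newA, 1, paste, collapse = ""),
    apply(newB, 1, paste, collapse = ""))
}

#' Progressive multiple alignment of protein sequences
#'
#' Pairwise Needleman-Wunsch identities feed a UPGMA guide tree; profiles
#' are then merged depth-first in guide-tree order with affine-gap
#' profile-profile alignment. Deterministic for a given input order.
#'
#' @param sequences character vector (>= 2) of amino-acid strings,
#'   optionally named.
#' @return character vector of gapped strings of equal length, in input
#'   order, named like the input.
#' @export
align_members <- function(sequences) {
  if (length(sequences) < 2) stop("need at least 2 sequences")
  if (any(!nzchar(sequences))) stop("empty sequence")
  nms <- names(sequences) %||% paste0("seq", seq_along(sequences))
  names(sequences) <- nms
  if (length(sequences) == 2) {
    al <- pairwise_align(sequences[[1]], sequences[[2]])
    return(setNames(c(al$aligned_a, al$aligned_b), nms))
  }
  d <- distance_matrix(sequences)
  hc <- hclust(as.dist(d), method = "average")
  # clusters: list of (indices, aligned strings)
  clust <- lapply(seq_along(sequences),
                  function(i) list(idx = i, aln = sequences[[i]]))
  merged <- vector("list", nrow(hc$merge))
  getc <- function(k) if (k < 0) clust[[-k]] else merged[[k]]
  for (s in seq_len(nrow(hc$merge))) {
    a <- getc(hc$merge[s, 1]); b <- getc(hc$merge[s, 2])
    aln <- align_profiles(as.list(a$aln), as.list(b$aln))
    merged[[s]] <- list(idx = c(a$idx, b$idx), aln = aln)
  }
  final <- merged[[nrow(hc$merge)]]
  out <- character(length(sequences))
  out[final$idx] <- final$aln
  setNames(out, nms)
}
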