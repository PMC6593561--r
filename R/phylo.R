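# Phylogeny of family members: Kimura two-parameter distances with pairwise
# deletion of gap/ambiguity columns, neighbor-joining trees, and a star-score
# statistic (terminal fraction of total branch length) that operationalises
# the "star-shaped tree = single rapid amplification" reading.

#' Kimura two-parameter distance between two aligned sequences
#'
#' Columns with a gap or non-ACGT character in either sequence are excluded
#' (pairwise deletion). With P the transition fraction and Q the transversion
#' fraction over the counted columns,
#' d = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q).
#'
#' @param aligned_a,aligned_b Equal-length aligned strings.
#' @return The distance, or `NA` with attribute `saturated = TRUE` when the
#'   log arguments are non-positive (substitution saturation).
#' @export
k2p_distance <- function(aligned_a, aligned_b) {
  ca <- seq_chars(aligned_a)
  cb <- seq_chars(aligned_b)
  if (length(ca) != length(cb)) {
    abort(sprintf("aligned sequences differ in length: %d vs %d", length(ca), length(cb)))
  }
  counted <- ca %in% DNA_BASES & cb %in% DNA_BASES
  ncol <- sum(counted)
  if (ncol == 0) abort("no comparable (gap-free, unambiguous) columns")
  a <- ca[counted]
  b <- cb[counted]
  diff <- a != b
  transition <- diff & (
    (a == "A" & b == "G") | (a == "G" & b == "A") |
    (a == "C" & b == "T") | (a == "T" & b == "C")
  )
  P <- sum(transition) / ncol
  Q <- sum(diff & !transition) / ncol
  arg1 <- 1 - 2 * P - Q
  arg2 <- 1 - 2 * Q
  if (arg1 <= 0 || arg2 <= 0) {
    return(structure(NA_real_, saturated = TRUE))
  }
  -0.5 * log(arg1) - 0.25 * log(arg2)
}

#' K2P distance matrix for a set of aligned sequences
#'
#' @param rows Character vector of equal-length aligned rows (named by
#'   taxon/element id when available).
#' @return A symmetric matrix; saturated pairs are `NA` (a warning reports
#'   how many).
#' @export
k2p_matrix <- function(rows) {
  n <- length(rows)
  labels <- names(rows) %||% sprintf("s%d", seq_len(n))
  D <- matrix(0, n, n, dimnames = list(labels, labels))
  saturated <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- k2p_distance(rows[i], rows[j])
      if (is.na(d)) saturated <- saturated + 1L
      D[i, j] <- D[j, i] <- as.numeric(d)
    }
  }
  if (saturated > 0) warn(sprintf("%d saturated pair(s) set to NA", saturated))
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei neighbor joining (via ape). The matrix must be
#' square, symmetric, non-negative, with a zero diagonal and at least three
#' taxa.
#'
#' @param distance_matrix Numeric distance matrix.
#' @param labels Optional taxon labels (defaults to the matrix dimnames).
#' @return An unrooted `phylo` tree with branch lengths; write it with
#'   [ape::write.tree()] for Newick output.
#' @export
nj_tree <- function(distance_matrix, labels = NULL) {
  D <- as.matrix(distance_matrix)
  if (nrow(D) != ncol(D)) abort("distance matrix must be square")
  if (nrow(D) < 3) abort("neighbor joining needs at least 3 taxa")
  if (any(is.na(D))) abort("distance matrix contains NA (saturated pairs?)")
  if (any(D < 0)) abort("distance matrix contains negative entries")
  if (any(abs(D - t(D)) > 1e-8)) abort("distance matrix is not symmetric")
  if (any(diag(D) != 0)) abort("distance matrix diagonal must be zero")
  if (!is.null(labels)) {
    if (length(labels) != nrow(D)) abort("labels length must match matrix dimension")
    dimnames(D) <- list(labels, labels)
  } else if (is.null(rownames(D))) {
    dimnames(D) <- list(sprintf("s%d", seq_len(nrow(D))), sprintf("s%d", seq_len(nrow(D))))
  }
  ape::nj(stats::as.dist(D))
}

#' Star score of a tree
#'
#' Fraction of the total branch length carried by terminal (leaf-adjacent)
#' edges. A perfect star (all internal branch lengths zero) scores 1; deep
#' clade structure pushes the score down. Used to flag families whose
#' amplification looks like a single rapid burst from one master element.
#'
#' @param tree A `phylo` object with branch lengths.
#' @return A fraction in \[0, 1\], or `NA` when the total branch length is
#'   zero.
#' @export
star_score <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) abort("tree has no branch lengths")
  total <- sum(tree$edge.length)
  if (total == 0) return(NA_real_)
  ntip <- length(tree$tip.label)
  terminal <- tree$edge[, 2] <= ntip
  sum(tree$edge.length[terminal]) / total
}
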