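# Alignment plumbing. Pairwise global alignment is delegated to
# Biostrings::pairwiseAlignment with a fixed scoring configuration so every
# identity/coverage decision in the package is reproducible. Multiple
# alignment uses a deterministic center-star progressive scheme (no external
# binary needed); mafft can be substituted when installed.

align_scoring <- function() {
  list(
    mat = Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1, baseOnly = FALSE),
    gap_opening = 4, gap_extension = 1
  )
}

# global pairwise alignment; returns the two aligned rows as characters
pairwise_align <- function(a, b) {
  sc <- align_scoring()
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = "global", substitutionMatrix = sc$mat,
    gapOpening = sc$gap_opening, gapExtension = sc$gap_extension
  )
  list(
    a = as.character(Biostrings::alignedPattern(aln)),
    b = as.character(Biostrings::alignedSubject(aln)),
    score = Biostrings::score(aln)
  )
}

# fraction of identical columns over all alignment columns (global, so no
# dual-gap columns arise in a pairwise alignment)
alignment_identity <- function(aln) {
  ca <- seq_chars(aln$a)
  cb <- seq_chars(aln$b)
  sum(ca == cb & ca != "-") / length(ca)
}

#' Multiple sequence alignment (deterministic center-star)
#'
#' Aligns a set of DNA sequences by globally aligning every sequence to a
#' center sequence (the longest; ties broken lexicographically) and merging
#' the pairwise alignments on center coordinates. Equal-length inputs are
#' returned unchanged (they are already a valid alignment under the no-indel
#' assumption the burst simulator uses by default). `method = "mafft"` shells
#' out to mafft when it is on the PATH.
#'
#' @param seqs Character vector of DNA sequences (optionally named).
#' @param method `"centerstar"` (default, built in) or `"mafft"`.
#' @return Character vector of equal-length aligned rows (gaps as `-`),
#'   same order and names as the input.
#' @export
align_sequences <- function(seqs, method = c("centerstar", "mafft")) {
  method <- match.arg(method)
  if (length(seqs) == 0) return(character(0))
  if (length(seqs) == 1) return(seqs)
  if (length(unique(nchar(seqs))) == 1) return(toupper(seqs))
  if (method == "mafft") {
    return(align_mafft(seqs))
  }
  align_centerstar(seqs)
}

align_centerstar <- function(seqs) {
  seqs <- toupper(seqs)
  ord <- order(-nchar(seqs), seqs)
  center_i <- ord[1]
  center <- seqs[center_i]
  others <- setdiff(seq_along(seqs), center_i)

  # per pairwise alignment, record gaps inserted into the center before each
  # center position (and at the end)
  pair <- map(others, function(i) pairwise_align(seqs[i], center))
  n <- nchar(center)
  # ins[k] = max gaps opened before center base k (k in 1..n+1)
  ins <- integer(n + 1L)
  gap_profiles <- map(pair, function(p) {
    cb <- seq_chars(p$b)
    pos <- cumsum(cb != "-")          # center base index at each column
    gaps <- integer(n + 1L)
    run <- rle(cb == "-")
    col <- 1L
    for (j in seq_along(run$lengths)) {
      if (run$values[j]) {
        k <- if (col == 1L) 1L else pos[col - 1L] + 1L
        gaps[k] <- gaps[k] + run$lengths[j]
      }
      col <- col + run$lengths[j]
    }
    gaps
  })
  for (g in gap_profiles) ins <- pmax(ins, g)

  pad_row <- function(row_chars, center_chars, gaps_here) {
    # rebuild a row on the master gap scaffold
    out <- character(0)
    col <- 1L
    for (k in seq_len(n + 1L)) {
      g_have <- gaps_here[k]
      g_need <- ins[k]
      if (g_have > 0) {
        out <- c(out, row_chars[col:(col + g_have - 1L)])
        col <- col + g_have
      }
      if (g_need > g_have) out <- c(out, rep("-", g_need - g_have))
      if (k <= n) {
        out <- c(out, row_chars[col])
        col <- col + 1L
      }
    }
    paste(out, collapse = "")
  }

  rows <- character(length(seqs))
  center_gaps0 <- integer(n + 1L)
  rows[center_i] <- pad_row(seq_chars(center), NULL, center_gaps0)
  for (j in seq_along(others)) {
    p <- pair[[j]]
    rows[others[j]] <- pad_row(seq_chars(p$a), NULL, gap_profiles[[j]])
  }
  names(rows) <- names(seqs)
  stopifnot(length(unique(nchar(rows))) == 1)
  rows
}

align_mafft <- function(seqs) {
  if (Sys.which("mafft") == "") abort("mafft not found on PATH")
  nm <- names(seqs) %||% sprintf("s%d", seq_along(seqs))
  fin <- tempfile(fileext = ".fa")
  fout <- tempfile(fileext = ".fa")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  write_fasta(setNames(seqs, nm), fin)
  system2("mafft", c("--auto", "--quiet", fin), stdout = fout)
  out <- read_fasta(fout)
  aligned <- setNames(toupper(out$seq), out$name)[nm]
  setNames(aligned, names(seqs))
}
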