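# Independent brute-force oracles used to cross-check the implementation.
# These are deliberately naive re-derivations from first principles and
# share no code with the package internals.

COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

oracle_revcomp <- function(s) {
  paste(rev(unname(COMP[strsplit(toupper(s), "")[[1]]])), collapse = "")
}

# longest L >= min_tir whose 5' prefix matches the RC of the 3' suffix with
# <= max_mismatch mismatches, scanning every L explicitly
oracle_tir <- function(seq, min_tir = 10, max_mismatch = 2) {
  s <- strsplit(toupper(seq), "")[[1]]
  n <- length(s)
  best <- NA_integer_
  for (L in seq_len(n %/% 2)) {
    if (L < min_tir) next
    prefix <- s[1:L]
    suffix_rc <- strsplit(oracle_revcomp(paste(s[(n - L + 1):n], collapse = "")), "")[[1]]
    mm <- sum(prefix != suffix_rc | prefix == "N" | suffix_rc == "N")
    if (mm <= max_mismatch) best <- L
  }
  best
}

oracle_tsd <- function(scaffold, start, end, ks = c(2, 3, 8, 9)) {
  n <- nchar(scaffold)
  for (k in sort(ks, decreasing = TRUE)) {
    if (start - k < 0 || end + k > n) next
    up <- toupper(substr(scaffold, start - k + 1, start))
    down <- toupper(substr(scaffold, end + 1, end + k))
    if (up == down) return(list(k = as.integer(k), tsd = up))
  }
  list(k = NA_integer_, tsd = NA_character_)
}

# mismatches / counted columns, dual-gap columns dropped, one-sided gaps
# count one mismatch per column
oracle_pairwise_diversity <- function(a, b) {
  ca <- strsplit(toupper(a), "")[[1]]
  cb <- strsplit(toupper(b), "")[[1]]
  mism <- 0; counted <- 0
  for (i in seq_along(ca)) {
    if (ca[i] == "-" && cb[i] == "-") next
    counted <- counted + 1
    if (ca[i] != cb[i]) mism <- mism + 1
  }
  mism / counted
}

# every exact occurrence of read (or its RC) in every element, by sliding
# window substring comparison
oracle_srna_matches <- function(reads, elements) {
  out <- list()
  for (ri in seq_len(nrow(reads))) {
    r <- toupper(reads$seq[ri])
    for (ei in seq_len(nrow(elements))) {
      subj <- toupper(elements$seq[ei])
      for (orient in c("sense", "antisense")) {
        pat <- if (orient == "sense") r else oracle_revcomp(r)
        L <- nchar(pat)
        if (L > nchar(subj)) next
        for (s0 in 0:(nchar(subj) - L)) {
          if (substr(subj, s0 + 1, s0 + L) == pat) {
            out[[length(out) + 1]] <- data.frame(
              srna_id = reads$name[ri], element_id = elements$element_id[ei],
              match_start = s0, match_end = s0 + L, orientation = orient,
              stringsAsFactors = FALSE
            )
          }
        }
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(
      srna_id = character(0), element_id = character(0),
      match_start = integer(0), match_end = integer(0), orientation = character(0)
    ))
  }
  do.call(rbind, out)
}

# set-based AS caller used as an oracle: events derived from junction and
# exon sets of each isoform pair (strand-aware labels)
oracle_as_events <- function(exons) {
  out <- list()
  for (g in unique(exons$gene_id)) {
    gx <- exons[exons$gene_id == g, ]
    isoforms <- split(gx, gx$transcript_id)
    isoforms <- lapply(isoforms, function(x) x[order(x$start), ])
    ids <- names(isoforms)
    if (length(ids) < 2) next
    strand <- gx$strand[1]
    for (pi in seq_along(ids)) for (qi in seq_along(ids)) {
      if (pi == qi) next
      A <- isoforms[[ids[pi]]]; B <- isoforms[[ids[qi]]]
      junB <- if (nrow(B) > 1) {
        paste(B$end[-nrow(B)], B$start[-1])
      } else character(0)
      exB <- paste(B$start, B$end)
      # ES: internal A exon not in B, flanks joined in B
      if (nrow(A) >= 3) for (i in 2:(nrow(A) - 1)) {
        if (paste(A$start[i], A$end[i]) %in% exB) next
        if (paste(A$end[i - 1], A$start[i + 1]) %in% junB) {
          out[[length(out) + 1]] <- data.frame(
            gene_id = g, mode = "ES", event_start = A$start[i], event_end = A$end[i]
          )
        }
      }
      # IR: A intron i with [A$start[i], A$end[i+1]) an exon of B
      if (nrow(A) >= 2) for (i in 1:(nrow(A) - 1)) {
        if (paste(A$start[i], A$end[i + 1]) %in% exB) {
          out[[length(out) + 1]] <- data.frame(
            gene_id = g, mode = "IR", event_start = A$end[i], event_end = A$start[i + 1]
          )
        }
      }
      # alt donor/acceptor: shared boundary + shared junction partner
      for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
        if (A$start[i] == B$start[j] && A$end[i] != B$end[j] &&
            i < nrow(A) && j < nrow(B) && A$start[i + 1] == B$start[j + 1]) {
          md <- if (strand == "-") "A3SS" else "A5SS"
          out[[length(out) + 1]] <- data.frame(
            gene_id = g, mode = md,
            event_start = min(A$end[i], B$end[j]), event_end = max(A$end[i], B$end[j])
          )
        }
        if (A$end[i] == B$end[j] && A$start[i] != B$start[j] &&
            i > 1 && j > 1 && A$end[i - 1] == B$end[j - 1]) {
          md <- if (strand == "-") "A5SS" else "A3SS"
          out[[length(out) + 1]] <- data.frame(
            gene_id = g, mode = md,
            event_start = min(A$start[i], B$start[j]), event_end = max(A$start[i], B$start[j])
          )
        }
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(
      gene_id = character(0), mode = character(0),
      event_start = integer(0), event_end = integer(0)
    ))
  }
  unique(do.call(rbind, out))
}

# closed-form expected pairwise site difference for two copies independently
# mutated from one master with per-site probability p and transition share
# kappa/(kappa+2) (same-base re-draw excluded)
expected_pairwise_k <- function(p, kappa = 2) {
  w_ts <- kappa / (kappa + 2)
  w_tv <- 1 / (kappa + 2)
  p_same_given_both <- w_ts^2 + 2 * w_tv^2
  2 * p * (1 - p) + p^2 * (1 - p_same_given_both)
}

# simple point mutation helper for fixtures (uniform over the 3 other bases)
mutate_seq <- function(s, p) {
  x <- strsplit(toupper(s), "")[[1]]
  hit <- which(runif(length(x)) < p)
  for (i in hit) x[i] <- sample(setdiff(c("A", "C", "G", "T"), x[i]), 1)
  paste(x, collapse = "")
}

random_dna_str <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
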