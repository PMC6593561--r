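# Family classification: TIR/TSD detection, superfamily assignment from the
# TSD signature, greedy 80-80-80 family clustering, MnX# naming, full-length
# calls against the family representative, and the superfamily summary table.

#' Detect a terminal inverted repeat
#'
#' Returns the longest `L >= min_tir` such that the first `L` bases and the
#' reverse complement of the last `L` bases differ at no more than
#' `max_mismatch` positions (`N` never matches). `L` is capped at half the
#' sequence length so the two termini cannot overlap.
#'
#' @param sequence DNA string.
#' @param min_tir Minimum TIR length in bases.
#' @param max_mismatch Maximum tolerated mismatches between the termini.
#' @return Integer TIR length, or `NA` if no qualifying repeat exists (in
#'   particular when the sequence is shorter than `2 * min_tir`).
#' @export
detect_tir <- function(sequence, min_tir = 10L, max_mismatch = 2L) {
  s <- seq_chars(sequence)
  n <- length(s)
  if (n < 2L * min_tir) return(NA_integer_)
  rc <- seq_chars(revcomp(paste(s, collapse = "")))
  # rc[i] pairs the i-th 5' base with the i-th-from-3' base
  lmax <- n %/% 2L
  ok_base <- s[seq_len(lmax)] %in% DNA_BASES & rc[seq_len(lmax)] %in% DNA_BASES
  mism <- cumsum(!(s[seq_len(lmax)] == rc[seq_len(lmax)] & ok_base))
  hits <- which(mism <= max_mismatch)
  hits <- hits[hits >= min_tir]
  if (length(hits) == 0) return(NA_integer_)
  as.integer(max(hits))
}

#' Detect a target-site duplication
#'
#' Compares, for each candidate length `k`, the `k` bases immediately 5' of
#' the element with the `k` bases immediately 3' of it (exact,
#' case-insensitive match). The largest matching `k` wins, so an 8-bp
#' duplication ending in TA is not mistaken for a Tc1/Mariner dinucleotide.
#'
#' @param scaffold_seq The full scaffold sequence carrying the element.
#' @param start,end Element interval, 0-based half-open.
#' @param k_candidates Candidate TSD lengths (defaults to the superfamily
#'   signature lengths 2, 3, 8, 9).
#' @return A list with `k` (integer or `NA`), `tsd` (string or `NA`) and
#'   `edge` (`TRUE` when no candidate had enough flanking sequence on both
#'   sides).
#' @export
detect_tsd <- function(scaffold_seq, start, end, k_candidates = c(2L, 3L, 8L, 9L)) {
  n <- nchar(scaffold_seq)
  ks <- sort(unique(as.integer(k_candidates)), decreasing = TRUE)
  any_room <- FALSE
  for (k in ks) {
    if (start < k || end + k > n) next
    any_room <- TRUE
    up <- toupper(subseq0(scaffold_seq, start - k, start))
    down <- toupper(subseq0(scaffold_seq, end, end + k))
    if (up == down) {
      return(list(k = k, tsd = up, edge = FALSE))
    }
  }
  list(k = NA_integer_, tsd = NA_character_, edge = !any_room)
}

#' Assign a superfamily from the TSD signature
#'
#' Vectorised. The rule follows the standard TSD signatures: a `TA`
#' dinucleotide indicates Tc1/Mariner, a `TWA` trinucleotide (IUPAC `W` = A
#' or T) PIF/Harbinger, an 8-bp duplication hAT and a 9-bp duplication
#' Mutator; everything else (including an absent TSD) is `Unknown` ("DTx").
#' The TIR length is accepted for interface completeness but is not
#' discriminative between these superfamilies.
#'
#' @param tsd_len Integer vector of TSD lengths (`NA` for absent).
#' @param tsd_seq Character vector of TSD sequences.
#' @param tir_length Optional integer vector of TIR lengths (unused by the
#'   decision rule).
#' @return Character vector of superfamily names.
#' @export
assign_superfamily <- function(tsd_len, tsd_seq, tir_length = NULL) {
  tsd_seq <- toupper(tsd_seq)
  dplyr::case_when(
    !is.na(tsd_len) & tsd_len == 2L & tsd_seq == "TA" ~ "Tc1/Mariner",
    !is.na(tsd_len) & tsd_len == 3L & stringr::str_detect(tsd_seq, "^T[AT]A$") ~ "PIF/Harbinger",
    !is.na(tsd_len) & tsd_len == 8L ~ "hAT",
    !is.na(tsd_len) & tsd_len == 9L ~ "Mutator",
    TRUE ~ "Unknown"
  )
}

# identity/coverage decision of the 80-80-80 rule for one candidate vs one
# representative; strands tried per `orientations`
matches_family <- function(seq, rep_seq, min_identity, min_coverage, both_strands) {
  la <- nchar(seq); lb <- nchar(rep_seq)
  if (min(la, lb) / max(la, lb) < min_coverage) return(FALSE)
  id <- alignment_identity(pairwise_align(seq, rep_seq))
  if (id >= min_identity) return(TRUE)
  if (both_strands) {
    id_rc <- alignment_identity(pairwise_align(revcomp(seq), rep_seq))
    return(id_rc >= min_identity)
  }
  FALSE
}

#' Cluster MITE copies into families (80-80-80 rule)
#'
#' Greedy centroid clustering: sequences are visited by decreasing length
#' (ties broken lexicographically by sequence); each joins the first existing
#' family whose representative it matches at `>= min_identity` global-alignment
#' identity with length coverage `>= min_coverage` (shorter/longer length
#' ratio), otherwise it founds a new family with itself as representative.
#' Sequences shorter than `min_length` are set aside as unclassified
#' (`family_id = NA`). Elements of unknown strand are compared in both
#' orientations and the better one is used.
#'
#' @param elements Tibble with `element_id` and `seq` (and optionally
#'   `strand`; strands other than `+`/`-` are treated as unknown).
#' @param min_identity,min_coverage,min_length The three 80s of the rule.
#' @return The input tibble with `family_id` (e.g. `"F1"`, in founding
#'   order), `representative` (the family representative sequence) and
#'   `is_representative` columns added. Deterministic and idempotent.
#' @export
cluster_families <- function(elements, min_identity = 0.8, min_coverage = 0.8,
                             min_length = 80L) {
  stopifnot(all(c("element_id", "seq") %in% names(elements)))
  if (nrow(elements) == 0) {
    return(mutate(elements,
      family_id = character(0), representative = character(0),
      is_representative = logical(0)
    ))
  }
  seqs <- toupper(elements$seq)
  strand <- if ("strand" %in% names(elements)) elements$strand else rep("*", length(seqs))
  unknown_strand <- !(strand %in% c("+", "-"))

  ord <- order(-nchar(seqs), seqs)
  fam <- rep(NA_character_, length(seqs))
  reps <- character(0)       # representative sequences in founding order
  rep_of <- character(0)

  for (i in ord) {
    if (nchar(seqs[i]) < min_length) next
    assigned <- FALSE
    for (f in seq_along(reps)) {
      if (matches_family(seqs[i], reps[f], min_identity, min_coverage, unknown_strand[i])) {
        fam[i] <- rep_of[f]
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      fid <- sprintf("F%d", length(reps) + 1L)
      reps <- c(reps, seqs[i])
      rep_of <- c(rep_of, fid)
      fam[i] <- fid
    }
  }
  rep_lookup <- setNames(reps, rep_of)
  elements %>%
    mutate(
      family_id = fam,
      representative = unname(rep_lookup[fam]),
      is_representative = !is.na(fam) & toupper(.data$seq) == .data$representative
    )
}

#' Name families with the MnX# scheme
#'
#' Family names are `Mn` + a superfamily code (`T` Tc1/Mariner, `h` hAT,
#' `P` PIF/Harbinger, `M` Mutator, `N` unknown) + a 1-based serial assigned
#' by decreasing element count within the superfamily (ties broken by the
#' representative sequence, lexicographically). The family-level superfamily
#' is the modal superfamily call among its members (ties broken
#' alphabetically; families whose members are all `Unknown` stay `Unknown`).
#'
#' @param elements Tibble with `family_id`, `superfamily` (per element) and
#'   `representative` columns, as produced by [cluster_families()] +
#'   [assign_superfamily()].
#' @return The input with `family` (the MnX# name) and `family_superfamily`
#'   columns added; unclassified elements keep `family = NA`.
#' @export
name_families <- function(elements) {
  stopifnot(all(c("family_id", "superfamily", "representative") %in% names(elements)))
  fams <- elements %>%
    filter(!is.na(.data$family_id)) %>%
    group_by(.data$family_id, .data$representative) %>%
    summarise(
      n_members = n(),
      family_superfamily = modal_superfamily(.data$superfamily),
      .groups = "drop"
    ) %>%
    group_by(.data$family_superfamily) %>%
    arrange(desc(.data$n_members), .data$representative, .by_group = TRUE) %>%
    mutate(serial = row_number()) %>%
    ungroup() %>%
    mutate(family = sprintf("Mn%s%d", SUPERFAMILY_CODE[.data$family_superfamily], .data$serial))
  elements %>%
    left_join(
      select(fams, "family_id", "family", "family_superfamily"),
      by = "family_id"
    )
}

modal_superfamily <- function(x) {
  x <- x[x != "Unknown"]
  if (length(x) == 0) return("Unknown")
  tab <- sort(table(x), decreasing = TRUE)
  names(tab)[1]
}

#' Is an element full length relative to its family representative?
#'
#' An element is full length when a global alignment to the representative
#' leaves at most `max_missing` unaligned representative bases at the 5'
#' terminus and at most `max_missing` at the 3' terminus (i.e. the element
#' may be up to 3 bp short at each end).
#'
#' @param element_seq,representative DNA strings.
#' @param max_missing Maximum representative bases missing per terminus.
#' @return Logical.
#' @export
is_full_length <- function(element_seq, representative, max_missing = 3L) {
  if (toupper(element_seq) == toupper(representative)) return(TRUE)
  aln <- pairwise_align(element_seq, representative)
  ca <- seq_chars(aln$a)
  lead <- match(TRUE, ca != "-") - 1L
  trail <- length(ca) - max(which(ca != "-"))
  lead <= max_missing && trail <= max_missing
}

#' Classify a MITE annotation set end to end
#'
#' Pipeline wrapper: extracts sequences, detects TIR and TSD per element,
#' assigns per-element superfamilies, clusters into families, names them and
#' calls full-length status against the family representative.
#'
#' @param elements MITE annotation tibble ([read_mite_annotations()]).
#' @param genome Genome tibble or named vector.
#' @param min_tir,max_mismatch Passed to [detect_tir()].
#' @param ... Passed to [cluster_families()].
#' @return The classified element tibble: adds `seq`, `tir_length`, `tsd`,
#'   `tsd_len`, `superfamily` (per element), `family_id`, `family`,
#'   `family_superfamily`, `representative`, `full_length`.
#' @export
classify_mites <- function(elements, genome, min_tir = 10L, max_mismatch = 2L, ...) {
  gv <- genome_vector(genome)
  el <- add_element_sequences(elements, gv)
  # an incoming family column (e.g. from a discovery tool) is kept for
  # reference; the pipeline assigns its own families
  if ("family" %in% names(el)) {
    el <- rename(el, annotated_family = "family")
  }
  structure_info <- pmap(
    list(el$scaffold, el$start, el$end, el$seq),
    function(sc, s, e, sq) {
      tsd <- detect_tsd(gv[[sc]], s, e)
      list(
        tir_length = detect_tir(sq, min_tir, max_mismatch),
        tsd = tsd$tsd, tsd_len = tsd$k, tsd_edge = tsd$edge
      )
    }
  )
  el <- el %>%
    mutate(
      tir_length = map_int(structure_info, "tir_length"),
      tsd = map_chr(structure_info, "tsd"),
      tsd_len = map_int(structure_info, "tsd_len"),
      tsd_edge = map_lgl(structure_info, "tsd_edge"),
      superfamily = assign_superfamily(.data$tsd_len, .data$tsd, .data$tir_length)
    ) %>%
    cluster_families(...) %>%
    name_families()
  el %>%
    mutate(full_length = map2_lgl_safe(.data$seq, .data$representative, is_full_length))
}

map2_lgl_safe <- function(x, y, f) {
  map_lgl(seq_along(x), function(i) {
    if (is.na(y[i])) return(NA)
    f(x[i], y[i])
  })
}

#' Summarise elements by superfamily (Table-1 style)
#'
#' Per superfamily (and a `Total` row): family count, element counts by
#' full/partial status, the full/partial percentage (100 * full / partial,
#' `NA` when there are no partial elements), and the percentage of the
#' genome covered (overlapping elements merged before summing bases).
#'
#' @param elements Classified element tibble; needs `superfamily` (the
#'   family-level call in `family_superfamily` is used when present),
#'   `full_length`, and `family` plus coordinates for the family/genome
#'   columns.
#' @param genome_length Total genome length in bases (> 0).
#' @return A tibble with one row per superfamily plus totals.
#' @export
summarize_superfamilies <- function(elements, genome_length) {
  if (!is.numeric(genome_length) || genome_length <= 0) {
    abort("genome_length must be a positive number")
  }
  sf_col <- if ("family_superfamily" %in% names(elements)) "family_superfamily" else "superfamily"
  el <- elements %>% mutate(.sf = .data[[sf_col]])
  has_coords <- all(c("scaffold", "start", "end") %in% names(el))
  one <- function(g, label) {
    masked <- if (has_coords) total_interval_width(reduce_intervals(g)) else NA_real_
    full <- sum(g$full_length, na.rm = TRUE)
    partial <- sum(!g$full_length, na.rm = TRUE)
    tibble(
      superfamily = label,
      family_count = if ("family" %in% names(g)) n_distinct(g$family[!is.na(g$family)]) else NA_integer_,
      total_elements = nrow(g),
      full_length_count = full,
      partial_count = partial,
      full_to_partial_percent = if (partial > 0) 100 * full / partial else NA_real_,
      full_length_fraction_percent = if (nrow(g) > 0) 100 * full / nrow(g) else NA_real_,
      genome_percent = 100 * masked / genome_length,
      tsd_signature = unname(TSD_SIGNATURE[label] %||% NA_character_)
    )
  }
  present <- intersect(SUPERFAMILIES, unique(el$.sf))
  rows <- map(present, function(sf) one(filter(el, .data$.sf == sf), sf))
  bind_rows(list_rbind(rows), one(el, "Total"))
}
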