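# Amplification dynamics from pairwise nucleotide diversity: per-family
# diversity matrices, kernel-density modality calls (how many amplification
# bursts), and divergence-time estimates from the neutral substitution rate.

#' Default neutral substitution rate
#'
#' Base substitutions per site per year used to convert pairwise diversity
#' to divergence time.
#' @export
DEFAULT_SUBSTITUTION_RATE <- 1.3e-8

#' Pairwise nucleotide diversity of two aligned sequences
#'
#' K = mismatching columns / counted columns, where a column mismatches when
#' the bases differ or exactly one sequence has a gap (so a gap run of
#' length g counts g mismatches), and columns where both sequences have a
#' gap are excluded entirely.
#'
#' @param aligned_a,aligned_b Equal-length aligned strings (gaps as `-`).
#' @return K in \[0, 1\].
#' @export
pairwise_diversity <- function(aligned_a, aligned_b) {
  ca <- seq_chars(aligned_a)
  cb <- seq_chars(aligned_b)
  if (length(ca) != length(cb)) {
    abort(sprintf("aligned sequences differ in length: %d vs %d", length(ca), length(cb)))
  }
  counted <- !(ca == "-" & cb == "-")
  if (!any(counted)) abort("alignment has no non-dual-gap columns")
  mismatch <- ca[counted] != cb[counted]
  sum(mismatch) / sum(counted)
}

# all pairwise K values from rows of one multiple alignment
pairwise_diversity_matrix <- function(rows) {
  n <- length(rows)
  m <- do.call(rbind, strsplit(toupper(rows), "", fixed = TRUE))
  ks <- numeric(n * (n - 1) / 2)
  idx <- 1L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      counted <- !(m[i, ] == "-" & m[j, ] == "-")
      ks[idx] <- sum(m[i, counted] != m[j, counted]) / sum(counted)
      idx <- idx + 1L
    }
  }
  ks
}

#' Diversity, modality and dating for one MITE family
#'
#' Aligns the full-length members once (multiple alignment), computes all
#' induced pairwise diversities, their mean, the modality of their
#' distribution, and converts the peak positions to amplification times.
#'
#' @param seqs Character vector of full-length member sequences (optionally
#'   named by element id).
#' @param family_name Label carried into the result.
#' @param rate Substitution rate per site per year.
#' @param aligner Function mapping sequences to equal-length aligned rows;
#'   defaults to [align_sequences()].
#' @param min_pairs Minimum number of pairwise values for a modality call.
#' @return An object of class `mite_diversity`: a list with `family_name`,
#'   `n_members`, `k_values`, `k_mean`, `modality`, `peaks` (diversity
#'   values) and `peak_times_mya`. With fewer than two members the diversity
#'   fields are `NA` (no error).
#' @export
family_diversity <- function(seqs, family_name = "family",
                             rate = DEFAULT_SUBSTITUTION_RATE,
                             aligner = align_sequences, min_pairs = 30L) {
  if (length(seqs) < 2) {
    out <- list(
      family_name = family_name, n_members = length(seqs),
      k_values = numeric(0), k_mean = NA_real_,
      modality = "insufficient", peaks = numeric(0),
      peak_times_mya = numeric(0), rate = rate
    )
    class(out) <- "mite_diversity"
    return(out)
  }
  rows <- aligner(seqs)
  ks <- pairwise_diversity_matrix(rows)
  mod <- classify_modality(ks, min_values = min_pairs)
  out <- list(
    family_name = family_name, n_members = length(seqs),
    k_values = ks, k_mean = mean(ks),
    modality = mod$modality, peaks = mod$peaks,
    peak_times_mya = estimate_amplification_time(mod$peaks, rate),
    rate = rate
  )
  class(out) <- "mite_diversity"
  out
}

#' @export
print.mite_diversity <- function(x, ...) {
  cat(sprintf(
    "<mite_diversity> %s: %d members, %d pairs, mean K = %s, %s\n",
    x$family_name, x$n_members, length(x$k_values),
    ifelse(is.na(x$k_mean), "NA", sprintf("%.4f", x$k_mean)), x$modality
  ))
  if (length(x$peaks) > 0) {
    cat(sprintf(
      "  peaks at K = %s (%s Mya)\n",
      paste(sprintf("%.3f", x$peaks), collapse = ", "),
      paste(sprintf("%.1f", x$peak_times_mya), collapse = ", ")
    ))
  }
  invisible(x)
}

#' Diversity summaries for every family in an element table
#'
#' @param elements Classified element tibble with `family`, `full_length`
#'   and `seq` columns.
#' @param rate,aligner,min_pairs Passed to [family_diversity()].
#' @return A tibble with one row per family: `family`, `n_full`, `n_pairs`,
#'   `k_mean`, `modality`, `peaks` and `peak_times_mya` (list columns), and
#'   `result` holding the full `mite_diversity` object.
#' @export
diversity_by_family <- function(elements, rate = DEFAULT_SUBSTITUTION_RATE,
                                aligner = align_sequences, min_pairs = 30L) {
  stopifnot(all(c("family", "full_length", "seq") %in% names(elements)))
  el <- elements %>% filter(!is.na(.data$family), .data$full_length)
  fams <- sort(unique(el$family))
  rows <- map(fams, function(f) {
    res <- family_diversity(el$seq[el$family == f], f, rate, aligner, min_pairs)
    tibble(
      family = f, n_full = res$n_members, n_pairs = length(res$k_values),
      k_mean = res$k_mean, modality = res$modality,
      peaks = list(res$peaks), peak_times_mya = list(res$peak_times_mya),
      result = list(res)
    )
  })
  list_rbind(rows)
}

#' Classify the modality of a pairwise-diversity distribution
#'
#' Gaussian kernel density estimate over \[0, 1\] (Silverman's rule-of-thumb
#' bandwidth); peaks are local maxima whose topographic prominence is at
#' least `prominence` times the global density maximum. One peak is
#' unimodal, two bimodal, three or more multimodal. Fewer than `min_values`
#' observations yield `"insufficient"`.
#'
#' @param k_values Numeric vector of pairwise diversities in \[0, 1\].
#' @param min_values Minimum sample size for a call.
#' @param prominence Prominence threshold as a fraction of the maximum.
#' @return List with `modality` and `peaks` (diversity values, ascending).
#' @export
classify_modality <- function(k_values, min_values = 30L, prominence = 0.1) {
  k_values <- k_values[!is.na(k_values)]
  if (length(k_values) < min_values) {
    return(list(modality = "insufficient", peaks = numeric(0)))
  }
  if (sd(k_values) == 0) {
    return(list(modality = "unimodal", peaks = k_values[1]))
  }
  d <- density(k_values, bw = "nrd0", from = 0, to = 1, n = 512)
  peaks_idx <- find_peaks(d$y, prominence_frac = prominence)
  px <- sort(d$x[peaks_idx])
  modality <- dplyr::case_when(
    length(px) == 1 ~ "unimodal",
    length(px) == 2 ~ "bimodal",
    TRUE ~ "multimodal"
  )
  list(modality = modality, peaks = px)
}

# local maxima of y (boundary points included) filtered by topographic
# prominence >= prominence_frac * max(y)
find_peaks <- function(y, prominence_frac = 0.1) {
  n <- length(y)
  is_max <- vapply(seq_len(n), function(i) {
    left <- if (i > 1) y[i - 1] else -Inf
    right <- if (i < n) y[i + 1] else -Inf
    y[i] > left && y[i] >= right
  }, logical(1))
  cand <- which(is_max)
  if (length(cand) == 0) return(integer(0))
  prom <- vapply(cand, function(i) {
    # extend left/right to the nearest strictly higher point (or boundary),
    # base on each side is the minimum over that stretch
    li <- i
    left_min <- y[i]
    while (li > 1 && y[li - 1] <= y[i]) {
      li <- li - 1
      left_min <- min(left_min, y[li])
    }
    if (li == 1) left_min <- min(y[1:i])
    ri <- i
    right_min <- y[i]
    while (ri < length(y) && y[ri + 1] <= y[i]) {
      ri <- ri + 1
      right_min <- min(right_min, y[ri])
    }
    if (ri == length(y)) right_min <- min(y[i:length(y)])
    y[i] - max(left_min, right_min)
  }, numeric(1))
  # the global maximum has full prominence by convention
  prom[which.max(y[cand] == max(y))] <- max(y)
  cand[prom >= prominence_frac * max(y)]
}

#' Estimate amplification time from pairwise diversity
#'
#' T = K / r in years, reported in millions of years: the convention that
#' reproduces both published worked examples (K = 0.160 at
#' r = 1.3e-8 -> 12.3 Mya; K = 0.312 -> 24 Mya). The population-genetic
#' convention T = K / (2r) is available via `convention = "K/2r"`.
#'
#' @param K Pairwise nucleotide diversity (vectorised).
#' @param rate Substitution rate per site per year (> 0).
#' @param convention `"K/r"` (default) or `"K/2r"`.
#' @return Time(s) in millions of years.
#' @export
estimate_amplification_time <- function(K, rate = DEFAULT_SUBSTITUTION_RATE,
                                        convention = c("K/r", "K/2r")) {
  convention <- match.arg(convention)
  if (!is.numeric(rate) || rate <= 0) abort("rate must be > 0")
  if (any(K < 0 | K > 1, na.rm = TRUE)) abort("K must be in [0, 1]")
  denom <- if (convention == "K/r") rate else 2 * rate
  K / denom / 1e6
}
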