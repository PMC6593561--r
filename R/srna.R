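# MITE-derived small RNAs: exact matching of reads to element sequences
# (both orientations), read-length distributions, relative-position
# profiles over percent-of-element bins, per-family positional-bias calls,
# and GS/IS attribution of matched reads.

#' Match small RNAs exactly to MITE sequences
#'
#' Every exact substring occurrence of a read (sense) or of its reverse
#' complement (antisense) in every element sequence is reported; a read
#' matching k elements yields k records. Reads outside the length window are
#' dropped, reads containing non-ACGT characters are skipped with a summary
#' warning. Positions are 0-based half-open within the element; relative
#' coordinates are percent of element length.
#'
#' @param srnas Tibble of reads (`name`, `seq`), e.g. [read_small_rnas()].
#' @param elements Tibble with `element_id` and `seq`.
#' @param min_len,max_len Read-length window (default 18-30 nt).
#' @return A match tibble: `srna_id`, `srna_seq`, `srna_length`,
#'   `element_id`, `match_start`, `match_end`, `orientation`,
#'   `element_length`, `relative_start`, `relative_end`.
#' @export
match_small_rnas <- function(srnas, elements, min_len = 18L, max_len = 30L) {
  stopifnot(all(c("name", "seq") %in% names(srnas)))
  stopifnot(all(c("element_id", "seq") %in% names(elements)))
  reads <- srnas %>%
    mutate(seq = toupper(.data$seq), srna_length = nchar(.data$seq)) %>%
    filter(.data$srna_length >= min_len, .data$srna_length <= max_len)
  bad <- stringr::str_detect(reads$seq, "[^ACGT]")
  if (any(bad)) {
    warn(sprintf("skipped %d read(s) containing non-ACGT characters", sum(bad)))
    reads <- reads[!bad, ]
  }
  subjects <- Biostrings::DNAStringSet(setNames(toupper(elements$seq), elements$element_id))
  el_len <- setNames(nchar(elements$seq), elements$element_id)

  hit_rows <- function(read_row, pattern, orientation) {
    m <- Biostrings::vmatchPattern(pattern, subjects)
    starts <- Biostrings::startIndex(m)
    hits <- which(lengths(starts) > 0)
    if (length(hits) == 0) return(NULL)
    list_rbind(map(hits, function(h) {
      s1 <- starts[[h]]                       # 1-based starts
      tibble(
        srna_id = read_row$name, srna_seq = read_row$seq,
        srna_length = read_row$srna_length,
        element_id = elements$element_id[h],
        match_start = s1 - 1L,
        match_end = s1 - 1L + read_row$srna_length,
        orientation = orientation,
        element_length = unname(el_len[elements$element_id[h]])
      )
    }))
  }

  out <- list_rbind(map(seq_len(nrow(reads)), function(i) {
    r <- reads[i, ]
    bind_rows(
      hit_rows(r, r$seq, "sense"),
      hit_rows(r, revcomp(r$seq), "antisense")
    )
  }))
  if (is.null(out) || nrow(out) == 0) {
    return(tibble(
      srna_id = character(0), srna_seq = character(0), srna_length = integer(0),
      element_id = character(0), match_start = integer(0), match_end = integer(0),
      orientation = character(0), element_length = integer(0),
      relative_start = numeric(0), relative_end = numeric(0)
    ))
  }
  out %>%
    mutate(
      relative_start = 100 * .data$match_start / .data$element_length,
      relative_end = 100 * .data$match_end / .data$element_length
    )
}

#' Length distribution of matched small RNAs
#'
#' Unique read sequences (not match records) are tallied by length, so a
#' read matching ten elements still counts once and duplicating an element
#' in the input changes nothing.
#'
#' @param matches Match tibble from [match_small_rnas()].
#' @return A tibble `srna_length` / `n` / `proportion` (proportions sum
#'   to 1); empty input gives an empty tibble.
#' @export
length_distribution <- function(matches) {
  matches %>%
    distinct(.data$srna_seq, .keep_all = TRUE) %>%
    count(.data$srna_length, name = "n") %>%
    mutate(proportion = .data$n / sum(.data$n))
}

#' Relative-position profile of matches over percent bins
#'
#' Each match increments every bin its relative interval
#' `[relative_start, relative_end)` overlaps. With the default 100 bins a
#' read spanning the 30-50% region of an element increments bins 30..49.
#'
#' @param matches Match tibble (restrict to full-length elements upstream
#'   when emulating the published full-length profile).
#' @param bins Number of bins across the element (default 100).
#' @return A tibble: `bin` (0-based), `rel_lo`, `rel_hi`, `count`,
#'   `fraction` (of total increments). All-zero when `matches` is empty.
#' @export
relative_position_profile <- function(matches, bins = 100L) {
  width <- 100 / bins
  counts <- integer(bins)
  if (nrow(matches) > 0) {
    lo <- pmin(pmax(floor(matches$relative_start / width), 0), bins - 1)
    hi <- pmin(pmax(ceiling(matches$relative_end / width) - 1, 0), bins - 1)
    for (i in seq_along(lo)) {
      counts[(lo[i]:hi[i]) + 1L] <- counts[(lo[i]:hi[i]) + 1L] + 1L
    }
  }
  total <- sum(counts)
  tibble(
    bin = 0:(bins - 1L),
    rel_lo = (0:(bins - 1L)) * width,
    rel_hi = (1:bins) * width,
    count = counts,
    fraction = if (total > 0) counts / total else rep(0, bins)
  )
}

#' Per-family position profiles with a positional-bias label
#'
#' Families qualify when their members have similar lengths (coefficient of
#' variation at most `max_length_cv`) and more than `min_srnas` distinct
#' matched reads. A qualifying family is labelled `"central"` when at least
#' half the profile mass falls in the 30-69% bins, `"terminal"` when at
#' least half falls in the 0-19% and 80-99% bins, else `"mixed"`.
#'
#' @param matches Match tibble.
#' @param elements Classified element tibble (`element_id`, `family`,
#'   `full_length`; lengths are taken from `seq` or `end - start`).
#' @param min_srnas Minimum distinct matched reads (strict: count must
#'   exceed this).
#' @param max_length_cv Maximum member-length coefficient of variation.
#' @param bins Profile resolution.
#' @return A tibble per qualifying family: `family`, `n_srnas`,
#'   `length_cv`, `bias`, and the `profile` tibble as a list column.
#' @export
family_position_profiles <- function(matches, elements, min_srnas = 100L,
                                     max_length_cv = 0.05, bins = 100L) {
  stopifnot("family" %in% names(elements))
  el <- elements %>% filter(!is.na(.data$family))
  if ("full_length" %in% names(el)) el <- filter(el, .data$full_length)
  el <- el %>%
    mutate(.len = if ("seq" %in% names(el)) nchar(.data$seq) else .data$end - .data$start)
  m <- matches %>%
    inner_join(select(el, "element_id", "family"), by = "element_id")
  fams <- el %>%
    group_by(.data$family) %>%
    summarise(length_cv = sd(.data$.len) / mean(.data$.len), .groups = "drop") %>%
    mutate(length_cv = if_else(is.na(.data$length_cv), 0, .data$length_cv))
  rows <- map(fams$family, function(f) {
    fm <- m[m$family == f, ]
    n_srnas <- n_distinct(fm$srna_seq)
    cv <- fams$length_cv[fams$family == f]
    if (cv > max_length_cv || n_srnas <= min_srnas) return(NULL)
    prof <- relative_position_profile(fm, bins)
    frac <- prof$fraction
    central <- sum(frac[prof$bin >= 0.30 * bins & prof$bin < 0.70 * bins])
    terminal <- sum(frac[prof$bin < 0.20 * bins | prof$bin >= 0.80 * bins])
    bias <- if (central >= 0.5) "central" else if (terminal >= 0.5) "terminal" else "mixed"
    tibble(family = f, n_srnas = n_srnas, length_cv = cv, bias = bias, profile = list(prof))
  })
  rows <- keep(rows, ~ !is.null(.x))
  if (length(rows) == 0) {
    return(tibble(
      family = character(0), n_srnas = integer(0), length_cv = numeric(0),
      bias = character(0), profile = list()
    ))
  }
  list_rbind(rows)
}

#' GS/IS origin of matched small RNAs
#'
#' Each distinct matched read is attributed to GS when at least one of its
#' matched elements lies in GS (midpoint rule), otherwise to IS (or
#' `"unplaced"` when none of its elements could be placed).
#'
#' @param matches Match tibble.
#' @param elements Element tibble carrying a `region` column
#'   ([assign_partition()]).
#' @return A tibble: `region`, `n`, `fraction` (of distinct matched reads).
#' @export
srna_origin_by_partition <- function(matches, elements) {
  stopifnot("region" %in% names(elements))
  m <- matches %>%
    left_join(select(elements, "element_id", "region"), by = "element_id") %>%
    group_by(.data$srna_seq) %>%
    summarise(
      region = if (any(.data$region == "GS", na.rm = TRUE)) "GS"
      else if (any(.data$region == "IS", na.rm = TRUE)) "IS"
      else "unplaced",
      .groups = "drop"
    )
  m %>%
    count(.data$region, name = "n") %>%
    mutate(fraction = .data$n / sum(.data$n))
}
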