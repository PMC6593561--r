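# Alternative splicing: the four basic modes (exon skipping, intron
# retention, alternative 5'/3' splice site) called from pairwise isoform
# comparisons, the MITE-association rules (splice site on a MITE, or MITE
# exonic in only a subset of isoforms), and per-tissue summary ratios.

#' Detect alternative-splicing events from multi-isoform gene models
#'
#' All isoform pairs of each gene are compared and events are deduplicated
#' by (mode, interval, splice sites). Definitions (strand-aware; donor = 5'
#' site, acceptor = 3' site):
#' * **ES** - an internal exon of one isoform is absent from the other while
#'   the two flanking junctions form a direct junction there.
#' * **IR** - an intron of one isoform is exactly spanned, together with its
#'   two flanking exons, by a single exon of the other.
#' * **A5SS / A3SS** - two exons share one boundary and differ at the other,
#'   the shifted boundary is an internal splice site in both isoforms, and
#'   the junction partner on the shifted side is shared.
#'
#' @param exons Exon-level tibble ([read_gff3_genes()] layout).
#' @return A tibble of events: `gene_id`, `mode`, `isoform_a`, `isoform_b`,
#'   `scaffold`, `strand`, `event_start`, `event_end` (the skipped exon,
#'   retained intron, or shift region; 0-based half-open) and `sites` (list
#'   column of the splice-site coordinates involved). Genes with a single
#'   isoform contribute nothing.
#' @export
detect_as_events <- function(exons) {
  stopifnot(all(c("gene_id", "transcript_id", "start", "end") %in% names(exons)))
  out <- exons %>%
    group_by(.data$gene_id) %>%
    group_split() %>%
    map(detect_as_events_one_gene) %>%
    list_rbind()
  if (nrow(out) == 0) {
    return(empty_events())
  }
  out
}

empty_events <- function() {
  tibble(
    gene_id = character(0), mode = character(0), isoform_a = character(0),
    isoform_b = character(0), scaffold = character(0), strand = character(0),
    event_start = integer(0), event_end = integer(0), sites = list()
  )
}

detect_as_events_one_gene <- function(gx) {
  isoforms <- split(gx[order(gx$start), ], gx$transcript_id[order(gx$start)])
  if (length(isoforms) < 2) return(NULL)
  ids <- names(isoforms)
  pairs <- combn(ids, 2, simplify = FALSE)
  evs <- list_rbind(map(pairs, function(p) {
    a <- isoforms[[p[1]]]
    b <- isoforms[[p[2]]]
    bind_rows(
      compare_isoforms(a, b, p[1], p[2]),
      compare_isoforms(b, a, p[2], p[1])
    )
  }))
  if (is.null(evs) || nrow(evs) == 0) return(NULL)
  evs %>%
    mutate(.key = paste(
      .data$mode, .data$event_start, .data$event_end,
      map_chr(.data$sites, ~ paste(.x, collapse = ","))
    )) %>%
    distinct(.data$.key, .keep_all = TRUE) %>%
    select(-".key")
}

# directional comparison: events where isoform A carries the structure
# (skipped exon present in A, intron of A retained in B, exon of A shifted
# relative to an exon of B)
compare_isoforms <- function(a, b, id_a, id_b) {
  sa <- a$start; ea <- a$end
  sb <- b$start; eb <- b$end
  na_ <- length(sa); nb_ <- length(sb)
  strand <- a$strand[1]
  scaffold <- a$scaffold[1]
  rows <- list()
  add <- function(mode, s, e, sites) {
    rows[[length(rows) + 1L]] <<- tibble(
      gene_id = a$gene_id[1], mode = mode, isoform_a = id_a, isoform_b = id_b,
      scaffold = scaffold, strand = strand,
      event_start = as.integer(s), event_end = as.integer(e),
      sites = list(sort(as.integer(sites)))
    )
  }

  # ES: internal exon i of A, absent from B, flanking junctions directly
  # joined in B
  if (na_ >= 3) {
    for (i in 2:(na_ - 1L)) {
      in_b <- any(sb == sa[i] & eb == ea[i])
      if (in_b) next
      j <- which(eb == ea[i - 1L])
      if (length(j) == 1 && j < nb_ && sb[j + 1L] == sa[i + 1L]) {
        add("ES", sa[i], ea[i], c(ea[i - 1L], sa[i], ea[i], sa[i + 1L]))
      }
    }
  }

  # IR: intron i of A retained in B (a single B exon spans A's exon i,
  # the intron, and A's exon i+1 exactly)
  if (na_ >= 2) {
    for (i in seq_len(na_ - 1L)) {
      if (any(sb == sa[i] & eb == ea[i + 1L])) {
        add("IR", ea[i], sa[i + 1L], c(ea[i], sa[i + 1L]))
      }
    }
  }

  # alternative donor/acceptor: exons sharing one boundary, shifted at the
  # other; the shifted boundary must be an internal splice site in both
  # isoforms and the junction partner on the shifted side must be shared
  for (i in seq_len(na_)) {
    # shared start, differing end (donor shift on + strand)
    j <- which(sb == sa[i] & eb != ea[i])
    for (jj in j) {
      if (i < na_ && jj < nb_ && sa[i + 1L] == sb[jj + 1L]) {
        mode <- if (strand == "-") "A3SS" else "A5SS"
        add(mode, min(ea[i], eb[jj]), max(ea[i], eb[jj]), c(ea[i], eb[jj]))
      }
    }
    # shared end, differing start (acceptor shift on + strand)
    j <- which(eb == ea[i] & sb != sa[i])
    for (jj in j) {
      if (i > 1 && jj > 1 && ea[i - 1L] == eb[jj - 1L]) {
        mode <- if (strand == "-") "A5SS" else "A3SS"
        add(mode, min(sa[i], sb[jj]), max(sa[i], sb[jj]), c(sa[i], sb[jj]))
      }
    }
  }
  if (length(rows) == 0) return(NULL)
  list_rbind(rows)
}

#' Associate splicing events with MITE insertions
#'
#' Two association routes, following the published rule: the event's splice
#' sites lie on a MITE (`site_on_mite`: any involved site position falls
#' within an element interval), or a MITE is exonized in only a subset of
#' the gene's isoforms (`mite_variant_specific`: some element overlaps
#' exonic sequence of at least one isoform but none of at least one other
#' isoform of the same gene). `associated` is the OR of the two flags.
#'
#' @param events Event tibble from [detect_as_events()].
#' @param elements MITE element tibble (`scaffold`, `start`, `end`), same
#'   coordinate system as the gene models.
#' @param exons Exon-level tibble for the genes in `events`.
#' @return `events` with `site_on_mite`, `mite_variant_specific` and
#'   `associated` columns added.
#' @export
associate_events_with_mites <- function(events, elements, exons) {
  if (nrow(events) == 0) {
    return(mutate(events,
      site_on_mite = logical(0), mite_variant_specific = logical(0),
      associated = logical(0)
    ))
  }
  site_on <- map_lgl(seq_len(nrow(events)), function(i) {
    sc <- events$scaffold[i]
    sites <- events$sites[[i]]
    m <- elements[elements$scaffold == sc, ]
    if (nrow(m) == 0) return(FALSE)
    any(vapply(sites, function(p) any(m$start <= p & p < m$end), logical(1)))
  })
  vs_by_gene <- map_lgl(unique(events$gene_id), function(g) {
    gene_variant_specific(g, elements, exons)
  })
  names(vs_by_gene) <- unique(events$gene_id)
  events %>%
    mutate(
      site_on_mite = site_on,
      mite_variant_specific = unname(vs_by_gene[.data$gene_id]),
      associated = .data$site_on_mite | .data$mite_variant_specific
    )
}

gene_variant_specific <- function(gene_id, elements, exons) {
  gx <- exons[exons$gene_id == gene_id, ]
  isoforms <- split(gx, gx$transcript_id)
  if (length(isoforms) < 2) return(FALSE)
  m <- elements[elements$scaffold == gx$scaffold[1], ]
  if (nrow(m) == 0) return(FALSE)
  overlaps <- vapply(isoforms, function(iso) {
    vapply(seq_len(nrow(m)), function(k) {
      any(m$start[k] < iso$end & iso$start < m$end[k])
    }, logical(1))
  }, logical(nrow(m)))
  overlaps <- matrix(overlaps, nrow = nrow(m))
  any(apply(overlaps, 1, function(r) any(r) && !all(r)))
}

#' Per-tissue, per-mode alternative-splicing summary
#'
#' Two ratios, per tissue: the share of alternatively spliced genes that are
#' MITE-associated (per mode and overall), and the share of events with a
#' splice site on a MITE relative to all alternatively spliced genes. A gene
#' counts in a tissue only when expressed there (RPKM >= `rpkm_min`); pass
#' `expression = NULL` to disable the gate (a single `"all"` tissue).
#'
#' @param events Associated event tibble ([associate_events_with_mites()]).
#' @param expression Long expression tibble or `NULL`.
#' @param tissues Tissues to report (default: all in `expression`).
#' @param rpkm_min Expression gate.
#' @return An object of class `mite_as_summary`: list with `by_mode`
#'   (`tissue`, `mode`, `n_assoc_genes`, `n_as_genes`, `percent`) and
#'   `site_on_mite` (`tissue`, `n_site_events`, `n_as_genes`, `percent`).
#'   Ratios are `NA` in tissues with no AS genes.
#' @export
as_summary <- function(events, expression = NULL, tissues = NULL, rpkm_min = 1) {
  stopifnot(all(c("associated", "site_on_mite") %in% names(events)))
  if (is.null(expression)) {
    tissues <- "all"
    expressed <- function(tis) unique(events$gene_id)
  } else {
    tissues <- tissues %||% unique(expression$tissue)
    missing <- setdiff(tissues, unique(expression$tissue))
    if (length(missing) > 0) abort(sprintf("tissue not in expression table: %s", missing[1]))
    expressed <- function(tis) {
      unique(expression$gene_id[expression$tissue == tis & expression$rpkm >= rpkm_min])
    }
  }
  modes <- c("ES", "IR", "A3SS", "A5SS")
  by_mode <- list_rbind(map(tissues, function(tis) {
    ev <- events[events$gene_id %in% expressed(tis), ]
    n_as <- n_distinct(ev$gene_id)
    list_rbind(map(c(modes, "any"), function(md) {
      sel <- if (md == "any") ev else ev[ev$mode == md, ]
      tibble(
        tissue = tis, mode = md,
        n_assoc_genes = n_distinct(sel$gene_id[sel$associated]),
        n_as_genes = n_as,
        percent = if (n_as > 0) 100 * n_distinct(sel$gene_id[sel$associated]) / n_as else NA_real_
      )
    }))
  }))
  site <- list_rbind(map(tissues, function(tis) {
    ev <- events[events$gene_id %in% expressed(tis), ]
    n_as <- n_distinct(ev$gene_id)
    tibble(
      tissue = tis,
      n_site_events = sum(ev$site_on_mite),
      n_as_genes = n_as,
      percent = if (n_as > 0) 100 * sum(ev$site_on_mite) / n_as else NA_real_
    )
  }))
  structure(list(by_mode = by_mode, site_on_mite = site), class = "mite_as_summary")
}

#' @export
print.mite_as_summary <- function(x, ...) {
  cat("<mite_as_summary>\nMITE-associated AS genes / all AS genes (%):\n")
  print(as.data.frame(x$by_mode))
  cat("Events with splice site on a MITE / all AS genes (%):\n")
  print(as.data.frame(x$site_on_mite))
  invisible(x)
}
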