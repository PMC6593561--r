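# Genomic context of MITE insertions: GS/IS partition of every scaffold
# (gene body plus a 2000-bp flank on each side, overlapping blocks merged),
# per-family GS/IS counts and regression, superfamily enrichment near genes,
# expression of MITE-inserted genes, and the gene-association summary table.

#' Partition scaffolds into gene sequence (GS) and intergenic sequence (IS)
#'
#' Each gene contributes the interval `[gene_start - flank, gene_end +
#' flank)` clipped to its scaffold; overlapping or abutting GS blocks are
#' merged (so any gap between adjacent genes shorter than the flank width is
#' absorbed into GS) and IS is the complement. GS and IS tile each scaffold
#' exactly.
#'
#' @param genes Exon-level tibble ([read_gff3_genes()]) or a gene-level
#'   tibble with `gene_id`, `scaffold`, `start`, `end`.
#' @param scaffold_lengths Named numeric vector, or tibble with `scaffold`
#'   and `length`. Must cover every scaffold carrying a gene.
#' @param flank Flank width in bases (default 2000).
#' @return A tibble with columns `scaffold`, `start`, `end`, `region`
#'   (`"GS"`/`"IS"`), sorted by scaffold and start; the flank width is kept
#'   in the `"flank"` attribute.
#' @export
partition_genome <- function(genes, scaffold_lengths, flank = 2000L) {
  sl <- scaffold_length_vector(scaffold_lengths)
  gn <- gene_extents(genes)
  missing <- setdiff(unique(gn$scaffold), names(sl))
  if (length(missing) > 0) abort(sprintf("no length given for scaffold %s", missing[1]))
  outside <- gn$start < 0 | gn$end > sl[gn$scaffold]
  if (any(outside)) {
    g <- gn[which(outside)[1], ]
    abort(sprintf("gene %s lies outside scaffold %s bounds", g$gene_id, g$scaffold))
  }
  parts <- map(names(sl), function(sc) {
    len <- sl[[sc]]
    gs <- gn %>%
      filter(.data$scaffold == sc) %>%
      mutate(start = pmax(0, .data$start - flank), end = pmin(len, .data$end + flank))
    if (nrow(gs) == 0) {
      return(tibble(scaffold = sc, start = 0, end = len, region = "IS"))
    }
    gs_ir <- IRanges::reduce(IRanges::IRanges(gs$start + 1L, gs$end))
    is_ir <- IRanges::gaps(gs_ir, start = 1L, end = len)
    bind_rows(
      tibble(scaffold = sc, start = IRanges::start(gs_ir) - 1, end = as.numeric(IRanges::end(gs_ir)), region = "GS"),
      tibble(scaffold = sc, start = IRanges::start(is_ir) - 1, end = as.numeric(IRanges::end(is_ir)), region = "IS")
    )
  })
  out <- list_rbind(parts) %>% arrange(.data$scaffold, .data$start)
  attr(out, "flank") <- flank
  out
}

gene_extents <- function(genes) {
  stopifnot(all(c("gene_id", "scaffold", "start", "end") %in% names(genes)))
  genes %>%
    group_by(.data$gene_id, .data$scaffold) %>%
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop")
}

#' Assign each element to GS or IS by its midpoint
#'
#' Midpoint assignment (rather than any-overlap) keeps per-family counts
#' exactly conserved: gs + is + unplaced = family size. Elements on
#' scaffolds absent from the partition are labelled `"unplaced"`.
#'
#' @param elements Element tibble (`scaffold`, `start`, `end`).
#' @param partition Output of [partition_genome()].
#' @return `elements` with a `region` column added.
#' @export
assign_partition <- function(elements, partition) {
  el <- elements %>% mutate(.mid = (.data$start + .data$end) %/% 2)
  by_sc <- split(seq_len(nrow(el)), el$scaffold)
  region <- rep("unplaced", nrow(el))
  for (sc in names(by_sc)) {
    p <- partition[partition$scaffold == sc, ]
    if (nrow(p) == 0) next
    p <- p[order(p$start), ]
    idx <- findInterval(el$.mid[by_sc[[sc]]], p$start)
    ok <- idx >= 1 & el$.mid[by_sc[[sc]]] < p$end[pmax(idx, 1)]
    region[by_sc[[sc]][ok]] <- p$region[idx[ok]]
  }
  el %>% mutate(region = region) %>% select(-".mid")
}

#' Per-family GS/IS counts
#'
#' @param elements Element tibble with a `family` column.
#' @param partition Output of [partition_genome()].
#' @return A tibble with one row per family: `family`, `gs`, `is`,
#'   `unplaced`, `total`.
#' @export
count_mites_by_partition <- function(elements, partition) {
  assign_partition(elements, partition) %>%
    filter(!is.na(.data$family)) %>%
    count(.data$family, .data$region) %>%
    tidyr::pivot_wider(
      names_from = "region", values_from = "n", values_fill = 0L
    ) %>%
    rename_region_cols() %>%
    mutate(total = .data$gs + .data$is + .data$unplaced)
}

rename_region_cols <- function(tbl) {
  for (col in c(GS = "gs", IS = "is", unplaced = "unplaced")) {
  }
  nm <- names(tbl)
  nm[nm == "GS"] <- "gs"
  nm[nm == "IS"] <- "is"
  names(tbl) <- nm
  for (col in c("gs", "is", "unplaced")) {
    if (!col %in% names(tbl)) tbl[[col]] <- 0L
  }
  tbl
}

#' Regression of intergenic on genic copy numbers across families
#'
#' Ordinary least squares of the IS count on the GS count, one point per
#' family. Families with a standardized residual above `outlier_threshold`
#' on the IS-excess side (more intergenic copies than the family-wide trend
#' predicts) are flagged as outliers.
#'
#' @param counts Output of [count_mites_by_partition()] (needs `family`,
#'   `gs`, `is`); at least 3 families, non-constant `gs`.
#' @param outlier_threshold Standardized-residual cutoff (default 2).
#' @return An object of class `mite_gsis`: list with `model` (the `lm`),
#'   `data`, `r_squared`, `p_value`, `slope`, `intercept`,
#'   `outlier_families`. Has [tidy()], [glance()] and [autoplot()] methods.
#' @export
gs_is_regression <- function(counts, outlier_threshold = 2) {
  stopifnot(all(c("family", "gs", "is") %in% names(counts)))
  if (nrow(counts) < 3) abort("need at least 3 families for the GS/IS regression")
  if (sd(counts$gs) == 0) abort("gs counts are constant; regression undefined")
  dat <- tibble(family = counts$family, gs = counts$gs, is = counts$is)
  fit <- lm(is ~ gs, data = dat)
  rs <- rstandard(fit)   # NaN for an exact fit: which() drops those
  outliers <- dat$family[which(rs > outlier_threshold & residuals(fit) > 0)]
  smry <- suppressWarnings(summary(fit))   # "perfect fit" warning on exact data
  out <- list(
    model = fit, data = dat,
    slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
    r_squared = smry$r.squared,
    p_value = smry$coefficients["gs", "Pr(>|t|)"],
    outlier_families = outliers,
    outlier_threshold = outlier_threshold
  )
  class(out) <- "mite_gsis"
  out
}

#' @export
print.mite_gsis <- function(x, ...) {
  cat(sprintf(
    "<mite_gsis> IS ~ GS over %d families: slope %.3f, r^2 = %.3f, p = %.3g\n",
    nrow(x$data), x$slope, x$r_squared, x$p_value
  ))
  if (length(x$outlier_families) > 0) {
    cat("  IS-excess outliers:", paste(x$outlier_families, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Superfamily enrichment in gene-flank zones
#'
#' Compares, per superfamily, its share of all MITEs genome-wide with its
#' share among MITEs whose midpoint falls in the flank-only zones (the
#' `flank`-bp windows upstream/downstream of genes, gene bodies excluded).
#' Enrichment is the near-gene share minus the genome-wide share; shares sum
#' to 1 within each zone.
#'
#' @param elements Classified element tibble (needs a superfamily column).
#' @param genes Gene or exon tibble.
#' @param flank Flank width in bases.
#' @return A tibble per superfamily: `n_total`, `n_near`, `genome_share`,
#'   `near_share`, `enrichment`.
#' @export
proximity_enrichment <- function(elements, genes, flank = 2000L) {
  sf_col <- if ("family_superfamily" %in% names(elements)) "family_superfamily" else "superfamily"
  gn <- gene_extents(genes)
  flanked <- gn %>% mutate(start = pmax(0, .data$start - flank), end = .data$end + flank)
  zones <- flank_zones(gn, flanked)
  el <- elements %>%
    mutate(
      .sf = .data[[sf_col]],
      .mid = (.data$start + .data$end) %/% 2,
      near = midpoint_in(.data$scaffold, .data$.mid, zones)
    )
  n_all <- nrow(el)
  n_near_all <- sum(el$near)
  el %>%
    group_by(superfamily = .data$.sf) %>%
    summarise(n_total = n(), n_near = sum(.data$near), .groups = "drop") %>%
    mutate(
      genome_share = .data$n_total / n_all,
      near_share = if (n_near_all > 0) .data$n_near / n_near_all else NA_real_,
      enrichment = .data$near_share - .data$genome_share
    )
}

# flank windows minus gene bodies, as a reduced interval tibble
flank_zones <- function(gene_bodies, flanked) {
  fl <- reduce_intervals(flanked)
  gb <- reduce_intervals(gene_bodies)
  parts <- map(unique(fl$scaffold), function(sc) {
    f <- fl[fl$scaffold == sc, ]
    g <- gb[gb$scaffold == sc, ]
    ir <- IRanges::setdiff(
      IRanges::IRanges(f$start + 1L, f$end),
      IRanges::IRanges(g$start + 1L, g$end)
    )
    tibble(scaffold = sc, start = IRanges::start(ir) - 1, end = as.numeric(IRanges::end(ir)))
  })
  list_rbind(parts)
}

midpoint_in <- function(scaffold, mid, zones) {
  out <- logical(length(mid))
  for (sc in unique(scaffold)) {
    z <- zones[zones$scaffold == sc, ]
    sel <- scaffold == sc
    if (nrow(z) == 0) next
    z <- z[order(z$start), ]
    idx <- findInterval(mid[sel], z$start)
    out[sel] <- idx >= 1 & mid[sel] < z$end[pmax(idx, 1)]
  }
  out
}

#' Expressed MITE-inserted gene ratio per superfamily and tissue
#'
#' The numerator counts genes with at least one MITE of the superfamily
#' overlapping an exon (any isoform) and RPKM >= `rpkm_min` in the tissue;
#' the denominator is all genes in the annotation.
#'
#' @param elements Classified element tibble.
#' @param exons Exon-level tibble.
#' @param expression Long expression tibble (`gene_id`, `tissue`, `rpkm`).
#' @param rpkm_min Expression gate (default 1).
#' @param tissues Tissues to report (default: all in `expression`); a
#'   requested tissue missing from the table is an error.
#' @return A tibble: `superfamily`, `tissue`, `n_genes`, `n_total_genes`,
#'   `percent`.
#' @export
expressed_gene_ratio <- function(elements, exons, expression, rpkm_min = 1,
                                 tissues = NULL) {
  tissues <- tissues %||% unique(expression$tissue)
  missing <- setdiff(tissues, unique(expression$tissue))
  if (length(missing) > 0) abort(sprintf("tissue not in expression table: %s", missing[1]))
  sf_col <- if ("family_superfamily" %in% names(elements)) "family_superfamily" else "superfamily"
  hits <- mite_exon_genes(elements, exons) %>%
    mutate(superfamily = elements[[sf_col]][.data$element_row]) %>%
    distinct(.data$superfamily, .data$gene_id)
  n_total <- n_distinct(exons$gene_id)
  grid <- tidyr::expand_grid(
    superfamily = sort(unique(elements[[sf_col]])),
    tissue = tissues
  )
  expressed <- expression %>% filter(.data$rpkm >= rpkm_min)
  grid %>%
    mutate(
      n_genes = map2_int_grid(.data$superfamily, .data$tissue, hits, expressed),
      n_total_genes = n_total,
      percent = 100 * .data$n_genes / n_total
    )
}

map2_int_grid <- function(sf, tis, hits, expressed) {
  map_int(seq_along(sf), function(i) {
    genes_sf <- hits$gene_id[hits$superfamily == sf[i]]
    genes_ex <- expressed$gene_id[expressed$tissue == tis[i]]
    length(intersect(genes_sf, genes_ex))
  })
}

# element-exon overlap join; returns element_row / gene_id pairs
mite_exon_genes <- function(elements, exons) {
  rows <- map(unique(elements$scaffold), function(sc) {
    ei <- which(elements$scaffold == sc)
    xi <- which(exons$scaffold == sc)
    if (length(ei) == 0 || length(xi) == 0) return(NULL)
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(elements$start[ei] + 1L, elements$end[ei]),
      IRanges::IRanges(exons$start[xi] + 1L, exons$end[xi])
    )
    tibble(
      element_row = ei[S4Vectors::queryHits(hits)],
      gene_id = exons$gene_id[xi[S4Vectors::subjectHits(hits)]],
      transcript_id = exons$transcript_id[xi[S4Vectors::subjectHits(hits)]]
    )
  })
  out <- list_rbind(keep(rows, ~ !is.null(.x)))
  if (nrow(out) == 0) {
    return(tibble(element_row = integer(0), gene_id = character(0), transcript_id = character(0)))
  }
  distinct(out)
}

#' Flag elements that overlap an exon of an expressed gene
#'
#' Adds `expressed_with_gene`: `TRUE` when the element overlaps an exon of a
#' gene with RPKM >= `rpkm_min` in at least one tissue.
#'
#' @inheritParams expressed_gene_ratio
#' @return `elements` with the flag column added.
#' @export
flag_expressed_with_gene <- function(elements, exons, expression, rpkm_min = 1) {
  expressed_genes <- expression %>%
    filter(.data$rpkm >= rpkm_min) %>%
    pull(.data$gene_id) %>%
    unique()
  hits <- mite_exon_genes(elements, exons) %>%
    filter(.data$gene_id %in% expressed_genes)
  elements %>%
    mutate(expressed_with_gene = seq_len(n()) %in% hits$element_row)
}

#' Flag elements matched by at least one small RNA
#'
#' @param elements Element tibble with `element_id`.
#' @param matches Small-RNA match tibble ([match_small_rnas()]).
#' @return `elements` with a logical `srna_related` column added.
#' @export
flag_srna_related <- function(elements, matches) {
  elements %>%
    mutate(srna_related = .data$element_id %in% unique(matches$element_id))
}

#' Gene-association summary (Table-2 style)
#'
#' Per superfamily (plus a `Total` row): total elements, gene-associated
#' elements (midpoint in GS), elements overlapping exons of expressed genes,
#' small-RNA-related elements, and the small-RNA-related percentage of the
#' total. Upstream flags are supplied by [assign_partition()],
#' [flag_expressed_with_gene()] and [flag_srna_related()]; absent flag
#' columns yield `NA` in the corresponding summary column.
#'
#' @param elements Element tibble with a superfamily column and whichever of
#'   `region`, `expressed_with_gene`, `srna_related` are available.
#' @return A tibble with one row per superfamily plus totals.
#' @export
gene_association_summary <- function(elements) {
  sf_col <- if ("family_superfamily" %in% names(elements)) "family_superfamily" else "superfamily"
  el <- elements %>% mutate(.sf = .data[[sf_col]])
  one <- function(g, label) {
    tibble(
      superfamily = label,
      total_elements = nrow(g),
      associated_with_genes = if ("region" %in% names(g)) sum(g$region == "GS") else NA_integer_,
      expressed_with_genes = if ("expressed_with_gene" %in% names(g)) sum(g$expressed_with_gene) else NA_integer_,
      srna_related = if ("srna_related" %in% names(g)) sum(g$srna_related) else NA_integer_,
      srna_related_percent = if ("srna_related" %in% names(g) && nrow(g) > 0) {
        100 * sum(g$srna_related) / nrow(g)
      } else NA_real_
    )
  }
  present <- intersect(SUPERFAMILIES, unique(el$.sf))
  bind_rows(
    list_rbind(map(present, function(sf) one(filter(el, .data$.sf == sf), sf))),
    one(el, "Total")
  )
}
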