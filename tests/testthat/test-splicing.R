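# Alternative-splicing event detection, the MITE association rules, and
# the per-tissue summary.

two_isoform_gene <- function(a_starts, a_ends, b_starts, b_ends, strand = "+",
                             gene = "g1", scaffold = "sc") {
  dplyr::bind_rows(
    toy_exons(gene, scaffold, a_starts, a_ends, strand, paste0(gene, ".t1")),
    toy_exons(gene, scaffold, b_starts, b_ends, strand, paste0(gene, ".t2"))
  )
}

test_that("the three canonical toy events are detected", {
  es <- detect_as_events(two_isoform_gene(
    c(0, 200, 400), c(100, 300, 500), c(0, 400), c(100, 500)
  ))
  expect_equal(es$mode, "ES")
  expect_equal(c(es$event_start, es$event_end), c(200L, 300L))
  expect_equal(es$sites[[1]], c(100L, 200L, 300L, 400L))

  ir <- detect_as_events(two_isoform_gene(c(0, 200), c(100, 300), 0, 300))
  expect_equal(ir$mode, "IR")
  expect_equal(c(ir$event_start, ir$event_end), c(100L, 200L))

  a3 <- detect_as_events(two_isoform_gene(
    c(0, 200), c(100, 300), c(0, 180), c(100, 300)
  ))
  expect_equal(a3$mode, "A3SS")
  expect_equal(c(a3$event_start, a3$event_end), c(180L, 200L))
  expect_equal(a3$event_end - a3$event_start, 20L)
})

test_that("single-isoform genes and duplicate isoforms produce no extra events", {
  expect_equal(nrow(detect_as_events(toy_exons("g1", "sc", c(0, 200), c(100, 300)))), 0L)
  gx <- two_isoform_gene(c(0, 200), c(100, 300), 0, 300)
  with_dup <- dplyr::bind_rows(
    gx, toy_exons("g1", "sc", c(0, 200), c(100, 300), transcript = "g1.t3")
  )
  ev1 <- detect_as_events(gx)
  ev2 <- detect_as_events(with_dup)
  expect_equal(
    ev2[, c("mode", "event_start", "event_end")],
    ev1[, c("mode", "event_start", "event_end")]
  )
})

test_that("flipping the strand swaps A5SS and A3SS labels, nothing else", {
  # same exon coordinates read on the opposite strand: the boundary that was
  # an acceptor becomes a donor, so the label swaps while the interval stays
  plus <- two_isoform_gene(c(0, 200), c(100, 300), c(0, 180), c(100, 300), strand = "+")
  minus <- dplyr::mutate(plus, strand = "-")
  ev_p <- detect_as_events(plus)
  ev_m <- detect_as_events(minus)
  expect_equal(ev_p$mode, "A3SS")
  expect_equal(ev_m$mode, "A5SS")
  expect_equal(ev_m$event_start, ev_p$event_start)
  expect_equal(ev_m$event_end, ev_p$event_end)
  # reflecting coordinates and flipping the strand leaves the biology, and
  # hence the label, unchanged
  L <- 1000L
  mirrored <- plus |>
    dplyr::mutate(s = L - end, e = L - start, start = s, end = e, strand = "-") |>
    dplyr::select(-s, -e)
  expect_equal(detect_as_events(mirrored)$mode, "A3SS")
})

test_that("event detection agrees with the set-based oracle on exhaustive small genes", {
  set.seed(91)
  key <- function(d) sort(unique(paste(d$gene_id, d$mode, d$event_start, d$event_end)))
  for (i in 1:40) {
    # random gene with 2-4 isoforms of 1-5 exons on a shared exon grid
    bounds <- sort(sample(seq(0, 2000, by = 50), 12))
    n_iso <- sample(2:4, 1)
    iso <- purrr::map(seq_len(n_iso), function(t) {
      n_ex <- sample(1:5, 1)
      starts <- sort(sample(bounds, n_ex))
      widths <- sample(30:45, n_ex, replace = TRUE)
      toy_exons("g", "sc", starts, starts + widths,
                transcript = sprintf("g.t%d", t))
    })
    gx <- dplyr::bind_rows(iso)
    # drop malformed isoforms with overlapping exons
    ok <- gx |>
      dplyr::group_by(transcript_id) |>
      dplyr::arrange(start, .by_group = TRUE) |>
      dplyr::summarise(good = all(diff(start) > 45 | dplyr::n() == 1))
    gx <- gx[gx$transcript_id %in% ok$transcript_id[ok$good], ]
    if (dplyr::n_distinct(gx$transcript_id) < 2) next
    got <- detect_as_events(gx)
    want <- oracle_as_events(gx)
    expect_equal(key(got), key(want), info = sprintf("gene set %d", i))
  }
})

test_that("association rules: site on MITE, variant-specific exonization", {
  # IR event whose retained intron contains a MITE spanning the acceptor site
  gx <- two_isoform_gene(c(0, 200), c(100, 300), 0, 300)
  ev <- detect_as_events(gx)
  mites_on_site <- tibble::tibble(element_id = "m1", scaffold = "sc", start = 150L, end = 230L)
  a1 <- associate_events_with_mites(ev, mites_on_site, gx)
  expect_true(a1$site_on_mite)

  # MITE inside the skipped exon: exonic in the inclusion isoform only
  gx2 <- two_isoform_gene(c(0, 200, 400), c(100, 300, 500), c(0, 400), c(100, 500))
  ev2 <- detect_as_events(gx2)
  mite_in_exon <- tibble::tibble(element_id = "m2", scaffold = "sc", start = 220L, end = 280L)
  a2 <- associate_events_with_mites(ev2, mite_in_exon, gx2)
  expect_false(a2$site_on_mite)
  expect_true(a2$mite_variant_specific)
  expect_true(a2$associated)

  # MITE far from the gene: both flags false
  far <- tibble::tibble(element_id = "m3", scaffold = "sc", start = 9000L, end = 9100L)
  a3 <- associate_events_with_mites(ev2, far, gx2)
  expect_false(a3$site_on_mite)
  expect_false(a3$mite_variant_specific)
  expect_false(a3$associated)
})

test_that("per-tissue summary computes both published ratio types", {
  # 20 AS genes, 1 with a MITE association
  gx <- purrr::list_rbind(purrr::map(1:20, function(i) {
    two_isoform_gene(c(0, 200), c(100, 300), 0, 300, gene = paste0("g", i))
  }))
  ev <- detect_as_events(gx)
  # element spans the donor site at 100, so the event is site-associated
  mites <- tibble::tibble(element_id = "m1", scaffold = "sc", start = 80L, end = 130L)
  # associate only for gene g1 by restricting exons per gene id
  assoc <- purrr::list_rbind(purrr::map(unique(ev$gene_id), function(g) {
    associate_events_with_mites(
      ev[ev$gene_id == g, ],
      if (g == "g1") mites else mites[0, ],
      gx[gx$gene_id == g, ]
    )
  }))
  s <- as_summary(assoc)
  any_row <- s$by_mode[s$by_mode$mode == "any", ]
  expect_equal(any_row$n_as_genes, 20L)
  expect_equal(any_row$percent, 5.0)
  expect_equal(s$site_on_mite$percent, 100 * 1 / 20)

  # expression gate: only genes expressed in the tissue count
  expr <- tibble::tibble(
    gene_id = paste0("g", 1:20),
    tissue = "flower",
    rpkm = c(rep(5, 10), rep(0, 10))
  )
  s2 <- as_summary(assoc, expression = expr)
  expect_equal(s2$by_mode$n_as_genes[s2$by_mode$mode == "any"], 10L)
  expect_error(as_summary(assoc, expression = expr, tissues = "root"), "root")

  # no associations and zero-AS-gene guard
  none <- dplyr::mutate(assoc, associated = FALSE, site_on_mite = FALSE)
  s3 <- as_summary(none)
  expect_true(all(s3$by_mode$percent == 0))
  s4 <- as_summary(assoc[0, ])
  expect_true(all(is.na(s4$by_mode$percent)))
  all_assoc <- dplyr::mutate(assoc, associated = TRUE)
  expect_equal(as_summary(all_assoc)$by_mode$percent[as_summary(all_assoc)$by_mode$mode == "any"], 100)
})
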