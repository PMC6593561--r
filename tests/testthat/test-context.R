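# GS/IS partitioning, midpoint counting, regression, enrichment and the
# gene-association summary.

test_that("partition follows the flank rule and tiles the scaffold", {
  genes <- toy_exons("g1", "sc", 5000, 8000)
  part <- partition_genome(genes, c(sc = 20000), flank = 2000)
  gs <- part[part$region == "GS", ]
  is <- part[part$region == "IS", ]
  expect_equal(c(gs$start, gs$end), c(3000, 10000))
  expect_equal(is$start, c(0, 10000))
  expect_equal(is$end, c(3000, 20000))
  expect_equal(sum(part$end - part$start), 20000)
})

test_that("genes closer than the flank merge into one GS block; edges clip", {
  genes <- dplyr::bind_rows(
    toy_exons("g1", "sc", 5000, 6000),
    toy_exons("g2", "sc", 7500, 8500)    # 1500-bp gap < flank
  )
  part <- partition_genome(genes, c(sc = 20000), flank = 2000)
  gs <- part[part$region == "GS", ]
  expect_equal(nrow(gs), 1L)
  expect_equal(c(gs$start, gs$end), c(3000, 10500))

  near0 <- partition_genome(toy_exons("g", "sc", 500, 1500), c(sc = 10000), flank = 2000)
  expect_equal(min(near0$start[near0$region == "GS"]), 0)

  # gene-free scaffolds are all IS
  part2 <- partition_genome(genes, c(sc = 20000, empty = 5000), flank = 2000)
  emp <- part2[part2$scaffold == "empty", ]
  expect_equal(emp$region, "IS")
  expect_equal(emp$end - emp$start, 5000)
})

test_that("partition tiling holds for random gene sets", {
  set.seed(71)
  for (i in 1:10) {
    n <- sample(1:6, 1)
    starts <- sort(sample(seq(0, 40000, by = 100), n))
    genes <- purrr::list_rbind(purrr::map(seq_len(n), function(j) {
      toy_exons(paste0("g", j), "sc", starts[j], starts[j] + sample(500:3000, 1))
    }))
    sl <- c(sc = max(genes$end) + sample(3000:10000, 1))
    part <- partition_genome(genes, sl)
    expect_equal(sum(part$end - part$start), unname(sl))
    # disjointness: sorted intervals never overlap
    p <- part[order(part$start), ]
    expect_true(all(utils::head(p$end, -1) <= utils::tail(p$start, -1) + 1e-9))
  }
  expect_error(
    partition_genome(toy_exons("g", "sc", 100, 9000), c(sc = 5000)),
    "outside"
  )
})

test_that("midpoint assignment conserves per-family counts", {
  genes <- toy_exons("g1", "sc", 5000, 8000)
  part <- partition_genome(genes, c(sc = 20000))
  el <- tibble::tibble(
    element_id = c("a", "b", "c", "d"),
    scaffold = c("sc", "sc", "sc", "other"),
    # b straddles the 10000 GS/IS boundary with its midpoint at 10100 (IS)
    start = c(4000L, 9900L, 11000L, 0L), end = c(4200L, 10300L, 11200L, 100L),
    family = "MnT1"
  )
  counts <- count_mites_by_partition(el, part)
  expect_equal(counts$gs, 1L)
  expect_equal(counts$is, 2L)
  expect_equal(counts$unplaced, 1L)
  expect_equal(counts$total, 4L)
  empty <- count_mites_by_partition(el[0, ], part)
  expect_equal(nrow(empty), 0L)
})

test_that("GS/IS regression matches the closed-form least squares and flags IS excess", {
  counts <- tibble::tibble(
    family = sprintf("f%d", 1:21),
    gs = c(1:20, 5), is = c(2 * (1:20) + 3, 55)   # last family far above the line
  )
  fit <- gs_is_regression(counts)
  # closed-form OLS on all 21 points
  b <- cov(counts$gs, counts$is) / var(counts$gs)
  a <- mean(counts$is) - b * mean(counts$gs)
  expect_equal(fit$slope, b, tolerance = 1e-10)
  expect_equal(fit$intercept, a, tolerance = 1e-10)
  expect_equal(fit$outlier_families, "f21")
  expect_lt(fit$p_value, 0.05)

  perfect <- tibble::tibble(family = c("a", "b", "c"), gs = 1:3, is = c(2, 4, 6))
  pf <- gs_is_regression(perfect)
  expect_equal(pf$r_squared, 1)
  expect_equal(length(pf$outlier_families), 0L)

  expect_error(gs_is_regression(perfect[1:2, ]), "3 families")
  flat <- tibble::tibble(family = c("a", "b", "c"), gs = c(2, 2, 2), is = 1:3)
  expect_error(gs_is_regression(flat), "constant")
})

test_that("proximity enrichment: shares sum to one, forced placement is enriched", {
  genes <- toy_exons("g1", "sc", 10000, 12000)
  el <- tibble::tibble(
    element_id = sprintf("e%d", 1:40),
    scaffold = "sc",
    start = c(seq(8200, 9700, length.out = 10),          # hAT: all in the upstream flank
              seq(30000, 68000, length.out = 30)),       # Tc1: far from the gene
    superfamily = rep(c("hAT", "Tc1/Mariner"), c(10, 30))
  ) |> dplyr::mutate(start = as.integer(start), end = start + 100L)
  pe <- proximity_enrichment(el, genes, flank = 2000)
  expect_equal(sum(pe$genome_share), 1)
  expect_equal(sum(pe$near_share), 1)
  expect_gt(pe$enrichment[pe$superfamily == "hAT"], 0)
  expect_lt(pe$enrichment[pe$superfamily == "Tc1/Mariner"], 0)
  # all elements of one superfamily near genes: both shares 1
  solo <- proximity_enrichment(el[1:10, ], genes, flank = 2000)
  expect_equal(solo$genome_share, 1)
  expect_equal(solo$near_share, 1)
})

test_that("uniform random placement yields near-zero enrichment", {
  set.seed(72)
  genes <- dplyr::bind_rows(
    toy_exons("g1", "sc", 20000, 23000),
    toy_exons("g2", "sc", 60000, 64000)
  )
  el <- tibble::tibble(
    element_id = sprintf("e%d", 1:2000),
    scaffold = "sc",
    start = sample.int(99800, 2000),
    superfamily = sample(c("hAT", "Tc1/Mariner"), 2000, TRUE)
  ) |> dplyr::mutate(end = start + 100L)
  pe <- proximity_enrichment(el, genes, flank = 2000)
  expect_lt(max(abs(pe$enrichment)), 0.06)
})

test_that("expressed gene ratio applies the exon-overlap and RPKM gates", {
  exons <- dplyr::bind_rows(
    purrr::map(1:100, function(i) toy_exons(paste0("g", i), "sc", i * 1000, i * 1000 + 200))
  )
  # MITEs in the exons of g1 and g2 only
  el <- tibble::tibble(
    element_id = c("m1", "m2", "m3"), scaffold = "sc",
    start = c(1050L, 2050L, 50L), end = c(1080L, 2080L, 80L),
    superfamily = "PIF/Harbinger"
  )
  expr <- tidyr::expand_grid(gene_id = paste0("g", 1:100), tissue = c("flower", "root")) |>
    dplyr::mutate(rpkm = dplyr::case_when(
      gene_id %in% c("g1", "g2") & tissue == "flower" ~ 5,
      gene_id == "g1" & tissue == "root" ~ 0.99,     # below the gate
      TRUE ~ 0
    ))
  r <- expressed_gene_ratio(el, exons, expr)
  expect_equal(r$percent[r$tissue == "flower"], 2.0)
  expect_equal(r$percent[r$tissue == "root"], 0)
  expect_error(expressed_gene_ratio(el, exons, expr, tissues = "bark"), "bark")
  # no exon overlap at all -> 0 everywhere
  far <- dplyr::mutate(el, start = c(300L, 320L, 340L), end = c(310L, 330L, 350L))
  r0 <- expressed_gene_ratio(far, exons, expr)
  expect_true(all(r0$percent == 0))
})

test_that("gene association summary reproduces Table-2-style arithmetic", {
  el <- tibble::tibble(
    element_id = sprintf("e%d", 1:10),
    superfamily = rep(c("PIF/Harbinger", "Mutator"), c(6, 4)),
    region = rep(c("GS", "IS"), 5),
    expressed_with_gene = c(rep(TRUE, 3), rep(FALSE, 7)),
    srna_related = c(rep(TRUE, 4), rep(FALSE, 6))
  )
  s <- gene_association_summary(el)
  pif <- s[s$superfamily == "PIF/Harbinger", ]
  expect_equal(pif$total_elements, 6L)
  expect_equal(pif$associated_with_genes, 3L)
  expect_equal(pif$srna_related_percent, 100 * 4 / 6)
  tot <- s[s$superfamily == "Total", ]
  expect_equal(tot$total_elements, 10L)
  expect_equal(tot$srna_related_percent, 40)
  # absent flag columns yield NA, all-zero flags yield zero percent
  s2 <- gene_association_summary(dplyr::select(el, element_id, superfamily))
  expect_true(all(is.na(s2$srna_related_percent)))
  s3 <- gene_association_summary(dplyr::mutate(el, srna_related = FALSE))
  expect_true(all(s3$srna_related_percent == 0))
})
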