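# TIR/TSD detection, superfamily rules, 80-80-80 clustering, naming,
# full-length calls and the superfamily summary.

test_that("detect_tir finds planted termini and respects the length guard", {
  set.seed(41)
  tir <- "CAGTG"
  seq <- paste0(tir, "TTTTCCCCAAAAGGGGTTTT", oracle_revcomp(tir))
  expect_equal(detect_tir(seq, min_tir = 5, max_mismatch = 0), 5L)
  # homopolymer termini are self-mismatching under reverse complement
  expect_true(is.na(detect_tir(strrep("A", 40), min_tir = 10)))
  # too short for any TIR
  expect_true(is.na(detect_tir("ACGTACGT", min_tir = 5)))
})

test_that("detect_tir agrees with the brute-force scan on random sequences", {
  set.seed(42)
  for (i in 1:40) {
    n <- sample(30:200, 1)
    s <- random_dna_str(n)
    if (i %% 3 == 0) {
      # plant a TIR to exercise the hit path
      L <- sample(10:14, 1)
      s <- paste0(substr(s, 1, n - L), oracle_revcomp(substr(s, 1, L)))
    }
    mm <- sample(0:3, 1)
    expect_equal(
      detect_tir(s, min_tir = 8, max_mismatch = mm),
      oracle_tir(s, min_tir = 8, max_mismatch = mm),
      info = sprintf("seq %d", i)
    )
  }
})

test_that("detect_tsd returns the largest matching duplication", {
  sc <- paste0(strrep("G", 20), "TA", strrep("C", 40), "TA", strrep("G", 20))
  d <- detect_tsd(sc, 22, 62)
  expect_equal(d$k, 2L)
  expect_equal(d$tsd, "TA")

  dup <- "ACGTACGT"
  sc8 <- paste0(strrep("G", 20), dup, strrep("C", 40), dup, strrep("G", 20))
  d8 <- detect_tsd(sc8, 28, 68)
  expect_equal(d8$k, 8L)
  expect_equal(d8$tsd, dup)

  set.seed(7)
  scr <- random_dna_str(100)
  # element at the very scaffold start: no flank at all
  edge <- detect_tsd(scr, 0, 50)
  expect_true(is.na(edge$k))
  expect_true(edge$edge)
})

test_that("detect_tsd agrees with direct flank comparison on random fixtures", {
  set.seed(43)
  for (i in 1:60) {
    sc <- random_dna_str(120)
    if (i %% 2 == 0) {
      k <- sample(c(2, 3, 8, 9), 1)
      tsd <- random_dna_str(k)
      sc <- paste0(substr(sc, 1, 30), tsd, substr(sc, 31, 70), tsd, substr(sc, 71, 120))
      start <- 30 + k; end <- 70 + k
    } else {
      start <- 30; end <- 70
    }
    got <- detect_tsd(sc, start, end)
    want <- oracle_tsd(sc, start, end)
    expect_equal(got$k, want$k, info = sprintf("fixture %d", i))
    expect_equal(got$tsd, want$tsd, info = sprintf("fixture %d", i))
  }
})

test_that("superfamily assignment follows the TSD signatures", {
  expect_equal(assign_superfamily(2L, "TA"), "Tc1/Mariner")
  expect_equal(assign_superfamily(3L, "TAA"), "PIF/Harbinger")
  expect_equal(assign_superfamily(3L, "TTA"), "PIF/Harbinger")
  expect_equal(assign_superfamily(3L, "TCA"), "Unknown")
  expect_equal(assign_superfamily(8L, "GGCCTTAA"), "hAT")
  expect_equal(assign_superfamily(9L, "GGCCTTAAC"), "Mutator")
  expect_equal(assign_superfamily(NA_integer_, NA_character_), "Unknown")
  expect_equal(assign_superfamily(2L, "AT"), "Unknown")
})

test_that("clustering groups mutated copies and splits unrelated or short-coverage sequences", {
  set.seed(44)
  master <- random_dna_str(200)
  el <- tibble::tibble(
    element_id = sprintf("e%d", 1:8),
    seq = c(
      planted_family(master, 5, 0.05),
      random_dna_str(200),
      random_dna_str(200),
      substr(master, 50, 139)       # exact 90-bp sub-fragment: coverage 45%
    )
  )
  cl <- cluster_families(el)
  fam_of <- cl$family_id
  expect_equal(length(unique(fam_of[1:5])), 1L)          # one family for the copies
  expect_false(fam_of[6] == fam_of[7])                   # unrelated random seqs split
  expect_false(fam_of[8] %in% fam_of[1:5])               # coverage rule splits the fragment
})

test_that("clustering is deterministic, idempotent, and exact on planted families", {
  set.seed(45)
  masters <- replicate(4, random_dna_str(sample(150:250, 1)))
  el <- tibble::tibble(
    element_id = sprintf("e%d", 1:40),
    seq = unlist(lapply(masters, planted_family, n = 10, p = 0.05))
  )
  cl1 <- cluster_families(el)
  cl2 <- cluster_families(el[sample(nrow(el)), ]) |> dplyr::arrange(element_id)
  expect_equal(dplyr::n_distinct(cl1$family_id), 4L)
  expect_equal(
    dplyr::arrange(cl1, element_id)$family_id |> as.factor() |> as.integer(),
    cl2$family_id |> as.factor() |> as.integer()
  )
  # idempotence: clustering the representatives reproduces the family count
  reps <- unique(cl1$representative)
  rl <- cluster_families(tibble::tibble(element_id = seq_along(reps), seq = reps))
  expect_equal(dplyr::n_distinct(rl$family_id), length(reps))
})

test_that("short sequences are set aside as unclassified", {
  el <- tibble::tibble(element_id = c("a", "b"), seq = c(random_dna_str(200), random_dna_str(60)))
  cl <- cluster_families(el)
  expect_true(is.na(cl$family_id[cl$element_id == "b"]))
})

test_that("family names follow the MnX# grammar, ordered by size", {
  set.seed(46)
  m1 <- random_dna_str(200); m2 <- random_dna_str(210); m3 <- random_dna_str(190)
  el <- tibble::tibble(
    element_id = sprintf("e%d", 1:12),
    seq = c(planted_family(m1, 6, 0.03), planted_family(m2, 4, 0.03), planted_family(m3, 2, 0.03)),
    superfamily = rep(c("Tc1/Mariner", "Tc1/Mariner", "PIF/Harbinger"), c(6, 4, 2))
  )
  named <- el |> cluster_families() |> name_families()
  byfam <- named |> dplyr::count(family, family_superfamily)
  expect_setequal(byfam$family, c("MnT1", "MnT2", "MnP1"))
  expect_equal(byfam$n[byfam$family == "MnT1"], 6L)  # largest Tc1/Mariner family is serial 1
  # an all-Unknown family gets the N code
  el2 <- tibble::tibble(
    element_id = c("x1", "x2"), seq = planted_family(random_dna_str(150), 2, 0.02),
    superfamily = "Unknown"
  )
  named2 <- el2 |> cluster_families() |> name_families()
  expect_true(all(startsWith(named2$family, "MnN")))
})

test_that("full-length calls implement the 3-bp terminus rule", {
  set.seed(47)
  rep_seq <- random_dna_str(150)
  expect_true(is_full_length(rep_seq, rep_seq))
  expect_true(is_full_length(substr(rep_seq, 4, 150), rep_seq))    # 3 bp short at 5'
  expect_false(is_full_length(substr(rep_seq, 5, 150), rep_seq))   # 4 bp short
  expect_false(is_full_length(substr(rep_seq, 1, 146), rep_seq))   # 4 bp short at 3'
  expect_true(is_full_length(substr(rep_seq, 3, 148), rep_seq))    # 2 + 2
})

test_that("superfamily summary reproduces count arithmetic and merges overlaps", {
  el <- tibble::tibble(
    scaffold = "sc", start = c(0L, 25L, 100L, 200L), end = c(50L, 75L, 150L, 260L),
    superfamily = c("hAT", "hAT", "hAT", "Mutator"),
    full_length = c(TRUE, FALSE, FALSE, TRUE),
    family = c("Mnh1", "Mnh1", "Mnh1", "MnM1")
  )
  s <- summarize_superfamilies(el, genome_length = 1000)
  hat <- s[s$superfamily == "hAT", ]
  expect_equal(hat$full_to_partial_percent, 100 * 1 / 2)
  # [0,50)+[25,75) merge to 75 bases, plus [100,150): 125 of 1000
  expect_equal(hat$genome_percent, 12.5)
  tot <- s[s$superfamily == "Total", ]
  expect_equal(tot$total_elements, 4L)
  expect_equal(tot$full_length_count + tot$partial_count, tot$total_elements)
  # all-full superfamily: ratio is NA, not a division error
  mut <- s[s$superfamily == "Mutator", ]
  expect_true(is.na(mut$full_to_partial_percent))
  expect_error(summarize_superfamilies(el, 0), "genome_length")
})

test_that("summary counts are conserved across superfamilies", {
  set.seed(48)
  el <- tibble::tibble(
    scaffold = "sc", start = seq(0L, 990L, 10L), end = seq(5L, 995L, 10L),
    superfamily = sample(c("Tc1/Mariner", "hAT", "Unknown"), 100, replace = TRUE),
    full_length = sample(c(TRUE, FALSE), 100, replace = TRUE),
    family = "f"
  )
  s <- summarize_superfamilies(el, 1e5)
  per_sf <- s[s$superfamily != "Total", ]
  expect_equal(sum(per_sf$total_elements), 100L)
  expect_equal(sum(per_sf$full_length_count), sum(el$full_length))
})
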