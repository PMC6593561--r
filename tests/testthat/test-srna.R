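# Small-RNA matching against MITE sequences and the positional statistics.

test_that("the published worked example maps to the 30-50% region", {
  set.seed(81)
  mite <- random_dna_str(100)
  read <- substr(mite, 31, 50)   # 0-based positions 30..49, 20 nt
  m <- match_small_rnas(
    tibble::tibble(name = "r1", seq = read),
    tibble::tibble(element_id = "m1", seq = mite)
  )
  sense <- m[m$orientation == "sense", ]
  expect_equal(sense$match_start, 30L)
  expect_equal(sense$match_end, 50L)
  expect_equal(sense$relative_start, 30)
  expect_equal(sense$relative_end, 50)
  prof <- relative_position_profile(sense)
  expect_equal(prof$bin[prof$count > 0], 30:49)
})

test_that("matching agrees with the naive substring oracle, both orientations", {
  set.seed(82)
  elements <- tibble::tibble(
    element_id = sprintf("m%d", 1:6),
    seq = replicate(6, random_dna_str(sample(120:300, 1)))
  )
  reads <- tibble::tibble(
    name = sprintf("r%d", 1:25),
    seq = c(
      # planted sense, antisense, multi-copy and absent reads
      substr(elements$seq[1], 11, 34),
      oracle_revcomp(substr(elements$seq[2], 51, 74)),
      substr(elements$seq[3], 1, 21),
      replicate(22, random_dna_str(sample(18:26, 1)))
    )
  )
  got <- match_small_rnas(reads, elements)
  want <- oracle_srna_matches(reads, elements)
  key <- function(d) sort(paste(d$srna_id, d$element_id, d$match_start, d$match_end, d$orientation))
  expect_equal(key(got), key(want))
  expect_true(all(got$match_end - got$match_start == got$srna_length))
  expect_true(all(got$relative_start >= 0 & got$relative_end <= 100))
})

test_that("reads outside the window or with ambiguous bases are excluded", {
  el <- tibble::tibble(element_id = "m1", seq = random_dna_str(100))
  reads <- tibble::tibble(
    name = c("short", "bad"),
    seq = c(substr(el$seq, 1, 10), paste0(substr(el$seq, 1, 20), "NNNN"))
  )
  expect_warning(m <- match_small_rnas(reads, el), "non-ACGT")
  expect_equal(nrow(m), 0L)
})

test_that("length distribution deduplicates reads, not match records", {
  set.seed(83)
  mite <- random_dna_str(200)
  reads <- tibble::tibble(
    name = sprintf("r%d", 1:100),
    seq = c(
      vapply(1:95, function(i) substr(mite, i, i + 23), character(1)),  # 24-nt
      vapply(1:5, function(i) substr(mite, 50 + i, 70 + i), character(1))  # 21-nt
    )
  )
  # duplicate the element: multi-mapping must not change the distribution
  elements <- tibble::tibble(element_id = c("m1", "m2"), seq = c(mite, mite))
  m <- match_small_rnas(reads, elements)
  ld <- length_distribution(m)
  expect_equal(ld$proportion[ld$srna_length == 24], 0.95)
  expect_equal(ld$proportion[ld$srna_length == 21], 0.05)
  expect_equal(sum(ld$proportion), 1)
  one <- length_distribution(m[m$srna_id == "r1", ])
  expect_equal(one$proportion, 1)
})

test_that("profile increments every overlapped bin and totals are consistent", {
  m <- tibble::tibble(relative_start = c(0, 98.2, 49.5), relative_end = c(1.0, 100, 50.5))
  prof <- relative_position_profile(m)
  expect_equal(prof$count[prof$bin == 0], 1L)
  expect_equal(prof$count[prof$bin %in% 98:99], c(1L, 1L))
  expect_equal(prof$count[prof$bin %in% 49:50], c(1L, 1L))
  expect_equal(sum(prof$count), 5L)
  empty <- relative_position_profile(m[0, ])
  expect_true(all(empty$count == 0))
})

test_that("uniformly placed reads give a flat profile", {
  set.seed(84)
  mite <- random_dna_str(1000)
  starts <- sample(0:(1000 - 24), 10000, replace = TRUE)
  m <- tibble::tibble(
    relative_start = 100 * starts / 1000,
    relative_end = 100 * (starts + 24) / 1000
  )
  prof <- relative_position_profile(m)
  inner <- prof$count[prof$bin %in% 3:96]  # end bins are reached by fewer reads
  expect_lt(max(inner) / min(inner), 1.5)
})

test_that("family profiles apply the filters and label positional bias", {
  set.seed(85)
  # 600-bp elements so the 20%-wide source regions admit well over 100
  # distinct reads; MnH1 members have wildly different lengths
  el <- tibble::tibble(
    element_id = sprintf("m%d", 1:6),
    family = rep(c("MnT1", "MnP1", "MnH1"), each = 2),
    seq = c(replicate(2, random_dna_str(600)), replicate(2, random_dna_str(600)),
            random_dna_str(150), random_dna_str(400)),
    full_length = TRUE
  )
  central <- simulate_small_rnas(el[el$family == "MnT1", ], regions = list(c(40, 60)),
                                 n_reads = 300, seed = 1)
  terminal <- simulate_small_rnas(el[el$family == "MnP1", ], regions = list(c(0, 20), c(80, 100)),
                                  n_reads = 300, seed = 2)
  few <- simulate_small_rnas(el[el$family == "MnH1", ], regions = list(c(0, 100)),
                             n_reads = 30, seed = 3)
  reads <- dplyr::bind_rows(central$reads, terminal$reads, few$reads) |>
    dplyr::mutate(name = sprintf("r%d", dplyr::row_number()))
  m <- match_small_rnas(reads, el)
  fp <- family_position_profiles(m, el, min_srnas = 100, max_length_cv = 0.05)
  expect_setequal(fp$family, c("MnT1", "MnP1"))   # MnH1 fails the length-cv filter
  expect_equal(fp$bias[fp$family == "MnT1"], "central")
  expect_equal(fp$bias[fp$family == "MnP1"], "terminal")
})

test_that("families at or below the read-count threshold are filtered out", {
  set.seed(86)
  el <- tibble::tibble(element_id = "m1", family = "MnT9", seq = random_dna_str(300), full_length = TRUE)
  m <- tibble::tibble(
    srna_id = sprintf("r%d", 1:99), srna_seq = sprintf("S%d", 1:99), srna_length = 24L,
    element_id = "m1", match_start = 0L, match_end = 24L, orientation = "sense",
    element_length = 300L, relative_start = 0, relative_end = 8
  )
  fp <- family_position_profiles(m, el, min_srnas = 99)
  expect_equal(nrow(fp), 0L)   # 99 is not "more than" 99
  fp2 <- family_position_profiles(m, el, min_srnas = 98)
  expect_equal(nrow(fp2), 1L)
})

test_that("GS/IS read attribution prefers GS on ties", {
  el <- tibble::tibble(
    element_id = c("a", "b", "c"),
    region = c("GS", "IS", "IS")
  )
  m <- tibble::tibble(
    srna_seq = c("r1", "r1", "r2", "r3"),
    element_id = c("a", "b", "c", "b")
  )
  o <- srna_origin_by_partition(m, el)
  expect_equal(o$n[o$region == "GS"], 1L)   # r1 matched GS and IS -> GS
  expect_equal(o$n[o$region == "IS"], 2L)
  expect_equal(sum(o$fraction), 1)
  # half/half disjoint fixture
  m2 <- tibble::tibble(srna_seq = c("x", "y"), element_id = c("a", "b"))
  o2 <- srna_origin_by_partition(m2, el)
  expect_equal(o2$fraction, c(0.5, 0.5))
})
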