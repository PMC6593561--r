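# Synthetic genomes with planted ground truth. The generator emulates the
# study conditions the pipeline targets: MITE families amplified in one or
# more neutral bursts from a master element, insertions flanked by
# superfamily-specific TSDs and carrying TIRs, genes with 2000-bp context
# zones, small RNAs sampled from defined relative regions of elements, and
# isoform sets exhibiting the four AS modes through intronic MITE
# exonization. Everything is deterministic given the config and seed.

#' Simulation configuration
#'
#' Collects and validates the generator parameters. Defaults encode the
#' study conditions: substitution rate 1.3e-8 per site per year, 2000-bp
#' gene flanks, read lengths concentrated at 24 nt (23-25 nt window),
#' transition/transversion ratio 2.
#'
#' @param seed Integer seed (mandatory).
#' @param scaffold_lengths Named numeric vector of scaffold lengths.
#' @param families List of per-family specs; each a list with `superfamily`,
#'   `master_length`, `tir_length`, `n_copies`, `burst_times` (years),
#'   optional `burst_weights`, `rate`, `truncation_prob`, `indel_rate`,
#'   `indel_mean`, `ts_tv_ratio`.
#' @param n_genes Number of genes to place.
#' @param exons_per_gene Range (min, max) of exons per gene.
#' @param exon_length,intron_length Ranges (min, max) in bases.
#' @param flank Gene context width in bases.
#' @param p_near_gene,p_intronic Placement probabilities for MITE copies
#'   (remainder is intergenic).
#' @return A validated list of class `sim_config`.
#' @export
simulation_config <- function(seed,
                              scaffold_lengths = c(scaffold1 = 100000L, scaffold2 = 80000L),
                              families = default_family_specs(),
                              n_genes = 12L,
                              exons_per_gene = c(2L, 4L),
                              exon_length = c(150L, 300L),
                              intron_length = c(800L, 1500L),
                              flank = 2000L,
                              p_near_gene = 0.5,
                              p_intronic = 0.1) {
  if (missing(seed)) abort("seed is mandatory")
  cfg <- list(
    seed = as.integer(seed), scaffold_lengths = scaffold_lengths,
    families = families, n_genes = as.integer(n_genes),
    exons_per_gene = exons_per_gene, exon_length = exon_length,
    intron_length = intron_length, flank = as.integer(flank),
    p_near_gene = p_near_gene, p_intronic = p_intronic
  )
  for (f in families) {
    stopifnot(
      f$superfamily %in% SUPERFAMILIES,
      f$master_length >= 80, f$n_copies >= 1,
      all(f$burst_times > 0)
    )
  }
  stopifnot(p_near_gene >= 0, p_intronic >= 0, p_near_gene + p_intronic <= 1)
  class(cfg) <- "sim_config"
  cfg
}

#' @rdname simulation_config
#' @export
default_family_specs <- function() {
  list(
    list(superfamily = "Tc1/Mariner", master_length = 250L, tir_length = 14L,
         n_copies = 18L, burst_times = 2e6, truncation_prob = 0.2),
    list(superfamily = "PIF/Harbinger", master_length = 300L, tir_length = 14L,
         n_copies = 18L, burst_times = 4e6),
    list(superfamily = "hAT", master_length = 350L, tir_length = 12L,
         n_copies = 14L, burst_times = 3e6, truncation_prob = 0.2),
    list(superfamily = "Mutator", master_length = 220L, tir_length = 12L,
         n_copies = 12L, burst_times = 2.5e6)
  )
}

#' Simulate one MITE family amplification
#'
#' Copies are partitioned across bursts (by `burst_weights`, equal by
#' default); a copy from the burst at time t receives independent per-site
#' substitutions with probability p = rate * t (two-parameter scheme: a
#' substitution is a transition with probability kappa / (kappa + 2)),
#' optional geometric indels, and optional 5'/3' truncation producing
#' partial copies.
#'
#' @param master Master element sequence (>= 80 bases).
#' @param n_copies Number of copies.
#' @param burst_times Burst ages in years.
#' @param rate Substitution rate per site per year.
#' @param burst_weights Relative burst sizes (default equal).
#' @param indel_rate Per-site indel probability (default 0).
#' @param indel_mean Mean indel length (geometric).
#' @param truncation_prob Probability a copy is truncated (made partial).
#' @param ts_tv_ratio kappa: transition rate relative to each transversion.
#' @param seed Optional seed (set when called standalone).
#' @return A tibble: `copy_id`, `seq`, `burst_time`, `p_sub`, `full_length`.
#'   Errors when any p = rate * t reaches 0.75 (beyond saturation).
#' @export
simulate_family <- function(master, n_copies, burst_times,
                            rate = DEFAULT_SUBSTITUTION_RATE,
                            burst_weights = NULL, indel_rate = 0,
                            indel_mean = 3, truncation_prob = 0,
                            ts_tv_ratio = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (nchar(master) < 80) abort("master must be at least 80 bases")
  p <- rate * burst_times
  if (any(p >= 0.75)) abort("substitution probability >= 0.75: beyond saturation")
  burst_weights <- burst_weights %||% rep(1, length(burst_times))
  stopifnot(length(burst_weights) == length(burst_times))
  sizes <- floor(n_copies * burst_weights / sum(burst_weights))
  rem <- n_copies - sum(sizes)
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  burst_of <- rep(seq_along(burst_times), sizes)

  mb <- seq_chars(master)
  copies <- map_chr(burst_of, function(b) {
    s <- mutate_sequence(mb, p[b], ts_tv_ratio)
    if (indel_rate > 0) s <- apply_indels(s, indel_rate, indel_mean)
    paste(s, collapse = "")
  })
  truncated <- runif(n_copies) < truncation_prob
  copies <- map_chr(seq_along(copies), function(i) {
    if (!truncated[i]) return(copies[i])
    truncate_copy(copies[i])
  })
  tibble(
    copy_id = sprintf("copy%d", seq_len(n_copies)),
    seq = copies,
    burst_time = burst_times[burst_of],
    p_sub = p[burst_of],
    full_length = !truncated
  )
}

mutate_sequence <- function(chars, p, kappa) {
  n <- length(chars)
  hit <- which(runif(n) < p)
  if (length(hit) == 0) return(chars)
  transitions <- c(A = "G", G = "A", C = "T", T = "C")
  for (i in hit) {
    base <- chars[i]
    if (!base %in% DNA_BASES) next
    if (runif(1) < kappa / (kappa + 2)) {
      chars[i] <- transitions[[base]]
    } else {
      chars[i] <- sample(setdiff(DNA_BASES, c(base, transitions[[base]])), 1)
    }
  }
  chars
}

apply_indels <- function(chars, indel_rate, indel_mean) {
  n_events <- rbinom(1, length(chars), indel_rate)
  if (n_events == 0) return(chars)
  for (k in seq_len(n_events)) {
    len <- 1L + stats::rgeom(1, 1 / indel_mean)
    pos <- sample(length(chars), 1)
    if (runif(1) < 0.5) {
      chars <- append(chars, sample(DNA_BASES, len, replace = TRUE), after = pos)
    } else {
      drop <- pos:min(length(chars), pos + len - 1L)
      if (length(drop) >= length(chars)) next
      chars <- chars[-drop]
    }
  }
  chars
}

# partial copies lose 4 bases to 10% of one terminus: enough to fail the
# up-to-3-bp full-length rule while keeping 80-80-80 coverage intact
truncate_copy <- function(seq) {
  n <- nchar(seq)
  cut <- sample(seq(4L, max(5L, floor(0.10 * n))), 1)
  if (runif(1) < 0.5) substr(seq, cut + 1L, n) else substr(seq, 1L, n - cut)
}

# master with a planted TIR: first tir_len bases mirrored (reverse
# complemented) at the 3' terminus
make_master <- function(length, tir_len) {
  body <- random_dna(length - tir_len)
  tir5 <- substr(body, 1, tir_len)
  paste0(body, revcomp(tir5))
}

sample_tsd <- function(superfamily) {
  switch(superfamily,
    "Tc1/Mariner" = "TA",
    "PIF/Harbinger" = sample(c("TAA", "TTA"), 1),
    "hAT" = random_dna(8L),
    "Mutator" = random_dna(9L),
    "Unknown" = ""
  )
}

#' Simulate a genome with planted MITE insertions
#'
#' Generates i.i.d. uniform background scaffolds, places non-overlapping
#' multi-exon genes, amplifies each configured family from a TIR-bearing
#' master, and writes each copy into the genome flanked by its
#' superfamily-specific TSD. Insertion sites are drawn near genes, inside
#' introns, or in intergenic space per the configured probabilities. The
#' generator guarantees that a planted TSD is the maximal flank duplication
#' (accidental longer duplications at the boundaries are broken) so
#' structure detection on the truth set is exact by construction.
#'
#' @param config A [simulation_config()].
#' @return A list of class `mite_sim`: `genome` (tibble name/seq), `exons`
#'   (single-isoform exon tibble), `mites` (annotation tibble), `truth`
#'   (per-element tibble incl. planted family, TSD, TIR length, burst time)
#'   and `config`. Errors when the requested insertions do not fit.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  sl <- scaffold_length_vector(config$scaffold_lengths)
  genome <- map(sl, function(n) seq_chars(random_dna(n)))

  exons <- place_genes(sl, config)

  # per-scaffold matrix of element-occupied intervals (plus a safety margin)
  occupied <- setNames(map(names(sl), ~ matrix(numeric(0), ncol = 2)), names(sl))
  truth <- list()
  for (fi in seq_along(config$families)) {
    spec <- config$families[[fi]]
    fam_name <- spec$name %||% sprintf("fam%d", fi)
    master <- make_master(spec$master_length, spec$tir_length)
    copies <- simulate_family(
      master, spec$n_copies, spec$burst_times,
      rate = spec$rate %||% DEFAULT_SUBSTITUTION_RATE,
      burst_weights = spec$burst_weights,
      indel_rate = spec$indel_rate %||% 0,
      indel_mean = spec$indel_mean %||% 3,
      truncation_prob = spec$truncation_prob %||% 0,
      ts_tv_ratio = spec$ts_tv_ratio %||% 2
    )
    for (ci in seq_len(nrow(copies))) {
      tsd <- sample_tsd(spec$superfamily)
      placed <- place_element(
        genome, sl, occupied, exons, nchar(copies$seq[ci]), nchar(tsd), config
      )
      if (is.null(placed)) abort("requested insertions exceed available space")
      sc <- placed$scaffold
      pos <- placed$pos
      elen <- nchar(copies$seq[ci])
      k <- nchar(tsd)
      # overwrite: [pos-k, pos) TSD, [pos, pos+elen) element, [pos+elen, pos+elen+k) TSD
      if (k > 0) {
        genome[[sc]][(pos - k + 1L):pos] <- seq_chars(tsd)
        genome[[sc]][(pos + elen + 1L):(pos + elen + k)] <- seq_chars(tsd)
      }
      genome[[sc]][(pos + 1L):(pos + elen)] <- seq_chars(copies$seq[ci])
      genome[[sc]] <- enforce_maximal_tsd(genome[[sc]], pos, pos + elen, k)
      occupied[[sc]] <- rbind(occupied[[sc]], c(pos - k - 10L, pos + elen + k + 10L))
      truth[[length(truth) + 1L]] <- tibble(
        element_id = sprintf("%s_%s", fam_name, copies$copy_id[ci]),
        family = fam_name, superfamily = spec$superfamily,
        scaffold = sc, start = pos, end = pos + elen, strand = "*",
        full_length = copies$full_length[ci],
        burst_time = copies$burst_time[ci],
        tsd = if (k > 0) tsd else NA_character_,
        tsd_len = if (k > 0) k else NA_integer_,
        tir_length = spec$tir_length,
        placement = placed$zone
      )
    }
  }
  truth <- if (length(truth) > 0) list_rbind(truth) else tibble(
    element_id = character(0), family = character(0), superfamily = character(0),
    scaffold = character(0), start = integer(0), end = integer(0),
    strand = character(0), full_length = logical(0), burst_time = numeric(0),
    tsd = character(0), tsd_len = integer(0), tir_length = integer(0),
    placement = character(0)
  )
  genome_tbl <- tibble(name = names(genome), seq = unname(map_chr(genome, paste, collapse = "")))
  mites <- truth %>%
    select("element_id", "scaffold", "start", "end", "strand", "family", "full_length")
  out <- list(
    genome = genome_tbl, exons = exons, mites = mites, truth = truth,
    config = config
  )
  class(out) <- "mite_sim"
  out
}

place_genes <- function(sl, config) {
  rows <- list()
  gi <- 0L
  cursor <- setNames(rep(3000, length(sl)), names(sl))
  scs <- rep(names(sl), length.out = config$n_genes)
  for (sc in scs) {
    gi <- gi + 1L
    n_ex <- sample(config$exons_per_gene[1]:config$exons_per_gene[2], 1)
    ex_len <- sample(config$exon_length[1]:config$exon_length[2], n_ex, replace = TRUE)
    in_len <- if (n_ex > 1) sample(config$intron_length[1]:config$intron_length[2], n_ex - 1, replace = TRUE) else integer(0)
    gstart <- cursor[[sc]] + sample(500:1500, 1)
    pos <- gstart
    starts <- ends <- integer(n_ex)
    for (e in seq_len(n_ex)) {
      starts[e] <- pos
      ends[e] <- pos + ex_len[e]
      pos <- ends[e] + if (e < n_ex) in_len[e] else 0L
    }
    if (pos + config$flank + 500 > sl[[sc]]) {
      abort("scaffolds too short for the requested gene set")
    }
    cursor[[sc]] <- pos + sample(4500:7000, 1)
    gene_id <- sprintf("gene%d", gi)
    rows[[gi]] <- tibble(
      gene_id = gene_id,
      transcript_id = paste0(gene_id, ".t1"),
      scaffold = sc, start = starts, end = ends, strand = "+",
      exon_rank = seq_len(n_ex)
    )
  }
  list_rbind(rows)
}

# sample an insertion point in the requested zone; returns NULL when no
# collision-free spot is found
place_element <- function(genome, sl, occupied, exons, elen, k, config) {
  zones <- c("near_gene", "intron", "intergenic")
  pz <- c(config$p_near_gene, config$p_intronic,
          1 - config$p_near_gene - config$p_intronic)
  gene_bodies <- gene_extents(exons)
  for (attempt in seq_len(300L)) {
    zone <- sample(zones, 1, prob = pz)
    cand <- switch(zone,
      near_gene = {
        if (nrow(gene_bodies) == 0 || config$flank - elen - 60L <= 60L) next
        g <- gene_bodies[sample(nrow(gene_bodies), 1), ]
        side <- sample(c("up", "down"), 1)
        pos <- if (side == "up") {
          g$start - sample(seq(60L, config$flank - elen - 60L), 1) - elen
        } else {
          g$end + sample(seq(60L, config$flank - elen - 60L), 1)
        }
        list(scaffold = g$scaffold, pos = pos)
      },
      intron = {
        gx <- exons[sample(nrow(exons), 1), ]
        nxt <- exons[exons$transcript_id == gx$transcript_id &
                       exons$exon_rank == gx$exon_rank + 1L, ]
        if (nrow(nxt) == 0) next
        lo <- gx$end + 30L
        hi <- nxt$start - 30L - elen
        if (hi <= lo) next
        list(scaffold = gx$scaffold, pos = sample(lo:hi, 1))
      },
      intergenic = {
        sc <- sample(names(sl), 1)
        list(scaffold = sc, pos = sample(seq(100L, sl[[sc]] - elen - 100L), 1))
      }
    )
    pos <- cand$pos
    sc <- cand$scaffold
    if (pos - k < 20 || pos + elen + k > sl[[sc]] - 20) next
    lo <- pos - k
    hi <- pos + elen + k
    # never overlap a previously placed element (with margin) or an exon;
    # intron bodies are fair game only for the intron zone, but the exon
    # check below is what actually protects gene structure
    occ <- occupied[[sc]]
    if (nrow(occ) > 0 && any(occ[, 1] < hi & lo < occ[, 2])) next
    gx <- exons[exons$scaffold == sc, ]
    if (nrow(gx) > 0 && any(gx$start < hi & lo < gx$end)) next
    return(list(scaffold = sc, pos = as.integer(pos), zone = zone))
  }
  NULL
}

# break accidental flank duplications longer than the planted TSD so the
# planted (k, seq) is exactly what detect_tsd recovers
enforce_maximal_tsd <- function(chars, start, end, planted_k,
                                k_candidates = c(2L, 3L, 8L, 9L)) {
  n <- length(chars)
  bigger <- sort(k_candidates[k_candidates != planted_k | planted_k == 0])
  for (rep_try in 1:20) {
    seqstr <- paste(chars, collapse = "")
    found <- detect_tsd(seqstr, start, end, k_candidates)
    ok <- if (planted_k > 0) identical(found$k, planted_k) else is.na(found$k)
    if (ok) return(chars)
    # mutate the outermost upstream base of the offending duplication
    k_bad <- found$k
    pos_up <- start - k_bad + 1L
    if (pos_up >= 1 && (planted_k == 0 || k_bad > planted_k)) {
      chars[pos_up] <- sample(setdiff(DNA_BASES, chars[pos_up]), 1)
    } else {
      break
    }
  }
  chars
}

#' Simulate MITE-derived small RNAs
#'
#' Reads are sampled from configured relative regions of the elements
#' (percent of element length), with a configured read-length distribution
#' (default: mass concentrated at 24 nt within 23-25 nt).
#'
#' @param elements Tibble with `element_id` and `seq`.
#' @param regions List of numeric `c(lo, hi)` percent windows the reads are
#'   drawn from (a region is picked uniformly per read).
#' @param n_reads Number of reads.
#' @param length_probs Named numeric vector: read length -> probability.
#' @param antisense_prob Probability a read is reported as the reverse
#'   complement.
#' @param seed Optional seed.
#' @return A list: `reads` (tibble name/seq) and `truth` (source element,
#'   region and 0-based position per read).
#' @export
simulate_small_rnas <- function(elements,
                                regions = list(c(40, 60)),
                                n_reads = 500L,
                                length_probs = c(`23` = 0.05, `24` = 0.9, `25` = 0.05),
                                antisense_prob = 0,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (nrow(elements) == 0) abort("elements must be non-empty")
  for (r in regions) {
    if (r[1] < 0 || r[2] > 100 || r[1] >= r[2]) abort("region outside [0, 100]")
  }
  lens <- as.integer(names(length_probs))
  rows <- map(seq_len(n_reads), function(i) {
    for (try in 1:50) {
      e <- elements[sample(nrow(elements), 1), ]
      L <- nchar(e$seq)
      region <- regions[[sample(length(regions), 1)]]
      rl <- lens[sample.int(length(lens), 1, prob = length_probs)]
      lo <- ceiling(region[1] / 100 * L)
      hi <- floor(region[2] / 100 * L) - rl
      if (hi < lo) next
      s0 <- sample(lo:hi, 1)              # 0-based start
      read <- subseq0(e$seq, s0, s0 + rl)
      anti <- runif(1) < antisense_prob
      if (anti) read <- revcomp(read)
      return(tibble(
        name = sprintf("read%d", i), seq = read,
        element_id = e$element_id, start = s0, end = s0 + rl,
        region_lo = region[1], region_hi = region[2],
        antisense = anti
      ))
    }
    abort("source region too narrow for the configured read lengths")
  })
  truth <- list_rbind(rows)
  list(reads = select(truth, "name", "seq"), truth = truth)
}

#' Simulate alternative isoforms via intronic MITE exonization
#'
#' For each gene containing an intronic MITE, an extra isoform is emitted
#' with probability `exonization_prob`. The planted structure depends on the
#' drawn mode: a new exon inside the MITE (ES pattern), a retained intron
#' (IR), or an exon boundary shifted to a position inside the MITE
#' (A3SS/A5SS).
#'
#' @param exons Single-isoform exon tibble (e.g. from [simulate_genome()]).
#' @param mites MITE element tibble with coordinates.
#' @param exonization_prob Probability per eligible gene.
#' @param modes Named probabilities over `ES`, `IR`, `A3SS`, `A5SS`.
#' @param shift Fixed boundary shift in bases for A3SS/A5SS (`NULL` =
#'   random within the MITE).
#' @param seed Optional seed.
#' @return A list: `exons` (multi-isoform exon tibble) and `truth` (tibble
#'   of planted events: `gene_id`, `mode`, `event_start`, `event_end`,
#'   `element_id`).
#' @export
simulate_isoforms <- function(exons, mites, exonization_prob = 1,
                              modes = c(ES = 0.4, IR = 0.2, A3SS = 0.2, A5SS = 0.2),
                              shift = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- exons
  truth <- list()
  for (g in unique(exons$gene_id)) {
    gx <- exons[exons$gene_id == g, ]
    gx <- gx[order(gx$start), ]
    if (nrow(gx) < 2) next
    # introns and any MITE fully inside one
    intr <- tibble(
      i = seq_len(nrow(gx) - 1L),
      start = gx$end[-nrow(gx)], end = gx$start[-1]
    )
    m <- mites[mites$scaffold == gx$scaffold[1], ]
    hits <- list_rbind(map(seq_len(nrow(intr)), function(ii) {
      sel <- m$start >= intr$start[ii] + 5 & m$end <= intr$end[ii] - 5
      if (!any(sel)) return(NULL)
      tibble(intron = ii, element_id = m$element_id[sel],
             m_start = m$start[sel], m_end = m$end[sel])
    }))
    if (is.null(hits) || nrow(hits) == 0) next
    if (runif(1) >= exonization_prob) next
    h <- hits[sample(nrow(hits), 1), ]
    mode <- sample(names(modes), 1, prob = modes)
    ii <- h$intron
    t2 <- paste0(g, ".t2")
    new_iso <- gx %>% mutate(transcript_id = t2)
    planted <- NULL
    if (mode == "ES") {
      width <- max(20L, min(60L, h$m_end - h$m_start - 10L))
      es <- h$m_start + 5L
      new_exon <- tibble(
        gene_id = g, transcript_id = t2, scaffold = gx$scaffold[1],
        start = es, end = es + width, strand = gx$strand[1], exon_rank = NA_integer_
      )
      new_iso <- bind_rows(new_iso, new_exon) %>% arrange(.data$start)
      planted <- tibble(gene_id = g, mode = "ES", event_start = es,
                        event_end = es + width, element_id = h$element_id)
    } else if (mode == "IR") {
      merged <- new_iso
      merged$end[ii] <- merged$end[ii + 1L]
      merged <- merged[-(ii + 1L), ]
      new_iso <- merged
      planted <- tibble(gene_id = g, mode = "IR", event_start = intr$start[ii],
                        event_end = intr$end[ii], element_id = h$element_id)
    } else if (mode == "A3SS") {
      # downstream exon's acceptor shifted upstream, to inside the MITE
      s_old <- new_iso$start[ii + 1L]
      s_new <- if (!is.null(shift)) s_old - shift else sample((h$m_start + 2L):(h$m_end - 2L), 1)
      if (s_new >= s_old) next
      new_iso$start[ii + 1L] <- s_new
      planted <- tibble(gene_id = g, mode = "A3SS", event_start = s_new,
                        event_end = s_old, element_id = h$element_id)
    } else {
      # upstream exon's donor shifted downstream, to inside the MITE
      e_old <- new_iso$end[ii]
      e_new <- if (!is.null(shift)) e_old + shift else sample((h$m_start + 2L):(h$m_end - 2L), 1)
      if (e_new <= e_old) next
      new_iso$end[ii] <- e_new
      planted <- tibble(gene_id = g, mode = "A5SS", event_start = e_old,
                        event_end = e_new, element_id = h$element_id)
    }
    new_iso <- new_iso %>% mutate(exon_rank = row_number())
    out <- bind_rows(out, new_iso)
    truth[[length(truth) + 1L]] <- planted
  }
  truth <- if (length(truth) > 0) list_rbind(truth) else
    tibble(gene_id = character(0), mode = character(0),
           event_start = integer(0), event_end = integer(0),
           element_id = character(0))
  list(
    exons = arrange(out, .data$gene_id, .data$transcript_id, .data$start),
    truth = truth
  )
}

#' Write a simulated data set to disk
#'
#' Emits exactly the formats the pipeline consumes: genome FASTA, gene
#' GFF3, MITE annotation TSV, and a truth JSON.
#'
#' @param sim A `mite_sim` object.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "mite_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    genome = file.path(dir, "genome.fa"),
    genes = file.path(dir, "genes.gff3"),
    mites = file.path(dir, "mites.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_fasta(sim$genome, paths[["genome"]])
  write_gff3(sim$exons, paths[["genes"]])
  write_mite_annotations(sim$mites, paths[["mites"]])
  jsonlite::write_json(sim$truth, paths[["truth"]], digits = NA)
  invisible(paths)
}
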