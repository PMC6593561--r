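# Readers and writers for the external formats the pipeline consumes:
# FASTA/FASTQ (Biostrings), GFF3 (rtracklayer), BED-like MITE annotation TSV
# and the tissue expression matrix (readr). Internally all coordinates are
# 0-based half-open; GFF3 is converted from/to 1-based inclusive at this
# boundary, BED-like input passes through unchanged.

#' Read a DNA FASTA file
#'
#' @param path Path to a FASTA file of DNA sequences (A/C/G/T/N plus IUPAC
#'   codes; case is normalised to upper).
#' @return A tibble with columns `name` and `seq`, in file order.
#' @details Duplicated record identifiers and empty sequences are rejected
#'   with an error naming the offending record.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  ss <- Biostrings::readDNAStringSet(path, format = "fasta")
  nm <- sub("\\s.*$", "", names(ss))
  dup <- nm[duplicated(nm)]
  if (length(dup) > 0) {
    abort(sprintf("duplicated FASTA identifier: %s", dup[1]))
  }
  empty <- nm[Biostrings::width(ss) == 0]
  if (length(empty) > 0) {
    abort(sprintf("empty sequence for FASTA record: %s", empty[1]))
  }
  tibble(name = nm, seq = unname(toupper(as.character(ss))))
}

#' Write sequences to FASTA
#'
#' @param seqs A tibble with columns `name` and `seq`, or a named character
#'   vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  v <- if (is.data.frame(seqs)) setNames(seqs$seq, seqs$name) else seqs
  ss <- Biostrings::DNAStringSet(v)
  Biostrings::writeXStringSet(ss, path, format = "fasta", width = 70L)
  invisible(path)
}

#' Read small-RNA reads from FASTA or FASTQ
#'
#' Quality values in FASTQ input are ignored; only the read sequences are
#' used (matching is exact, not quality-aware).
#'
#' @param path Path to a FASTA or FASTQ file (format auto-detected from the
#'   first non-empty character).
#' @return A tibble with columns `name` and `seq`.
#' @export
read_small_rnas <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  first <- substr(trimws(readLines(path, n = 1L)), 1, 1)
  if (identical(first, "@")) {
    ss <- Biostrings::readDNAStringSet(path, format = "fastq")
    tibble(name = sub("\\s.*$", "", names(ss)), seq = unname(toupper(as.character(ss))))
  } else {
    read_fasta(path)
  }
}

#' Read gene models (with isoforms) from GFF3
#'
#' Expects `gene`, `mRNA`/`transcript` and `exon` features with `ID`/`Parent`
#' attributes (1-based inclusive coordinates, per the GFF3 standard). Exons
#' are grouped under their parent transcript and transcripts under their
#' parent gene; out-of-order exons are sorted, orphan exons are an error.
#'
#' @param path Path to a GFF3 file.
#' @return An exon-level tibble with columns `gene_id`, `transcript_id`,
#'   `scaffold`, `start`, `end` (0-based half-open), `strand`, `exon_rank`.
#' @export
read_gff3_genes <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  ids <- as.character(gr$ID)
  parents <- gr$Parent          # CharacterList
  first_parent <- map_chr(as.list(parents), function(p) {
    if (length(p) == 0) NA_character_ else p[[1]]
  })

  gene_ids <- ids[type == "gene"]
  tx_idx <- type %in% c("mRNA", "transcript")
  tx <- tibble(
    transcript_id = ids[tx_idx],
    gene_id = first_parent[tx_idx]
  )
  if (any(is.na(tx$gene_id))) {
    abort(sprintf("transcript without a gene parent: %s", tx$transcript_id[is.na(tx$gene_id)][1]))
  }
  ex_idx <- type == "exon"
  if (!any(ex_idx)) abort("no exon features found in GFF3")
  ex <- tibble(
    transcript_id = first_parent[ex_idx],
    scaffold = as.character(GenomicRanges::seqnames(gr))[ex_idx],
    start = GenomicRanges::start(gr)[ex_idx] - 1L,
    end = GenomicRanges::end(gr)[ex_idx],
    strand = as.character(GenomicRanges::strand(gr))[ex_idx]
  )
  if (any(is.na(ex$transcript_id))) {
    abort("exon without a Parent attribute")
  }
  orphan <- setdiff(unique(ex$transcript_id), tx$transcript_id)
  # tolerate exons attached directly to a gene feature (single-isoform shorthand)
  direct <- intersect(orphan, gene_ids)
  orphan <- setdiff(orphan, direct)
  if (length(orphan) > 0) {
    abort(sprintf("orphan exon: parent %s is not a declared mRNA or gene", orphan[1]))
  }
  if (length(direct) > 0) {
    tx <- bind_rows(tx, tibble(
      transcript_id = direct,
      gene_id = direct
    ))
  }
  check_intervals(ex, "exon")
  ex %>%
    left_join(tx, by = "transcript_id") %>%
    arrange(.data$gene_id, .data$transcript_id, .data$start) %>%
    group_by(.data$transcript_id) %>%
    mutate(exon_rank = row_number()) %>%
    ungroup() %>%
    select("gene_id", "transcript_id", "scaffold", "start", "end", "strand", "exon_rank")
}

#' Write gene models to GFF3
#'
#' @param exons Exon-level tibble as returned by [read_gff3_genes()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(exons, path) {
  stopifnot(all(c("gene_id", "transcript_id", "scaffold", "start", "end", "strand") %in% names(exons)))
  lines <- c("##gff-version 3")
  genes <- exons %>%
    group_by(.data$gene_id, .data$scaffold, .data$strand) %>%
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop")
  for (g in seq_len(nrow(genes))) {
    gid <- genes$gene_id[g]
    lines <- c(lines, sprintf(
      "%s\tmitescape\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
      genes$scaffold[g], genes$start[g] + 1L, genes$end[g], genes$strand[g], gid
    ))
    gx <- exons[exons$gene_id == gid, ]
    for (tid in unique(gx$transcript_id)) {
      txx <- gx[gx$transcript_id == tid, ]
      lines <- c(lines, sprintf(
        "%s\tmitescape\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
        txx$scaffold[1], min(txx$start) + 1L, max(txx$end), txx$strand[1], tid, gid
      ))
      lines <- c(lines, sprintf(
        "%s\tmitescape\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
        txx$scaffold, txx$start + 1L, txx$end, txx$strand, tid
      ))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read MITE copy annotations (BED-like TSV)
#'
#' The file is a tab-separated table with a header and at least the columns
#' `scaffold`, `start`, `end`, `strand`, `family`, `status` (BED convention:
#' 0-based half-open). `status` is `full` or `partial`; extra columns
#' (e.g. `element_id`, `superfamily`, `tsd`, `tir_length`) are preserved.
#'
#' @param path Path to the TSV.
#' @return A tibble of MITE elements with `full_length` as a logical column
#'   and a guaranteed unique `element_id`.
#' @export
read_mite_annotations <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("scaffold", "start", "end", "strand", "family", "status")
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0) {
    abort(sprintf("missing required column(s) in %s: %s", path, paste(missing, collapse = ", ")))
  }
  check_intervals(tbl, "MITE annotation")
  tbl <- tbl %>%
    mutate(full_length = .data$status == "full") %>%
    select(-"status")
  if (!"element_id" %in% names(tbl)) {
    tbl$element_id <- sprintf("%s:%d-%d", tbl$scaffold, tbl$start, tbl$end)
  }
  tbl$element_id <- make.unique(as.character(tbl$element_id), sep = "_dup")
  as_tibble(tbl)
}

#' Write MITE copy annotations (BED-like TSV)
#'
#' Round-trips all fields written by the classification pipeline.
#'
#' @param elements MITE element tibble (needs `scaffold`, `start`, `end`,
#'   `strand`, `family` and either `status` or logical `full_length`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mite_annotations <- function(elements, path) {
  tbl <- as_tibble(elements)
  if (!"status" %in% names(tbl)) {
    stopifnot("full_length" %in% names(tbl))
    tbl$status <- if_else(tbl$full_length, "full", "partial")
    tbl$full_length <- NULL
  }
  lead <- c("scaffold", "start", "end", "strand", "family", "status")
  tbl <- tbl[, c(lead, setdiff(names(tbl), lead))]
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(path)
}

#' Read a per-gene, per-tissue expression table
#'
#' A TSV with a `gene_id` column and one RPKM column per tissue.
#'
#' @param path Path to the TSV.
#' @return A long tibble with columns `gene_id`, `tissue`, `rpkm`.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"gene_id" %in% names(tbl)) abort("expression table must have a gene_id column")
  long <- tbl %>%
    tidyr::pivot_longer(-"gene_id", names_to = "tissue", values_to = "rpkm")
  if (any(long$rpkm < 0, na.rm = TRUE)) {
    bad <- long[which(long$rpkm < 0)[1], ]
    abort(sprintf("negative RPKM for gene %s in tissue %s", bad$gene_id, bad$tissue))
  }
  long
}

#' Write a per-gene, per-tissue expression table
#'
#' @param expression Long tibble (`gene_id`, `tissue`, `rpkm`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expression, path) {
  wide <- tidyr::pivot_wider(expression, names_from = "tissue", values_from = "rpkm")
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}

#' Extract element sequences from a genome
#'
#' Adds a `seq` column (plus-strand scaffold sequence of each interval) to a
#' MITE element tibble. Sequences are always stored as the plus strand;
#' orientation-sensitive operations handle the reverse complement themselves.
#'
#' @param elements MITE element tibble (`scaffold`, `start`, `end`).
#' @param genome Genome as returned by [read_fasta()] (or a named vector).
#' @return `elements` with a `seq` column added.
#' @export
add_element_sequences <- function(elements, genome) {
  gv <- genome_vector(genome)
  missing <- setdiff(unique(elements$scaffold), names(gv))
  if (length(missing) > 0) {
    abort(sprintf("scaffold not in genome: %s", missing[1]))
  }
  too_long <- elements$end > nchar(gv)[elements$scaffold]
  if (any(too_long)) {
    i <- which(too_long)[1]
    abort(sprintf(
      "element %s:%d-%d extends past the end of the scaffold",
      elements$scaffold[i], elements$start[i], elements$end[i]
    ))
  }
  elements %>%
    mutate(seq = subseq0(gv[.data$scaffold], .data$start, .data$end))
}
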