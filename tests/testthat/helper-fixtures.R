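# Shared fixture builders.

withr_local_tempfile <- function(ext) {
  tf <- tempfile(fileext = ext)
  withr::defer(unlink(tf), envir = parent.frame())
  tf
}

# a toy single-isoform exon tibble: one gene per row of `spec`, where spec
# gives scaffold, exon starts and ends as list columns
toy_exons <- function(gene_id, scaffold, starts, ends, strand = "+",
                      transcript = paste0(gene_id, ".t1")) {
  tibble::tibble(
    gene_id = gene_id, transcript_id = transcript, scaffold = scaffold,
    start = as.integer(starts), end = as.integer(ends), strand = strand,
    exon_rank = seq_along(starts)
  )
}

# plant a family of mutated copies of one master (no indels)
planted_family <- function(master, n, p, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n), function(i) mutate_seq(master, p), character(1))
}
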