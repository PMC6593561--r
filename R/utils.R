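# Internal helpers shared across modules. All genomic coordinates inside the
# package are 0-based half-open; conversion to/from 1-based formats happens
# only in the I/O layer.

DNA_BASES <- c("A", "C", "G", "T")

TISSUES <- c("root", "bark", "bud", "flower", "leaf")

SUPERFAMILIES <- c("Tc1/Mariner", "PIF/Harbinger", "hAT", "Mutator", "Unknown")

# one-letter family-name codes per superfamily
SUPERFAMILY_CODE <- c(
  "Tc1/Mariner" = "T", "hAT" = "h", "PIF/Harbinger" = "P",
  "Mutator" = "M", "Unknown" = "N"
)

# canonical TSD signatures reported per superfamily
TSD_SIGNATURE <- c(
  "Tc1/Mariner" = "TA", "PIF/Harbinger" = "TWA", "hAT" = "8 bp",
  "Mutator" = "9 bp", "Unknown" = "-"
)

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

seq_chars <- function(x) strsplit(toupper(x), "", fixed = TRUE)[[1]]

# genome can be a tibble (name, seq) or a named character vector
genome_vector <- function(genome) {
  if (is.data.frame(genome)) {
    stopifnot(all(c("name", "seq") %in% names(genome)))
    return(setNames(toupper(genome$seq), genome$name))
  }
  if (is.character(genome) && !is.null(names(genome))) {
    return(toupper(genome))
  }
  abort("`genome` must be a tibble with columns name/seq or a named character vector.")
}

scaffold_length_vector <- function(scaffold_lengths) {
  if (is.data.frame(scaffold_lengths)) {
    stopifnot(all(c("scaffold", "length") %in% names(scaffold_lengths)))
    return(setNames(scaffold_lengths$length, scaffold_lengths$scaffold))
  }
  if (is.numeric(scaffold_lengths) && !is.null(names(scaffold_lengths))) {
    return(scaffold_lengths)
  }
  abort("`scaffold_lengths` must be a named numeric vector or a tibble with scaffold/length.")
}

# extract [start, end) (0-based half-open) from a scaffold string
subseq0 <- function(scaffold_seq, start, end) {
  substr(scaffold_seq, start + 1L, end)
}

check_intervals <- function(tbl, what = "interval") {
  bad <- which(tbl$start < 0 | tbl$end <= tbl$start)
  if (length(bad) > 0) {
    i <- bad[1]
    abort(sprintf(
      "invalid %s on line %d: start %d, end %d (1-based positions %d-%d); need 0 <= start < end",
      what, i, tbl$start[i], tbl$end[i], tbl$start[i] + 1L, tbl$end[i]
    ))
  }
  invisible(tbl)
}

# merged (reduced) interval tibble per scaffold; input 0-based half-open
reduce_intervals <- function(tbl) {
  if (nrow(tbl) == 0) return(tbl[, c("scaffold", "start", "end")])
  tbl %>%
    group_by(.data$scaffold) %>%
    group_split() %>%
    map(function(g) {
      ir <- IRanges::reduce(IRanges::IRanges(start = g$start + 1L, end = g$end))
      tibble(
        scaffold = g$scaffold[1],
        start = IRanges::start(ir) - 1L,
        end = IRanges::end(ir)
      )
    }) %>%
    list_rbind()
}

total_interval_width <- function(tbl) {
  if (nrow(tbl) == 0) return(0)
  sum(tbl$end - tbl$start)
}

`%||%` <- rlang::`%||%`
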