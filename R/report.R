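# Pipeline driver: a config object with the study defaults, subcommands
# that tie the stages together on files, and a JSON/text report assembler.
# The Rscript dispatcher in inst/cli/mite.R is a thin wrapper over
# run_subcommand().

#' Pipeline configuration
#'
#' Paths plus the analysis defaults: 2000-bp flank, substitution rate
#' 1.3e-8 per site per year, RPKM gate 1, 18-30-nt read window.
#'
#' @param ... Named overrides of the defaults (unknown keys are an error).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    genome = NULL, mites = NULL, genes = NULL, reads = NULL,
    expression = NULL, out_dir = ".",
    flank = 2000L, rate = DEFAULT_SUBSTITUTION_RATE, rpkm_min = 1,
    srna_min_len = 18L, srna_max_len = 30L,
    min_pairs = 30L, prominence = 0.1,
    seed = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) abort(sprintf("unknown config key: %s", unknown[1]))
  cfg[names(dots)] <- dots
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration file
#'
#' JSON, or a flat `key = value` document mirroring the flag names.
#'
#' @param path Path to the config file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  if (grepl("\\.json$", path)) {
    vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    lines <- readLines(path)
    lines <- lines[!grepl("^\\s*(#|$)", lines)]
    kv <- stringr::str_match(lines, "^\\s*([a-zA-Z_]+)\\s*=\\s*(.*?)\\s*$")
    vals <- as.list(kv[, 3])
    names(vals) <- kv[, 2]
    vals <- map(vals, function(v) {
      num <- suppressWarnings(as.numeric(v))
      if (!is.na(num)) num else v
    })
  }
  do.call(pipeline_config, vals)
}

need_input <- function(path, what) {
  if (is.null(path)) abort(sprintf("missing input: %s", what))
  if (!file.exists(path)) abort(sprintf("input path does not exist: %s", path))
  path
}

stage_log <- function(stage, msg) {
  inform(sprintf("[%s] %s", stage, msg))
}

#' Run a pipeline subcommand
#'
#' Subcommands: `simulate`, `classify`, `diversity`, `date`, `context`,
#' `srna`, `splice`, `report`. Each reads its declared inputs from `config`,
#' writes its declared outputs under `config$out_dir`, and returns the
#' written paths invisibly. `report` aggregates whatever stage outputs are
#' present into `report.json` plus a human-readable summary.
#'
#' @param name Subcommand name.
#' @param config A [pipeline_config()].
#' @return Named character vector of written paths, invisibly.
#' @export
run_subcommand <- function(name, config) {
  stopifnot(inherits(config, "pipeline_config"))
  name <- match.arg(name, c(
    "simulate", "classify", "diversity", "date", "context", "srna",
    "splice", "report"
  ))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  paths <- switch(name,
    simulate = {
      sim <- simulate_genome(simulation_config(seed = config$seed))
      stage_log("simulate", sprintf(
        "%d scaffolds, %d genes, %d elements",
        nrow(sim$genome), n_distinct(sim$exons$gene_id), nrow(sim$mites)
      ))
      write_simulation(sim, out_dir)
    },
    classify = {
      genome <- read_fasta(need_input(config$genome, "genome FASTA"))
      mites <- read_mite_annotations(need_input(config$mites, "MITE annotation TSV"))
      cl <- classify_mites(mites, genome)
      stage_log("classify", sprintf(
        "%d elements, %d families", nrow(cl), n_distinct(cl$family[!is.na(cl$family)])
      ))
      fam_path <- file.path(out_dir, "classified.tsv")
      write_mite_annotations(
        cl %>% select(-"representative", -"is_representative", -"family_id"),
        fam_path
      )
      smry <- summarize_superfamilies(cl, sum(nchar(genome$seq)))
      smry_path <- file.path(out_dir, "superfamily_summary.tsv")
      readr::write_tsv(smry, smry_path, progress = FALSE)
      c(classified = fam_path, summary = smry_path)
    },
    diversity = {
      cl <- read_classified(need_input(config$mites, "classified MITE TSV"),
                            config$genome)
      dv <- diversity_by_family(cl, rate = config$rate, min_pairs = config$min_pairs)
      stage_log("diversity", sprintf("%d families analysed", nrow(dv)))
      div_path <- file.path(out_dir, "diversity.json")
      jsonlite::write_json(
        dv %>% select(-"result"), div_path,
        digits = NA, auto_unbox = FALSE
      )
      pair_path <- file.path(out_dir, "pairwise_diversity.tsv")
      pairs_tbl <- dv %>%
        mutate(k_values = map(.data$result, "k_values")) %>%
        select("family", "k_values") %>%
        tidyr::unnest("k_values")
      readr::write_tsv(pairs_tbl, pair_path, progress = FALSE)
      c(diversity = div_path, pairs = pair_path)
    },
    date = {
      div_path <- need_input(file.path(out_dir, "diversity.json"), "diversity.json")
      dv <- jsonlite::read_json(div_path, simplifyVector = TRUE)
      dv$time_mya <- estimate_amplification_time(dv$k_mean, config$rate)
      stage_log("date", sprintf("%d families dated at rate %g", nrow(dv), config$rate))
      date_path <- file.path(out_dir, "dating.tsv")
      readr::write_tsv(
        as_tibble(dv[, c("family", "k_mean", "modality", "time_mya")]),
        date_path, progress = FALSE
      )
      c(dating = date_path)
    },
    context = {
      cl <- read_classified(need_input(config$mites, "classified MITE TSV"),
                            config$genome)
      genome <- read_fasta(need_input(config$genome, "genome FASTA"))
      exons <- read_gff3_genes(need_input(config$genes, "gene GFF3"))
      sl <- setNames(nchar(genome$seq), genome$name)
      part <- partition_genome(exons, sl, flank = config$flank)
      counts <- count_mites_by_partition(cl, part)
      stage_log("context", sprintf("%d families counted in GS/IS", nrow(counts)))
      part_path <- file.path(out_dir, "partition.bed")
      readr::write_tsv(part, part_path, col_names = FALSE, progress = FALSE)
      counts_path <- file.path(out_dir, "gs_is_counts.tsv")
      readr::write_tsv(counts, counts_path, progress = FALSE)
      written <- c(partition = part_path, counts = counts_path)
      if (nrow(counts) >= 3 && sd(counts$gs) > 0) {
        fit <- gs_is_regression(counts)
        reg_path <- file.path(out_dir, "gs_is_regression.json")
        jsonlite::write_json(
          list(
            slope = fit$slope, intercept = fit$intercept,
            r_squared = fit$r_squared, p_value = fit$p_value,
            outlier_families = fit$outlier_families
          ),
          reg_path, digits = NA, auto_unbox = TRUE
        )
        written <- c(written, regression = reg_path)
      }
      written
    },
    srna = {
      cl <- read_classified(need_input(config$mites, "classified MITE TSV"),
                            config$genome)
      reads <- read_small_rnas(need_input(config$reads, "small-RNA reads"))
      matches <- match_small_rnas(reads, cl, config$srna_min_len, config$srna_max_len)
      stage_log("srna", sprintf(
        "%d reads, %d match records, %d elements matched",
        nrow(reads), nrow(matches), n_distinct(matches$element_id)
      ))
      m_path <- file.path(out_dir, "srna_matches.tsv")
      readr::write_tsv(matches, m_path, progress = FALSE)
      ld_path <- file.path(out_dir, "srna_lengths.tsv")
      readr::write_tsv(length_distribution(matches), ld_path, progress = FALSE)
      full <- matches %>%
        semi_join(filter(cl, .data$full_length), by = "element_id")
      prof_path <- file.path(out_dir, "srna_profile.tsv")
      readr::write_tsv(relative_position_profile(full), prof_path, progress = FALSE)
      c(matches = m_path, lengths = ld_path, profile = prof_path)
    },
    splice = {
      exons <- read_gff3_genes(need_input(config$genes, "isoform GFF3"))
      mites <- read_mite_annotations(need_input(config$mites, "MITE annotation TSV"))
      events <- detect_as_events(exons)
      assoc <- associate_events_with_mites(events, mites, exons)
      stage_log("splice", sprintf(
        "%d events in %d genes, %d MITE-associated",
        nrow(assoc), n_distinct(assoc$gene_id), sum(assoc$associated)
      ))
      ev_path <- file.path(out_dir, "as_events.tsv")
      readr::write_tsv(
        assoc %>% mutate(sites = map_chr(.data$sites, paste, collapse = ",")),
        ev_path, progress = FALSE
      )
      c(events = ev_path)
    },
    report = {
      rep <- assemble_report(out_dir)
      rep_path <- file.path(out_dir, "report.json")
      jsonlite::write_json(rep, rep_path, digits = NA, auto_unbox = TRUE, null = "null")
      txt_path <- file.path(out_dir, "report.txt")
      writeLines(render_report(rep), txt_path)
      c(report = rep_path, text = txt_path)
    }
  )
  stage_log(name, sprintf("done in %.2fs", as.numeric(Sys.time() - t0, units = "secs")))
  invisible(paths)
}

# classified.tsv round trip; re-extracts sequences when a genome is given
read_classified <- function(path, genome_path = NULL) {
  cl <- read_mite_annotations(path)
  if (!"seq" %in% names(cl) && !is.null(genome_path) && file.exists(genome_path)) {
    cl <- add_element_sequences(cl, read_fasta(genome_path))
  }
  cl
}

assemble_report <- function(dir) {
  grab_tsv <- function(f) {
    p <- file.path(dir, f)
    if (file.exists(p)) readr::read_tsv(p, show_col_types = FALSE, progress = FALSE) else NULL
  }
  grab_json <- function(f) {
    p <- file.path(dir, f)
    if (file.exists(p)) jsonlite::read_json(p, simplifyVector = TRUE) else NULL
  }
  list(
    superfamily_summary = grab_tsv("superfamily_summary.tsv"),
    dating = grab_tsv("dating.tsv"),
    gs_is_regression = grab_json("gs_is_regression.json"),
    srna_lengths = grab_tsv("srna_lengths.tsv"),
    as_events = grab_tsv("as_events.tsv")
  )
}

render_report <- function(rep) {
  fmt_pct <- function(x) sprintf("%.2f", x)
  out <- c("MITE pipeline report", strrep("=", 40))
  if (!is.null(rep$superfamily_summary)) {
    s <- rep$superfamily_summary
    out <- c(out, "", "Superfamily summary:")
    out <- c(out, sprintf(
      "  %-14s %6s elements, %5s full, full/partial %% = %s",
      s$superfamily, s$total_elements, s$full_length_count,
      ifelse(is.na(s$full_to_partial_percent), "-", fmt_pct(s$full_to_partial_percent))
    ))
  }
  if (!is.null(rep$dating) && nrow(rep$dating) > 0) {
    out <- c(out, "", "Amplification dating:")
    out <- c(out, sprintf(
      "  %-10s K = %.4f (%s) -> %.1f Mya",
      rep$dating$family, rep$dating$k_mean, rep$dating$modality, rep$dating$time_mya
    ))
  }
  if (!is.null(rep$gs_is_regression)) {
    r <- rep$gs_is_regression
    out <- c(out, "", sprintf(
      "GS/IS regression: slope %.3f, r^2 = %.2f, p = %.3g",
      r$slope, r$r_squared, r$p_value
    ))
  }
  if (length(out) == 2) out <- c(out, "", "(no stage outputs found)")
  out
}
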