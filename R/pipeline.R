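## End-to-end orchestration: simulate -> process -> variants -> classify ->
## stats, plus bundled demo loci so the whole pipeline can run out of the box.

#' Default FLAG-element insert
#'
#' A standard DNA encoding of the DYKDDDDK (FLAG) epitope followed by a TAA
#' stop codon. The experimentally used FLAG DNA sequence is configurable per
#' locus; this constant is the shipped default.
#' @export
FLAG_TAA_INSERT <- "GACTACAAGGACGACGATGACAAGTAA"

## Synthetic stand-in amplicons. The gene-specific primer sequences, the
## analysis windows and the per-locus assembly overlaps are the published
## assay constants; the interior sequence between the primers is a fixed
## synthetic stand-in (the genomic amplicons are not part of this package),
## with an NGG protospacer placed so both 90-nt and 36-nt homology arms fit.
DEMO_AMPLICONS <- list(
  slc45a2 = paste0(
    "CAGATGTCCAGAGGCTGCTGCTATGTTAAAGCGTGTCTTGGGGTAACGGATAGTCCGATC",
    "GTTGCCGGTGTGCAGTAAGAGACGGATTTCCTGTGCCGTTCAGGCTAGCTGAATGAGCGC",
    "AGTGCACTTACCCGGGTCGTTGAGTCTCAATGCGAGTTCCAATACCCAATCTCAGCAGCA",
    "AAACACAGGCAAGGTCCGGCGATGGGACACGCACTTCGTGTTGAGCCGTTTCTAGATTCC",
    "TGTTTTGCCGCACACTAAATCCAGATACTGTACATTCTGAGGCTGTGGCA"),
  dnd = paste0(
    "GGGGAAAGGCTAGGGAGAGAGGGAGATGTCCAACATTTTGCCGTCGCTCGCGGGAATGAC",
    "CTTAGACGTACGCCCGCATATACTTCGTGCGGAGATACGACCATTTAAGAAGGAGAACGT",
    "ATGCTAGTCCAATCATAAGGATCTCATAAGGCGTGTGAACAGGGCTGGTACAGTCGGCGT",
    "AGCTGAATGTTTTTTTAACCTGTACTATAGATGATACAGGGTTGGATGGGATCGAAAACT",
    "AATTGGGGGGTGGGGGGCATAGTAGTCGTAAACTTCAGCGGACAGAACCG"))

#' Bundled demo locus
#'
#' Returns a [target_locus()] for one of the two demonstration targets.
#' Primer sequences, analysis windows (20-200 for `slc45a2`, 60-230 for
#' `dnd`) and assembly overlaps (150/200 bp) are the assay constants; the
#' amplicon interior is a synthetic stand-in.
#'
#' @param gene `"slc45a2"` or `"dnd"`.
#' @return A `target_locus`.
#' @export
demo_locus <- function(gene = c("slc45a2", "dnd")) {
  gene <- match.arg(gene)
  if (gene == "slc45a2") {
    amp <- DEMO_AMPLICONS$slc45a2
    target_locus("slc45a2", amp,
                 fwd_primer = "CAGATGTCCAGAGGCTGCTGCT",
                 rev_primer = "TGCCACAGCCTCAGAATGTACA",
                 window = c(20L, 200L),
                 guide = guide_rna(substr(amp, 114, 133), substr(amp, 134, 136),
                                   "+", 114L))
  } else {
    amp <- DEMO_AMPLICONS$dnd
    target_locus("dnd", amp,
                 fwd_primer = "GGGGAAAGGCTAGGGAGAGA",
                 rev_primer = "CGGTTCTGTCCGCTGAAGTT",
                 window = c(60L, 230L),
                 guide = guide_rna(substr(amp, 129, 148), substr(amp, 149, 151),
                                   "+", 129L))
  }
}

#' Bundled demo locus/edit preset
#'
#' Combines a [demo_locus()] with an edit (FLAG + TAA knock-in at the cut
#' site, or a three-base single nucleotide replacement for `dnd`), the
#' 90 + 36 asymmetric sense-strand donor and the per-locus assembly overlap.
#'
#' @param gene `"slc45a2"` or `"dnd"`.
#' @param edit `"flag_ki"` or `"snr"` (`snr` only for `dnd`).
#' @param anchor_k Junction/context k-mer length.
#' @return List `locus`, `edit`, `donor`, `expected`, `min_overlap`.
#' @export
demo_preset <- function(gene = c("slc45a2", "dnd"), edit = c("flag_ki", "snr"),
                        anchor_k = 10L) {
  gene <- match.arg(gene)
  edit <- match.arg(edit)
  locus <- demo_locus(gene)
  es <- if (edit == "flag_ki") {
    edit_spec("insertion", insert = FLAG_TAA_INSERT)
  } else {
    if (gene != "dnd") stop("the SNR preset targets dnd", call. = FALSE)
    ## three replaced bases in the PAM-proximal protospacer end, disrupting
    ## re-cutting and creating the premature stop context
    edit_spec("substitution",
              substitutions = data.frame(pos = c(146L, 147L, 148L),
                                         base = c("G", "A", "G")))
  }
  list(locus = locus, edit = es,
       donor = design_asymmetric_odn(locus, es),
       expected = build_expected_alleles(locus, es, anchor_k = anchor_k),
       min_overlap = if (gene == "slc45a2") 150L else 200L)
}

#' Process, call and classify one sample against one locus preset
#'
#' @param pairs Read-pair data frame for this sample (already demultiplexed).
#' @param preset List with `locus`, `expected`, `min_overlap` (see
#'   [demo_preset()] / [locus_from_config()]).
#' @param sample_id,group Identifiers for the summary row.
#' @param params Named list of stage parameters overriding the defaults
#'   (`min_len`, `max_mismatch_frac`, `q_thresh`, `max_n`, `max_n_diff`,
#'   `min_reads`).
#' @return List `summary` (one-row data frame or `NULL` if flagged),
#'   `calls`, `ledger`, `denominator`, `flagged`.
#' @export
process_sample <- function(pairs, preset, sample_id = "sample",
                           group = NA_character_, params = list()) {
  p <- utils::modifyList(list(min_len = 100L, max_mismatch_frac = 0.20,
                              q_thresh = 20L, max_n = 5L, max_n_diff = 5L,
                              min_reads = 100L), params)
  proc <- process_reads(pairs, preset$locus, min_len = p$min_len,
                        min_overlap = preset$min_overlap,
                        max_mismatch_frac = p$max_mismatch_frac,
                        q_thresh = p$q_thresh, max_n = p$max_n)
  vc <- call_variants(proc$reads, max_n_diff = p$max_n_diff,
                      min_reads = p$min_reads)
  calls <- classify_variants(vc$variants, preset$expected)
  summary <- if (vc$flagged) NULL else {
    summarize_sample(calls, vc$denominator, sample_id = sample_id, group = group)
  }
  list(summary = summary, calls = calls, ledger = proc$ledger,
       denominator = vc$denominator, flagged = vc$flagged)
}

#' Run the full pipeline over a configured cohort
#'
#' Reads a run configuration (a YAML file path or an equivalent named list):
#' `loci` is a list of locus configs (see [locus_from_config()]), `samples`
#' a sample sheet (TSV path or data frame with columns `sample_id`,
#' `fastq_r1`, `fastq_r2`, `gene`, `group`), `params` optional stage
#' parameters, `output_dir` an optional directory for result TSVs and
#' `alpha` the significance level. Each sample's reads are demultiplexed
#' across all configured loci and the pairs assigned to the sample's gene
#' are processed, called, classified and summarised; per-gene group
#' statistics (Kruskal-Wallis + Dunn for three or more groups, Mann-Whitney
#' for two, paired Wilcoxon for 5' vs 3' junction percentages) are computed
#' over the per-individual summaries.
#'
#' @param config Path to a YAML run configuration or a named list.
#' @return A `run_report` list: `summaries`, `aggregates`, `stats`,
#'   `ledgers`, `flagged_samples`, `params`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    base_dir <- dirname(config)
    config <- yaml::read_yaml(config)
  } else {
    base_dir <- config$base_dir %||% "."
  }
  presets <- lapply(config$loci, locus_from_config, base_dir = base_dir)
  names(presets) <- vapply(presets, function(p) p$locus$name, character(1))
  loci <- lapply(presets, `[[`, "locus")
  sheet <- config$samples
  if (is.character(sheet)) {
    path <- if (file.exists(sheet)) sheet else file.path(base_dir, sheet)
    sheet <- read.delim(path, stringsAsFactors = FALSE)
  }
  sheet <- as.data.frame(sheet, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "fastq_r1", "fastq_r2", "gene", "group") %in% names(sheet)))
  params <- config$params %||% list()
  summaries <- list()
  ledgers <- list()
  flagged <- character(0)
  for (i in seq_len(nrow(sheet))) {
    row <- sheet[i, ]
    if (is.na(match(row$gene, names(presets)))) {
      stop("sample ", row$sample_id, " references unconfigured gene ", row$gene,
           call. = FALSE)
    }
    r1 <- if (file.exists(row$fastq_r1)) row$fastq_r1 else file.path(base_dir, row$fastq_r1)
    r2 <- if (file.exists(row$fastq_r2)) row$fastq_r2 else file.path(base_dir, row$fastq_r2)
    pairs <- read_fastq_pair(r1, r2)
    dmx <- demultiplex_pairs(pairs, loci)
    res <- process_sample(dmx$assigned[[row$gene]], presets[[row$gene]],
                          sample_id = row$sample_id,
                          group = paste(row$gene, row$group), params = params)
    res$ledger <- rbind(
      data.frame(stage = "demultiplexed", kept = nrow(dmx$assigned[[row$gene]]),
                 dropped = nrow(pairs) - nrow(dmx$assigned[[row$gene]]),
                 stringsAsFactors = FALSE),
      res$ledger)
    ledgers[[row$sample_id]] <- res$ledger
    if (res$flagged) {
      flagged <- c(flagged, row$sample_id)
    } else {
      summaries[[length(summaries) + 1L]] <- res$summary
    }
  }
  summaries <- do.call(rbind, summaries)
  aggregates <- if (!is.null(summaries)) aggregate_groups(summaries) else NULL
  stats <- if (!is.null(summaries)) cohort_stats(summaries, sheet,
                                                 alpha = config$alpha %||% 0.05)
           else NULL
  report <- list(summaries = summaries, aggregates = aggregates, stats = stats,
                 ledgers = ledgers, flagged_samples = flagged, params = params)
  class(report) <- "run_report"
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

## Per-gene nonparametric comparisons over the per-individual summaries.
cohort_stats <- function(summaries, sheet, alpha = 0.05) {
  out <- list()
  genes <- unique(sheet$gene)
  for (gene in genes) {
    rows <- summaries[startsWith(summaries$group, paste0(gene, " ")), , drop = FALSE]
    if (nrow(rows) == 0L) next
    groups <- split(rows$pct_perfect, rows$group)
    entry <- list(gene = gene, n_groups = length(groups))
    if (length(groups) >= 3L) {
      entry$kruskal <- kruskal_wallis(groups)
      entry$dunn <- dunn_posthoc(groups, alpha = alpha)
    } else if (length(groups) == 2L) {
      entry$mann_whitney <- mann_whitney(groups[[1]], groups[[2]])
    }
    entry$wilcoxon_5p_vs_3p <- wilcoxon_paired(rows$pct_perfect_5p,
                                               rows$pct_perfect_3p)
    out[[gene]] <- entry
  }
  out
}

write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name) {
    write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (!is.null(report$summaries)) tsv(report$summaries, "sample_summaries.tsv")
  if (!is.null(report$aggregates)) tsv(report$aggregates, "group_aggregates.tsv")
  ledger <- do.call(rbind, lapply(names(report$ledgers), function(s) {
    cbind(sample_id = s, report$ledgers[[s]], stringsAsFactors = FALSE)
  }))
  if (!is.null(ledger)) tsv(ledger, "read_ledger.tsv")
  invisible(dir)
}

#' Simulate a designed cohort and recover it through the pipeline
#'
#' Convenience wrapper for recovery studies: takes a per-individual
#' allele-fraction table (e.g. from [design_cohort_fractions()]), simulates
#' every individual's reads and runs the complete processing, variant-calling
#' and classification chain, returning the per-individual summaries next to
#' the simulation truth.
#'
#' @param preset Locus/edit preset (see [demo_preset()]).
#' @param fractions Data frame/matrix of per-individual allele fractions
#'   (columns `wild_type`, `perfect_hdr`, `erroneous_hdr_5p`,
#'   `erroneous_hdr_3p`, `nhej`).
#' @param group Group label.
#' @param n_read_pairs Simulated read pairs per individual.
#' @param seed Integer seed.
#' @param params Stage parameter overrides (see [process_sample()]).
#' @return List `summaries` (per-individual summary data frame) and `truth`
#'   (true fractions).
#' @export
simulate_and_recover <- function(preset, fractions, group = "group",
                                 n_read_pairs = 6000L, seed = 1L,
                                 params = list()) {
  cfg <- read_sim_config(n_read_pairs, seed = seed)
  sim <- simulate_cohort(list(list(label = group, fractions = fractions)),
                         preset$locus, preset$edit, cfg)
  summaries <- do.call(rbind, lapply(sim$samples, function(s) {
    process_sample(s$pairs, preset, s$sample_id, group, params)$summary
  }))
  list(summaries = summaries, truth = sim$truth_fracs)
}

#' Generate a small bundled demonstration cohort on disk
#'
#' Writes paired FASTQ files, a sample sheet and a YAML run configuration
#' for two loci (a FLAG knock-in and a three-base replacement) with a few
#' mosaic individuals per donor-concentration group, sized to run in
#' seconds. Returns the configuration path, ready for [run_pipeline()].
#'
#' @param dir Output directory.
#' @param seed Integer seed.
#' @param n_read_pairs Read pairs per individual.
#' @return Path to the written `config.yaml`.
#' @export
make_demo_fixtures <- function(dir, seed = 1L, n_read_pairs = 600L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  presets <- list(slc45a2 = demo_preset("slc45a2", "flag_ki"),
                  dnd = demo_preset("dnd", "snr"))
  cohorts <- list(
    slc45a2 = list(
      list(label = "0.5uM", n = 2L,
           mean_fracs = c(wild_type = 0.45, perfect_hdr = 0.20,
                          erroneous_hdr_5p = 0.0, erroneous_hdr_3p = 0.0,
                          nhej = 0.35), concentration = 60),
      list(label = "1.5uM", n = 2L,
           mean_fracs = c(wild_type = 0.30, perfect_hdr = 0.35,
                          erroneous_hdr_5p = 0.0, erroneous_hdr_3p = 0.0,
                          nhej = 0.35), concentration = 60)),
    dnd = list(
      list(label = "1.5uM", n = 2L,
           mean_fracs = c(wild_type = 0.30, perfect_hdr = 0.35,
                          erroneous_hdr_5p = 0.0, erroneous_hdr_3p = 0.0,
                          nhej = 0.35), concentration = 60)))
  sheet <- list()
  for (gene in names(cohorts)) {
    cfg <- read_sim_config(n_read_pairs, seed = seed + match(gene, names(cohorts)))
    sim <- simulate_cohort(cohorts[[gene]], presets[[gene]]$locus,
                           presets[[gene]]$edit, cfg)
    for (s in sim$samples) {
      sid <- paste(gene, s$sample_id, sep = "_")
      r1 <- file.path(dir, paste0(sid, "_R1.fastq"))
      r2 <- file.path(dir, paste0(sid, "_R2.fastq"))
      write_fastq_pair(s$pairs, r1, r2)
      sheet[[length(sheet) + 1L]] <- data.frame(
        sample_id = sid, fastq_r1 = basename(r1), fastq_r2 = basename(r2),
        gene = gene, group = s$group, stringsAsFactors = FALSE)
    }
  }
  sheet <- do.call(rbind, sheet)
  write.table(sheet, file.path(dir, "sample_sheet.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  loci_cfg <- list(
    list(name = "slc45a2", amplicon = DEMO_AMPLICONS$slc45a2,
         fwd_primer = "CAGATGTCCAGAGGCTGCTGCT", rev_primer = "TGCCACAGCCTCAGAATGTACA",
         guide = list(protospacer = substr(DEMO_AMPLICONS$slc45a2, 114, 133),
                      pam = substr(DEMO_AMPLICONS$slc45a2, 134, 136),
                      strand = "+", start = 114L),
         window = list(start = 20L, end = 200L),
         edit = list(insert = FLAG_TAA_INSERT),
         donor = list(arm_long = 90L, arm_short = 36L, polarity = "sense"),
         min_overlap = 150L),
    list(name = "dnd", amplicon = DEMO_AMPLICONS$dnd,
         fwd_primer = "GGGGAAAGGCTAGGGAGAGA", rev_primer = "CGGTTCTGTCCGCTGAAGTT",
         guide = list(protospacer = substr(DEMO_AMPLICONS$dnd, 129, 148),
                      pam = substr(DEMO_AMPLICONS$dnd, 149, 151),
                      strand = "+", start = 129L),
         window = list(start = 60L, end = 230L),
         edit = list(substitutions = list(list(pos = 146L, base = "G"),
                                          list(pos = 147L, base = "A"),
                                          list(pos = 148L, base = "G"))),
         donor = list(arm_long = 90L, arm_short = 36L, polarity = "sense"),
         min_overlap = 200L))
  config <- list(loci = loci_cfg, samples = "sample_sheet.tsv",
                 params = list(min_reads = 100L), alpha = 0.05)
  path <- file.path(dir, "config.yaml")
  yaml::write_yaml(config, path)
  path
}
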