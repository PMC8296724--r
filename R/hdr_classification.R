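## HDR outcome classification. Each retained variant gets exactly one label
## by a fixed cascade: perfect HDR (N-compatibly equal to the edited window),
## wild type (N-compatibly equal to the reference window), erroneous HDR
## (carries the intact core insert/replacement but differs elsewhere), or
## other (typically NHEJ indels without donor sequence). For HDR variants
## the 5' and 3' junctions are additionally scored: a side is "perfect" when
## the variant reproduces the edited reference contiguously and in register
## on that side of the core. N matches any base throughout (masked bases
## encode low quality, not mismatch).

LABEL_LEVELS <- c("perfect_hdr", "wild_type", "erroneous_hdr", "other")

#' Classify variants against the expected alleles
#'
#' @param variants Variant data frame (or a character vector of sequences).
#' @param expected An [build_expected_alleles()] object.
#' @return The variant data frame with columns `label`, `perfect_5p`,
#'   `perfect_3p` added (side flags are `FALSE` for wild-type/other variants,
#'   where they are undefined).
#' @export
classify_variants <- function(variants, expected) {
  if (is.character(variants)) {
    variants <- data.frame(sequence = variants, stringsAsFactors = FALSE)
  }
  stopifnot(inherits(expected, "expected_alleles"))
  if (nrow(variants) == 0L) {
    variants$label <- character(0)
    variants$perfect_5p <- logical(0)
    variants$perfect_3p <- logical(0)
    return(variants)
  }
  res <- .classify_cpp(variants$sequence, expected$hdr_window,
                       expected$wt_window, expected$core,
                       as.integer(expected$core_start), expected$hdr_ext)
  variants$label <- LABEL_LEVELS[res$label]
  variants$perfect_5p <- res$perfect_5p
  variants$perfect_3p <- res$perfect_3p
  variants
}

#' Classify a single variant sequence
#'
#' @param sequence Windowed variant sequence (may contain N).
#' @param expected An [build_expected_alleles()] object.
#' @return One-row data frame `sequence`, `label`, `perfect_5p`, `perfect_3p`.
#' @export
classify_variant <- function(sequence, expected) {
  classify_variants(sequence, expected)
}

#' Summarise classified variants for one individual
#'
#' Percentages are of the retained-read denominator (reads in variants that
#' passed the support filter). Junction percentages count reads in perfect-
#' or erroneous-HDR variants whose respective side is perfect, over the same
#' denominator, so `pct_perfect <= pct_perfect_5p` and `<= pct_perfect_3p`.
#'
#' @param calls Classified variant data frame from [classify_variants()].
#' @param denominator Retained read count from [filter_support()].
#' @param sample_id,group Identifiers carried into the summary row.
#' @return One-row data frame (`sample_id`, `group`, `denominator`,
#'   `pct_perfect`, `pct_erroneous`, `pct_wild_type`, `pct_other`,
#'   `pct_perfect_5p`, `pct_perfect_3p`), or `NULL` when `denominator` is 0
#'   (flagged sample).
#' @export
summarize_sample <- function(calls, denominator, sample_id = NA_character_,
                             group = NA_character_) {
  if (denominator <= 0L) {
    warning("sample ", sample_id, " has no callable variants; summary omitted")
    return(NULL)
  }
  stopifnot(sum(calls$read_count) == denominator)
  pct <- function(keep) 100 * sum(calls$read_count[keep]) / denominator
  hdr <- calls$label %in% c("perfect_hdr", "erroneous_hdr")
  data.frame(sample_id = sample_id, group = group, denominator = denominator,
             pct_perfect = pct(calls$label == "perfect_hdr"),
             pct_erroneous = pct(calls$label == "erroneous_hdr"),
             pct_wild_type = pct(calls$label == "wild_type"),
             pct_other = pct(calls$label == "other"),
             pct_perfect_5p = pct(hdr & calls$perfect_5p),
             pct_perfect_3p = pct(hdr & calls$perfect_3p),
             stringsAsFactors = FALSE)
}

#' Per-group descriptive statistics over individuals
#'
#' @param summaries Data frame of per-sample summaries (rows from
#'   [summarize_sample()]).
#' @param metrics Summary columns to aggregate.
#' @return Data frame with one row per group and metric: `mean`, `sd`
#'   (sample), `sem` (`sd/sqrt(n)`), `max`, `n`.
#' @export
aggregate_groups <- function(summaries,
                             metrics = c("pct_perfect", "pct_erroneous",
                                         "pct_wild_type", "pct_other",
                                         "pct_perfect_5p", "pct_perfect_3p")) {
  stopifnot(nrow(summaries) > 0L)
  out <- list()
  for (g in unique(summaries$group)) {
    rows <- summaries[summaries$group == g, , drop = FALSE]
    for (m in metrics) {
      v <- rows[[m]]
      out[[length(out) + 1L]] <- data.frame(
        group = g, metric = m, n = length(v), mean = mean(v),
        sd = if (length(v) > 1L) sd(v) else 0,
        sem = if (length(v) > 1L) sd(v) / sqrt(length(v)) else 0,
        max = max(v), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
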