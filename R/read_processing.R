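## Read processing: raw paired FASTQ -> masked, window-trimmed sequences.
## Stage order is fixed: demultiplex -> length filter -> overlap merge ->
## forward-read rescue -> window extraction -> quality masking, and every
## stage reports kept/dropped counts so the per-sample ledger conserves the
## input pair count.

#' Demultiplex read pairs by gene-specific primer
#'
#' A pair is assigned to the unique locus whose forward primer matches the
#' forward-read prefix and whose reverse primer matches the reverse-read
#' prefix, each within `max_mismatch` substitutions (no indels). Pairs
#' matching no locus or more than one are counted and dropped.
#'
#' @param pairs Read-pair data frame (`id`, `fwd_seq`, `fwd_qual`, `rev_seq`,
#'   `rev_qual`).
#' @param loci List of [target_locus()] objects.
#' @param max_mismatch Per-primer mismatch tolerance (default 2).
#' @return List with `assigned` (named list of pair data frames per locus
#'   name) and `counts` (named integer vector incl. `unassigned` and
#'   `ambiguous`).
#' @export
demultiplex_pairs <- function(pairs, loci, max_mismatch = 2L) {
  if (is.null(names(loci)) || any(!nzchar(names(loci)))) {
    names(loci) <- vapply(loci, function(l) l$name, character(1))
  }
  ## Loci whose primer pairs sit within twice the tolerance could both claim
  ## one read: refuse the configuration outright.
  if (length(loci) > 1L) {
    for (a in seq_along(loci)) for (b in seq_along(loci)) {
      if (a >= b) next
      if (primer_prefix_dist(loci[[a]]$fwd_primer, loci[[b]]$fwd_primer) <= 2L * max_mismatch &&
          primer_prefix_dist(loci[[a]]$rev_primer, loci[[b]]$rev_primer) <= 2L * max_mismatch) {
        stop(sprintf("primers of loci '%s' and '%s' are within the demultiplex tolerance",
                     names(loci)[a], names(loci)[b]), call. = FALSE)
      }
    }
  }
  hit <- vapply(loci, function(locus) {
    prefix_mismatches(pairs$fwd_seq, locus$fwd_primer) <= max_mismatch &
      prefix_mismatches(pairs$rev_seq, locus$rev_primer) <= max_mismatch
  }, logical(nrow(pairs)))
  hit <- matrix(hit, nrow = nrow(pairs))
  nhit <- rowSums(hit)
  assigned <- lapply(seq_along(loci), function(j) {
    pairs[hit[, j] & nhit == 1L, , drop = FALSE]
  })
  names(assigned) <- names(loci)
  counts <- c(vapply(assigned, nrow, integer(1)),
              unassigned = sum(nhit == 0L), ambiguous = sum(nhit > 1L))
  list(assigned = assigned, counts = counts)
}

## Mismatches between each read's prefix and a primer (reads shorter than the
## primer count the missing bases as mismatches).
prefix_mismatches <- function(seqs, primer) {
  plen <- nchar(primer)
  pr <- strsplit(primer, "", fixed = TRUE)[[1]]
  mm <- integer(length(seqs))
  for (i in seq_len(plen)) {
    mm <- mm + (substring(seqs, i, i) != pr[i])
  }
  mm
}

primer_prefix_dist <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  hamming(substr(a, 1, n), substr(b, 1, n)) + abs(nchar(a) - nchar(b))
}

#' Remove pairs with a short mate
#'
#' Pairs where either mate is shorter than `min_len` bases are removed
#' (boundary inclusive: mates of exactly `min_len` are kept).
#'
#' @param pairs Read-pair data frame.
#' @param min_len Minimum per-mate read length (default 100).
#' @return List with `pairs` (kept rows) and `dropped` (count).
#' @export
filter_length <- function(pairs, min_len = 100L) {
  keep <- nchar(pairs$fwd_seq) >= min_len & nchar(pairs$rev_seq) >= min_len
  list(pairs = pairs[keep, , drop = FALSE], dropped = sum(!keep))
}

#' Assemble read pairs by ungapped overlap
#'
#' The reverse read is reverse-complemented and slid over the forward read;
#' among all overlaps of at least `min_overlap` bases the placement with the
#' most matching bases wins (ties to the longer overlap). The merge is
#' accepted if the mismatch fraction in the overlap is at most
#' `max_mismatch_frac`; disagreeing positions take the higher-quality base
#' (forward on ties) and merged qualities are the per-position maximum.
#' Failure is a value: unmerged pairs are returned for rescue.
#'
#' @param pairs Read-pair data frame.
#' @param min_overlap Minimum overlap in bp (150 and 200 in the shipped
#'   locus presets).
#' @param max_mismatch_frac Maximum mismatch fraction in the overlap
#'   (default 0.20).
#' @return List with `merged` (data frame `id`, `seq`, `qual`) and `failed`
#'   (read-pair data frame of pairs that did not assemble).
#' @export
merge_pairs <- function(pairs, min_overlap, max_mismatch_frac = 0.20) {
  if (nrow(pairs) == 0L) {
    return(list(merged = data.frame(id = character(0), seq = character(0),
                                    qual = character(0), stringsAsFactors = FALSE),
                failed = pairs))
  }
  res <- .merge_pairs_cpp(pairs$fwd_seq, pairs$fwd_qual,
                          revcomp(pairs$rev_seq), .rev_str_cpp(pairs$rev_qual),
                          as.integer(min_overlap), max_mismatch_frac)
  ok <- res$ok
  list(merged = data.frame(id = pairs$id[ok], seq = res$seq[ok],
                           qual = res$qual[ok], stringsAsFactors = FALSE),
       failed = pairs[!ok, , drop = FALSE])
}

#' Combine assembled reads with rescued forward reads
#'
#' Pairs that fail assembly contribute their forward mate unchanged (own
#' sequence and qualities), so the output stream accounts for every input
#' pair exactly once.
#'
#' @param merged `merged` element of [merge_pairs()].
#' @param failed `failed` element of [merge_pairs()].
#' @return Data frame `id`, `seq`, `qual`, `origin`
#'   (`"assembled"`/`"forward_only"`).
#' @export
rescue_unassembled <- function(merged, failed) {
  out <- rbind(
    if (nrow(merged)) cbind(merged, origin = "assembled", stringsAsFactors = FALSE),
    if (nrow(failed)) data.frame(id = failed$id, seq = failed$fwd_seq,
                                 qual = failed$fwd_qual, origin = "forward_only",
                                 stringsAsFactors = FALSE))
  if (is.null(out)) {
    out <- data.frame(id = character(0), seq = character(0), qual = character(0),
                      origin = character(0), stringsAsFactors = FALSE)
  }
  out
}

#' Extract the analysis window from assembled/rescued reads
#'
#' Reads are anchored at the forward primer, so read coordinates coincide
#' with amplicon coordinates up to any upstream indel; the window is taken
#' at 1-based positions `window[1]..window[2]` of each read. Reads shorter
#' than `window[2]` are dropped and counted.
#'
#' @param reads Data frame from [rescue_unassembled()].
#' @param window Integer `c(start, end)`.
#' @return List with `reads` (columns gain `window_seq`, `window_qual`) and
#'   `dropped` (count).
#' @export
extract_window <- function(reads, window) {
  window <- as.integer(window)
  if (length(window) != 2L || window[1] < 1L || window[1] >= window[2]) {
    stop("invalid analysis window", call. = FALSE)
  }
  keep <- nchar(reads$seq) >= window[2]
  kept <- reads[keep, , drop = FALSE]
  kept$window_seq <- substr(kept$seq, window[1], window[2])
  kept$window_qual <- substr(kept$qual, window[1], window[2])
  list(reads = kept, dropped = sum(!keep))
}

#' Mask low-quality bases and drop over-masked reads
#'
#' Bases with Phred quality below `q_thresh` become `N`; reads with more
#' than `max_n` Ns are dropped. Quality exactly `q_thresh` is kept as-is.
#'
#' @param reads Data frame with `window_seq` and `window_qual`.
#' @param q_thresh Phred masking threshold (default 20).
#' @param max_n Maximum Ns tolerated per read (default 5).
#' @return List with `reads` (data frame `id`, `window_seq`, `n_count`,
#'   `origin`) and `dropped` (count).
#' @export
mask_low_quality <- function(reads, q_thresh = 20L, max_n = 5L) {
  if (nrow(reads) == 0L) {
    return(list(reads = data.frame(id = character(0), window_seq = character(0),
                                   n_count = integer(0), origin = character(0),
                                   stringsAsFactors = FALSE),
                dropped = 0L))
  }
  m <- .mask_cpp(reads$window_seq, reads$window_qual, as.integer(q_thresh))
  keep <- m$n_count <= max_n
  list(reads = data.frame(id = reads$id[keep], window_seq = m$seq[keep],
                          n_count = m$n_count[keep], origin = reads$origin[keep],
                          stringsAsFactors = FALSE),
       dropped = sum(!keep))
}

#' Run the full read-processing stage for one sample and locus
#'
#' Applies, in order: length filter, overlap merge, forward-read rescue,
#' window extraction and quality masking (demultiplexing across loci is done
#' upstream by [demultiplex_pairs()]). The returned ledger accounts for every
#' input pair.
#'
#' @param pairs Read-pair data frame already assigned to this locus.
#' @param locus A [target_locus()].
#' @param min_len Minimum per-mate read length.
#' @param min_overlap Minimum assembly overlap for this locus.
#' @param max_mismatch_frac Maximum mismatch fraction in the overlap.
#' @param q_thresh Phred masking threshold.
#' @param max_n Maximum Ns per windowed read.
#' @return List with `reads` (processed-read data frame) and `ledger`
#'   (data frame `stage`, `kept`, `dropped`).
#' @export
process_reads <- function(pairs, locus, min_len = 100L, min_overlap = 150L,
                          max_mismatch_frac = 0.20, q_thresh = 20L, max_n = 5L) {
  n_in <- nrow(pairs)
  fl <- filter_length(pairs, min_len)
  mg <- merge_pairs(fl$pairs, min_overlap, max_mismatch_frac)
  combined <- rescue_unassembled(mg$merged, mg$failed)
  win <- extract_window(combined, locus$window)
  masked <- mask_low_quality(win$reads, q_thresh, max_n)
  ledger <- data.frame(
    stage = c("input", "length_filter", "assembled", "forward_only",
              "window", "quality_mask"),
    kept = c(n_in, nrow(fl$pairs), nrow(mg$merged), nrow(mg$failed),
             nrow(win$reads), nrow(masked$reads)),
    dropped = c(0L, fl$dropped, 0L, 0L, win$dropped, masked$dropped),
    stringsAsFactors = FALSE)
  stopifnot(nrow(fl$pairs) == nrow(mg$merged) + nrow(mg$failed),
            nrow(win$reads) + win$dropped == nrow(combined),
            nrow(masked$reads) + masked$dropped == nrow(win$reads))
  list(reads = masked$reads, ledger = ledger)
}
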