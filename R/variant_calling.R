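## Variant calling: collapse equal-length masked reads into supported
## variants. Two reads belong together when they are identical, or when they
## differ only at positions where one of them is masked (N) - up to 5 such
## positions - and never at two informative bases. The grouping the original
## rule induces is not transitive, so a deterministic greedy order is fixed:
## variants are visited in descending read count (ties lexicographic), each
## joining the first compatible group, and groups are then re-merged under
## the same rule until no merge applies.

#' Collapse identical reads into variants
#'
#' @param reads Processed-read data frame (`id`, `window_seq`, ...).
#' @return Variant data frame `sequence`, `read_count`, `n_count`,
#'   `member_ids` (list column).
#' @export
collapse_identical <- function(reads) {
  if (nrow(reads) == 0L) {
    return(data.frame(sequence = character(0), read_count = integer(0),
                      n_count = integer(0), stringsAsFactors = FALSE))
  }
  if (length(unique(nchar(reads$window_seq))) != 1L) {
    stop("windowed reads of mixed length; window extraction is broken", call. = FALSE)
  }
  grp <- split(reads$id, reads$window_seq)
  out <- data.frame(sequence = names(grp),
                    read_count = lengths(grp, use.names = FALSE),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$n_count <- nchar(out$sequence) - nchar(gsub("N", "", out$sequence, fixed = TRUE))
  out$member_ids <- unname(grp)
  out[order(-out$read_count, out$sequence), , drop = FALSE]
}

#' Merge variants that differ only by masked bases
#'
#' Variants merge when no position carries two different informative
#' (non-N) bases and at most `max_n_diff` positions have an N in exactly one
#' of them. The representative of each merged group is the member with the
#' fewest Ns (ties: higher read count, then lexicographic); read counts are
#' summed.
#'
#' @param variants Variant data frame from [collapse_identical()].
#' @param max_n_diff Maximum N-only differences allowed for a merge
#'   (default 5).
#' @return Variant data frame (same columns; `n_members` added).
#' @export
merge_n_compatible <- function(variants, max_n_diff = 5L) {
  if (nrow(variants) == 0L) return(cbind(variants, n_members = integer(0)))
  ord <- order(-variants$read_count, variants$sequence)
  v <- variants[ord, , drop = FALSE]
  cid <- .nmerge_cpp(v$sequence, as.integer(max_n_diff))
  out <- lapply(split(seq_len(nrow(v)), cid), function(ix) {
    grp <- v[ix, , drop = FALSE]
    rep_ix <- order(grp$n_count, -grp$read_count, grp$sequence)[1L]
    data.frame(sequence = grp$sequence[rep_ix],
               read_count = sum(grp$read_count),
               n_count = grp$n_count[rep_ix],
               member_ids = I(list(unlist(grp$member_ids))),
               n_members = nrow(grp),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(-out$read_count, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Retain variants with sufficient read support
#'
#' @param variants Variant data frame.
#' @param min_reads Minimum supporting reads (default 100).
#' @return List with `variants` (retained rows), `denominator` (total
#'   retained reads; the per-sample percentage denominator), `dropped_reads`
#'   and `flagged` (`TRUE` when no variant survives).
#' @export
filter_support <- function(variants, min_reads = 100L) {
  keep <- variants$read_count >= min_reads
  kept <- variants[keep, , drop = FALSE]
  list(variants = kept,
       denominator = sum(kept$read_count),
       dropped_reads = sum(variants$read_count[!keep]),
       flagged = nrow(kept) == 0L)
}

#' Collapse, N-merge and support-filter processed reads
#'
#' Convenience wrapper running [collapse_identical()],
#' [merge_n_compatible()] and [filter_support()] in the fixed order
#' (support filtering comes after N-merging).
#'
#' @param reads Processed-read data frame.
#' @param max_n_diff Maximum N-only differences for merging.
#' @param min_reads Minimum supporting reads per variant.
#' @return As [filter_support()], plus `n_input_reads`.
#' @export
call_variants <- function(reads, max_n_diff = 5L, min_reads = 100L) {
  collapsed <- collapse_identical(reads)
  merged <- merge_n_compatible(collapsed, max_n_diff)
  stopifnot(sum(merged$read_count) == nrow(reads))
  res <- filter_support(merged, min_reads)
  res$n_input_reads <- nrow(reads)
  res
}
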