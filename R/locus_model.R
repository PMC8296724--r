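## Locus model: target amplicon, guide, intended edit, asymmetric ssODN donor
## and the expected (wild-type / edited) alleles used downstream for
## classification.
##
## Coordinate conventions (used package-wide):
##   * windows are 1-based inclusive positions on the assembled read, which is
##     anchored at the first base of the forward gene-specific primer;
##   * cut sites are 0-based gap indices: gap g sits between amplicon
##     positions g and g+1.

#' Construct a guide RNA description
#'
#' @param protospacer 20-nt protospacer sequence, 5'->3' on the guide strand.
#' @param pam 3-nt PAM (NGG for SpCas9), immediately 3' of the protospacer on
#'   the guide strand.
#' @param strand `"+"` if the protospacer lies on the amplicon sense strand,
#'   `"-"` if on its reverse complement.
#' @param start 1-based position on the amplicon sense strand of the first
#'   base occupied by the protospacer (for `"-"` guides this is the start of
#'   the protospacer's reverse complement).
#' @return An object of class `guide_rna`.
#' @export
guide_rna <- function(protospacer, pam, strand = c("+", "-"), start) {
  strand <- match.arg(strand)
  assert_dna(protospacer, "protospacer")
  assert_dna(pam, "pam")
  if (nchar(protospacer) != 20L) stop("protospacer must be 20 nt", call. = FALSE)
  if (nchar(pam) != 3L) stop("pam must be 3 nt", call. = FALSE)
  start <- as.integer(start)
  stopifnot(length(start) == 1L, start >= 1L)
  structure(list(protospacer = protospacer, pam = pam, strand = strand,
                 start = start),
            class = "guide_rna")
}

#' Construct a target locus
#'
#' The amplicon is the sense-strand sequence amplified between the
#' gene-specific primers: it begins with `fwd_primer` and ends with the
#' reverse complement of `rev_primer` (primers are given as sequenced).
#' The guide is validated against the amplicon at construction.
#'
#' @param name Locus identifier (e.g. gene name).
#' @param amplicon Amplicon sequence, sense strand, 5'->3'.
#' @param fwd_primer Forward gene-specific primer.
#' @param rev_primer Reverse gene-specific primer (reverse-complement of the
#'   amplicon tail).
#' @param window Integer vector `c(start, end)`: 1-based inclusive analysis
#'   window on the assembled read.
#' @param guide A [guide_rna()] object.
#' @return An object of class `target_locus`.
#' @export
target_locus <- function(name, amplicon, fwd_primer, rev_primer, window, guide) {
  assert_dna(amplicon, "amplicon")
  assert_dna(fwd_primer, "fwd_primer")
  assert_dna(rev_primer, "rev_primer")
  if (!inherits(guide, "guide_rna")) stop("guide must be a guide_rna", call. = FALSE)
  window <- as.integer(window)
  if (length(window) != 2L || is.na(window[1]) || is.na(window[2])) {
    stop("window must be c(start, end)", call. = FALSE)
  }
  if (!startsWith(amplicon, fwd_primer)) {
    stop("amplicon must start with fwd_primer", call. = FALSE)
  }
  if (!endsWith(amplicon, revcomp(rev_primer))) {
    stop("reverse complement of rev_primer must be a suffix of the amplicon",
         call. = FALSE)
  }
  if (!(window[1] >= 1L && window[1] < window[2] && window[2] <= nchar(amplicon))) {
    stop("window must satisfy 1 <= start < end <= length(amplicon)", call. = FALSE)
  }
  locus <- structure(list(name = as.character(name), amplicon = amplicon,
                          fwd_primer = fwd_primer, rev_primer = rev_primer,
                          window = window, guide = guide),
                     class = "target_locus")
  validate_guide(locus)     # protospacer/PAM must sit where stated
  cut <- locate_cut_site(locus)
  if (!(cut > window[1] && cut < window[2])) {
    stop("cut site must lie strictly inside the analysis window", call. = FALSE)
  }
  locus
}

## Check the guide occupies its stated amplicon position with a consistent PAM.
validate_guide <- function(locus) {
  g <- locus$guide
  amp <- locus$amplicon
  s <- g$start
  if (s + 19L > nchar(amp)) stop("guide does not fit on the amplicon", call. = FALSE)
  occupied <- substr(amp, s, s + 19L)
  if (g$strand == "+") {
    if (occupied != g$protospacer) {
      stop("protospacer not found on amplicon + strand at stated position",
           call. = FALSE)
    }
    if (s + 22L > nchar(amp) || substr(amp, s + 20L, s + 22L) != g$pam) {
      stop("PAM not found immediately 3' of protospacer", call. = FALSE)
    }
  } else {
    if (occupied != revcomp(g$protospacer)) {
      stop("protospacer reverse complement not found at stated position",
           call. = FALSE)
    }
    if (s - 3L < 1L || substr(amp, s - 3L, s - 1L) != revcomp(g$pam)) {
      stop("PAM not found immediately 3' of protospacer (on - strand)",
           call. = FALSE)
    }
  }
  invisible(locus)
}

#' @export
print.target_locus <- function(x, ...) {
  cat(sprintf("<target_locus> %s: %d-nt amplicon, window %d-%d, guide %s strand @%d, cut gap %d\n",
              x$name, nchar(x$amplicon), x$window[1], x$window[2],
              x$guide$strand, x$guide$start, locate_cut_site(x)))
  invisible(x)
}

#' Locate the Cas9 cut site on the amplicon
#'
#' SpCas9 cuts bluntly 3 bp 5' of the PAM, i.e. between protospacer positions
#' 17 and 18. The cut is reported as a 0-based gap index on the amplicon
#' sense strand: gap `g` lies between amplicon positions `g` and `g + 1`.
#' For minus-strand guides the gap is mapped onto sense coordinates.
#'
#' @param locus A [target_locus()].
#' @param offset Gap position within the protospacer counted from its
#'   PAM-distal end (default 17, the canonical blunt cut).
#' @return Integer 0-based gap index.
#' @export
locate_cut_site <- function(locus, offset = 17L) {
  validate_guide(locus)
  s <- locus$guide$start
  offset <- as.integer(offset)
  if (locus$guide$strand == "+") {
    s + offset - 1L        # gap after amplicon position s + offset - 1
  } else {
    ## Protospacer rc occupies s..s+19; the guide 5'->3' runs from amplicon
    ## position s+19 down to s, so guide position i sits at s + 20 - i and the
    ## gap between guide positions offset and offset+1 maps to the gap after
    ## amplicon position s + 19 - offset.
    s + 19L - offset
  }
}

#' Construct an edit specification
#'
#' Either an insertion placed at the Cas9 cut site (e.g. a FLAG element
#' followed by a TAA stop codon) or a set of base substitutions (single
#' nucleotide replacement, SNR).
#'
#' @param kind `"insertion"` or `"substitution"`.
#' @param insert Inserted sequence (insertions only).
#' @param substitutions Data frame with columns `pos` (1-based amplicon
#'   position) and `base` (replacement base), substitutions only.
#' @return An object of class `edit_spec`.
#' @export
edit_spec <- function(kind = c("insertion", "substitution"), insert = NULL,
                      substitutions = NULL) {
  kind <- match.arg(kind)
  if (kind == "insertion") {
    if (is.null(insert)) stop("insertion edit requires a non-empty insert", call. = FALSE)
    assert_dna(insert, "insert")
    structure(list(kind = kind, insert = insert), class = "edit_spec")
  } else {
    if (is.null(substitutions) || nrow(substitutions) == 0L) {
      stop("substitution edit requires a non-empty substitution table", call. = FALSE)
    }
    stopifnot(all(c("pos", "base") %in% names(substitutions)))
    substitutions$pos <- as.integer(substitutions$pos)
    substitutions <- substitutions[order(substitutions$pos), , drop = FALSE]
    if (anyDuplicated(substitutions$pos)) {
      stop("duplicate substitution positions", call. = FALSE)
    }
    if (!all(substitutions$base %in% DNA_BASES)) {
      stop("substitution bases must be A/C/G/T", call. = FALSE)
    }
    structure(list(kind = kind, substitutions = substitutions), class = "edit_spec")
  }
}

## Validate an edit against a locus; returns the edit invisibly.
validate_edit <- function(locus, edit) {
  if (!inherits(edit, "edit_spec")) stop("edit must be an edit_spec", call. = FALSE)
  if (edit$kind == "substitution") {
    w <- locus$window
    for (i in seq_len(nrow(edit$substitutions))) {
      p <- edit$substitutions$pos[i]
      b <- edit$substitutions$base[i]
      if (p < w[1] || p > w[2]) {
        stop("substitution position outside the analysis window", call. = FALSE)
      }
      if (substr(locus$amplicon, p, p) == b) {
        stop(sprintf("substitution at %d does not change the reference base", p),
             call. = FALSE)
      }
    }
  }
  invisible(edit)
}

## Apply an edit to the full amplicon; returns the edited amplicon string.
apply_edit <- function(locus, edit) {
  validate_edit(locus, edit)
  amp <- locus$amplicon
  if (edit$kind == "insertion") {
    g <- locate_cut_site(locus)
    paste0(substr(amp, 1L, g), edit$insert, substr(amp, g + 1L, nchar(amp)))
  } else {
    for (i in seq_len(nrow(edit$substitutions))) {
      substr(amp, edit$substitutions$pos[i], edit$substitutions$pos[i]) <-
        edit$substitutions$base[i]
    }
    amp
  }
}

#' Design an asymmetric ssODN donor
#'
#' Copies `arm_long` bases 5' of the cut site and `arm_short` bases 3' of it
#' (on the amplicon sense strand) around the intended edit: for insertions
#' the insert sits between the arms, for substitutions the replaced bases are
#' carried inside the arms. `polarity = "antisense"` returns the reverse
#' complement, i.e. the donor as it would be synthesised against the target
#' strand.
#'
#' @param locus A [target_locus()].
#' @param edit An [edit_spec()].
#' @param arm_long,arm_short Homology arm lengths in nt (defaults 90 and 36).
#' @param polarity `"sense"` or `"antisense"` relative to the amplicon sense
#'   strand.
#' @param swap_arms If `TRUE`, place the long arm 3' of the cut instead of 5'.
#' @return An object of class `donor_odn` with fields `sequence`, `arm5`,
#'   `arm3`, `polarity`.
#' @export
design_asymmetric_odn <- function(locus, edit, arm_long = 90L, arm_short = 36L,
                                  polarity = c("sense", "antisense"),
                                  swap_arms = FALSE) {
  polarity <- match.arg(polarity)
  validate_edit(locus, edit)
  arm5 <- if (swap_arms) as.integer(arm_short) else as.integer(arm_long)
  arm3 <- if (swap_arms) as.integer(arm_long) else as.integer(arm_short)
  g <- locate_cut_site(locus)
  amp_len <- nchar(locus$amplicon)
  if (g - arm5 + 1L < 1L || g + arm3 > amp_len) {
    stop(sprintf("insufficient flank: need %d nt 5' and %d nt 3' of cut gap %d on a %d-nt amplicon",
                 arm5, arm3, g, amp_len), call. = FALSE)
  }
  edited <- apply_edit(locus, edit)
  ins_len <- if (edit$kind == "insertion") nchar(edit$insert) else 0L
  ## On the edited amplicon the 3' arm starts ins_len later.
  seq <- substr(edited, g - arm5 + 1L, g + ins_len + arm3)
  if (edit$kind == "substitution") {
    subs <- edit$substitutions$pos
    if (any(subs <= g - arm5 | subs > g + arm3)) {
      stop("substituted positions must fall inside the donor arms", call. = FALSE)
    }
  }
  if (polarity == "antisense") seq <- revcomp(seq)
  structure(list(sequence = seq, arm5 = arm5, arm3 = arm3, polarity = polarity),
            class = "donor_odn")
}

#' @export
print.donor_odn <- function(x, ...) {
  cat(sprintf("<donor_odn> %d nt (%d + %d arms, %s)\n%s\n",
              nchar(x$sequence), x$arm5, x$arm3, x$polarity, x$sequence))
  invisible(x)
}

#' Build the expected wild-type and edited alleles for a locus
#'
#' Computes the window sequences a read would produce from the unedited and
#' the perfectly edited amplicon, plus the anchoring k-mers used by the
#' classifier. Windows are extracted from both amplicons at the locus window
#' positions, so `wt_window` and `hdr_window` have the same length; for
#' insertions the edited window contains the insert and correspondingly less
#' 3' flank.
#'
#' @param locus A [target_locus()].
#' @param edit An [edit_spec()].
#' @param anchor_k Junction k-mer length (default 10).
#' @return An object of class `expected_alleles` with fields `wt_window`,
#'   `hdr_window`, `core`, `core_start` (1-based position of the core in
#'   `hdr_window`), `anchor5`, `anchor3`, `hdr_ext` (edited amplicon from the
#'   window start to the amplicon end, used to score junctions on
#'   length-shifted variants) and `window_len`.
#' @export
build_expected_alleles <- function(locus, edit, anchor_k = 10L) {
  validate_edit(locus, edit)
  anchor_k <- as.integer(anchor_k)
  w <- locus$window
  amp <- locus$amplicon
  edited <- apply_edit(locus, edit)
  wt_window <- substr(amp, w[1], w[2])
  hdr_window <- substr(edited, w[1], w[2])
  if (identical(wt_window, hdr_window)) {
    stop("edit has no effect inside the analysis window", call. = FALSE)
  }
  if (edit$kind == "insertion") {
    g <- locate_cut_site(locus)
    core <- edit$insert
    core_abs <- g + 1L                       # first inserted base, edited coords
    core_end_abs <- g + nchar(core)
  } else {
    subs <- edit$substitutions$pos
    core_abs <- min(subs) - anchor_k
    core_end_abs <- max(subs) + anchor_k
    if (core_abs < w[1] || core_end_abs > w[2]) {
      stop("window too small to contain the substitution context k-mer",
           call. = FALSE)
    }
    core <- substr(edited, core_abs, core_end_abs)
  }
  core_start <- core_abs - w[1] + 1L
  if (core_start < 1L || core_end_abs > w[2]) {
    stop("core does not fit inside the analysis window", call. = FALSE)
  }
  if (core_abs - anchor_k < w[1] || core_end_abs + anchor_k > nchar(edited)) {
    stop("window too small to contain the junction anchors", call. = FALSE)
  }
  anchor5 <- substr(edited, core_abs - anchor_k + 1L, core_abs)
  anchor3 <- substr(edited, core_end_abs, core_end_abs + anchor_k - 1L)
  if (grepl(core, wt_window, fixed = TRUE)) {
    stop("core sequence occurs in the wild-type window; pick a longer anchor_k",
         call. = FALSE)
  }
  structure(list(wt_window = wt_window, hdr_window = hdr_window,
                 core = core, core_start = core_start,
                 anchor5 = anchor5, anchor3 = anchor3,
                 hdr_ext = substr(edited, w[1], nchar(edited)),
                 window_len = w[2] - w[1] + 1L),
            class = "expected_alleles")
}

#' Read a reference amplicon from a FASTA file
#'
#' @param path FASTA file path.
#' @param name Optional record name; defaults to the first record.
#' @return Amplicon sequence as an upper-case character string.
#' @export
read_amplicon_fasta <- function(path, name = NULL) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("no sequences in ", path, call. = FALSE)
  if (!is.null(name)) {
    idx <- match(name, names(set))
    if (is.na(idx)) stop("record not found: ", name, call. = FALSE)
  } else {
    idx <- 1L
  }
  toupper(as.character(set[[idx]]))
}

#' Build a locus and edit from a configuration list
#'
#' The configuration dialect mirrors the YAML used by [run_pipeline()]:
#' keys `name`, `amplicon` (or `fasta` + optional `fasta_record`),
#' `fwd_primer`, `rev_primer`, `guide` (`protospacer`, `pam`, `strand`,
#' `start`), `window` (`start`, `end`), `edit` (`kind`, `insert` or
#' `substitutions` as a list of `{pos, base}`), optional `donor`
#' (`arm_long`, `arm_short`, `polarity`), optional `min_overlap`.
#'
#' @param config A named list (e.g. one entry of `yaml::read_yaml(...)$loci`).
#' @param base_dir Directory against which relative FASTA paths are resolved.
#' @return List with elements `locus`, `edit`, `donor` (or `NULL`),
#'   `expected`, `min_overlap`.
#' @export
locus_from_config <- function(config, base_dir = ".") {
  amp <- config$amplicon
  if (is.null(amp)) {
    path <- config$fasta
    if (is.null(path)) stop("config needs 'amplicon' or 'fasta'", call. = FALSE)
    if (!file.exists(path)) path <- file.path(base_dir, path)
    amp <- read_amplicon_fasta(path, config$fasta_record)
  }
  guide <- guide_rna(config$guide$protospacer, config$guide$pam,
                     config$guide$strand %||% "+",
                     config$guide$start)
  locus <- target_locus(config$name, amp, config$fwd_primer, config$rev_primer,
                        c(config$window$start, config$window$end), guide)
  edit <- if (!is.null(config$edit$insert)) {
    edit_spec("insertion", insert = config$edit$insert)
  } else {
    subs <- do.call(rbind, lapply(config$edit$substitutions, function(s) {
      data.frame(pos = s$pos, base = s$base, stringsAsFactors = FALSE)
    }))
    edit_spec("substitution", substitutions = subs)
  }
  donor <- NULL
  if (!is.null(config$donor)) {
    donor <- design_asymmetric_odn(locus, edit,
                                   arm_long = config$donor$arm_long %||% 90L,
                                   arm_short = config$donor$arm_short %||% 36L,
                                   polarity = config$donor$polarity %||% "sense")
  }
  list(locus = locus, edit = edit, donor = donor,
       expected = build_expected_alleles(locus, edit,
                                         anchor_k = config$anchor_k %||% 10L),
       min_overlap = as.integer(config$min_overlap %||% 150L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
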