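# Fixtures are generated in code. Toy loci are small enough for exhaustive
# enumeration; the demo presets carry the realistic assay constants.

# Deterministic random amplicon with a plus-strand guide at `gstart` (PAM
# forced to NGG) and the given primers at the ends.
make_toy_amplicon <- function(len, gstart, seed = 99) {
  set.seed(seed)
  amp <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  substr(amp, gstart + 21L, gstart + 22L) <- "GG"
  amp
}

make_toy_locus <- function(len = 80L, gstart = 21L, window = c(25L, 48L),
                           seed = 99) {
  amp <- make_toy_amplicon(len, gstart, seed)
  target_locus("toy", amp,
               fwd_primer = substr(amp, 1, 8),
               rev_primer = revcomp(substr(amp, len - 7L, len)),
               window = window,
               guide = guide_rna(substr(amp, gstart, gstart + 19L),
                                 substr(amp, gstart + 20L, gstart + 22L),
                                 "+", gstart))
}

# Toy presets for exhaustive classification: cut gap at gstart + 16 = 37.
toy_insertion_preset <- function() {
  locus <- make_toy_locus()
  edit <- edit_spec("insertion", insert = "GATTACA")
  list(locus = locus, edit = edit,
       expected = build_expected_alleles(locus, edit, anchor_k = 5L),
       min_overlap = 20L)
}

toy_substitution_preset <- function() {
  locus <- make_toy_locus(seed = 101)
  ref <- function(p) substr(locus$amplicon, p, p)
  other <- function(b) setdiff(c("A", "C", "G", "T"), b)[1]
  subs <- data.frame(pos = 36:38,
                     base = vapply(36:38, function(p) other(ref(p)), character(1)))
  edit <- edit_spec("substitution", substitutions = subs)
  list(locus = locus, edit = edit,
       expected = build_expected_alleles(locus, edit, anchor_k = 5L),
       min_overlap = 20L)
}

# ---- Independent classification oracle (plain R, no shared code with the
# package's C++ cascade). Implements the same scientific definition from
# first principles on character vectors.
oracle_nc_eq <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  all(a == b | a == "N" | b == "N")
}

oracle_classify <- function(seq, expected) {
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  hw <- strsplit(expected$hdr_window, "", fixed = TRUE)[[1]]
  ww <- strsplit(expected$wt_window, "", fixed = TRUE)[[1]]
  core <- strsplit(expected$core, "", fixed = TRUE)[[1]]
  ext <- strsplit(expected$hdr_ext, "", fixed = TRUE)[[1]]
  lc <- length(core)
  occ <- integer(0)
  if (length(s) >= lc) {
    for (o in 1:(length(s) - lc + 1L)) {
      if (oracle_nc_eq(s[o:(o + lc - 1L)], core)) occ <- c(occ, o)
    }
  }
  f5 <- f3 <- FALSE
  cs <- expected$core_start
  for (o in occ) {
    en <- o + lc - 1L
    if (!f5 && en <= length(ext) && oracle_nc_eq(s[1:en], ext[1:en])) f5 <- TRUE
    tail_len <- length(s) - o + 1L
    if (!f3 && cs + tail_len - 1L <= length(ext) &&
        oracle_nc_eq(s[o:length(s)], ext[cs:(cs + tail_len - 1L)])) f3 <- TRUE
  }
  if (oracle_nc_eq(s, hw)) {
    list(label = "perfect_hdr", perfect_5p = f5, perfect_3p = f3)
  } else if (oracle_nc_eq(s, ww)) {
    list(label = "wild_type", perfect_5p = FALSE, perfect_3p = FALSE)
  } else if (length(occ) > 0L) {
    list(label = "erroneous_hdr", perfect_5p = f5, perfect_3p = f3)
  } else {
    list(label = "other", perfect_5p = FALSE, perfect_3p = FALSE)
  }
}

# All sequences within one edit operation (substitution incl. N, deletion,
# ACGT insertion) of `s`.
edit_neighbors <- function(s) {
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(v)
  out <- character(0)
  for (i in seq_len(n)) {
    for (b in setdiff(c("A", "C", "G", "T", "N"), v[i])) {
      w <- v; w[i] <- b
      out <- c(out, paste(w, collapse = ""))
    }
    out <- c(out, paste(v[-i], collapse = ""))
  }
  for (i in 0:n) {
    for (b in c("A", "C", "G", "T")) {
      out <- c(out, paste(c(head(v, i), b, if (i < n) v[(i + 1):n]), collapse = ""))
    }
  }
  unique(out)
}

# Simple read-pair construction from template sequences (uniform quality).
pairs_from_templates <- function(templates, read_length = 250L, q = 38L) {
  qc <- intToUtf8(q + 33L)
  len <- nchar(templates)
  fwd <- substr(templates, 1L, pmin(read_length, len))
  rev <- revcomp(substr(templates, pmax(1L, len - read_length + 1L), len))
  data.frame(id = sprintf("t%04d", seq_along(templates)),
             fwd_seq = fwd, fwd_qual = strrep(qc, nchar(fwd)),
             rev_seq = rev, rev_qual = strrep(qc, nchar(rev)),
             stringsAsFactors = FALSE)
}
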