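## Small sequence/quality helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse-complement DNA strings
#'
#' Vectorised reverse complement over plain character strings (alphabet
#' `A,C,G,T,N`).
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  chartr("ACGTN", "TGCAN", .rev_str_cpp(x))
}

## Phred+33 encoding helpers. Qualities travel as ASCII strings (as in FASTQ)
## and are decoded to integer scores only where a rule needs them.
phred_to_int <- function(qual) {
  lapply(qual, function(q) utf8ToInt(q) - 33L)
}

int_to_phred <- function(scores) {
  vapply(scores, function(s) intToUtf8(s + 33L), character(1))
}

## Validate a DNA string (used by constructors; N allowed where stated).
assert_dna <- function(x, name, allow_n = FALSE) {
  alphabet <- if (allow_n) "ACGTN" else "ACGT"
  if (length(x) != 1L || !is.character(x) || is.na(x) || nchar(x) == 0L) {
    stop(sprintf("'%s' must be a single non-empty DNA string", name), call. = FALSE)
  }
  bad <- gsub(sprintf("[%s]", alphabet), "", x)
  if (nchar(bad) > 0L) {
    stop(sprintf("'%s' contains non-DNA characters: %s", name,
                 paste(unique(strsplit(bad, "")[[1]]), collapse = ",")),
         call. = FALSE)
  }
  invisible(x)
}

## Hamming distance between equal-length strings (no N semantics).
hamming <- function(a, b) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  stopifnot(length(av) == length(bv))
  sum(av != bv)
}
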