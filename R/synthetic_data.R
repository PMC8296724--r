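## Synthetic mosaic-embryo read generator. Each simulated individual is a
## mixture of allele classes (wild type, perfect HDR, erroneous HDR with an
## indel 5' or 3' of the edit, NHEJ indels) amplified between the locus
## primers and sequenced as overlapping 2 x read_length pairs with a simple
## Phred quality/error model. Truth tables accompany every output so the
## pipeline can be scored against known composition.

ALLELE_LABELS <- c("wild_type", "perfect_hdr", "erroneous_hdr_5p",
                   "erroneous_hdr_3p", "nhej")

## Run `expr` under a temporary RNG state seeded with `seed` (NULL = use the
## current stream untouched).
with_sim_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

#' Read-simulation configuration
#'
#' @param n_read_pairs Number of read pairs to simulate.
#' @param read_length Read length in nt (2 x 250 MiSeq by default).
#' @param per_base_error Per-base substitution error probability.
#' @param q_high,q_low Phred scores assigned to ordinary and low-quality
#'   base calls.
#' @param p_lowq Probability that a base call receives `q_low`.
#' @param seed Integer seed; the same seed reproduces the FASTQ byte-for-byte.
#' @return A `read_sim_config` list.
#' @export
read_sim_config <- function(n_read_pairs, read_length = 250L,
                            per_base_error = 0.001, q_high = 38L, q_low = 12L,
                            p_lowq = 0.002, seed = 1L) {
  stopifnot(n_read_pairs >= 0, read_length >= 100L,
            per_base_error >= 0, per_base_error <= 1,
            p_lowq >= 0, p_lowq <= 1, q_high >= 0, q_low >= 0)
  structure(list(n_read_pairs = as.integer(n_read_pairs),
                 read_length = as.integer(read_length),
                 per_base_error = per_base_error,
                 q_high = as.integer(q_high), q_low = as.integer(q_low),
                 p_lowq = p_lowq, seed = seed),
            class = "read_sim_config")
}

#' Construct one allele sequence of a given outcome class
#'
#' `wild_type` returns the amplicon unchanged; `perfect_hdr` applies the edit
#' exactly; `erroneous_hdr_5p`/`erroneous_hdr_3p` apply the edit plus a
#' random 1-10 bp indel strictly on the stated side of the edited bases,
#' inside the analysis window (the core insert/replacement itself is never
#' touched); `nhej` applies a random 1-15 bp indel at the cut site with no
#' donor sequence. Indels never disturb the primer-matching prefix.
#'
#' @param locus A [target_locus()].
#' @param edit An [edit_spec()].
#' @param label One of `wild_type`, `perfect_hdr`, `erroneous_hdr_5p`,
#'   `erroneous_hdr_3p`, `nhej`.
#' @param seed Optional integer seed for the indel draw.
#' @return Allele sequence (full amplicon coordinates) as a string.
#' @export
make_allele <- function(locus, edit, label, seed = NULL) {
  label <- match.arg(label, ALLELE_LABELS)
  with_sim_seed(seed, {
    amp <- locus$amplicon
    if (label == "wild_type") return(amp)
    edited <- apply_edit(locus, edit)
    if (label == "perfect_hdr") return(edited)
    exp_all <- build_expected_alleles(locus, edit)
    w <- locus$window
    if (label == "nhej") {
      g <- locate_cut_site(locus)
      return(random_indel(amp, lo = max(w[1], nchar(locus$fwd_primer) + 1L),
                          hi = w[2] - 1L, at = g, max_size = 15L))
    }
    ## erroneous HDR: indel confined to one side of the core on the edited
    ## amplicon (core position in full edited coordinates).
    core_abs <- exp_all$core_start + w[1] - 1L
    core_end_abs <- core_abs + nchar(exp_all$core) - 1L
    if (label == "erroneous_hdr_5p") {
      lo <- max(w[1], nchar(locus$fwd_primer) + 1L)
      hi <- core_abs - 1L
    } else {
      lo <- core_end_abs + 1L
      hi <- w[2] - 1L
    }
    if (hi - lo < 12L) stop("window leaves no room for a flanking indel", call. = FALSE)
    random_indel(edited, lo = lo, hi = hi, at = NULL, max_size = 10L)
  })
}

## Insert or delete 1..max_size bases within [lo, hi] (1-based, inclusive).
## If `at` is a gap index the indel is placed at/over that gap (NHEJ at the
## cut); otherwise the position is drawn uniformly inside the range.
random_indel <- function(seq, lo, hi, at = NULL, max_size = 10L) {
  size <- sample.int(max_size, 1L)
  is_del <- runif(1) < 0.5
  if (is_del) {
    if (is.null(at)) {
      start <- lo + sample.int(max(hi - size - lo + 1L, 1L), 1L) - 1L
    } else {
      ## deletion covering the cut gap: start within (at - size + 1)..(at + 1)
      start <- max(lo, at - sample.int(size, 1L) + 1L)
    }
    end <- min(start + size - 1L, hi)
    paste0(substr(seq, 1L, start - 1L), substr(seq, end + 1L, nchar(seq)))
  } else {
    gap <- if (is.null(at)) lo + sample.int(hi - lo, 1L) - 1L else at
    ins <- paste(sample(DNA_BASES, size, replace = TRUE), collapse = "")
    paste0(substr(seq, 1L, gap), ins, substr(seq, gap + 1L, nchar(seq)))
  }
}

#' Define an allele mixture for one simulated individual
#'
#' @param labels Character vector of allele class labels.
#' @param sequences Character vector of allele sequences (full amplicon
#'   coordinates, primer to primer).
#' @param fractions Numeric vector of mixture proportions (must sum to 1).
#' @param locus Optional [target_locus()]; if given, sequences are checked to
#'   start with the forward primer and end with the reverse-complemented
#'   reverse primer.
#' @return An `allele_mixture` data frame.
#' @export
allele_mixture <- function(labels, sequences, fractions, locus = NULL) {
  stopifnot(length(labels) == length(sequences),
            length(labels) == length(fractions))
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-9) {
    stop("fractions must be non-negative and sum to 1", call. = FALSE)
  }
  if (!is.null(locus)) {
    suffix <- revcomp(locus$rev_primer)
    ok <- startsWith(sequences, locus$fwd_primer) & endsWith(sequences, suffix)
    if (!all(ok)) stop("allele sequences must run primer to primer", call. = FALSE)
  }
  structure(data.frame(label = labels, sequence = sequences,
                       fraction = fractions, stringsAsFactors = FALSE),
            class = c("allele_mixture", "data.frame"))
}

#' Simulate one individual's paired-end reads
#'
#' Each read pair draws its source allele multinomially from the mixture;
#' the forward read is the first `read_length` bases of the allele and the
#' reverse read the reverse complement of its last `read_length` bases.
#' Substitution errors occur independently per base; each base call receives
#' quality `q_low` with probability `p_lowq` and `q_high` otherwise.
#'
#' @param mixture An [allele_mixture()].
#' @param cfg A [read_sim_config()].
#' @param sample_id Identifier prefixed to read names.
#' @return List with `pairs` (data frame `id`, `fwd_seq`, `fwd_qual`,
#'   `rev_seq`, `rev_qual`) and `truth` (data frame `id`, `label` of the
#'   source allele).
#' @export
simulate_sample <- function(mixture, cfg, sample_id = "sample") {
  stopifnot(inherits(mixture, "allele_mixture"), inherits(cfg, "read_sim_config"))
  n <- cfg$n_read_pairs
  empty <- data.frame(id = character(0), fwd_seq = character(0),
                      fwd_qual = character(0), rev_seq = character(0),
                      rev_qual = character(0), stringsAsFactors = FALSE)
  if (n == 0L) {
    return(list(pairs = empty,
                truth = data.frame(id = character(0), label = character(0),
                                   stringsAsFactors = FALSE)))
  }
  with_sim_seed(cfg$seed, {
    pick <- sample.int(nrow(mixture), n, replace = TRUE, prob = mixture$fraction)
    rl <- cfg$read_length
    alen <- nchar(mixture$sequence)[pick]
    fwd <- substr(mixture$sequence[pick], 1L, pmin(rl, alen))
    rev <- revcomp(substr(mixture$sequence[pick], pmax(1L, alen - rl + 1L), alen))
    fwd <- add_seq_errors(fwd, cfg$per_base_error)
    rev <- add_seq_errors(rev, cfg$per_base_error)
    ids <- sprintf("%s_r%06d", sample_id, seq_len(n))
    list(pairs = data.frame(id = ids,
                            fwd_seq = fwd,
                            fwd_qual = draw_quals(nchar(fwd), cfg),
                            rev_seq = rev,
                            rev_qual = draw_quals(nchar(rev), cfg),
                            stringsAsFactors = FALSE),
         truth = data.frame(id = ids, label = mixture$label[pick],
                            stringsAsFactors = FALSE))
  })
}

## Sparse substitution errors: most reads are untouched, so only reads with a
## non-zero Binomial error count are edited individually.
add_seq_errors <- function(seqs, p) {
  if (p <= 0) return(seqs)
  lens <- nchar(seqs)
  nerr <- rbinom(length(seqs), lens, p)
  for (i in which(nerr > 0L)) {
    pos <- sample.int(lens[i], nerr[i])
    for (p1 in pos) {
      cur <- substr(seqs[i], p1, p1)
      substr(seqs[i], p1, p1) <- sample(setdiff(DNA_BASES, cur), 1L)
    }
  }
  seqs
}

draw_quals <- function(lens, cfg) {
  hi <- intToUtf8(cfg$q_high + 33L)
  lo <- intToUtf8(cfg$q_low + 33L)
  quals <- strrep(hi, lens)
  if (cfg$p_lowq > 0) {
    nlow <- rbinom(length(lens), lens, cfg$p_lowq)
    for (i in which(nlow > 0L)) {
      for (p1 in sample.int(lens[i], nlow[i])) substr(quals[i], p1, p1) <- lo
    }
  }
  quals
}

#' Simulate a cohort of mosaic individuals
#'
#' Per-individual allele-class fractions are either drawn from a Dirichlet
#' distribution around the group mean (concentration parameter
#' `concentration`; larger = less mosaic variation between individuals) or
#' taken verbatim from a `fractions` matrix in the group spec. Each
#' individual receives its own allele sequences (fresh indel draws for the
#' erroneous/NHEJ classes) and its own read set.
#'
#' @param groups List of group specs: `list(label =, n =, mean_fracs = named
#'   vector over the five allele classes, concentration = )` or `list(label =,
#'   fractions = matrix/data.frame with the five class columns)`.
#' @param locus A [target_locus()].
#' @param edit An [edit_spec()].
#' @param cfg A [read_sim_config()] (its `seed` seeds the whole cohort; each
#'   individual gets an independent derived stream).
#' @return List with `samples` (list of per-individual lists: `sample_id`,
#'   `group`, `pairs`, `truth`) and `truth_fracs` (data frame of true class
#'   fractions per individual).
#' @export
simulate_cohort <- function(groups, locus, edit, cfg) {
  samples <- list()
  truth <- list()
  idx <- 0L
  for (gi in seq_along(groups)) {
    g <- groups[[gi]]
    fr <- if (!is.null(g$fractions)) {
      as.matrix(g$fractions)[, ALLELE_LABELS, drop = FALSE]
    } else {
      mu <- g$mean_fracs[ALLELE_LABELS]
      stopifnot(abs(sum(mu) - 1) < 1e-9)
      with_sim_seed(cfg$seed * 131L + gi, {
        draws <- vapply(seq_len(g$n), function(i) {
          a <- rgamma(length(mu), shape = pmax(g$concentration * mu, 1e-8))
          a / sum(a)
        }, numeric(length(mu)))
        t(draws)
      })
    }
    colnames(fr) <- ALLELE_LABELS
    for (i in seq_len(nrow(fr))) {
      idx <- idx + 1L
      sid <- sprintf("%s_ind%02d", g$label, i)
      ind_seed <- (cfg$seed * 7919L + idx * 104729L) %% .Machine$integer.max
      keep <- fr[i, ] > 0
      seqs <- vapply(ALLELE_LABELS[keep], function(lab) {
        make_allele(locus, edit, lab, seed = ind_seed + match(lab, ALLELE_LABELS))
      }, character(1))
      mix <- allele_mixture(ALLELE_LABELS[keep], unname(seqs),
                            unname(fr[i, keep] / sum(fr[i, keep])), locus)
      ind_cfg <- cfg
      ind_cfg$seed <- ind_seed
      sim <- simulate_sample(mix, ind_cfg, sample_id = sid)
      samples[[idx]] <- list(sample_id = sid, group = g$label,
                             pairs = sim$pairs, truth = sim$truth)
      truth[[idx]] <- data.frame(sample_id = sid, group = g$label,
                                 t(fr[i, ]), stringsAsFactors = FALSE)
    }
  }
  list(samples = samples, truth_fracs = do.call(rbind, truth))
}

#' Design a deterministic mosaic cohort with prescribed summary statistics
#'
#' Builds a per-individual allele-fraction table whose perfect-HDR column has
#' exactly the requested group mean and (optionally) maximum, with a skewed
#' mosaic-like spread: fixed top individuals, a linear ramp over a subset of
#' the rest, and unedited individuals at zero. Erroneous-HDR fractions are
#' allocated the same way to the most HDR-active individuals, each individual
#' carrying its erroneous allele on the 5' side of the edit except every
#' fourth, which carries it 3' (the polarity bias of sense-strand donors).
#' All non-zero allocations are at least `min_frac` so every simulated allele
#' can clear the read-support filter at realistic depth.
#'
#' @param n Number of individuals.
#' @param mean_perfect Target group mean perfect-HDR percentage.
#' @param tops Optional fixed top individual percentages (e.g. the group
#'   maximum).
#' @param mean_erroneous Target group mean erroneous-HDR percentage.
#' @param min_frac Smallest non-zero percentage allocated to any allele.
#' @param nhej_share Fraction of the non-HDR remainder given to NHEJ indel
#'   alleles (rest is wild type).
#' @return Data frame with columns `wild_type`, `perfect_hdr`,
#'   `erroneous_hdr_5p`, `erroneous_hdr_3p`, `nhej` (fractions summing to 1
#'   per row).
#' @export
design_cohort_fractions <- function(n, mean_perfect, tops = NULL,
                                    mean_erroneous = 2.5, min_frac = 2.5,
                                    nhej_share = 0.5) {
  tops <- as.numeric(tops %||% numeric(0))
  total <- n * mean_perfect
  rest_total <- total - sum(tops)
  if (rest_total < -1e-9) stop("tops exceed n * mean_perfect", call. = FALSE)
  max_allowed <- if (length(tops)) 0.95 * min(tops) else max(3 * mean_perfect, 4 * min_frac)
  perfect <- c(tops, ramp_alloc(rest_total, n - length(tops), min_frac, max_allowed))
  err_total <- n * mean_erroneous
  err_max <- max(2.5 * mean_erroneous, 2.2 * min_frac)
  err_by_rank <- ramp_alloc(err_total, n, min_frac, err_max)
  ## Give erroneous alleles to the most HDR-active individuals.
  err <- numeric(n)
  err[order(perfect, decreasing = TRUE)] <- err_by_rank
  side3 <- seq_len(n) %% 4L == 0L
  err5 <- ifelse(side3, 0, err)
  err3 <- ifelse(side3, err, 0)
  stopifnot(all(perfect + err <= 100 + 1e-9))
  remainder <- 100 - perfect - err
  nhej <- nhej_share * remainder
  wt <- remainder - nhej
  out <- data.frame(wild_type = wt, perfect_hdr = perfect,
                    erroneous_hdr_5p = err5, erroneous_hdr_3p = err3,
                    nhej = nhej) / 100
  stopifnot(abs(rowSums(out) - 1) < 1e-9)
  out
}

## Allocate `total` percentage points over n individuals: a linear ramp from
## `max_allowed`-bounded high values down to min_pos over k individuals,
## zeros elsewhere. Deterministic; mean is exact by construction.
ramp_alloc <- function(total, n, min_pos, max_allowed) {
  if (n == 0L) return(numeric(0))
  if (total < 1e-9) return(numeric(n))
  k_max <- min(n, floor(total / min_pos))
  if (k_max < 1L) stop("total too small for the minimum allele fraction", call. = FALSE)
  k <- max(1L, min(k_max, ceiling(2 * total / (max_allowed + min_pos))))
  h <- 2 * total / k - min_pos
  if (h > max_allowed + 1e-9 || k == 1L) {
    ## cannot respect the cap with a ramp; fall back to a uniform allocation
    k <- k_max
    vals <- rep(total / k, k)
  } else {
    vals <- seq(h, min_pos, length.out = k)
  }
  c(vals, numeric(n - k))
}

#' Write a simulated sample as a FASTQ pair
#'
#' Standard 4-line Phred+33 FASTQ via Biostrings.
#'
#' @param pairs Data frame as returned by [simulate_sample()]`$pairs`.
#' @param r1_path,r2_path Output paths for the forward/reverse reads.
#' @export
write_fastq_pair <- function(pairs, r1_path, r2_path) {
  write_one <- function(seqs, quals, ids, path) {
    x <- Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(seqs),
      Biostrings::PhredQuality(quals))
    names(x) <- ids
    Biostrings::writeQualityScaledXStringSet(x, path)
  }
  write_one(pairs$fwd_seq, pairs$fwd_qual, pairs$id, r1_path)
  write_one(pairs$rev_seq, pairs$rev_qual, pairs$id, r2_path)
  invisible(c(r1_path, r2_path))
}

#' Read a FASTQ pair into the package's read-pair table
#'
#' @param r1_path,r2_path FASTQ paths (optionally gzipped). Records are
#'   paired by position; ids are taken from R1.
#' @return Data frame `id`, `fwd_seq`, `fwd_qual`, `rev_seq`, `rev_qual`.
#' @export
read_fastq_pair <- function(r1_path, r2_path) {
  r1 <- Biostrings::readQualityScaledDNAStringSet(r1_path)
  r2 <- Biostrings::readQualityScaledDNAStringSet(r2_path)
  if (length(r1) != length(r2)) stop("R1/R2 record counts differ", call. = FALSE)
  data.frame(id = sub("\\s.*$", "", names(r1)),
             fwd_seq = as.character(r1),
             fwd_qual = as.character(Biostrings::quality(r1)),
             rev_seq = as.character(r2),
             rev_qual = as.character(Biostrings::quality(r2)),
             stringsAsFactors = FALSE, row.names = NULL)
}
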