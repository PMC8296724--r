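slc <- demo_preset("slc45a2", "flag_ki")
dnd <- demo_preset("dnd", "snr")

test_that("pairs demultiplex to the locus whose primers they carry", {
  loci <- list(slc$locus, dnd$locus)
  pairs <- rbind(pairs_from_templates(slc$locus$amplicon),
                 pairs_from_templates(dnd$locus$amplicon))
  # a read matching neither primer within tolerance
  noise <- pairs_from_templates(paste(rep("ACGT", 70), collapse = ""))
  pairs <- rbind(pairs, noise)
  dmx <- demultiplex_pairs(pairs, loci)
  expect_identical(unname(dmx$counts[["slc45a2"]]), 1L)
  expect_identical(unname(dmx$counts[["dnd"]]), 1L)
  expect_identical(unname(dmx$counts[["unassigned"]]), 1L)
  expect_true(startsWith(dmx$assigned$slc45a2$fwd_seq, "CAGATGTCCAGAGGCTGCTGCT"))
  expect_true(startsWith(dmx$assigned$dnd$fwd_seq, "GGGGAAAGGCTAGGGAGAGA"))
  # two mismatches in the primer are tolerated, three are not
  p2 <- pairs_from_templates(slc$locus$amplicon)
  substr(p2$fwd_seq, 3, 4) <- "TT"
  expect_identical(nrow(demultiplex_pairs(p2, loci)$assigned$slc45a2), 1L)
  substr(p2$fwd_seq, 6, 6) <- "C"
  expect_identical(unname(demultiplex_pairs(p2, loci)$counts[["unassigned"]]), 1L)
})

test_that("near-identical primer pairs are a configuration error", {
  twin <- slc$locus
  twin$name <- "twin"
  expect_error(demultiplex_pairs(pairs_from_templates(slc$locus$amplicon),
                                 list(slc$locus, twin)),
               "demultiplex tolerance")
})

test_that("length filter drops pairs with a mate below 100 bp, inclusive", {
  tpl <- slc$locus$amplicon
  pairs <- pairs_from_templates(rep(tpl, 3))
  pairs$fwd_seq[1] <- substr(pairs$fwd_seq[1], 1, 99)
  pairs$fwd_qual[1] <- substr(pairs$fwd_qual[1], 1, 99)
  pairs$rev_seq[2] <- substr(pairs$rev_seq[2], 1, 100)
  pairs$rev_qual[2] <- substr(pairs$rev_qual[2], 1, 100)
  fl <- filter_length(pairs, 100L)
  expect_identical(fl$dropped, 1L)
  expect_identical(fl$pairs$id, c("t0002", "t0003"))
})

test_that("merge accepts or rejects by the per-locus minimum overlap", {
  # 330-nt template with 250-nt reads -> 170-nt overlap
  set.seed(31)
  tpl <- paste(sample(c("A", "C", "G", "T"), 330, TRUE), collapse = "")
  pairs <- pairs_from_templates(tpl)
  ok150 <- merge_pairs(pairs, min_overlap = 150L)
  expect_identical(nrow(ok150$merged), 1L)
  expect_identical(ok150$merged$seq, tpl)
  ok200 <- merge_pairs(pairs, min_overlap = 200L)
  expect_identical(nrow(ok200$merged), 0L)
  expect_identical(nrow(ok200$failed), 1L)
  # fully overlapping identical mates
  short <- pairs_from_templates(substr(tpl, 1, 250))
  m <- merge_pairs(short, min_overlap = 150L)
  expect_identical(nchar(m$merged$seq), 250L)
  expect_identical(m$merged$seq, substr(tpl, 1, 250))
})

test_that("the 20% overlap mismatch rule is a hard boundary", {
  # 350-nt template: overlap region is template positions 101-250 (150 nt)
  set.seed(32)
  tpl <- paste(sample(c("A", "C", "G", "T"), 350, TRUE), collapse = "")
  flip <- function(b) chartr("ACGT", "TGCA", b)
  corrupt <- function(n_mm) {
    pairs <- pairs_from_templates(tpl)
    rev_rc <- revcomp(pairs$rev_seq)       # template 101..350
    for (k in seq_len(n_mm)) {             # corrupt overlap positions
      pos <- k                             # rev_rc position k = template 100+k
      substr(rev_rc, pos, pos) <- flip(substr(rev_rc, pos, pos))
    }
    pairs$rev_seq <- revcomp(rev_rc)
    pairs
  }
  expect_identical(nrow(merge_pairs(corrupt(30), 150L)$merged), 1L)  # 20.0%
  expect_identical(nrow(merge_pairs(corrupt(31), 150L)$merged), 0L)  # 20.7%
})

test_that("merge resolves disagreements to the higher-quality base", {
  set.seed(33)
  tpl <- paste(sample(c("A", "C", "G", "T"), 250, TRUE), collapse = "")
  pairs <- pairs_from_templates(tpl)                 # full 250-nt overlap
  # plant a disagreement at position 100: reverse read carries a G at high
  # quality, forward keeps the template base at low quality
  rev_rc <- revcomp(pairs$rev_seq)
  base_f <- substr(pairs$fwd_seq, 100, 100)
  base_r <- if (base_f == "G") "C" else "G"
  substr(rev_rc, 100, 100) <- base_r
  pairs$rev_seq <- revcomp(rev_rc)
  substr(pairs$fwd_qual, 100, 100) <- intToUtf8(10 + 33)
  m <- merge_pairs(pairs, 150L)
  expect_identical(substr(m$merged$seq, 100, 100), base_r)
  expect_identical(substr(m$merged$qual, 100, 100), intToUtf8(38 + 33))
  # same disagreement with equal qualities -> forward base wins
  pairs2 <- pairs_from_templates(tpl)
  rev_rc2 <- revcomp(pairs2$rev_seq)
  substr(rev_rc2, 100, 100) <- base_r
  pairs2$rev_seq <- revcomp(rev_rc2)
  m2 <- merge_pairs(pairs2, 150L)
  expect_identical(substr(m2$merged$seq, 100, 100), base_f)
})

test_that("rescue keeps every input pair exactly once", {
  tpl_good <- slc$locus$amplicon                        # assembles
  tpl_bad <- paste0(substr(tpl_good, 1, 250),
                    paste(rep("A", 180), collapse = ""))  # overlap too short
  pairs <- pairs_from_templates(c(tpl_good, tpl_good, tpl_bad))
  mg <- merge_pairs(pairs, 150L)
  out <- rescue_unassembled(mg$merged, mg$failed)
  expect_identical(nrow(out), 3L)
  expect_identical(sum(out$origin == "assembled"), 2L)
  expect_identical(sum(out$origin == "forward_only"), 1L)
  expect_identical(nchar(out$seq[out$origin == "forward_only"]), 250L)
  # degenerate cases
  all_good <- merge_pairs(pairs_from_templates(tpl_good), 150L)
  expect_identical(unique(rescue_unassembled(all_good$merged, all_good$failed)$origin),
                   "assembled")
  none <- merge_pairs(pairs_from_templates(tpl_bad), 260L)
  expect_identical(unique(rescue_unassembled(none$merged, none$failed)$origin),
                   "forward_only")
})

test_that("window extraction matches the printed window lengths", {
  reads <- data.frame(id = "r", seq = strrep("A", 250), qual = strrep("I", 250),
                      origin = "assembled", stringsAsFactors = FALSE)
  expect_identical(nchar(extract_window(reads, c(20L, 200L))$reads$window_seq), 181L)
  expect_identical(nchar(extract_window(reads, c(60L, 230L))$reads$window_seq), 171L)
  short <- data.frame(id = "s", seq = strrep("A", 150), qual = strrep("I", 150),
                      origin = "forward_only", stringsAsFactors = FALSE)
  ex <- extract_window(short, c(60L, 230L))
  expect_identical(nrow(ex$reads), 0L)
  expect_identical(ex$dropped, 1L)
  expect_error(extract_window(reads, c(200L, 20L)), "window")
})

test_that("quality masking converts sub-Q20 bases to N with a 5-N cap", {
  mk <- function(qs) {
    data.frame(id = "r", window_seq = strrep("A", length(qs)),
               window_qual = intToUtf8(qs + 33, multiple = FALSE),
               origin = "assembled", stringsAsFactors = FALSE)
  }
  clean <- mask_low_quality(mk(rep(40L, 20)))
  expect_identical(clean$reads$window_seq, strrep("A", 20))
  expect_identical(clean$reads$n_count, 0L)
  # boundary: quality exactly 20 is kept
  at20 <- mask_low_quality(mk(c(rep(40L, 19), 20L)))
  expect_identical(at20$reads$n_count, 0L)
  five <- mask_low_quality(mk(c(rep(19L, 5), rep(40L, 15))))
  expect_identical(five$reads$n_count, 5L)
  expect_identical(substr(five$reads$window_seq, 1, 6), "NNNNNA")
  expect_identical(nchar(five$reads$window_seq), 20L)
  six <- mask_low_quality(mk(c(rep(19L, 6), rep(40L, 14))))
  expect_identical(nrow(six$reads), 0L)
  expect_identical(six$dropped, 1L)
})

test_that("the per-sample ledger conserves every input pair", {
  mix <- allele_mixture(
    c("wild_type", "perfect_hdr", "nhej"),
    c(make_allele(dnd$locus, dnd$edit, "wild_type"),
      make_allele(dnd$locus, dnd$edit, "perfect_hdr"),
      make_allele(dnd$locus, dnd$edit, "nhej", seed = 8)),
    c(0.5, 0.3, 0.2), dnd$locus)
  sim <- simulate_sample(mix, read_sim_config(800, seed = 9, p_lowq = 0.02), "s")
  proc <- process_reads(sim$pairs, dnd$locus, min_overlap = dnd$min_overlap)
  led <- proc$ledger
  kept <- function(st) led$kept[led$stage == st]
  drop <- function(st) led$dropped[led$stage == st]
  expect_identical(kept("input"), 800L)
  expect_identical(kept("length_filter") + drop("length_filter"), kept("input"))
  expect_identical(kept("assembled") + kept("forward_only"), kept("length_filter"))
  expect_identical(kept("window") + drop("window"),
                   kept("assembled") + kept("forward_only"))
  expect_identical(kept("quality_mask") + drop("quality_mask"), kept("window"))
  expect_identical(nrow(proc$reads), kept("quality_mask"))
  expect_true(all(nchar(proc$reads$window_seq) == 171L))
  expect_true(all(proc$reads$n_count <= 5L))
})
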