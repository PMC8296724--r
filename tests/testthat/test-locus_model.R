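test_that("cut site sits 3 bp 5' of the PAM on either strand", {
  # plus strand: protospacer at 101-120, PAM 121-123 -> gap after 117
  set.seed(11)
  amp <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  substr(amp, 122, 123) <- "GG"
  plus <- target_locus("p", amp, substr(amp, 1, 10),
                       revcomp(substr(amp, 291, 300)), c(50, 250),
                       guide_rna(substr(amp, 101, 120), substr(amp, 121, 123),
                                 "+", 101))
  expect_identical(locate_cut_site(plus), 117L)

  # minus strand: protospacer rc occupies 101-120, PAM rc at 98-100 -> gap 103
  set.seed(12)
  amp2 <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  substr(amp2, 98, 99) <- "CC"   # revcomp(PAM) = CCN at 98-100
  minus <- target_locus("m", amp2, substr(amp2, 1, 10),
                        revcomp(substr(amp2, 291, 300)), c(50, 250),
                        guide_rna(revcomp(substr(amp2, 101, 120)),
                                  revcomp(substr(amp2, 98, 100)), "-", 101))
  expect_identical(locate_cut_site(minus), 103L)
})

test_that("reverse-complementing the amplicon mirrors the cut gap", {
  set.seed(13)
  amp <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  substr(amp, 122, 123) <- "GG"
  fwd_p <- substr(amp, 1, 10)
  rev_p <- revcomp(substr(amp, 291, 300))
  plus <- target_locus("p", amp, fwd_p, rev_p, c(50, 250),
                       guide_rna(substr(amp, 101, 120), substr(amp, 121, 123),
                                 "+", 101))
  len <- nchar(amp)
  # flip everything onto the reverse complement; the guide becomes a minus-
  # strand guide whose protospacer rc occupies len-120+1 .. len-101+1
  flipped <- target_locus("pr", revcomp(amp), rev_p, fwd_p,
                          c(len - 250 + 1, len - 50 + 1),
                          guide_rna(plus$guide$protospacer, plus$guide$pam,
                                    "-", len - 120 + 1))
  expect_identical(locate_cut_site(flipped), len - locate_cut_site(plus))
})

test_that("guide validation rejects a misplaced protospacer", {
  set.seed(14)
  amp <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  substr(amp, 122, 123) <- "GG"
  expect_error(
    target_locus("p", amp, substr(amp, 1, 10), revcomp(substr(amp, 291, 300)),
                 c(50, 250),
                 guide_rna(substr(amp, 101, 120), substr(amp, 121, 123),
                           "+", 102)),
    "protospacer")
})

test_that("asymmetric donor lengths follow the 90+36 arm rule", {
  ki <- demo_preset("slc45a2", "flag_ki")
  expect_identical(nchar(ki$donor$sequence), 90L + 27L + 36L)  # 153 nt
  snr <- demo_preset("dnd", "snr")
  expect_identical(nchar(snr$donor$sequence), 90L + 36L)       # 126 nt
})

test_that("donor arms are exact copies of the amplicon flanks", {
  ki <- demo_preset("slc45a2", "flag_ki")
  g <- locate_cut_site(ki$locus)
  d <- ki$donor
  expect_identical(substr(d$sequence, 1, d$arm5),
                   substr(ki$locus$amplicon, g - d$arm5 + 1, g))
  expect_identical(substr(d$sequence, d$arm5 + 28, nchar(d$sequence)),
                   substr(ki$locus$amplicon, g + 1, g + d$arm3))
  expect_identical(substr(d$sequence, d$arm5 + 1, d$arm5 + 27), FLAG_TAA_INSERT)
  # substitution donor: arms differ from the reference only at edited bases
  snr <- demo_preset("dnd", "snr")
  ref_span <- substr(snr$locus$amplicon, locate_cut_site(snr$locus) - 89,
                     locate_cut_site(snr$locus) + 36)
  expect_identical(hdramp:::hamming(snr$donor$sequence, ref_span), 3L)
})

test_that("antisense donor is the reverse complement of the sense donor", {
  p <- demo_preset("dnd", "snr")
  anti <- design_asymmetric_odn(p$locus, p$edit, polarity = "antisense")
  expect_identical(revcomp(anti$sequence), p$donor$sequence)
  expect_identical(revcomp(revcomp(anti$sequence)), anti$sequence)
})

test_that("swap_arms exchanges the long and short arm", {
  p <- demo_preset("dnd", "snr")
  sw <- design_asymmetric_odn(p$locus, p$edit, swap_arms = TRUE)
  expect_identical(sw$arm5, 36L)
  expect_identical(sw$arm3, 90L)
  expect_identical(nchar(sw$sequence), 126L)
})

test_that("degenerate edits and insufficient flanks are rejected", {
  expect_error(edit_spec("insertion"), "non-empty")
  expect_error(edit_spec("substitution",
                         substitutions = data.frame(pos = integer(0),
                                                    base = character(0))),
               "non-empty")
  p <- demo_preset("slc45a2", "flag_ki")
  # substitution that does not change the base
  b <- substr(p$locus$amplicon, 150, 150)
  expect_error(build_expected_alleles(
    p$locus, edit_spec("substitution",
                       substitutions = data.frame(pos = 150, base = b))),
    "reference base")
  expect_error(design_asymmetric_odn(p$locus, p$edit, arm_long = 150L),
               "insufficient flank")
})

test_that("expected alleles carry the edit and the anchoring core", {
  ki <- demo_preset("slc45a2", "flag_ki")
  e <- ki$expected
  expect_false(e$wt_window == e$hdr_window)
  expect_identical(nchar(e$wt_window), nchar(e$hdr_window))
  expect_true(grepl(e$core, e$hdr_window, fixed = TRUE))
  expect_false(grepl(e$core, e$wt_window, fixed = TRUE))
  expect_identical(e$core, FLAG_TAA_INSERT)
  # substitution core: 2*anchor_k + span centred on the edited bases
  snr <- demo_preset("dnd", "snr")
  expect_identical(nchar(snr$expected$core), 2L * 10L + 3L)
  # anchors overlap the core on both sides
  expect_identical(substr(e$anchor5, nchar(e$anchor5), nchar(e$anchor5)),
                   substr(e$core, 1, 1))
  expect_identical(substr(e$anchor3, 1, 1),
                   substr(e$core, nchar(e$core), nchar(e$core)))
})

test_that("applying and reverting an edit restores the reference window", {
  ki <- demo_preset("slc45a2", "flag_ki")
  g <- locate_cut_site(ki$locus)
  edited <- hdramp:::apply_edit(ki$locus, ki$edit)
  reverted <- paste0(substr(edited, 1, g),
                     substr(edited, g + 28, nchar(edited)))
  expect_identical(reverted, ki$locus$amplicon)
  snr <- demo_preset("dnd", "snr")
  edited2 <- hdramp:::apply_edit(snr$locus, snr$edit)
  for (i in seq_len(nrow(snr$edit$substitutions))) {
    p1 <- snr$edit$substitutions$pos[i]
    substr(edited2, p1, p1) <- substr(snr$locus$amplicon, p1, p1)
  }
  expect_identical(edited2, snr$locus$amplicon)
})

test_that("locus config round-trips through the YAML dialect", {
  cfg <- list(name = "dnd", amplicon = hdramp:::DEMO_AMPLICONS$dnd,
              fwd_primer = "GGGGAAAGGCTAGGGAGAGA",
              rev_primer = "CGGTTCTGTCCGCTGAAGTT",
              guide = list(protospacer = substr(hdramp:::DEMO_AMPLICONS$dnd, 129, 148),
                           pam = substr(hdramp:::DEMO_AMPLICONS$dnd, 149, 151),
                           strand = "+", start = 129L),
              window = list(start = 60L, end = 230L),
              edit = list(substitutions = list(list(pos = 146L, base = "G"),
                                               list(pos = 147L, base = "A"),
                                               list(pos = 148L, base = "G"))),
              donor = list(arm_long = 90L, arm_short = 36L, polarity = "sense"),
              min_overlap = 200L)
  built <- locus_from_config(cfg)
  ref <- demo_preset("dnd", "snr")
  expect_identical(built$locus$amplicon, ref$locus$amplicon)
  expect_identical(built$donor$sequence, ref$donor$sequence)
  expect_identical(built$expected$hdr_window, ref$expected$hdr_window)
  expect_identical(built$min_overlap, 200L)
})
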