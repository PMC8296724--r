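test_that("allele construction matches the outcome classes", {
  p <- demo_preset("dnd", "snr")
  expect_identical(make_allele(p$locus, p$edit, "wild_type"), p$locus$amplicon)
  perfect <- make_allele(p$locus, p$edit, "perfect_hdr")
  expect_identical(substr(perfect, 60, 230), p$expected$hdr_window)
  # erroneous alleles keep the intact core but break one flank
  for (i in 1:10) {
    e5 <- make_allele(p$locus, p$edit, "erroneous_hdr_5p", seed = i)
    cl <- classify_variant(substr(e5, 60, 230), p$expected)
    expect_identical(cl$label, "erroneous_hdr")
    expect_false(cl$perfect_5p)
    expect_true(cl$perfect_3p)
    e3 <- make_allele(p$locus, p$edit, "erroneous_hdr_3p", seed = i)
    cl3 <- classify_variant(substr(e3, 60, 230), p$expected)
    expect_identical(cl3$label, "erroneous_hdr")
    expect_true(cl3$perfect_5p)
    expect_false(cl3$perfect_3p)
    nh <- make_allele(p$locus, p$edit, "nhej", seed = i)
    expect_identical(classify_variant(substr(nh, 60, 230), p$expected)$label,
                     "other")
  }
})

test_that("the same seed reproduces the FASTQ byte-for-byte", {
  p <- demo_preset("slc45a2", "flag_ki")
  mix <- allele_mixture(c("wild_type", "perfect_hdr"),
                        c(make_allele(p$locus, p$edit, "wild_type"),
                          make_allele(p$locus, p$edit, "perfect_hdr")),
                        c(0.5, 0.5), p$locus)
  cfg <- read_sim_config(300, seed = 77, per_base_error = 0.01, p_lowq = 0.05)
  s1 <- simulate_sample(mix, cfg, "a")
  s2 <- simulate_sample(mix, cfg, "a")
  expect_identical(s1, s2)
  d <- withr::local_tempdir()
  write_fastq_pair(s1$pairs, file.path(d, "a_R1.fastq"), file.path(d, "a_R2.fastq"))
  write_fastq_pair(s2$pairs, file.path(d, "b_R1.fastq"), file.path(d, "b_R2.fastq"))
  expect_identical(readLines(file.path(d, "a_R1.fastq")),
                   readLines(file.path(d, "b_R1.fastq")))
  # and FASTQ round-trips through the reader
  back <- read_fastq_pair(file.path(d, "a_R1.fastq"), file.path(d, "a_R2.fastq"))
  expect_identical(back$fwd_seq, s1$pairs$fwd_seq)
  expect_identical(back$rev_qual, s1$pairs$rev_qual)
})

test_that("error-free wild-type reads reassemble the amplicon exactly", {
  p <- demo_preset("slc45a2", "flag_ki")
  mix <- allele_mixture("wild_type", p$locus$amplicon, 1, p$locus)
  cfg <- read_sim_config(50, per_base_error = 0, p_lowq = 0, seed = 3)
  sim <- simulate_sample(mix, cfg)
  mg <- merge_pairs(sim$pairs, p$min_overlap)
  expect_identical(nrow(mg$failed), 0L)
  expect_true(all(mg$merged$seq == p$locus$amplicon))
})

test_that("an empty simulation yields empty FASTQ and truth", {
  p <- demo_preset("slc45a2", "flag_ki")
  mix <- allele_mixture("wild_type", p$locus$amplicon, 1, p$locus)
  sim <- simulate_sample(mix, read_sim_config(0, seed = 1))
  expect_identical(nrow(sim$pairs), 0L)
  expect_identical(nrow(sim$truth), 0L)
})

test_that("with no errors the recovered class fractions equal the draw exactly", {
  p <- demo_preset("dnd", "snr")
  mix <- allele_mixture(
    c("wild_type", "perfect_hdr", "erroneous_hdr_5p"),
    c(make_allele(p$locus, p$edit, "wild_type"),
      make_allele(p$locus, p$edit, "perfect_hdr"),
      make_allele(p$locus, p$edit, "erroneous_hdr_5p", seed = 4)),
    c(0.85, 0.10, 0.05), p$locus)
  cfg <- read_sim_config(400, per_base_error = 0, p_lowq = 0, seed = 21)
  sim <- simulate_sample(mix, cfg, "s")
  res <- process_sample(sim$pairs, p, "s", "g", params = list(min_reads = 1L))
  drawn <- table(factor(sim$truth$label,
                        c("wild_type", "perfect_hdr", "erroneous_hdr_5p")))
  expect_equal(res$summary$pct_perfect, 100 * drawn[["perfect_hdr"]] / 400)
  expect_equal(res$summary$pct_wild_type, 100 * drawn[["wild_type"]] / 400)
  expect_equal(res$summary$pct_erroneous, 100 * drawn[["erroneous_hdr_5p"]] / 400)
  expect_equal(res$summary$pct_other, 0)
})

test_that("designed cohort fractions hit the requested mean and maximum", {
  fr <- design_cohort_fractions(30, 13.6, tops = 36.7, mean_erroneous = 2.0)
  expect_equal(mean(fr$perfect_hdr) * 100, 13.6, tolerance = 1e-9)
  expect_equal(max(fr$perfect_hdr) * 100, 36.7, tolerance = 1e-9)
  err <- fr$erroneous_hdr_5p + fr$erroneous_hdr_3p
  expect_equal(mean(err) * 100, 2.0, tolerance = 1e-9)
  expect_true(all(abs(rowSums(fr) - 1) < 1e-9))
  # non-zero allele fractions stay above the support-filter floor
  vals <- unlist(fr) * 100
  expect_true(all(vals[vals > 0] >= 2.4))
  # two fixed top individuals
  fr2 <- design_cohort_fractions(24, 7.4, tops = c(49.1, 47.4),
                                 mean_erroneous = 3.0)
  expect_equal(sort(fr2$perfect_hdr, decreasing = TRUE)[1:2] * 100,
               c(49.1, 47.4), tolerance = 1e-9)
  expect_equal(mean(fr2$perfect_hdr) * 100, 7.4, tolerance = 1e-9)
})

test_that("huge Dirichlet concentration collapses to the group means", {
  p <- demo_preset("slc45a2", "flag_ki")
  mu <- c(wild_type = 0.5, perfect_hdr = 0.25, erroneous_hdr_5p = 0.05,
          erroneous_hdr_3p = 0.05, nhej = 0.15)
  cfg <- read_sim_config(10, seed = 5)
  sim <- simulate_cohort(list(list(label = "g", n = 4L, mean_fracs = mu,
                                   concentration = 1e9)),
                         p$locus, p$edit, cfg)
  fr <- as.matrix(sim$truth_fracs[, names(mu)])
  expect_true(all(abs(sweep(fr, 2, mu)) < 1e-3))
})

test_that("identical group specs give a calibrated Mann-Whitney null", {
  p <- demo_preset("slc45a2", "flag_ki")
  mu <- c(wild_type = 0.6, perfect_hdr = 0.2, erroneous_hdr_5p = 0,
          erroneous_hdr_3p = 0, nhej = 0.2)
  spec <- list(label = "g", n = 8L, mean_fracs = mu, concentration = 25)
  reject <- 0L
  for (r in 1:200) {
    cfg <- read_sim_config(0, seed = 1000L + r)
    tf <- simulate_cohort(list(modifyList(spec, list(label = "g1")),
                               modifyList(spec, list(label = "g2"))),
                          p$locus, p$edit, cfg)$truth_fracs
    g1 <- tf$perfect_hdr[tf$group == "g1"]
    g2 <- tf$perfect_hdr[tf$group == "g2"]
    if (mann_whitney(g1, g2)$p_value < 0.05) reject <- reject + 1L
  }
  expect_lt(reject / 200, 0.10)
})
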