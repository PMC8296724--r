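---
title: "Quantifying CRISPR/Cas9 HDR outcomes from amplicon deep sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying CRISPR/Cas9 HDR outcomes from amplicon deep sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdramp)
```

## The problem

Microinjecting Cas9, a guide RNA and a single-stranded oligodeoxynucleotide
(ssODN) donor into a fertilised egg produces a mosaic founder (F0) animal:
different cells carry different repair outcomes of the same double-strand
break. Deep sequencing of a PCR amplicon spanning the cut site turns each
animal into a mixture of allele read classes:

* **perfect HDR** — reads matching the entire expected edited sequence;
* **erroneous HDR** — reads carrying the correct insert or replaced bases
  but with mismatches or indels in a flanking homology region;
* **wild type** — reads matching the unedited reference;
* **other** — everything else, mostly NHEJ indels at the cut site.

`hdramp` implements the complete path from raw paired-end FASTQ to
per-individual class percentages and group-level nonparametric statistics,
together with a truth-known simulator of mosaic founders so that every stage
can be validated without sequencing data.

## Locus model and asymmetric donor design

A `target_locus` holds the amplicon (sense strand, starting at the forward
gene-specific primer), both primers, the analysis window and the guide.
SpCas9 cuts bluntly 3 bp 5′ of the PAM; `locate_cut_site()` reports the cut
as a 0-based gap index on the sense strand (for minus-strand guides the gap
is mirrored into sense coordinates). Windows are 1-based inclusive positions
on the assembled read; because reads start at the forward primer, read and
amplicon coordinates coincide for reads without upstream indels. These two
conventions are used package-wide.

`design_asymmetric_odn()` builds the donor by copying `arm_long` (default
90) bases 5′ of the cut and `arm_short` (default 36) bases 3′ of it around
the edit. Which physical arm is long is not uniquely determined by the
assay constants we mirror, so the long-arm-5′ choice is the default and a
`swap_arms` flag preserves the other reading; `polarity = "antisense"`
returns the reverse complement. Two edit kinds are supported: an insertion
placed at the cut (the shipped default insert is a standard DYKDDDDK FLAG
encoding plus a TAA stop, `FLAG_TAA_INSERT`, as the experimentally used DNA
sequence is not public) and a set of base substitutions (single nucleotide
replacement, SNR).

`build_expected_alleles()` derives the classification references. A design
point worth spelling out: since the analysis window is taken at fixed read
positions, *every* windowed read has the same length, so the edited
reference window `hdr_window` is defined as the edited amplicon sliced at
the same window positions — for an insertion it contains the insert and
correspondingly less 3′ flank. The `core` is the inserted segment (or, for
substitutions, the replaced bases with `anchor_k` = 10 bases of context on
each side — long enough to be unique in a 200-nt window, short enough to
survive nearby indels). The core must not occur in the wild-type window;
construction fails otherwise.

## Read processing

The processing order is fixed: demultiplex → length filter → overlap merge
→ forward-read rescue → window extraction → quality masking, and a ledger
accounts for every input pair. Defaults are the assay constants:

| rule | default |
|---|---|
| demultiplex primer mismatch tolerance | ≤ 2 substitutions per primer, no indels |
| minimum mate length | 100 bp (per mate, inclusive) |
| minimum assembly overlap | 150 bp (`slc45a2`-type) / 200 bp (`dnd`-type) |
| maximum overlap mismatch fraction | 0.20 (inclusive) |
| masking threshold | Phred < 20 → N |
| maximum Ns per windowed read | 5 |

Merging slides the reverse-complemented reverse read over the forward read
without gaps; among all overlaps of at least the minimum length, the
placement with the most matching bases wins (ties go to the longer overlap,
then the smaller offset). Disagreements resolve to the higher-quality base,
forward winning quality ties; merged qualities are the per-position
maximum. Pairs that fail assembly are not discarded: their forward mate
passes through with its own qualities. Masking runs after window
extraction, so the 5-N budget counts only windowed bases; whether the
original analysis ordered these two steps the same way is not recorded, so
the order is fixed here and documented.

## Variant calling

Windowed, masked reads collapse to variants (identical strings), and
variants that differ only where one of them is masked are then grouped:
a merge is allowed when no position carries two different informative bases
and at most 5 positions have an N on exactly one side. Pairwise
N-compatibility is not transitive, so the package fixes a deterministic
convention: variants are visited in descending read count (ties
lexicographic), each joins the first cluster whose consensus it is
compatible with (the consensus fills in as members contribute informative
bases), and clusters are re-merged under the same rule until nothing
changes. The representative is the member with the fewest Ns (ties: higher
read count, then lexicographic). Only variants with at least 100 supporting
reads are retained, and the retained total is the per-sample percentage
denominator. A sample in which no variant survives is flagged, not fatal.

## Classification and junction scoring

The cascade is total and deterministic: perfect HDR (N-compatibly equal to
`hdr_window`), else wild type (equal to `wt_window`), else erroneous HDR
(the core occurs N-compatibly as a substring), else other. N is a wildcard
throughout — masked bases encode low quality, not mismatch. Perfect HDR is
checked before wild type; the two references differ inside the window by
construction, and erroneous HDR must not shadow perfect HDR.

For HDR variants the junctions are scored separately: the 5′ side is
perfect when the variant up to the end of the core reproduces the edited
reference in register from the window start; the 3′ side is perfect when
the variant from the core onwards reproduces the edited reference
contiguously (using reference sequence past the window end when an upstream
deletion shifted the read). This substring/prefix/suffix formulation — an
exact, alignment-free operationalisation of "correct insert with a perfect
5′/3′ side" — is deliberately oracle-checkable: the test suite compares it
exhaustively against a brute-force reference on every sequence within two
edit operations of either reference window. One consequence to be aware
of: a deletion at the extreme 3′ end of the window is indistinguishable
from a shorter read, so such variants score a perfect 3′ junction.

Side percentages use the same retained-read denominator as the class
percentages (rather than HDR reads only), so junction plots are comparable
across samples; the alternative denominator is a documented open choice.

## Synthetic mosaic founders

`simulate_sample()` draws each read pair's source allele multinomially from
an `allele_mixture`, reads 2 × 250 bases from the allele ends (MiSeq-like,
configurable), applies independent per-base substitution errors (default
0.001) and assigns each base a low quality (default Q12, probability 0.002)
or a high quality (Q38). Erroneous-HDR alleles carry the exact edit plus a
uniform 1–10 bp indel strictly on one side of the core inside the window;
NHEJ alleles carry a uniform 1–15 bp indel at the cut without donor
sequence. Uniform indel sizes are the least-assumption choice; no empirical
indel spectrum is modelled. The simulator does **not** model PCR
duplicates, chimeras, position-dependent MiSeq error profiles or adapter
read-through — passing tests show the analysis rules are implemented
correctly and recover known mixtures, not that real MiSeq artefacts are
handled.

Cohorts come in two flavours. `simulate_cohort()` draws per-individual
class fractions from a Dirichlet around group means — the single
concentration knob stands in for unknown true inter-embryo mosaicism
distributions, and its defaults are placeholders, not claims.
`design_cohort_fractions()` instead builds a deterministic per-individual
table with an exact group mean and maximum and a skewed, mosaic-like
spread (a fixed top individual, a linear ramp over part of the cohort,
unedited individuals at zero). It exists because the published
per-individual efficiency table is not redistributable here: the printed
group summaries serve as *inputs* to a synthetic stand-in cohort, and the
pipeline's job is to recover them from raw simulated reads. All non-zero
allele fractions are kept at ≥ 2.5% so that, at the package's standard
simulation depth of 5000–6000 read pairs per individual, every designed
allele clears the 100-read support filter with margin; reads are cheap in
simulation and this depth keeps recovery error per individual well under
one percentage point.

## Group statistics

Per-individual percentages are compared nonparametrically, mirroring
standard practice for such cohorts: D'Agostino–Pearson K² to screen
normality (implemented from the published skewness/kurtosis
transformations and verified to machine precision against an independent
reference implementation; undefined below n = 8), Kruskal–Wallis with
tie-corrected H for three or more groups followed by Dunn's z-tests on the
pooled ranks with Bonferroni family-wise adjustment (configurable) and a
compact letter display (groups share a letter exactly when their adjusted
p ≥ α), Mann–Whitney for two groups and the paired Wilcoxon signed-rank
test for within-individual 5′-vs-3′ junction comparisons. Zero paired
differences are dropped (classic convention). Exact small-sample
distributions are used when tie-free and small (n·m ≤ 10 000 for
Mann–Whitney, ≤ 25 non-zero pairs for Wilcoxon); otherwise the
continuity-corrected normal approximation, which still returns exactly
p = 1 for identical groups. Enumeration of the full U distribution at
n = m = 8 shows the two branches agree within 0.011 in absolute p, the gap
peaking in the extreme tail.

## Worked example

```{r example, eval = FALSE}
p <- demo_preset("dnd", "snr")       # printed primers/window/overlap,
                                     # synthetic stand-in amplicon interior
mix <- allele_mixture(
  c("perfect_hdr", "wild_type"),
  c(make_allele(p$locus, p$edit, "perfect_hdr"),
    make_allele(p$locus, p$edit, "wild_type")),
  c(0.592, 0.408), p$locus)
sim <- simulate_sample(mix, read_sim_config(20000, seed = 42), "embryo1")
res <- process_sample(sim$pairs, p, "embryo1", "dnd 1.5uM")
res$summary$pct_perfect      # ~59.2 (the simulated truth)
```

A complete on-disk run — FASTQ pairs, sample sheet, YAML configuration —
is produced by `make_demo_fixtures()` and consumed by `run_pipeline()`,
which returns per-sample summaries, per-group aggregates (mean, sample SD,
SEM, max, n), the statistics above and a read-accounting ledger.

## Numerical conventions and limitations

* Coordinates: 1-based inclusive windows, 0-based cut gaps; documented in
  the locus-model help and used consistently.
* All thresholds are inclusive at their printed boundary (a 100-bp mate, a
  20.0% mismatch overlap, a Q20 base and a 100-read variant all pass).
* Merge, N-merge and representative tie-breaks are deterministic and
  documented; rerunning any pipeline with the same configuration and seed
  reproduces the report exactly.
* Gapped overlap merging, adapter trimming, quality recalibration,
  error-model denoising, donor concatemer detection and structural
  variants are out of scope.
* The demo amplicon interiors and the FLAG/SNR edit bases are synthetic
  stand-ins (the true sequences are not public); every quantitative claim
  in the package's tests therefore concerns pipeline behaviour on
  simulated data, not re-analysis of the original reads.
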