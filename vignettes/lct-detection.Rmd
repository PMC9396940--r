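---
title: "Detecting and characterizing L1 antisense promoter chimeric transcripts"
author: "lctscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and characterizing L1 antisense promoter chimeric transcripts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lctscape)
```

## The model

Recent LINE-1 retrotransposons (subfamilies L1PA1/L1Hs through L1PA8)
carry an antisense promoter (L1-ASP) in their 5' UTR, with initiation
hotspots near consensus positions +200 and +450. An active L1-ASP
transcribes outward across the element's 5' boundary into flanking
unique sequence, producing an L1 chimeric transcript (LCT). In a
stranded paired-end library made from total RNA, an LCT leaves a
characteristic footprint: the transcript-sense mate of a junction
fragment matches the L1 5' UTR antisense to the element, while its
partner aligns to unique sequence just outside the element's 5' end.
`lctscape` detects that footprint, clusters the supporting pairs into
loci, and layers on the classifications and statistics used to
characterize the landscape: splice status, genic context, TSS mapping
from long reads, effect-size-based deregulation prediction, qAMP
methylation indices, and CNV/chromatin correlates.

### Reference construction

ASP competence is decided on the RepeatMasker consensus interval: an
element is kept when its aligned consensus start lies strictly below
400 bp and its consensus end strictly above 600 bp, so the
promoter-bearing portion of the 5' UTR survives in the copy. The UCSC
rmsk dialect swaps the roles of `repStart` and `repLeft` on the minus
strand; the parser normalises this at the boundary, reading the
consensus 5' offset from `repStart` on `+` rows and from `|repLeft|`
on `-` rows. A compound filter applied to both fields only makes sense
under this normalisation, which is why it is fixed at parse time rather
than left to the caller. All internal coordinates are 0-based
half-open; rmsk and BED enter as 0-based, GTF as 1-based closed,
converted at the I/O boundary. Elements shorter than the 500 bp
reference window are kept and flagged truncated — the ASP filter
already guarantees at least ~200 bp of alignable 5' UTR.

### Chimera detection

Matching is gapless with substitutions only: the selection criterion is
a match of at least 50 bp tolerating one mismatch (a SNP allowance),
not an alignment score, so an aligner with gap penalties would change
the semantics. The matcher is a seed-and-extend search in C++: any
qualifying window of length `min_len` with at most `max_mm`
substitutions must contain an exact k-mer with
`k = floor((min_len - max_mm) / (max_mm + 1))` (24 for the defaults),
so an exact k-mer index over the references finds every qualifying
diagonal, which is then scanned with a two-pointer window. Ties are
broken deterministically: longest, fewest mismatches, lowest element
id, sense before antisense.

When a read alignment table is available — the simulator's truth
alignments, or a BAM reduced to a table — the element of record for a
pair is the element overlapping the L1-side mate's alignment (largest
overlap on ties), and the sequence matcher acts as the L1-evidence
gate. This was a genuinely open design point: pure best-match
assignment is also implemented (and is the behaviour of
`match_read_to_l1()` standalone), but with realistic within-subfamily
copy divergence two L1 copies are frequently identical across a 100 bp
window, and sequence-only assignment with a lexicographic tie-break
would misplace a small fraction of reads onto distant copies. Those
misplacements either vanish against the 50 kb insert bound or, rarely,
fabricate a locus; anchoring on the mate's placement removes both
failure modes and mirrors how chimeras are actually located in real
pipelines (by genomic alignment of the pair).

The pair filters record a reason for every rejection —
`same_orientation`, `no_5utr`, `insert_undefined` (mates on different
chromosomes), `insert_too_large` — so the accounting
`candidates = retained + rejections` is conserved at every stage and
surfaces in the pipeline's JSON summary. The insert bound is inclusive
at exactly 50 kb, and deliberately loose so spliced chimeras survive.
Clustering merges unique-side intervals per element and transcript
strand when they overlap or lie within `merge_gap` of each other;
300 bp — roughly the upper bound of the library insert (280–340 bp) —
is the default, exposed as a parameter, since the exact concatenation
rule of upstream tools is not standardised.

The locus geometry drives the splice classifier, so its conventions
matter: `r1r2_distance` is measured along the transcription direction,
from the 5'-most end of the L1-side alignments to the start of the
merged unique interval; zero or negative values mean juxtaposition or
overlap. `total_size` is the outermost genomic span of the locus.

### Splice, TSS and polyA classification

A locus is spliced when any one of three rules fires: distance > 500 bp
(continuous transcription cannot bridge it at this insert size), span
> 1000 bp *and* unique sequence > 700 bp (the parenthetical about very
large unique sequence is read as part of the rule, making it a
conjunction), or a splice junction within ±200 bp of the element start.
A distance of 200–499 bp with a span of 600–999 bp is undetermined.
Precedence is spliced > undetermined > unspliced, and rule evaluation
is order-independent. The rules are silent about distances of 1–199 bp
combined with spans of 600–999 bp; such loci are called unspliced and
flagged (`gray_zone`) rather than silently absorbed, since guessing an
intent here would be invention.

Walking-PCR patterns map each validated chimera's TSS to the +450
region (common and downstream primers amplify, upstream does not), the
+200 region (only the common primer amplifies), or an upstream
initiation (`NO_LCT`). Any amplification with the upstream primer is
read as initiation beyond both ASP regions, including the combination
(common+, downstream−, upstream+) that the assay itself should not
produce. The polyA classifier reads the three reverse-transcription
conditions: oligo-dT amplification means polyadenylated; oligo-dT
failure with polyU-tailing rescue means non-polyadenylated; failure of
both is undetermined because a long transcript can defeat full-length
reverse transcription. The bounds it reports — confirmed non-polyA
versus all oligo-dT failures — bracket the true non-polyA count.

Long-read TSS mapping keeps alignments with MapQ ≥ 30 that overlap an
LCT-producing element antisense and cross its 5' boundary, and
repositions each read's 5' end as a genomic distance from the element's
strand-aware 5' edge (not a consensus position — copies are truncated
by varying amounts, and the genomic offset is what the heatmap and
window fractions use). The 0–500 and 0–900 bp summary windows are
inclusive at their upper bound; undetected elements are reported
separately rather than entering the denominators.

### Expression statistics

Relative expression follows the efficiency-corrected ratio model with
the geometric mean of TBP, RPL13A and PPIA as the normaliser;
replicates are averaged on the Ct scale. Group comparisons use
two-sided Mann–Whitney tests — exact by enumeration when both groups
have at most eight observations and no ties, the tie-corrected normal
approximation otherwise — with Holm's step-down correction across the
locus family.

Deregulation prediction uses Hedges' g with the small-sample factor
`J = 1 - 3/(4(n1+n2) - 9)`. The orientation is fixed as control minus
tumor, so tumor overexpression gives negative g and the call mapping is
`up` ⟺ g < −cutoff, `down` ⟺ g > +cutoff, both strict. This sign
convention is stated prominently because nothing in the downstream
arithmetic would catch a flip. g is computed on raw supporting-read
counts by default; depth normalisation is the caller's responsibility
if libraries differ grossly. Cutoff calibration against qPCR-derived
truth reports the full sensitivity/specificity table and selects the
Youden-optimal cutoff (ties toward the smaller value) — "best
compromise" needed an operational definition, and Youden's J is the
conventional one, but the table is always emitted so a cutoff can be
fixed by eye instead. Sensitivity is direction-matched: a locus truly
up-regulated but called down counts as a miss, which is the stricter
reading. Host-gene comparisons report raw-scale medians and a Welch
t-test on `log2(fpkm + 1)`; the transform is configurable and defaults
to the variance-stabilising choice.

### Methylation and chromatin

The qAMP index converts ΔCt = Ct(enzyme) − Ct(sham) into a surviving
template fraction 2^(−ΔCt). Methylation protects against HhaI and
HpaII, so the fraction estimates methylation directly; McrBC cuts
methylated DNA, so methylation is 1 − 2^(−ΔCt). The index averages the
three estimates on a 0–100 scale (and also emits them separately, since
reporting conventions differ). Negative ΔCt is clamped to zero —
measurement noise, not biology — and `Ct = Inf` encodes no
amplification, which makes the index exact at the fully (un)methylated
limits. Primer efficiency below 1.85 triggers a validation warning, not
a failure.

The chromatin metaprofile is a scale-regions computation: 1000 bp
flanks taken as-is, the element body rescaled to 1000 bp by
nearest-neighbour per-base resampling, everything oriented 5'→3' of the
element, averaged in 10 bp bins (the window sizes are the conventional
ones; the bin width is the customary default for this resolution).
Positions without track coverage count as zero, and all-zero rows are
dropped when `skip_zeros` is set, matching the usual treatment of
unmappable regions.

## The synthetic study

The generator is first-class, tested code, and its defaults are the
study conditions the rest of the package is validated under:

- 11 samples in two groups (3 control, 8 tumor), the design of a small
  tissue cohort; per-group planted fold changes with standardized
  effect size 2 for deregulated loci (16.2% down, 5.8% up by default).
- L1 copies from a seeded per-subfamily consensus ladder: consensus
  stubs are pseudo-random (no licensed consensus sequences needed), and
  per-copy divergence grows with subfamily age (1% for L1PA1 up to 8%
  for L1PA8), emulating the mappability gradient between young and old
  subfamilies. 35% of copies are 5'-truncated past the ASP and 5% lose
  the consensus-end condition, so both arms of the filter are
  exercised.
- LCT geometry: for a plus-strand element the unique exon lies
  genomically upstream of the element start (ASP transcription exits
  the 5' end), mirrored for minus-strand elements. Spliced LCTs (2.9%
  by default) get a single donor–acceptor gap of 600–2000 bp.
  TSS choices are weighted 60/40 between the +450 and +200 consensus
  positions, falling back to +450 when truncation removed +200.
- Libraries: 280–340 bp inserts, 100 bp reads, read 1 carrying the
  transcript-sense fragment end (the strandedness convention is
  explicit and configurable because chemistry kits differ). Host-gene
  exons splice around planted repeats, so gene reads never produce L1
  matches and the planted-truth closure (precision 100%) is a property
  of the biology being simulated, not an accident.
- qPCR/qAMP: every reported Ct is the mean of three technical wells
  with per-well noise `ct_noise_sd` (0.1 cycles by default). Technical
  replication is the standard measurement convention for plate qPCR and
  is what makes the 2^(−ΔCt) inversion robust: the exponential model
  amplifies Ct noise sharply at high methylation, and single-well
  readouts would not keep the index within a 5-point band reliably.
- Coverage: an H3K36me3-like track with background 1, +3 over
  LCT-producing element bodies, per-bin Gaussian noise — enough to
  validate the metaprofile contrast, not a chromatin model.

What the simulator does **not** emulate — and therefore what passing
tests do not show about real data: base-quality-dependent errors,
indels and PCR duplicates; multi-mapping ambiguity beyond the planted
subfamily homology; expression-level distributions with realistic
dispersion; sample contamination or batch effects; genome
rearrangements that displace L1 copies relative to the reference. On
real libraries the matcher's mismatch budget and the alignment-table
contract are the load-bearing interfaces: reads should be aligned with
a spliced aligner and reduced to the normalised table before entering
`find_chimeras()`.

## Numerical choices and degenerate inputs

- Boundaries are exactly as stated everywhere: match length ≥ 50,
  unique length ≥ 30, insert ≤ 50 000 inclusive, MapQ ≥ 30, TSS
  windows inclusive at 500/900, consensus filter strict at 400/600,
  deregulation cutoffs strict.
- Degenerate statistics: all-tied groups give p = 1; zero pooled SD
  gives g = 0 (equal means) or a flagged ±Inf; constant vectors have
  undefined Spearman rho and are flagged rather than coerced.
- The binomial enrichment test is the exact two-sided tail sum
  (outcomes no more likely than the observed one).
- Metaprofile bins must divide the window sizes exactly; violating
  this is an error, not a silent truncation.
- Determinism: a fixed simulator seed makes every output byte-identical
  across runs; stage seeds are derived from it by fixed offsets so
  stages can be rerun independently.

## Problem sizes used in the test suite

The planted-recovery property runs on a 6 Mb genome with 440 L1 copies
and ~280 planted LCTs at error rate 0, two samples per group; the
statistical properties use 1000 random samples (effect-size oracle),
500 replicates at n = 8 per group (effect recovery within two standard
errors), and 1000 simulated assays (qAMP robustness). These sizes make
the suite complete in a few minutes on one core while keeping every
probabilistic bound comfortably away from its threshold.

## Known limitations

- The built-in matcher is the tested reference path; it is not a
  replacement for a spliced aligner on real data, and unique-side
  placement always comes from the mate's alignment.
- Expression counts are raw supporting-read counts; no size-factor or
  negative-binomial machinery is provided, by design.
- The walking and polyA classifiers interpret binary amplification
  calls; they do not model partial amplification or primer failure
  beyond the unevaluable flag.
- Somatic L1 insertions absent from the reference are out of scope: a
  tumor-specific copy will surface, at best, as reads assigned to its
  nearest reference relative.
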