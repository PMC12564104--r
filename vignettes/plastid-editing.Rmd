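---
title: "Detecting plastid RNA editing from strand-specific RNA-seq: methods and design"
author: "plastedit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting plastid RNA editing from strand-specific RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Plant plastids post-transcriptionally edit specific cytidines to uridines
(and, rarely, uridines to cytidines) in their transcripts. Finding these
sites from RNA-seq means calling RNA-DNA differences against the sample's
own plastome, which is dominated not by biology but by technical artifacts:
misaligned reads near splice junctions, residual second-strand cDNA in dUTP
libraries, reverse-transcriptase misincorporation across modified rRNA
bases, and occasional strand misassignment by the caller. `plastedit`
implements the whole discovery pipeline — strand-aware candidate calling,
a four-class artifact filter, codon-level annotation, and cross-replicate
synthesis into a high-confidence set — together with a synthetic-data
generator that reproduces the signal and artifact structure at desk scale,
so every stage is testable against a known truth.

## Calling model

Input is a per-base, per-strand pileup for each experiment (sample x
library strategy): counts of A/C/G/T in plastome-forward orientation with
the transcript strand assigned under the dUTP/RF convention (mate 1
antisense, mate 2 sense). A candidate variant at a position/strand is the
highest-count non-reference base, emitted when

* variant-supporting reads >= 3 (strand-specific), and
* variant allele fraction (VAF) >= 10%, with VAF = variant reads divided by
  the total strand depth over all four bases.

Substitutions are always expressed in transcript orientation: on the minus
strand the reference base and the counts are complemented, so a genuine
edit reads C>U on the coding strand no matter which strand the gene lies
on. Multi-allelic records report the major alternative with a flag. A
relaxed query exposes sub-threshold evidence (down to a single read), which
the reproducibility stage uses to distinguish "present at 5–9% editing"
from truly absent.

## The four artifact classes

All screens set flags; nothing is deleted. Final exclusion happens only
when the high-confidence set is derived, which keeps every decision
auditable in the classified-calls table.

1. **Splice-junction misalignment** (`flag_junction`): any variant within
   10 bp (default, tunable) of an exon–intron boundary. No junction width
   is canonical in the literature; 10 bp covers the soft-clip/anchor
   artifacts seen with spliced aligners while staying far smaller than a
   typical exon.
2. **dUTP second-strand carryover** (`flag_carryover`): an opposite-strand
   record whose substitution is the base-complement of a coding-strand call
   at the same position (G>A mirroring C>U) and whose VAF is at most 10% of
   the coding-strand VAF. Observed carryover sits orders of magnitude lower
   (roughly 1/2840 to 1/63 of the edited signal), so the 0.10 ceiling
   brackets the real range with margin while never touching the coding
   call. Because carryover is usually sub-threshold, the classifier first
   materializes the complementary opposite-strand counts straight from the
   pileups (`augment_with_opposite()`); relying on the major-alt relaxed
   query alone would occasionally hide a one-read carryover behind an
   unrelated error base.
3. **rRNA modification misincorporation** (`flag_rrna`): everything inside
   annotated rRNA loci. These regions show a broad, noncanonical
   substitution spectrum (transitions dominating, C>U a small minority)
   consistent with RT misreading modified bases, so all rRNA-region calls
   are excluded from the final set — including canonical-looking C>U there.
   The spectrum summary table reports the rRNA versus non-rRNA substitution
   spectra so this behaviour is visible per run.
4. **Strand misassignment** (`flag_reassigned`): a G>A call antisense to a
   gene whose coding strand shows the complementary C>U dominating in the
   pileups is re-expressed as C>U on the coding strand with the coding
   support. The rewrite only fires when no coding-strand call already
   exists (otherwise the carryover detector owns the pair), which makes the
   operation idempotent.

Two further screens: `flag_noncanonical` (anything other than C>U/U>C in
transcript orientation) and `flag_discordant` (opposite-strand variant
reads / (expected + opposite) above 10% — "needs inspection", not
rejection). Our discordance denominator is the variant reads summed over
both strands; a definition using total reads instead would differ only for
heavily discordant sites, and we document ours rather than asserting it as
the only one.

## High-confidence synthesis

Plastome assemblies differ slightly between individuals, so sites are
harmonized through a whole-plastome multiple alignment: each sample's
positions map bijectively to alignment columns (gaps unmapped, reported as
`no_counterpart`). The site x experiment matrix records per cell
`detected`, `sub_threshold` (any variant reads below a threshold, with the
exact frequency) or `absent`.

A site enters the high-confidence set when it is canonical, non-rRNA, on
its gene's coding strand, never junction- or carryover-flagged, and
detected in at least `min_detected = 2` experiments. At exactly the
minimum, one further experiment must show detected or sub-threshold signal
(`corroborate = TRUE`). This formalizes how a site detected in only two
experiments is admissible when the remaining experiments still show 3–8%
editing; the narrative rule it mirrors was never stated formally by anyone,
so the switch is exposed and documented rather than presented as canonical.
`intersections()` provides exact UpSet-style subset counts (verified in the
tests against brute-force enumeration over all 63 subsets of six
experiments), and `compare_strategies()` tallies per-strategy recall
against a reference set, rRNA/noncanonical artifact loads, and strand
dominance.

## What the synthetic generator emulates — and what it does not

`sim_config()` defaults are the study conditions the pipeline targets:
three biological samples, total and rRNA-depleted strand-specific
libraries, mean coding-strand depth 500, 40 planted C>U edits with
efficiencies uniform on [0.15, 0.95], carryover fraction 1/100, twelve rRNA
artifact sites drawn from a ten-type spectrum holding C>U at 6.25%,
junction-proximal mismatches at 25% within 6 bp of boundaries, and uniform
base error 1e-3. The poly(A) strategy, when enabled, uses 2% of total-RNA
depth to mimic the collapse in plastid mapping rate under poly(A)
selection.

Depth is Poisson per strand around the strategy mean — both strands of a
transcribed locus receive the same mean, reflecting pervasive
double-stranded plastid transcription and ensuring the opposite-strand
denominator of the carryover ratio is well measured. Edited counts are
Binomial(depth, e) on the coding strand; carryover counts are
Binomial(opposite depth, rho * e) deposited as the complementary
substitution. A truth `carryover` event is recorded per edit x experiment
with its realized read count; draws that produce zero reads leave no event
(there is nothing on disk to flag). rRNA artifact sites draw their
substitution type once (a modified base misreads characteristically) and
sit on the noncoding strand with probability 0.9.

The generator works at pileup level: read lengths, mapping ambiguity, PCR
duplicates, quality scores and coverage autocorrelation are *not* modelled
(a small SAM conversion path exists solely to test the converter). Passing
the synthetic end-to-end test therefore demonstrates the correctness of
the calling/filtering/synthesis logic under the modelled noise structure —
it does not certify performance against alignment pathologies absent from
the model, which is exactly why the artifact screens exist as flags that a
human can audit on real data.

## Numerical and interface choices

* Coordinates are 1-based inclusive everywhere; "position on gene" is the
  1-based offset along the spliced CDS (concatenated exons,
  reverse-complemented for minus-strand genes), which makes codon index
  `(p-1) %/% 3 + 1` and codon position `(p-1) %% 3 + 1`.
* Region priority at overlapping features is CDS > rRNA > tRNA > 5'UTR >
  3'UTR > intron > intergenic: each site gets exactly one context, and
  coding impact dominates.
* The genetic code is the standard table with no start-codon
  special-casing: an edited ACG start codon is reported as T>M.
* Features wrapping the circular origin are rejected (assemblies are
  linearized); N bases are excluded from counts and depth.
* Ties between equal-count alternative bases break alphabetically
  (A < C < G < T) for determinism.
* UTR features are honored only when explicit in the GFF3; no UTR
  inference is attempted.
* The curated 38-site fixture ships as a plain TSV; its reference genome is
  engineered deterministically (`curated_reference()`) so that every
  curated site occupies its published spliced position with its published
  codon — the packaged table and the codon arithmetic validate each other.
  The published text mentions seven tyrosine codons after editing while the
  printed codon table contains four H>Y rows; the package reproduces the
  table-derived value and leaves the discrepancy visible rather than
  guessing.

## Problem sizes used in tests

The shipped tests run the full pipeline on a 24 kb synthetic plastome
(eight genes, one intron, one rRNA locus) at depth 500 across six
experiments, which finishes in seconds while leaving every stage
statistically comfortable: a 0.15-efficiency edit at depth 500 sits ~9 SDs
above the VAF threshold, and a 1/100 carryover at the same depth is
detected with essentially no false assignment. Efficiency calibration uses
200 replicates per efficiency at depth 10^4 against the 3-binomial-SD
band. These sizes are the package's own test design; the generator scales
to larger genomes and depths through `sim_config()`.

## Known limitations

* BLAST-style checks against nuclear/mitochondrial insertions of plastid
  DNA are out of scope; run them upstream if paralogy is a concern.
* The SAM/BAM converter assumes paired-end RF libraries and approximates
  "uniquely mapped" with a MAPQ floor (default 1).
* Statistical tests of strategy differences are deliberately absent; the
  comparison is descriptive set arithmetic.
* Cross-sample harmonization assumes a trustworthy whole-plastome
  alignment; structural rearrangements between samples are not handled.
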