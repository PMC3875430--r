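---
title: "mirphase: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mirphase: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

mirphase analyses plant small-RNA sequencing studies that compare a small
number of unreplicated libraries — the design typical of early
deep-sequencing surveys of developmental transitions. Its running example
is a wild-rice flowering study: two vegetative libraries (V1 from a
single-flowering plant group, V2 from a double-flowering group) and one
flowering library (F2, double-flowering group). This vignette explains the
models and the decisions behind them; the README shows the user-facing
workflow.

## The annotation cascade

Reads are length-filtered to 18–30 nt (the gel-purified size range),
collapsed to unique tags, and matched to the genome by exact, full-length
search on both strands. Only genome-matched ("clean") tags proceed;
unmatched tags are reported separately. Each clean tag receives exactly one
category through a fixed priority:

rRNA > tRNA > snRNA > snoRNA > scRNA > repeat > exon > intron >
known miRNA > unannotated.

This mirrors the classical filtering order in which structural RNA,
repeats and degradation fragments are removed before miRNA assignment. Two
rules keep the category table a true partition of the clean total:

* a multi-locus tag is annotated once, by the highest-priority class any
  of its loci overlaps — reads are never counted per locus;
* sense/antisense for exon and intron is decided by strand agreement
  between tag locus and feature, with sense winning when both kinds of
  overlap exist.

The priority is configurable because the fate of a miRNA residing inside
an annotated exon is genuinely ambiguous: under the default order the exon
filter would claim it. Users who want miRNA assignment to take precedence
can move `known_miRNA` up the list.

## Known-miRNA quantification

A tag counts toward a catalog mature if it equals the mature or a
*templated* end variant: trimmed or extended by at most 2 nt at either
end, with extensions required to match the hairpin precursor sequence.
Non-templated tailing is deliberately not matched — an untemplated variant
cannot be distinguished from sequencing error or a different locus without
evidence the catalog does not contain. A tag claimed by several matures
(common within families) is assigned to exactly one: zero-offset match
first, then smallest total end offset, then smallest id. This keeps the
module conservation invariant: matched records plus unmatched reads equal
the cascade's known-miRNA category total.

Star (passenger-strand) partners are ordinary catalog entries connected by
a star link; dominance is compared per library on raw counts with ties
going to the mature, since the mature annotation is the prior. "Expressed"
means raw count ≥ 1; there is no deeper justification available for any
particular threshold, so it is a configurable argument.

## Stem-loop RT-qPCR assay design

The RT primer is a fixed 44-nt stem-loop scaffold completed by 8 nt
reverse-complementary to the miRNA's 3' octamer; the forward PCR primer
carries the miRNA's first 10 nt behind a short GC clamp; the reverse
primer is a universal primer annealing inside the scaffold. The amplicon
length is therefore miRNA length + a scaffold constant. The constant
defaults to 48 nt, calibrated so a 21-nt miRNA yields a 69-bp product —
the standard worked example for this assay family — and is an argument
rather than a hard-coded value because scaffold designs differ between
laboratories.

## Novel-miRNA discovery

Unannotated tags with at least `min_reads` (default 5) summed reads are
candidate matures. Each genomic locus is expanded by 150 nt on each side
(≈ 320-nt window for a 20-nt tag), folded, and checked against
plant-miRNA annotation criteria:

a. the tag lies wholly on one arm of a single stem-loop;
b. at most 4 of its bases are unpaired against the star region;
c. no internal loop/bulge in the duplex is asymmetric by more than 2 nt;
d. folding energy ≤ −18 kcal/mol;
e. trimmed hairpin length within 60–380 nt.

The duplex thresholds (b, c) follow the community annotation standard for
plant miRNAs; the energy floor and length window bracket the values
reported for accepted plant precursors. Every failed criterion is recorded
as a reason code, which makes acceptance monotone in the thresholds — a
property the test suite checks directly. Windows are fixed at tag ± 150 nt;
genuine precursors longer than the window cannot be represented and their
trimmed length is underestimated. This is a known limitation, accepted in
exchange for a fixed, auditable window rule.

Folding is a pluggable contract (dot-bracket string plus an energy, and
deterministic for a fixed engine). Two engines ship:

* **builtin** — a maximum weighted base-pairing (Nussinov-style) dynamic
  program with pair weights GC > AU > GU and a stacking-energy readout:
  only pairs stacked on another pair contribute energy (≈ −2 to −3
  kcal/mol per stack, the magnitude of nearest-neighbour stacking terms).
  Isolated pairs in random sequence therefore contribute nothing, which
  keeps the energy criterion discriminative. Compiled, dependency-free,
  deterministic.
* **vienna** — RNAfold, when the executable is installed.

Acceptance thresholds are calibrated per engine; the shipped defaults
refer to the builtin engine. On dinucleotide-shuffled windows
(Altschul–Erickson exact shuffle) the full criteria accept well under 5%
of candidates, so the procedure's false-discovery behaviour is dominated
by the duplex criteria rather than the energy model.

Genomic context uses the precedence UTR > intron–exon junction > exon >
intron > intergenic, so the published style of mutually exclusive context
counts is representable. Candidates with identical mature sequence merge
into a single novel miRNA carrying all loci (ids `oru-miR1…n` in discovery
order); a star is flagged as observed when a sequenced tag overlaps the
predicted star region by ≥ 75% of the tag length, a pragmatic rule chosen
because no published star-calling rule exists for this setting.

## Target scoring

Complementarity is scored with a miRU/psRNATarget-style penalty
("expectation"): mismatch 1.0, G:U wobble 0.5, single-nt internal gap 2.0,
all doubled at miRNA positions 2–13 (the seed-proximal region that
dominates plant target recognition), with at most one gap and a reporting
cutoff of 3.0. The miRNA binds antiparallel, so position 1 pairs the 3'
end of the site. Terminal gaps are not treated as gaps — they are simply
shorter sites — which keeps a perfect planted site reporting exactly one
hit. This scheme is a documented approximation of the web services used in
the literature, not a re-implementation of any service's exact scoring;
all constants live in `target_config()`.

One stated symmetry deserves a note: the scored duplex is *not* invariant
under reverse-complementing both strands (a G:U wobble maps to C:A, a
mismatch, and the seed window is not reflection-symmetric). The invariant
that does hold, and is property-tested, is reversal symmetry of the
unweighted penalty.

Flowering annotation is a local join against a packaged gene/keyword list
(ids plus patterns like "heading date", "photoperiod", "florigen") —
a deliberate replacement for live GO/KEGG enrichment, whose database-
version-dependent P-values are out of scope. 5'-RACE clone ends are
re-expressed as the bond between miRNA positions i and i+1 (position 1 =
miRNA 5' end, which pairs the site's 3' end); the modal site is the
highest clone count with ties to the first position.

## Differential expression and phase classes

Expression is normalized to reads per million of the library's clean
total; a zero count is replaced by 0.01 RPM so fold-changes stay defined.
The fold-change is log2(B/A) on normalized values. Significance comes from
the conditional count statistic for two unreplicated libraries
(Audic–Claverie): given x counts among N1 clean reads, the count y among
N2 follows

p(y | x) = (N2/N1)^y (x+y)! / ( x! y! (1 + N2/N1)^(x+y+1) ),

a negative binomial with size x+1 and success probability N1/(N1+N2),
evaluated through `pnbinom` in log space. The two-sided P is
min(1, m1 + m2) where each m is the smaller of the lower and upper tails
(both including the observed point), conditioning in each direction. This
form was chosen over the usual "2 × min(tails)" doubling because the
doubling is not symmetric under swapping the libraries for discrete
counts; the implemented form is symmetric by construction, reduces to the
doubling in the symmetric case, and holds its nominal type-I error
(measured 0.043–0.049 at α = 0.05 in the seeded null suite).

Labels: `**` for |log2FC| > 1 and P < 0.01; `*` for |log2FC| > 1 and
0.01 ≤ P < 0.05; `ns` otherwise. Three conventions are ours where the
source convention is ambiguous, each with a configuration escape hatch:
boundary P-values fall in the less significant bin (strict inequalities as
printed); the fold bound applies to `**` as well as `*`; and no
multiple-testing correction is applied by default, since the procedure
this reproduces used raw P thresholds.

miRNAs weak in every library (raw count ≤ 20 everywhere) are excluded
before testing — with single-digit counts in all libraries the test has
essentially no power and the fold-change is floor-dominated.

The phase classifier turns the three pairwise calls into exclusive
classes by precedence: **F** if significant between V2 and F2 (the
flowering transition proper); else **E** if significant between V1 and F2
(the early-flowering difference between plant groups); else **N** if
significant only between the two vegetative libraries; else unresolved.
The precedence makes the classes exclusive and exhaustive over significant
miRNAs, which published exclusive class counts imply but never state.

## The synthetic study generator

No sequencing data is deposited for the motivating study, so the
generator is a first-class module: every pipeline stage is exercised
against planted ground truth.

What it emulates, and why those values:

* three libraries with the V1/V2/F2 stage-group design;
* read lengths 18–30 nt with ≥ 60% of mass on 20–24 nt and a 21-nt mode,
  matching the reported length profile of clean plant sRNA libraries;
* a 5'-U bias of 0.345 among planted matures (the reported first-base
  fraction, reflecting AGO1 loading preference);
* an rRNA-dominated contaminant background (~40% rRNA, ~8% tRNA, ~10%
  repeats, a few percent exon/intron fragments) so the category table has
  realistic shape; ~17% of reads are known-miRNA-derived;
* negative-binomial counts with size 100 — mild overdispersion, chosen
  once as representative of technical variation in libraries without
  biological replicates (strong overdispersion is not identifiable from a
  one-library-per-condition design anyway);
* nominal depth 1e5 reads per library and a 200-kb genome: desk-scale
  sizes at which every statistic of interest (counts in the hundreds to
  thousands for planted effects) sits in the regime the thresholds were
  designed for;
* planted fold effects: F-miRNAs 6× between V2 and F2, E-miRNAs 6×
  in both double-flowering libraries, N-miRNAs 2.6× between V1 and V2
  with F2 placed at the geometric midpoint so neither flowering
  comparison crosses the |log2FC| > 1 bound; half of each class up, half
  down, so library masses stay balanced and the fold-changes of null
  miRNAs are not dragged by composition shifts;
* stage-exclusive miRNAs (multiplier 0), star partners including two
  star-dominant pairs, templated isomiRs at 15%, intergenic novel
  hairpins with perfect-stem precursors, and a 2% genome-unmatched read
  share.

The expected F/E/N truth is computed from the planted multipliers through
the *same* thresholds the classifier applies, at expected counts and
expected clean totals — so recovery measures the pipeline, not a private
reimplementation of it.

What it does not emulate: sequencing errors and quality strings, adapter
contamination, true Rfam secondary structure in contaminant loci (the
cascade only consumes intervals), repeat-induced multi-mapping ambiguity,
and genome-scale sequence composition. Passing the recovery suites
therefore demonstrates that the machinery is correct and calibrated under
the stated generative model; it does not certify accuracy on real
libraries, where mapping ambiguity and error-derived tags are the dominant
nuisances.

## Numerical and degenerate-input choices

* All internal sequence comparison is DNA-alphabet (U→T on input); RNA is
  reproduced on output where conventional (assays, folding).
* Interval work uses the Bioconductor stack; internal coordinates are
  1-based closed (`GRanges`), emitted GFF3 is 1-based inclusive, BED I/O
  converts automatically.
* The folding traceback breaks ties deterministically (first maximizing
  split wins), so candidate tables are reproducible run-to-run.
* An empty counts table, a header-only FASTA, a tag absent from the
  genome, a miRNA with no target hits, and a star set with no links all
  return well-typed empty results; invalid values (negative counts,
  non-positive totals, zero-length sequences, duplicate ids) raise
  immediate errors naming the offending record.
* Problem sizes in the shipped test suite: one default study (seed 1,
  depth 1e5, 200-kb genome) shared across suites, 10,000-replicate null
  and 1,000-replicate power simulations, a 51 × 51 exact-oracle grid for
  the count test, and 100–200 shuffle-null folds. These were chosen as the
  smallest sizes at which the binomial error of each estimated rate is
  comfortably inside the asserted band.

## Known limitations

* Exact matching only: a tag with a single mismatch to the genome is
  dropped, which on real data loses SNP-bearing and error-bearing reads.
* The fixed ±150-nt window truncates long precursors.
* The builtin energy model ranks hairpins sensibly but is not a
  thermodynamic nearest-neighbour model; energies from different engines
  are not comparable, hence per-engine threshold calibration.
* The target scheme approximates, but is not identical to, any given
  web service's scoring; absolute expectation values should not be
  compared across tools.
* With one library per condition, "significance" is sampling significance
  under the conditional model, not biological replication; the package
  deliberately refuses to dress this up further (no replicate-aware GLM).
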