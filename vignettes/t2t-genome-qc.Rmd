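---
title: "Methods: telomere, centromere, QV and gene-family analysis for T2T assemblies"
author: "T2Tqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: telomere, centromere, QV and gene-family analysis for T2T assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and model

T2Tqc implements, as reusable and testable functions, the bespoke
computational steps that surround a telomere-to-telomere (T2T) plant
genome assembly: telomere identification and terminal patching from
ultra-long read alignments, multi-evidence centromere prediction,
k-mer-spectrum consensus quality (QV) estimation, and cytochrome P450
gene-family mining including the SRS6 diagnostic-residue classification
of flavonoid B-ring hydroxylases (FBH). Raw assembly, scaffolding,
polishing, annotation and phylogenetics are deliberately out of scope:
the package consumes their standard outputs (FASTA, GFF3, PAF, BED,
domain tables, FPKM matrices) and implements the decision rules applied
on top of them.

Every detector can be exercised against planted ground truth: the
synthetic-data generator builds genome, read, family and expression
fixtures from a configuration and a single seed, and its truth manifest
fully determines the expected output of every detector on error-free
input. All empirical statements below are reproduced by the test suite
or by `scripts/acceptance.R`; none are imported from elsewhere.

# Coordinate conventions

Internally everything lives in Bioconductor containers:
`DNAStringSet`/`AAStringSet` for sequences and `GRanges` (1-based,
closed) for intervals. Conversions happen only at I/O boundaries: GFF3
is natively 1-based inclusive and imported as-is; PAF and BED are
0-based half-open and shifted by one on the start coordinate when read,
and shifted back when written. Keeping a single internal convention, with
conversion isolated in `readPaf()`/`writePaf()` and
`readBed()`/`writeBed()`, is what prevents off-by-one drift between
modules.

Gene `rank` is the 1-based index of a gene in its chromosome's gene
order, assigned after sorting by start. Only rank *differences* are ever
used (the cluster rule), so the choice of base does not affect any
result.

# Telomere identification and terminal patching

A chromosome end is scanned for exact, non-overlapping copies of the
plant telomere motifs — `CCCATTT` at the 5' terminus and `TTTAGGG` at
the 3' terminus. The two motifs are searched strand-specifically and
are independent configuration fields rather than being derived from one
another by reverse complement: the canonical complement of `TTTAGGG` is
`CCCTAAA`, and whether a 5' search motif of `CCCATTT` is intentional in
any given study cannot be resolved from the search procedure itself, so
the package takes both motifs as explicit inputs and defaults to this
pair.

Two parameters govern the verdict, neither of which has a universal
published value:

* `terminalWindow` (default 150 kb): how far from each terminus the scan
  extends. The default comfortably exceeds the longest arrays the
  defaults generate (2673 copies x 7 bp ≈ 18.7 kb) while staying cheap.
* `minRepeats` (default 100): the acceptance threshold. The default is
  chosen so that the smallest accepted array in the emulated study
  conditions (111 copies) passes and the rejected case (2 copies at one
  chromosome's upstream end) fails, with a wide margin on either side.

Terminal patching mirrors the repair procedure used for T2T gap
closure: reads whose alignments come within `screenWindow` (default
50 bp) of a chromosome terminus are collected per end; the read with
the most motif copies becomes the *reference* (ties break to the
longest read, then the lexicographically smallest id, making the choice
deterministic); and the terminal span covered by the reference read's
alignment is replaced by the read itself, extending the chromosome when
the read runs past the assembled end. Consensus polishing of
reference-plus-query reads is an external tool's job in the original
procedure and is not re-implemented; the reference read is the patch
donor. An end already carrying at least as many repeats as the
reference read is left untouched (`already_complete`), which gives the
procedure its monotonicity guarantee: a patch never decreases a repeat
count.

# Centromere prediction

Centromeres are located by combining four kinds of window evidence in
fixed 60-kb screening windows: tandem-repeat coverage, gene density,
Gypsy-LTR coverage, and (optionally) a Hi-C blank-region mask.

The tandem-array detector is a functional replacement for an
alignment-based tandem repeat finder, designed for centromere-scale
arrays rather than microsatellites. Candidate regions are seeded by
k-mer recurrence: in an array of period *p*, the 11-mer starting at
position *i* recurs at *i + p*, so positions whose previous identical
11-mer lies `minPeriod`–`maxPeriod` bp upstream mark repetitive
territory, and runs with enough seed density become candidates. Within
a candidate, the reported period is the *smallest* offset whose exact
self-match fraction `s[i] == s[i+p]` reaches `minPurity` — this is what
prevents a dimer of the monomer being reported in place of the monomer
— and boundaries are refined to the maximal extent supported by a
sliding purity window, then trimmed to exact self-matching positions.
Purity is defined directly as the self-match fraction over the reported
interval, so it can be (and is, in the tests) recomputed independently
from the sequence. On i.i.d. random sequence the seeding density is
orders of magnitude below the threshold, so the detector stays silent;
this is verified empirically rather than assumed.

Defaults: `minPeriod = 20`, `maxPeriod = 2000`, `minArrayLen = 10 kb`,
`minPurity = 0.7`, all package choices (an alignment-based finder's
scoring model is out of scope). The window rule's thresholds
(`minTandem = 0.3`, `maxGeneCount = 1` per 60-kb window,
`minGypsy = 0.1`, merge gap 2 windows) are likewise package defaults:
"low gene density" and "high Gypsy density" have no published
quantitative definition, so the defaults are set to separate the
generator's centromeric windows (tandem ≈ 1, genes ≈ 0, Gypsy ≈ 0.45)
from its background (tandem ≈ 0, ~4–5 genes, Gypsy ≈ 0.06) with a wide
margin on each conjunct. Every threshold is an explicit parameter.

Passing windows merged across small gaps become candidates, ranked by
summed tandem coverage. The *selected* interval is reported at
array resolution, not window resolution: the extent of the tandem
arrays overlapping the top candidate. When the runner-up candidate
scores within `ambiguityMargin = 0.2` (relative) of the top one, the
call is withheld and flagged ambiguous — the behaviour expected of a
chromosome carrying two comparable arrays, where window evidence alone
cannot decide which is the centromere. Hi-C blank evidence is consumed
as a pre-derived BED mask and simply becomes a further conjunct when
present; deriving blank regions from a contact map is out of scope.

# Consensus QV

The QV module adopts the standard k-mer-spectrum estimator: with *Y*
assembly k-mer positions (canonical k-mers, k = 21 by default, k-mers
containing N skipped) and *X* of them unsupported by the read k-mer
set, the per-base error probability is

$$E = 1 - (1 - X/Y)^{1/k}, \qquad \mathrm{QV} = -10\log_{10} E,$$

with a configurable cap (default 99) when *X* = 0. Read k-mers seen
fewer than `readKmerMinCount` times (default 2) are treated as absent,
which filters sequencing errors out of deep read sets; with error-free
read sets a floor of 1 is appropriate. Canonical k-mers are encoded as
base-4 integers held exactly in doubles (4^21 < 2^53), so the survey
needs no external counting tool. An isolated substitution creates
exactly k novel k-mers; at rate 1e-4 substitutions occasionally fall
within k bp of each other, so recovered QV sits within about one phred
unit of the planted rate rather than exactly on it — the tolerance used
by the recovery tests.

# Gene-family mining

The profile-HMM search itself is consumed, not implemented: the module
parses domain-table output with configurable column indices. The rules
implemented on top are:

* **Length filter**: candidates shorter than 400 aa or longer than
  600 aa are removed; the boundaries read as exclusive removal
  conditions, so lengths of exactly 400 and 600 survive.
* **Cluster rule**: two family genes are linked iff they lie on the same
  chromosome within eight open reading frames of each other,
  operationalised as a gene-rank difference ≤ 8 in the annotated gene
  order, and clusters are the transitive closure of this relation with
  singletons excluded. The alternative reading — at most eight
  *intervening* genes — is available by setting `maxGap = 9`. Adjacent
  ranks are additionally flagged as tandem pairs.
* **Pairwise identity**: global (Needleman–Wunsch) alignment with
  BLOSUM62 and affine gaps by default, identity = identical columns
  over all alignment columns with gaps in the denominator. Printed
  identities from any particular study depend on its (unstated)
  aligner and parameters, so comparisons carry method tolerance of a
  point or two.
* **SRS6 classification**: the candidate is globally aligned to an
  annotated anchor protein whose SRS6 coordinates are supplied in
  configuration (no universal coordinates exist; they are a property of
  the chosen reference), the anchor's SRS6 columns are projected onto
  the candidate, and the residue in the column of SRS6 position 8
  decides the class: Thr/Ser → F3'H-like (CYP75B-type), Ala →
  F3'5'H-like (CYP75A-type), anything else (including a gap) remains
  unclassified.
* **Expression summaries**: heatmap values are `log10(FPKM + 1)`; fold
  ratios between genes are computed on raw per-tissue mean FPKM, not on
  logged values, and reported to two decimals.

# The synthetic-data generator

The generator's defaults are the package's standard study conditions:
nine 1-Mb chromosomes; 17 telomeric ends with repeat counts spanning
111–2673 and one sub-threshold end (2 copies) on chromosome 5's
upstream side; one 171-bp-monomer centromeric array per chromosome at
2% divergence occupying a tenth of the chromosome; background genes
every 13 kb with length 4 kb (≈73 genes/Mb, matching the emulated
genome's 28 097 genes over 384.59 Mb, with the 4-kb gene length
matching its 4004-bp mean), nearly absent inside centromeres; Gypsy
annotation at ~6% background coverage (the emulated genome's Gypsy
fraction is 6.32%) and ~45% inside centromeres. Chromosome length is
scaled down by roughly 40x from the real ~43-Mb pseudochromosomes to
keep every stage desk-sized; centromere fractions (6–16% of the
chromosome in the centromere-recovery conditions) are preserved under
the scaling.

Background sequence is i.i.d. uniform ACGT, and Gypsy intervals are
annotations only — detectors consume annotations, not element
structure, so retroelement sequence realism would add nothing the tests
could see. One deliberate departure from plain i.i.d. background: chance
occurrences of the telomere motifs outside the planted arrays are
scrubbed (one base of each occurrence resampled), because the truth
manifest promises that planted counts *are* the expected scan results;
without scrubbing, a 150-kb terminal window would pick up ~9 random
7-mer hits and the manifest would systematically under-state the truth.
GC content of the synthetic genome is accordingly ~50%, not the AT-rich
value of a real plant genome — a known, accepted difference between the
fixture and real data.

What passing tests on this generator do show: the detectors implement
their stated rules exactly (counts, thresholds, tie-breaks,
boundaries), recover planted structure through realistic nuisance
(monomer divergence, read-sampled telomere extensions, substitution
errors), and are deterministic under a fixed seed. What they do not
show: robustness to ONT/HiFi error profiles, heterozygosity,
softmasking conventions, or biased base composition — real-data
behaviour must be validated on real data.

Reads simulated for terminal patching carry per-read telomere
extensions (sampled up to a configured maximum, with one read always
carrying the maximum so the expected reference read is well defined)
and truthful PAF records; the extension parameter counts motif copies,
the natural unit for repeat arithmetic. The family generator derives
members from an anchor (or from each other, for tandem-duplicate pairs)
at configured identities by point substitution, plants the diagnostic
residue last, and places members at configured gene ranks in a filler
scaffold.

# Numerical and degenerate-input choices

* Motif counting is greedy left-to-right and strand-specific; 7-bp
  telomere motifs cannot self-overlap, so greedy equals exhaustive.
* Terminal windows clip to short sequences instead of erroring.
* Reference-read ties break count → length → id, in that order.
* The 3' terminus of each chromosome is patched before the 5' one so
  stored alignment coordinates stay valid while the length changes.
* GC% excludes N from the denominator; N50 uses the standard
  cumulative-length definition.
* `estimateQV` errors on Y = 0 (e.g. an all-N assembly) rather than
  returning a number.
* Alignment tie-breaking is delegated to the deterministic dynamic
  program; scores, not alignments, are the contract checked against the
  exhaustive oracle.
* Interval containers reject zero- and negative-width ranges by
  construction (IRanges), enforcing `start <= end` everywhere.

# Problem sizes

The test suite runs the full recovery conditions at the generator's
default scale: 9 x 1 Mb for telomere recovery, 2 x 1 Mb for QV
recovery (≈200 planted errors at rate 1e-4), 3 x 5 Mb for centromere
recovery with 0.3–0.8 Mb arrays, 200 random instances (≤ 50 genes) for
the cluster-rule oracle, and exhaustive-plus-sampled pairs up to length
8 for the alignment oracle. `scripts/acceptance.R` re-runs the whole
pipeline at the same scales from a single seed and writes every
headline number it computes to JSON.

# Known limitations

* Exact motif matching only by default; a single substitution inside a
  motif copy splits the count. The repair procedure is robust to this
  (it selects by count, and error-free fixtures make truth exact), but
  highly diverged telomeres would need mismatch-tolerant counting.
* The tandem detector reports one array per seeded region and resolves
  overlaps greedily by purity x length; deeply nested higher-order
  repeat structure is summarised, not decomposed.
* The QV survey holds read k-mer counts in memory; it is sized for
  desk-scale fixtures and tens of Mb, not for 100x short-read archives.
* The centromere rule set is conjunctive; a centromere that fails one
  evidence channel (e.g. unusually gene-rich) is withheld rather than
  rescued by the others.
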