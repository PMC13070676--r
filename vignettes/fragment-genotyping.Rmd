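---
title: "Fragment-level genotyping and fragmentomic features for cfDNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragment-level genotyping and fragmentomic features for cfDNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragtyper)
```

## The problem

Cell-free DNA (cfDNA) in plasma is a mixture of molecules released by many
cell populations; in cancer patients a minority fraction is tumor-derived
(ctDNA). Tumor-derived fragments differ from the background both genetically
(they carry somatic mutations) and physically: they tend to be shorter, and
their end motifs differ. Joining the two signals requires, for every
sequenced fragment overlapping a known mutation, (i) accurate physical
features of the fragment and (ii) a per-fragment mutation status. `fragtyper`
computes both, starting from a coordinate-sorted BAM of paired-end reads, a
reference FASTA, and a list of small mutations in any common representation.

Two technical obstacles make this harder than it sounds:

* **TLEN is wrong in exactly the interesting cases.** The SAM template-length
  field is the signed reference span between the outermost aligned ends. A
  fragment carrying a deletion of $d$ bases spans $d$ more reference bases
  than its molecule is long, so TLEN overestimates its size by $d$ (and
  underestimates by the inserted length for insertions); soft-clipped bases
  are ignored entirely. For a clinically central case such as a 15 bp
  in-frame deletion, every mutated fragment's TLEN-based size is off by
  15 bp — a shift larger than the biological size difference one is trying
  to detect.
* **Indels have many valid representations.** The same physical deletion in
  a repeat tract can be written at any shift position, with or without an
  anchor base, in 1-based or 0-based coordinates. Genotyping must be
  invariant to all of them.

## Mutation harmonization

All inputs converge to one canonical form: 1-based, fully-closed
coordinates; non-empty REF and ALT over `ACGTN`; indels anchored on a shared
leading base (VCF convention); left-aligned and parsimonious. The
normalization is the standard iterative algorithm for biallelic small
variants: trim shared trailing bases (re-extending leftward with the
reference base whenever an allele would empty, which is what shifts indels
left through repeat tracts), then trim shared leading bases while both
alleles keep at least one. Shifting stops at position 1 of a contig.
`bcftools norm` performs the same computation for biallelic records; it is
not a dependency here — the implementation is native and is verified by a
brute-force oracle (`enumerateEquivalentRepresentations()`) that enumerates
*every* (pos, ref, alt) triple denoting the same edit and asserts they all
normalize to the same fixed point. Variants that remain length-changing with
both alleles longer than one base after trimming have no anchor-based small
variant form and are rejected as complex rather than silently mis-handled.

Missing-allele conventions are resolved before normalization: `-`, `.` or
empty REF means an insertion whose position names the base to its left;
`-`, `.` or empty ALT means a deletion whose position names the first
deleted base. Both are rewritten to anchor form by prepending the reference
base to the left of the event.

## Fragment selection

For each mutation, reads are fetched through the BAM index over the
mutation position ± `windowBp` (default 600 bp, enough to recover the full
human cfDNA size distribution around a locus) and paired by query name.
Window overlap is assessed on the pair's *outer span*, so a fragment whose
mates flank the locus without covering it is still recovered — it will
simply genotype as non-informative. Because establishing the outer span
requires seeing both mates, the scan extends `scanMargin` (default 5000 bp)
beyond the window; a mate farther away than that degrades the fragment to a
flagged single-read record. Default read filters are permissive and
configurable: unmapped, secondary, supplementary and QC-fail records are
always dropped (they cannot form fragments), duplicates are dropped by
default, and there is no MAPQ or proper-pair requirement unless requested.
Mates on different contigs or in the same orientation do not form a
coherent fragment; the package keeps one flagged single-read fragment
(higher MAPQ, then leftmost) so the information is preserved and
filterable downstream.

## Indel-aware fragment size

The physical size of a fragment is computed as

$$\mathrm{size} = (\mathrm{outer\ end} - \mathrm{outer\ start} + 1)
  + \sum \mathrm{I} - \sum \mathrm{D}
  \;[+\; \mathrm{outer\ soft\ clips}],$$

i.e. the reference span of the outermost aligned bases, plus inserted
bases, minus deleted bases, plus (by default) soft-clipped bases adjacent to
the fragment's outer ends. Reference skips (`N`) subtract like deletions by
default and set a flag — cfDNA data should not contain them, so this is
fail-soft with visibility. Clips at inner read ends never count.

Where the two mates overlap, the same indel appears in both CIGARs and must
count once; events are therefore deduplicated by (type, position, length,
inserted sequence) within the overlap. Only events *observable by both
reads* are conflict material — an insertion anchored at the exact base where
the mate's alignment ends, or a deletion touching an alignment boundary, is
invisible to that mate and is not treated as contradicted. When the two
reads genuinely disagree inside their overlap, the higher-MAPQ read's events
are used (tie: left read) and the fragment is flagged
`size_discordant_mates`.

The soft-clip policy is a biological assumption, not an inference: with
`keepSoftclips = TRUE` (default) outer clipped bases are counted as molecule
sequence (appropriate when clips represent real non-reference ends); with
`FALSE` they are treated as technical artifacts such as adapter
read-through on short fragments. Indels falling in the unsequenced gap
between non-overlapping mates are unobservable in principle; sizes there
assume the gap is reference-like. This is a limitation of short-read
fragmentomics itself, not of the implementation.

`inner_distance` (right mate's aligned start − left mate's aligned end − 1,
negative when mates overlap) is reported alongside, as are |TLEN|, per-end
soft-clip counts and total inserted/deleted bases, so TLEN-based and
indel-aware views can always be compared.

## End motifs

Motifs are read from the *reference*, not the read, so sequencing errors do
not contaminate motif statistics: `motif5` is the k-mer (default k = 5)
reading inward from the fragment's outer start on the top strand; `motif3`
is the reverse complement of the k-mer reading inward from the outer end, so
both motifs read 5'→3' into the fragment — the usual convention in the
end-motif literature. Because conventions differ between tools, the raw
top-strand 3' context is also emitted (`motif3_top_strand`). Motifs anchor
at aligned outer ends; fragments with outer soft clips are flagged because
their true terminus may extend past the anchor, and reference-derived motifs
cannot follow into unaligned sequence. Ends within k−1 bases of a contig
edge yield `NA` motifs with a flag.

## Genotyping

Genotyping compares each read, over a type-specific reference window, to two
haplotypes: the wild-type window sequence and the window with the mutation
applied.

**Windows.** For SNVs/MNVs the window is exactly the substituted bases; a
±1-base extended window is checked only to *flag* potentially larger events
(`possible_larger_event`) and never changes the status. For indels the
window starts at the anchor base and must end at a position that
distinguishes the two haplotypes even for a read truncated at the window's
edge: it covers the varying bases, the base after the event, and extends
right through any repeats of the indel unit — including partial-unit repeats
(unit `TG` followed by `TGT…`) — plus one terminating non-repeat base.

**Read status.** The read's query bases are projected onto the window
through a per-base CIGAR walk (insertions anchored inside the window are
included in query order; soft clips never are). Consistency with each
haplotype is then assessed with truncation-aware anchoring: a read covering
the whole window must match exactly; a read truncated on the right must be
a prefix, on the left a suffix, on both a substring. Consistent with exactly
one haplotype → `MUT` or `WT`; with neither → `OTH`; with both (the
truncated haplotypes coincide — e.g. a read ending inside a homopolymer
run) or no coverage at all → `AMBIGUOUS`. This subsumes the classical
string-equality rule and is robust to aligners that encode a truncated
indel as plain matches. With `minBaseq > 0`, any observed window base below
the threshold makes the read `AMBIGUOUS` (`low_baseq`).

**CIGAR precedence for indels.** Every I/D operation in a read is converted
to an anchor-based event and *normalized with the same left-alignment
algorithm as the input mutations*; an event whose normalized form equals the
queried mutation is the expected indel, and such a read is called `MUT`
regardless of window noise (`cigar_seq_discordant` flags a disagreeing
sequence window). Exact length match after left-alignment is required —
near-miss lengths count as `other_indel`, which never changes the
sequence-derived status but is flagged. This single rule makes genotyping
invariant to the aligner's indel placement.

**Fragment status.** Reads aggregate per fragment, never per read — mates
that both cover the locus can never double-count in the VAF. Equal definite
statuses are concordant; one `AMBIGUOUS` plus one definite resolves to the
definite status; two different definite statuses are irreconcilable
(`discrepant`) — there are only two reads, so no majority vote is possible
and the conservative answer is non-informative; two ambiguous reads are
`ambiguous`. A mate with no coverage behaves like an absent mate
(`single_read`). `discrepant` and `ambiguous` fragments form the
non-informative (`NI`) class, excluded from the locus VAF:

$$\mathrm{VAF} = \frac{n_{MUT}}{n_{MUT} + n_{WT} + n_{OTH}}.$$

## Output

`runFragtyper()` returns a `FragmentTable`: one row per (fragment ×
mutation) with all features, the fragment status and resolution, and
semicolon-joined diagnostic flags; per-locus VAF summaries and a per-locus
processing status ride along as metadata (a failing locus is recorded and
does not stop the others). `verboseReads = TRUE` adds per-read FLAG, MAPQ,
CIGAR and mean in-window base quality columns. The table writes to TSV with
`NA` for missing values and round-trips losslessly. The per-locus loop can
run on several workers (`threads`); the output is byte-identical for any
worker count, by construction (no shared state, deterministic ordering by
mutation input order, outer start, fragment id).

Four plot functions (`plotSizeDistribution`, `plotMotifBarplot`,
`plotFreqBarplot`, `plotSeqLogo`) each return both a ggplot and the plain
numeric matrix it was drawn from; tests and downstream code use the
matrices, figures stay a side effect. The motif barplot's three modes are
within-group proportions, raw counts, and the proportion difference between
exactly two groups — a concrete naming of the three comparative views the
tool is expected to offer.

## The synthetic-data generator

`simulateReads()` builds everything the workflow consumes — reference FASTA
(+index), coordinate-sorted indexed BAM, normalized mutation table — plus a
truth record per fragment, with no aligner involved: CIGARs are constructed
from the known edit operations of each simulated molecule. Defaults emulate
human plasma cfDNA: fragment sizes from a normal mixture with a
mononucleosomal mode at 167 bp (sd 10, weight 0.8) and a shorter
tumor-like mode at 145 bp (sd 8, weight 0.2), truncated to [60, 500] bp;
150 bp read pairs; error-free bases unless an error rate is requested.
Planted mutation counts per locus are a seeded binomial draw at the
requested VAF, recorded exactly in the truth table.

Design choices that matter for interpretation:

* **TLEN is written deliberately indel-blind** (signed outer reference
  span), reproducing exactly the discrepancy the indel-aware size removes;
  a mutated fragment's |TLEN| minus its true size equals the deletion
  length by construction.
* **Fragments are placed so the planted event lies in sequenced bases**
  (at least one read covers the locus). Events in the unsequenced inner gap
  are unobservable in principle, so truth about them could not be verified;
  locus depth is therefore "fragments sequenced across the locus".
* **Soft clips carry a label.** `genuine` clips are unaligned molecule
  sequence at the outer ends (the molecule is longer than its aligned
  span); `artifact` clips are junk appended to reads. The truth table
  records the expected size under *both* soft-clip policies, so the size
  oracle is exact for either policy on either label.
* **`shiftIndelCigars`** encodes planted indels at the rightmost equivalent
  CIGAR position, emulating a non-normalizing aligner, to exercise the
  left-alignment step inside CIGAR matching.
* A fixed seed makes all outputs byte-identical across runs.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: base-quality profiles (qualities are constant
Q37), PCR duplicates and UMIs, GC bias, chimeric or split alignments,
multi-contig genomes, and alignment errors other than the modeled clip and
shift cases. Results on simulated data validate the *computation*; they do
not certify caller behavior under real-world alignment pathology.

## Validation design and problem sizes

The test suite validates each module against independent oracles: hand-walked
CIGAR correspondences, brute-force representation enumeration, direct
group-by tallies for every plot matrix, and the simulator truth for sizes and
statuses. The heavier studies, chosen to finish in minutes on one core, are:

* **TLEN discrepancy**: one locus with a 15 bp deletion at depth 200,
  VAF 0.3 — every mutated fragment's |TLEN| minus indel-aware size is
  exactly 15; wild-type fragments differ by 0.
* **Size oracle**: 20 indel loci (1–20 bp, deletions and insertions, some
  in homopolymer context) at depth 25 under each clip label — 1000
  fragments with sizes 60–500 bp and clips up to 20 bp; the indel-aware
  size equals the policy-matched truth for 100% of fragments, for both
  policies and both labels.
* **VAF recovery**: planted VAFs {0.01, 0.05, 0.2, 0.5} × five mutation
  classes (SNV, 2 bp MNV, 1 bp homopolymer deletion, 15 bp deletion, 3 bp
  insertion) at depth 1000, error-free; the measured mutated count equals
  the planted draw exactly in every cell, and the measured VAF is compared
  against the exact binomial 99% interval of the planted value. With 20
  cells at the 99% level, roughly one cell in five runs is expected to fall
  outside purely through the generator's own sampling; under the fixed
  validation seed one such tail draw occurs (456/1000 planted at VAF 0.5,
  measured 456/1000) and is asserted as-is rather than re-seeded away.
* **Representation invariance**: for every fixture indel, all enumerated
  equivalent raw representations normalize to one canonical mutation and
  produce identical genotyping tables.
* **Determinism and partition**: `n_MUT + n_WT + n_OTH + n_NI` equals the
  fragment count at every locus, and runs with 1 and 4 workers produce
  byte-identical TSVs.

## Numerical and degenerate-input choices

* Coordinates are 1-based fully-closed everywhere inside the package;
  0-based input is converted at parse time only.
* Normalization at a contig start stops shifting at position 1 and still
  marks the mutation normalized; genotyping windows clip at contig ends and
  are marked edge-truncated (reads then compare against the clipped
  haplotypes, with ambiguity resolved conservatively).
* `windowBp = 0` degenerates cleanly to "fragments touching the mutated
  bases"; an empty locus yields zero rows, an `NA` VAF and a warning.
* Ties in the discordant-mate size rule go to the left read; flag order in
  the output is alphabetical so tables are stable.
* Minimum supported allele alphabet is `ACGTN`; `N` in REF is accepted only
  where the reference itself has `N`. Symbolic ALTs and breakends are
  rejected with explicit errors.

## Known limitations

Phasing across mutations, somatic-vs-germline classification, UMI
collapsing, duplicate marking and realignment are out of scope. Genotyping
quality is bounded by the aligner's local accuracy: a read whose alignment
hides the event in ways other than representation shift (e.g. clipping the
event entirely) genotypes from what the alignment exposes. Fragment-level
VAFs are unbiased only insofar as informativeness is independent of status;
extremely repetitive windows reduce the informative fraction and widen VAF
uncertainty rather than biasing the point estimate.
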