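---
title: "Characterising transgene-rDNA junctions from R2-mediated insertion"
author: "printmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterising transgene-rDNA junctions from R2-mediated insertion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(printmap)
```

## The biological problem

R2 retrotransposons insert site-specifically into 28S ribosomal DNA by
target-primed reverse transcription (TPRT): the R2 protein nicks one strand
of the rDNA target, and the liberated 3'-OH primes synthesis of a cDNA copy
of the element's RNA directly into the locus. PRINT (precise RNA-mediated
insertion of transgenes) leverages this machinery: an mRNA encoding an R2
protein and an RNA template carrying a transgene cassette are co-delivered,
and the template is written into 28S rDNA.

The template's 5' module — typically an HDV-like ribozyme that self-cleaves
to leave a defined 5' end, optionally retaining h nucleotides of rRNA
sequence — becomes, after reverse transcription, the cDNA **3'** end, and
therefore shapes the transgene **5'** junction with rDNA. When the cDNA 3'
end carries rRNA homology it can base-pair with the upstream target site and
complete a seamless ("anneal") junction; without homology the cDNA is
end-joined to the upstream DNA, with or without microhomology, sometimes
with nontemplated bases in between, sometimes after snap-back (self-primed)
synthesis or copying of a second template molecule.

`printmap` implements the computational side of characterising these
junctions from whole-genome sequencing: a reference model of the target
site, a ground-truth simulator of insertion alleles and paired-end reads, a
split-read alignment cascade, 3'/5' junction classification, microhomology
statistics against a geometric chance model, join-position accounting, and
the ddPCR-style productive-insertion (PI%) utility.

## Coordinate system

All positions are expressed on the top (rRNA-sense) strand. The first-strand
nick defines junction coordinate 0: position 0 is the first scaffold base 3'
of the nick, and upstream positions are negative. The second-strand nick
sits 2 nt upstream by default (the offset characterised for the sparrow
ZoAl R2 protein). Internally the package uses 1-based closed intervals, the
convention of the Biostrings/IRanges stack it is built on; the signed
junction coordinate is the only user-facing coordinate.

A `transgene_template` is the template in DNA sense, 5'→3': the 5' module
(whose first h bases, when h > 0, equal the h scaffold bases immediately
upstream of the nick), an optional cassette body, the 3' module (the default
fixture uses a 98-nt 3' UTR fragment, mirroring the minimised template used
for junction sequencing), and a tail of 4 nt downstream rRNA plus 22
adenosines. Template coordinate 0 is the template 5' terminus — the cDNA 3'
terminus. Since the cDNA is primed at the nick and synthesised from the
template 3' end, the template reads left-to-right in genomic orientation:
5' module at the upstream junction, tail at the downstream (3') junction.

`mapping_references()` builds the composite alignment reference
(`junction_ref`): an rDNA flank (840 bp by default, matching the reference
used for the original analysis; test fixtures use 400 bp, which still
exceeds the read length), the template *as inserted by a seamless
full-length anneal* (one copy of the homology region), and a downstream
flank. Outside the homology region every `junction_ref` position maps
unambiguously to either an rDNA junction coordinate or a template
coordinate.

## The five 5'-junction mechanisms

`make_allele()` constructs the post-insertion locus for each mechanism:

* **anneal** — seamless: `upstream + template[h+1..] + downstream`. Requires
  h ≥ 1. Because template positions 1..h equal the upstream rDNA, any
  5' truncation within the homology yields the identical sequence; an anneal
  breakpoint is therefore reported as an interval property (no point
  coordinate), and an anneal call is full-length whenever the whole
  non-homology region is observed.
* **join** — direct fusion of the (possibly truncated) cDNA to upstream rDNA
  at junction coordinate `join_pos` (0 = directly opposite the nick), with
  an optional nontemplated insert. When a target microhomology m is
  requested, the generator searches `join_pos`/`template_start`
  combinations whose *naturally realised* microhomology — recomputed
  against the unmodified references — equals m; references are never
  mutated, so every simulated junction remains biologically coherent. The
  realised value is recorded and is what all downstream comparisons use.
* **snapback** — a reverse-complement copy of template sequence adjacent to
  the cDNA 5' end precedes the template suffix, the signature of self-primed
  second-strand synthesis before joining.
* **extra template** — sequence from a second template molecule's 3' region
  precedes the suffix on the plus strand.
* **other** — the upstream sequence derives from elsewhere in the host
  genome; simulated as fusion to a random host-decoy segment, which
  exercises the residual category without inventing biology.

The 3' junction is placed exactly at the nick in all mechanisms, matching
the precise TPRT initiation observed for these insertions.

## Read simulation

`simulate_reads()` emulates the sequencing setup used for junction
characterisation: fragments of 400–500 bp (gDNA shear range) sequenced as
150-bp paired-end reads with PHRED+33 qualities. Substitution errors,
exact-duplicate pairs, contaminant read pairs, and an uninserted-locus
background class are injected at configurable rates; everything is
reproducible from a single mandatory seed. Published junction-sequencing
protocols do not state their sequencing error or duplicate rates; the
defaults (0.1% substitutions, 1% duplicates) are conventional
Illumina-like placeholders, not claims.
`focus = "junctions"` concentrates fragment placement so that one mate spans
a junction — the desk-scale equivalent of deep junction coverage.

What the simulator does *not* emulate: indel sequencing errors (off by
default so oracle comparisons stay crisp), PCR chimeras, optical-duplicate
spatial structure, quality-score correlation along the read, and rDNA copy
number variation. A passing test suite therefore demonstrates correctness of
the *analysis* under controlled conditions, not robustness to every artefact
of real libraries.

## Read hygiene

The stated rules are: remove duplicates, quality-trim, and discard reads
shorter than 36 bp or with PHRED quality below 30, together with their
mates. "PHRED quality < 30" could mean per-base, mean, or a
sliding window; `printmap` reads it as a **mean-quality** rule (the simplest
reading), applied after end-trimming at a conventional low threshold
(Q < 3, Trimmomatic's LEADING/TRAILING style). A uniform-Q29 read is thus
discarded for quality, and a read with a long Q2 tail is trimmed and then
discarded for length. A sliding-window mode (window 4, mean < 15) is
provided for sensitivity analyses.

## The alignment cascade

Reads are mapped in the stated stage order: (1) `junction_ref`, with
iterative split re-alignment of clipped portions on the same reference; (2)
remaining fragments against the rDNA scaffold; (3) against the host
reference; (4) approximate-match rescue against a 60-bp context around the
insertion site (edit distance ≤ 3), standing in for the original regex-based
rescue, whose distance threshold is unstated. A fragment explained at stage
k is never re-assigned later.

Alignment is affine-gap local alignment (Biostrings) with match 1, mismatch
−4, gap open 6, gap extend 1 — short-read-mapper-like magnitudes, all
configurable since the original pipeline ran an external mapper at
defaults. Three numerical guards keep desk-scale alignment faithful:

* Segments found by dynamic programming must score ≥ 18 (chance local
  alignments of a 150-nt read against these references stay below this);
  exact substring hits are accepted from 10 nt up.
* A local alignment may extend a few bases past a true fusion point whenever
  a mismatch is followed by chance matches (any non-negative-scoring suffix
  is admissible in Smith–Waterman). Gapless segments are therefore trimmed
  back to their exact cores when a mismatch falls within 10 nt of an end, so
  on error-free data every reported segment matches its reference verbatim.
* An alignment that bridges an indel longer than 15 nt (e.g. a 40-nt
  snap-back arm absorbed as a gap) is split at the divergence point and the
  bridged sequence re-mapped on its own.

Discard rules follow the stated ones, with two interpretations made
explicit: "aligning better to the human genome than to the transgene" is
implemented as a per-pair comparison of alignment score totals, applied only
when both mates are essentially fully explained by the host (≥ 90%
coverage) — so that a genuine junction read whose upstream arm maps to the
host (the "other" category) is not discarded; and "mapping to contaminants"
is checked for reads that remain poorly explained after all stages. Pairs
without both mates mapped are discarded.

## Junction calling

Per read, segments are canonicalised to top-strand orientation and scanned
for context switches. The caller collects *all* candidate junction
interpretations for a read and lets the taxonomy's decision order arbitrate:
anneal → snap-back → extra template → join → other. The order is an artifact
rule (the categories are published without one); it resolves, for example, a
read showing rDNA → 3'-module arm → template start, which is simultaneously
consistent with a join onto the arm and with extra-template copying — the
earlier category wins because it explains more of the read's structure.

Three systematic ambiguities deserve note:

* **Seamless evidence with h = 0.** A boundary-crossing read with no
  preceding segment is an anneal only when the template has rRNA homology;
  with h = 0 the identical evidence is a direct join opposite the nick
  (annealing is impossible without complementarity).
* **Absorbed inserts and truncations.** The affine gap penalty makes a
  mapper bridge short nontemplated inserts (read longer than reference span)
  and short truncations (reference span longer) within one alignment. The
  caller re-examines every lone boundary-crossing segment base by base and
  re-expresses the bridged difference as a join with an extracted insert or
  a truncation offset. When insert bases coincidentally match the template
  start, the insert's position (and hence its exact content) is inherently
  ambiguous; the call is canonicalised to the boundary placement.
* **Anneal/join overlap.** For h > 0 templates, a full-length join (which
  duplicates the homology region) produces some reads indistinguishable from
  anneal reads — those starting inside the duplicated homology. Calls are
  made per read and merged; populations mixing the two will show both
  categories, which is faithful to the evidence. Reads supporting both an
  anneal and a join interpretation are flagged rather than silently
  assigned.

Join breakpoints are canonicalised to the maximal-rDNA placement before
merging, so reads that split the same junction differently merge into one
call. Both extreme placements are reported: assigning all potential
microhomology to the rDNA (`rdna_coord_max_rdna`) or to the transgene
(`rdna_coord_max_transgene`); they differ by exactly the microhomology.
Full-length status uses the maximal-transgene placement (the junction is
full-length if the full cDNA length *could* be present), with the anneal
allowance for the homology region. One junction-spanning read suffices to
define a call by default (`min_support = 1`), appropriate for the low
per-insertion coverage of whole-genome data; the threshold is configurable.

## Microhomology statistics

Maximum possible microhomology at a join is counted in both directions from
the breakpoint: bases 3' of it that also match the upstream reference's
continuation, plus bases 5' of it that also match the downstream reference's
extension — contiguous identity only, capped at a 20-nt window per side
(ambiguity beyond 20 nt does not occur at these junction scales). Whether
the published counting summed both directions or took the larger one is not
fully explicit; the sum is the "maximum possible" reading implemented here,
and both one-sided values are reported so either convention can be
tabulated. Nontemplated inserted bases belong to neither reference, so a
junction with an insert has microhomology 0 by definition.

The chance model: with a uniform 4-letter alphabet, a junction shows exactly
x bp of microhomology with probability (3/4)·(1/4)^x — a geometric law with
per-base match probability 1/4. The expected count among N joins is
N·(3/4)·(1/4)^x (the printed form of this formula omits the fraction bars;
the reading used here is the only one consistent with the stated binomial
p = 0.75). Confidence bands come from resampling: N geometric lengths per
replicate, 100,000 replicates, bands at expected ± 2 SD. Drawing geometric
lengths directly is equivalent to the per-junction Bernoulli construction
and is asserted as such in the tests.

Join positions are tabulated relative to the nick (coordinate 0), split by
full-length versus truncated, under three assignments: joins without
microhomology only (unambiguous positions, the preferred analysis), maximal
rDNA, and maximal transgene.

## Copy number and PI%

`copy_number()` converts a ddPCR concentration to copies per cell against a
reference gene of known copy number (default 3, the RPP30 copy number in
the assayed cell line). `pi_percent()` is the productive-insertion
percentage: 100 × (promoter copies − background) / 3'-module copies, with
the promoter background (default 1 copy, from a matching promoter in the
immortalisation plasmid of the parental line) floored at zero. Droplet
partitioning statistics are out of scope; concentrations are taken as given.

## Problem sizes and numerical choices

The test suite runs entirely on synthetic references: a 1.2-kb rDNA scaffold
stand-in (nick at position 600), templates of ~180–190 nt (module + 98-nt 3'
module + R4/A22 tail), a 20-kb host decoy, and 400-bp `junction_ref` flanks.
These sizes keep a 500-allele recovery experiment — 20 read pairs per
allele, junction-focused — inside a few minutes on one CPU while preserving
every geometric property the method depends on (flank > read length,
template shorter than a fragment, unique 10-mers at desk scale). Real
references (a consensus rDNA scaffold, a full genome) are accepted by the
same interfaces but never required.

Determinism: a single seed drives each simulation and each resampling; all
tie-breaks in alignment are fixed (leftmost reference coordinate for exact
hits, plus strand on score ties); reports serialise identically across runs
with the same seed.

## Known limitations

* The caller assumes one insertion allele per junction-spanning read; loci
  with multiple insertions per rDNA unit are not phased.
* Assembly-based breakpoint refinement is not attempted; coordinates carry
  the ambiguity inherent to microhomology and low-complexity sequence (the
  A22 tail) rather than a false precision.
* The host stage is a desk-scale local aligner, not an FM-index mapper; with
  multi-megabase hosts the cascade will be slow. The module boundaries
  accept drop-in replacement by an external mapper's segment table.
* The "aligning better to the host" and "PHRED < 30" rules are
  interpretations of under-specified published rules; both are parameters,
  and the defaults are documented above.

## A minimal end-to-end example

```{r example, eval = FALSE}
set.seed(7)
site <- target_site(random_dna(1200), nick_coord = 600)
mod <- five_prime_module("gRz-like", random_dna(55), rrna_homology_len = 0)
tpl <- transgene_template(mod, three_prime_seq = random_dna(98), site = site)
refs <- mapping_references(site, tpl, flank_len = 400,
                           host_ref = random_dna(20000))

alleles <- list(
  make_allele(site, tpl, "join", microhomology = 2, id = "j2"),
  make_allele(site, tpl, "join", insert = "GG", id = "jGG"),
  make_allele(site, tpl, "snapback", id = "sb"))
sim <- simulate_reads(alleles, config = read_sim_config(
  n_pairs = 300, rng_seed = 1, focus = "junctions"), site = site)

res <- run_insertion_pipeline(sim$reads, refs)
res$calls
res$report
autoplot(res$report$mh)
```
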