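---
title: "Simulating transcriptomic long reads with lrtsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating transcriptomic long reads with lrtsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lrtsim)
```

## The model: a library preparation as a chain of molecule transformations

Benchmarking transcriptomic long-read tools (isoform callers, fusion
detectors, single-cell demultiplexers) needs reads with known truth, and the
truth that matters is set not only by the sequencer but by everything that
happens to an RNA molecule before it: polyadenylation, reverse transcription
artifacts, end truncation, PCR, barcode attachment. `lrtsim` therefore
simulates the *library*, not just the sequencer: a simulation is a chain of
independent modules, each representing one cellular or library-preparation
process, and every core module consumes and produces the same tabular
Molecule Description Format (MDF).

An MDF record describes one molecule as an ordered, 5'→3' chain of segments
— genomic intervals (contig, 0-based half-open coordinates, strand, plus a
substitution list) and literal sequences (adapters, barcodes, polyA tails) —
together with an integer *depth* (copy count) and free-form `key=value`
tags. Because the molecule is coordinates-plus-edits rather than a realized
string, every downstream fact about a read (source transcript, cell
barcode, UMI, PCR edits, trim lengths) remains exactly recoverable, and
intermediate files stay small and hand-editable.

Three module classes exist:

* **entry** (`transcribe`): samples molecules from a transcript expression
  profile and starts the stream;
* **core** (`tag`, `polya`, `flip`, `truncate`, `filter`, `merge`,
  `barcode`, `pcr`): MDF in, MDF out;
* **exit** (`sequence`): realizes each molecule against the reference and
  emits error-bearing FASTQ reads plus a per-read truth table.

Utilities estimate module parameters from real transcriptome alignments
(PAF): an expression profile from primary-alignment counts and an empirical
truncation model from unaligned target ends.

## Coordinate and randomness conventions

All genomic coordinates are 0-based half-open (BED convention); GTF input is
converted on load. Substitution offsets index the *oriented* segment
sequence — after reverse-complementing '-' strand segments — because
downstream modules (PCR, the sequencer) think in molecule space, not genome
space.

Every stochastic module derives per-molecule randomness from a hash of
(global seed, module name, molecule id). The practical consequences: a
module is a pure function of its input, parameters and seed; processing a
stream in chunks gives byte-identical output to processing it whole; and
inserting a pipeline step never perturbs the randomness of unrelated steps
(each step's seed is derived from the global seed and the step *name*).
This is what makes the two pipeline execution modes — in-process function
calls and one OS process per step — provably interchangeable: both
materialize each step's output as files, and the per-molecule RNG leaves
nothing order-dependent between them.

## The modules and their parameters

**Transcribe.** Draws each of `n_molecules` transcripts independently with
probability TPM/10^6 (per cell when the profile has a `cell_id` column;
cells are drawn uniformly). TPM is used directly as the sampling weight with
no length re-weighting: the entry module counts *molecules*, and length
effects enter later through truncation and sequencing. The molecule count is
a user parameter rather than being derived from target read depth, because
PCR and per-molecule depth multiply read counts downstream.

**PolyA.** Appends `A×L` with `L ~ round(Normal(mu, sigma))` clamped at
`min_len`/0. Defaults in the presets are mu = 60, sigma = 20 bases, a
typical scale for poly(A) tail estimates from nanopore direct-RNA studies.

**Tag.** Prepends/appends IUPAC patterns (each ambiguity code drawn
uniformly), recording the instantiated sequence in `tag5`/`tag3`.

**Flip.** Reverse-complements each molecule with probability `p`, modelling
strand randomization during cDNA synthesis. Flipping is an involution:
segment order reverses, strands toggle, literal segments complement, and
substitution offsets remap to `len − 1 − offset` with complemented bases.

**Truncate.** Draws a (5' trim, 3' trim) pair per molecule from a
truncation model and removes those bases from the oriented molecule —
*after* any flip, because truncation is a physical end-degradation effect
on the molecule as sequenced, not a genomic phenomenon. Molecules consumed
entirely are dropped. Two model families: an empirical joint grid (what
`estimate_truncation()` emits; bin width 1 makes it exact) and a lognormal
3'-only parametric form for the classic oligo-dT degradation shape.

**Filter / Merge.** `filter` partitions a stream by a predicate (tag
presence/equality, length window, seeded Bernoulli, locus overlap) into
`pass`/`fail` substreams; `merge` concatenates streams, prefixing ids
`S<k>_` per source only when ids collide. Together they express branching
protocols: the single-cell preset barcodes only the molecules that carry a
cell tag, then merges the branches back.

**Single-cell barcode.** For each `CB=<cell>`-tagged molecule, prepends
adapter + cell barcode + UMI (10x 3'-kit orientation). Cells are mapped to
a seeded shuffle of the whitelist in order of first appearance, so the
map is stable under re-chunking; UMIs are fresh uniform draws of
`umi_len` bases.

**PCR.** Per molecule, a lineage tree: each cycle, every copy duplicates
with probability `efficiency`; each *new* copy draws
`Binomial(length, error_rate)` substitution positions, each set to a
uniformly chosen *different* base, and bequeaths all its edits to its
descendants. Copies with identical edit sets aggregate into one record by
depth, so the error-free lineage stays a single record and MDF output stays
compact without losing truth. Expected copies follow
`n0 · (1 + efficiency)^cycles`; `target_count` subsamples the final copy
pool uniformly (multivariate hypergeometric over records). Errors are
substitution-only: polymerase error spectra are substitution-dominated, and
substitutions keep truth tracking exact. Drawing a *different* base
requires knowing the current one, so PCR needs the reference whenever
`error_rate > 0`.

**Sequence.** Realizes each molecule and emits `depth` reads, each
corrupted independently. The error model visits template positions left to
right: delete with `del_rate` (run length `1 + Geom(p_geo)` truncated at
`max_indel_len`; positions inside a run receive no further draws),
otherwise substitute with `sub_rate`; independently insert before the
position with `ins_rate`. Event rates are therefore exactly binomial in
the number of *visited* positions, which is what the calibration tests and
the truth table's edit counts rely on. Qualities are constant per class
(defaults: Phred 20 for retained bases, 7 for error bases). Default rates
(3% substitution, 2% insertion, 2% deletion ≈ 93% read identity) are in
the range of recent nanopore transcriptome basecalls; no specific
basecaller's error profile is claimed, and a per-position rate-modifier
hook is reserved for future homopolymer-aware models. Truth is a sidecar
TSV rather than FASTQ-header smuggling; `truth_in_header` optionally adds
a `mol=` comment.

## Model estimation from real alignments

`estimate_abundance()` counts primary alignments (`tp:A:P`, or untagged)
per transcriptome target — secondary alignments are ignored and no EM
multi-mapper rescue is attempted, keeping the estimator deterministic.
`estimate_truncation()` reads the unaligned target prefix/suffix of each
primary alignment (swapping ends for '-' strand) into a joint (d5, d3)
histogram. The model is marginal over targets; conditioning truncation on
transcript length is a known refinement this version does not implement.
PAF was chosen over BAM as the alignment interface: it is plain text,
carries every field the estimators need, and makes fixtures trivial to
synthesize with exact truth.

## Pipelines

A pipeline is a YAML document: named steps, each with a module, parameters,
and the name of its upstream MDF step (filter outputs are referenced as
`<name>.pass` / `<name>.fail`; `after:` adds file-level dependencies such
as a fusion step feeding the entry step's profile). Validation is
all-or-nothing and reports every violation — unknown modules or parameters,
dangling or type-mismatched references, cycles — before anything runs.

Fusion transcripts cannot be expressed in GTF (they span genes, strands,
even contigs), so the fusion step writes them as an MDF *annotation patch*:
one molecule per fusion whose segment chain is the transcript structure;
`transcribe` merges the patch into the loaded annotation.

Execution materializes every step's output in the working directory in both
modes. The chunked `mdf_reader()` gives bounded-memory traversal of MDF
streams at the parser level; the runner itself executes step-at-a-time
rather than streaming records between concurrently running steps — a
deliberate simplification that trades peak memory (bounded by one stream,
not one record) for a much simpler reproducibility argument across the two
execution modes.

## The synthetic fixtures, and what passing tests do not show

`make_fixtures()` builds everything the presets need with no downloads:
uniform-random genomes; non-overlapping gene models (2–8 exons of 30–300
bases, introns 30–300 bases, both strands, optional skipped-exon second
isoforms); Dirichlet(1) expression profiles normalized to TPM; random
barcode whitelists; and PAF files whose coordinates encode known abundance
and truncation truths exactly. Scales used by the shipped tests: 20–60
genes for module tests, a 420-gene annotation for the fusion pipeline
(100 events need 200 distinct multi-exon genes), 10^4 alignments for
estimator recovery, 10^5 molecules for sampling goodness-of-fit, 10^5
bases for sequencer calibration.

These fixtures are deliberately *unlike* real data in composition: uniform
base composition, no repeats, no GC structure, no shared exons between
genes, no empirically-shaped error profiles. Passing tests therefore
demonstrate that the machinery is correct — formats round-trip, seeds
reproduce, estimators recover what generated the data, truth tables are
exact — not that simulated reads are indistinguishable from any particular
instrument's output. Fidelity to a real sample is obtained by *estimating*
the profile and truncation model from that sample's alignments and
supplying realistic error rates.

## Fusion simulation

`generate_fusions()` draws gene pairs uniformly without replacement (so
`2n` distinct genes across `n` events), represents each gene by its
highest-TPM transcript, and joins the donor's oriented exons before a
uniformly chosen internal junction to the acceptor's oriented exons after
one. Breakpoints sit only at exon junctions — matching splice-mediated
fusion transcripts and keeping truth reconstruction exact — and each event
receives `expression_fraction` (default 1.0) of its donor's TPM before the
profile renormalizes; the assignment rule is this package's choice. The
truth table stores the exact 40-mer spanning each junction; the packaged
fusion preset omits truncation, flipping and PCR errors so that every
fusion read's error-free realization provably contains its junction
40-mer — with those modules enabled, junction recovery becomes a property
of the downstream tool under test, not of the simulator.

## Numerical and degenerate-input choices

* Zero-length draws are strict identities: a polyA draw of 0, a (0,0)
  truncation draw, or a flip with `p = 0` leaves the molecule untouched
  (no empty segments, no bookkeeping tags), so degenerate parameters
  compose cleanly.
* Profiles are renormalized to TPM (sum 10^6, per cell) on every load,
  with a warning when rescaling was needed; zero-TPM rows are kept but
  never sampled.
* Reference bases outside ACGT collapse to `N`; substitutions never target
  an `N` (no-op with a warning), keeping realization deterministic on
  ambiguous bases.
* Ties and orderings are fixed everywhere randomness is not intended:
  gene representatives break TPM ties lexicographically, cell-to-barcode
  maps follow first appearance, merge preserves argument order.
* PCR caps per-molecule copies (default 10^6) and fails with a pointer to
  `target_count` rather than exhausting memory.

## Known limitations

No intron retention or novel splicing; no genomic (intronic/intergenic)
fusion breakpoints; no GC- or length-biased PCR efficiency and no PCR
chimeras; no signal-level or basecaller-specific error structure; no EM
rescue of multi-mapping reads; GTF only (no GFF3/BED12) for annotation;
single-molecule coverage biases beyond the truncation model are out of
scope.
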