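# lrtsim — modular simulation of transcriptomic long-read sequencing

Tools that call isoforms, detect gene fusions, or demultiplex single-cell
long reads need benchmark data with exact truth — and that truth is shaped
by the whole library preparation, not just the sequencer. `lrtsim`
simulates a transcriptomic long-read experiment as a chain of independent
molecule-transformation modules, one per cellular or library process:

```
transcribe ──► [tag | polya | flip | truncate | filter | merge | barcode | pcr]* ──► sequence
 (entry)                          (core, MDF -> MDF)                               (exit, FASTQ)
```

Every core module reads and writes the same tabular **Molecule Description
Format (MDF)**: one header line per molecule (`+<id> <depth> <k=v;...>`)
followed by one line per segment — a genomic interval (contig, 0-based
half-open start/end, strand, substitution list) or a literal sequence
(adapter, barcode, polyA tail) — ordered 5'→3'. Because molecules stay
symbolic until the exit module realizes them against the reference, every
fact about a read (source transcript, cell barcode, UMI, PCR edits, trim
lengths, injected sequencing errors) is recorded exactly in a per-read
truth table.

Key quantities and their models:

* transcript sampling: molecule *i*'s transcript drawn with probability
  TPM/10⁶ (per cell for single-cell profiles);
* truncation: per-molecule (5′ trim, 3′ trim) from an empirical joint grid
  or a lognormal 3′ model;
* PCR: per-cycle duplication with probability *e* (expected copies
  n₀·(1+e)^c), substitution errors inherited by descendants;
* sequencing: per-base substitution/insertion/deletion with
  geometric-length indels and per-class Phred qualities.

Preprocessing utilities estimate the expression profile (primary-alignment
counts) and the truncation grid from real transcriptome alignments in PAF,
so simulations can be parameterized from the sample they should resemble.
A YAML-configured runner composes modules into pipelines with one derived
seed per step; reruns — and the in-process vs one-process-per-step
execution modes — are byte-identical. A fixtures generator builds synthetic
genomes, annotations, profiles, whitelists and truth-encoding PAF files, so
everything is testable offline.

## Worked example

```r
library(lrtsim)
wd <- file.path(tempdir(), "demo")
fx  <- make_fixtures("bulk", seed = 1, outdir = wd)   # synthetic genome + profile
ab  <- load_abundance(fx$abundance)
ann <- load_annotation(fx$gtf)
ref <- load_reference(fx$fasta)

mols <- transcribe(ab, ann, n_molecules = 5, seed = 1)
mols <- add_polya(mols, mu = 60, sigma = 20, seed = 1)
mols <- pcr_amplify(mols, cycles = 2, efficiency = 0.8, error_rate = 0.001,
                    seed = 1, reference = ref)
cat(head(write_mdf(mols), 5), sep = "\n")
res <- sequence_reads(mols, ref, error_model(), seed = 1,
                      fastq = file.path(wd, "reads.fastq"),
                      truth = file.path(wd, "truth.tsv"))
cat(sprintf("reads: %d  identity: %.3f\n", res$n_reads,
            1 - (res$sub_events + res$ins_bases + res$del_bases) / res$total_bases))
```

prints

```
+M1	1	tid=G44.T1;pA=45
ctg2	43659	43898	+
ctg2	44040	44249	+
ctg2	44359	44551	+
ctg2	44641	44791	+
...
reads: 15  identity: 0.894
```

— molecule `M1` is a copy of transcript `G44.T1` (four exons on contig
`ctg2`) with a 45-base polyA tail; the five entry molecules amplified to a
total depth of 15 under 2 PCR cycles at 80% efficiency, and the default
error model (3% sub, 2% ins, 2% del) yields ~89% read identity once the
polyA draw and PCR edits are included. `truth.tsv` links every read id to
its molecule, transcript and edit counts.

The same experiment as a pipeline:

```r
pipeline_run(preset_config("bulk"), workdir = wd, seed = 42)
```

Three presets ship with the package (`bulk`, `singlecell` with
filter/barcode/merge branching, `fusion` with 100 random fusion events and
a junction truth table); `make_fixtures(<preset>, ...)` generates the
inputs each expects. A thin CLI wraps every module
(`Rscript $(Rscript -e 'cat(system.file("cli/lrtsim.R", package="lrtsim"))') transcribe --help-style flags ...`).

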