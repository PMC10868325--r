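# Hybrid short-long single-cell protocol: cell-barcoded and ambient
# branches pooled; only CB-tagged molecules receive the Illumina read-1
# adapter, a cell barcode, and a UMI.
steps:
  - name: sc
    module: transcribe
    params:
      abundance: abundance_cells.tsv
      gtf: annotation.gtf
      molecule_count: 600
  - name: ambient
    module: transcribe
    params:
      abundance: abundance_ambient.tsv
      gtf: annotation.gtf
      molecule_count: 150
  - name: pool
    module: merge
    input: [sc, ambient]
  - name: tail
    module: polya
    input: pool
    params:
      mu: 60
      sigma: 20
  - name: split
    module: filter
    input: tail
    params:
      predicate: "tag:CB"
  - name: bc
    module: barcode
    input: split.pass
    params:
      whitelist: whitelist.txt
      umi_len: 12
      adapter: "CTACACGACGCTCTTCCGATCT"
  - name: lib
    module: merge
    input: [bc, split.fail]
  - name: reads
    module: sequence
    input: lib
    params:
      reference: reference.fa
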