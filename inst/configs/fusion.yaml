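# Bulk RNA-seq with 100 random gene-fusion transcripts and PCR.
# No truncation/flip, and error-free PCR: fusion junctions stay intact
# in molecule space, so junction truth is exact.
steps:
  - name: fusions
    module: fusion
    params:
      gtf: annotation.gtf
      abundance: abundance.tsv
      reference: reference.fa
      events: 100
  - name: transcripts
    module: transcribe
    after: [fusions]
    params:
      abundance: fusions_abundance.tsv
      gtf: annotation.gtf
      patch: fusions_transcripts.mdf
      molecule_count: 1200
  - name: tail
    module: polya
    input: transcripts
    params:
      mu: 60
      sigma: 20
  - name: amplified
    module: pcr
    input: tail
    params:
      cycles: 1
      efficiency: 0.5
      error_rate: 0
  - name: reads
    module: sequence
    input: amplified
    params:
      reference: reference.fa
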