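# Bulk long-read RNA-seq: linear entry -> core -> exit chain.
steps:
  - name: transcripts
    module: transcribe
    params:
      abundance: abundance.tsv
      gtf: annotation.gtf
      molecule_count: 800
  - name: trunc
    module: truncate
    input: transcripts
    params:
      model: truncation_model.tsv
  - name: tail
    module: polya
    input: trunc
    params:
      mu: 60
      sigma: 20
  - name: adapters
    module: tag
    input: tail
    params:
      pattern5: "TTTCTGTTGGTGCTGATATTGC"
  - name: reads
    module: sequence
    input: adapters
    params:
      reference: reference.fa
      sub_rate: 0.03
      ins_rate: 0.02
      del_rate: 0.02
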