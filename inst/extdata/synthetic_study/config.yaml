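inputs:
  bs: bs.tsv
  oxbs: oxbs.tsv
  coverage_bs: coverage_bs.tsv
  coverage_ox: coverage_ox.tsv
  detection_p: detection_p.tsv
  sample_sheet: sample_sheet.tsv
  blacklist: blacklist.txt
  manifest: manifest_synthetic.csv
seed: 1
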