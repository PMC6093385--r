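seed: 1
cohorts:
  young:
  - Y1
  - Y2
  - Y3
  - Y4
  - Y5
  aged:
  - A1
  - A2
  - A3
  - A4
  - A5
reference_cohort: young
depth_tsv: demo_depth.tsv
lengths:
  t1: 100
  t2: 100
  t3: 100
  t4: 100
  t5: 100
filters:
  min_max_depth: 5
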