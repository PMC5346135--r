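mode: adult
ranges:
  etco2:
  - 0.0
  - 100.0
  rr:
  - 0.0
  - 60.0
  spo2:
  - 0.0
  - 110.0
  pr:
  - 0.0
  - 250.0
partitions:
  etco2:
    VL:
    - 0.0
    - 0.0
    - 5.0
    - 15.0
    L:
    - 5.0
    - 15.0
    - 28.0
    - 33.0
    'N':
    - 28.0
    - 33.0
    - 43.0
    - 48.0
    H:
    - 43.0
    - 48.0
    - 55.0
    - 60.0
    VH:
    - 55.0
    - 60.0
    - 100.0
    - 100.0
  rr:
    VL:
    - 0.0
    - 0.0
    - 4.0
    - 8.0
    L:
    - 4.0
    - 8.0
    - 10.0
    - 12.0
    'N':
    - 10.0
    - 12.0
    - 20.0
    - 24.0
    H:
    - 20.0
    - 24.0
    - 30.0
    - 35.0
    VH:
    - 30.0
    - 35.0
    - 60.0
    - 60.0
  spo2:
    L:
    - 0.0
    - 0.0
    - 85.0
    - 93.0
    'N':
    - 85.0
    - 93.0
    - 100.0
    - 105.0
    H:
    - 100.0
    - 105.0
    - 110.0
    - 110.0
  pr:
    L:
    - 0.0
    - 0.0
    - 45.0
    - 55.0
    'N':
    - 45.0
    - 55.0
    - 100.0
    - 115.0
    H:
    - 100.0
    - 115.0
    - 250.0
    - 250.0
rule_matrix:
  VL:
  - 1
  - 1
  - 2
  - 1
  - 1
  L:
  - 3
  - 5
  - 6
  - 4
  - 3
  'N':
  - 5
  - 8
  - 10
  - 8
  - 5
  H:
  - 4
  - 6
  - 8
  - 6
  - 3
  VH:
  - 3
  - 4
  - 5
  - 3
  - 2
spo2_drop:
  L: 7
  'N': 0
  H: 0
spo2_preserve_max: 3
pr_rules:
- pr: L
  etco2:
  - H
  - VH
  rr:
  - H
  - VH
  subtract: 1.0
- pr: H
  etco2:
  - L
  - VL
  rr:
  - L
  - VL
  subtract: 1.0
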