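{
  "comment": "Hand-enumerated A/CA/N values for the fixture predictions scored against the fixture compound table (5 expanded instances).",
  "n_instances": 5,
  "levels": {
    "level": [1, 2, 3, 4],
    "n": [5, 5, 5, 5],
    "A_count": [4, 4, 3, 3],
    "A": [80, 80, 60, 60],
    "CA": [80, 80, 73.33333333333333, 70],
    "N_count": [4, 4, 3, 2],
    "N": [80, 80, 60, 40]
  }
}
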