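{
  "task_id": "task1a",
  "reference_appearance": "transparent",
  "test_appearance": "transparent",
  "include_equal_pair": true,
  "dedup_policy": "within_appearance",
  "groups": {
    "A": {"reference": 4, "tests": [1, 2, 3, 5, 6, 7]},
    "B": {"reference": 7, "tests": [4, 5, 6, 8, 9, 10]},
    "C": {"reference": 10, "tests": [7, 8, 9, 11, 12, 13]},
    "D": {"reference": 13, "tests": [10, 11, 12, 14, 15, 16]},
    "E": {"reference": 18, "tests": [15, 16, 17, 19, 20, 21]}
  }
}
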