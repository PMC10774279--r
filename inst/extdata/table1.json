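{
  "comment": "Published demographic/clinical tables for the three diagnostic groups; rows UD, tBD, BD.",
  "sex_counts": [[43, 26], [14, 9], [30, 18]],
  "medication_counts": [[24, 45], [8, 15], [34, 14]],
  "first_episode_counts": [[59, 3, 7], [20, 2, 1], [18, 28, 2]],
  "hamd_summary": {
    "group": ["UD", "tBD", "BD"],
    "n": [69, 23, 48],
    "mean": [24.6, 24.3, 15.6],
    "sd": [8.1, 6.7, 7.3]
  }
}
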