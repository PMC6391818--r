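{
  "D4": {
    "predictors": ["miranda", "mirdb", "pita", "targetscan"],
    "t_true_1": [-0.179, -0.702, -0.449, 0.896],
    "t_false_1": [0.844, 0.059, 0.257, 0.982],
    "t_true_2": [0.067, -0.480, -0.203, 0.964],
    "t_false_2": [0.199, -0.269, -0.107, 0.972]
  }
}
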