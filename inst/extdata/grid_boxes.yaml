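"2IKH":
  center: [14.17, -0.095, 23.464]
  dims: [60, 40, 56]
"4IXC":
  center: [63.267, 25.856, 0.231]
  dims: [66, 72, 66]
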