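# Baseline nano-scale detector graph, 4 behaviour classes (stand/lie/eat/drink).
# Layer lines: [from, repeats, block, args]; widths are scaled by
# width_multiple (capped at max_channels, rounded up to multiples of 8),
# repeats by depth_multiple.
nc: 4
depth_multiple: 0.5
width_multiple: 0.25
max_channels: 1024
backbone:
  - [-1, 1, Conv, [64, 3, 2]]           # 0  P1/2
  - [-1, 1, Conv, [128, 3, 2]]          # 1  P2/4
  - [-1, 2, C3k2, [256, false, 0.25]]   # 2
  - [-1, 1, Conv, [256, 3, 2]]          # 3  P3/8
  - [-1, 2, C3k2, [512, false, 0.25]]   # 4
  - [-1, 1, Conv, [512, 3, 2]]          # 5  P4/16
  - [-1, 2, C3k2, [512, true]]          # 6
  - [-1, 1, Conv, [1024, 3, 2]]         # 7  P5/32
  - [-1, 2, C3k2, [1024, true]]         # 8
  - [-1, 1, SPPF, [1024, 5]]            # 9
  - [-1, 2, C2PSA, [1024]]              # 10
head:
  - [-1, 1, Upsample, [2]]              # 11
  - [[-1, 6], 1, Concat, []]            # 12
  - [-1, 2, C3k2, [512, false]]         # 13
  - [-1, 1, Upsample, [2]]              # 14
  - [[-1, 4], 1, Concat, []]            # 15
  - [-1, 2, C3k2, [256, false]]         # 16  P3 out
  - [-1, 1, Conv, [256, 3, 2]]          # 17
  - [[-1, 13], 1, Concat, []]           # 18
  - [-1, 2, C3k2, [512, false]]         # 19  P4 out
  - [-1, 1, Conv, [512, 3, 2]]          # 20
  - [[-1, 10], 1, Concat, []]           # 21
  - [-1, 2, C3k2, [1024, true]]         # 22  P5 out
  - [[16, 19, 22], 1, Detect, []]       # 23
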