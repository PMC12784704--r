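# Desk-scale variant for the toy training harness: same block vocabulary,
# reduced widths, intended for 64x64 inputs (grids 8/4/2 at strides 8/16/32).
nc: 4
depth_multiple: 1.0
width_multiple: 1.0
max_channels: 64
backbone:
  - [-1, 1, Conv, [8, 3, 2]]            # 0  P1/2
  - [-1, 1, Conv, [16, 3, 2]]           # 1  P2/4
  - [-1, 1, C3_GDConv, [16, false]]     # 2
  - [-1, 1, Conv, [32, 3, 2]]           # 3  P3/8
  - [-1, 1, C3_GDConv, [32, true]]      # 4  P3 out
  - [-1, 1, Conv, [64, 3, 2]]           # 5  P4/16
  - [-1, 1, FPSC, [64]]                 # 6  P4 out
  - [-1, 1, Conv, [64, 3, 2]]           # 7  P5/32
  - [-1, 1, CBAM, [4, 7]]               # 8  P5 out
head:
  - [[4, 6, 8], 1, EfficientHead, []]   # 9
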