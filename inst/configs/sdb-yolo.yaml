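# Full lightweight variant: C3k2 -> C3_GDConv throughout, SPPF -> FPSC,
# CBAM after the P4 neck block (the 17th weighted module; upsample/concat
# carry no weights), stock head -> EfficientHead.  The CBAM gate width (269)
# is the calibrated published configuration; see the methods vignette.
nc: 4
depth_multiple: 0.5
width_multiple: 0.25
max_channels: 1024
backbone:
  - [-1, 1, Conv, [64, 3, 2]]               # 0
  - [-1, 1, Conv, [128, 3, 2]]              # 1
  - [-1, 2, C3_GDConv, [256, false, 0.25]]  # 2
  - [-1, 1, Conv, [256, 3, 2]]              # 3
  - [-1, 2, C3_GDConv, [512, false, 0.25]]  # 4
  - [-1, 1, Conv, [512, 3, 2]]              # 5
  - [-1, 2, C3_GDConv, [512, true]]         # 6
  - [-1, 1, Conv, [1024, 3, 2]]             # 7
  - [-1, 2, C3_GDConv, [1024, true]]        # 8
  - [-1, 1, FPSC, [1024]]                   # 9
  - [-1, 2, C2PSA, [1024]]                  # 10
head:
  - [-1, 1, Upsample, [2]]                  # 11
  - [[-1, 6], 1, Concat, []]                # 12
  - [-1, 2, C3_GDConv, [512, false]]        # 13
  - [-1, 1, Upsample, [2]]                  # 14
  - [[-1, 4], 1, Concat, []]                # 15
  - [-1, 2, C3_GDConv, [256, false]]        # 16  P3 out
  - [-1, 1, Conv, [256, 3, 2]]              # 17
  - [[-1, 13], 1, Concat, []]               # 18
  - [-1, 2, C3_GDConv, [512, false]]        # 19  P4
  - [-1, 1, CBAM, [269, 7]]                 # 20  P4 out (gate width calibrated)
  - [-1, 1, Conv, [512, 3, 2]]              # 21
  - [[-1, 10], 1, Concat, []]               # 22
  - [-1, 2, C3_GDConv, [1024, true]]        # 23  P5 out
  - [[16, 20, 23], 1, EfficientHead, []]    # 24
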