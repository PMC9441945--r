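name: yolov5s-ghost-c3mb-cbam-head
nc: 4.0
depth_multiple: 0.33
width_multiple: 0.5
activation: silu
anchors:
- - 19.0
  - 27.0
  - 44.0
  - 40.0
  - 38.0
  - 94.0
- - 96.0
  - 68.0
  - 86.0
  - 152.0
  - 180.0
  - 137.0
- - 140.0
  - 301.0
  - 303.0
  - 264.0
  - 238.0
  - 542.0
- - 436.0
  - 615.0
  - 739.0
  - 380.0
  - 925.0
  - 792.0
backbone:
- from: -1.0
  repeats: 1.0
  kind: focus
  args:
  - 64.0
  - 3.0
- from: -1.0
  repeats: 1.0
  kind: ghost_conv
  args:
  - 128.0
  - 3.0
  - 2.0
- from: -1.0
  repeats: 3.0
  kind: c3ghost
  args:
  - 128.0
  - yes
- from: -1.0
  repeats: 1.0
  kind: ghost_conv
  args:
  - 256.0
  - 3.0
  - 2.0
- from: -1.0
  repeats: 9.0
  kind: c3ghost
  args:
  - 256.0
  - yes
- from: -1.0
  repeats: 1.0
  kind: ghost_conv
  args:
  - 512.0
  - 3.0
  - 2.0
- from: -1.0
  repeats: 9.0
  kind: c3ghost
  args:
  - 512.0
  - yes
- from: -1.0
  repeats: 1.0
  kind: ghost_conv
  args:
  - 1024.0
  - 3.0
  - 2.0
- from: -1.0
  repeats: 1.0
  kind: spp
  args:
  - 1024.0
  - - 5.0
    - 9.0
    - 13.0
- from: -1.0
  repeats: 3.0
  kind: c3mb
  args:
  - 1024.0
  - no
  - cbam
  - 6.0
head:
- from: -1.0
  repeats: 1.0
  kind: ghost_conv
  args:
  - 512.0
  - 1.0
  - 1.0
- from: -1.0
  repeats: 1.0
  kind: upsample
  args: []
- from:
  - -1.0
  - 7.0
  repeats: 1.0
  kind: concat
  args: []
- from: -1.0
  repeats: 3.0
  kind: c3mb
  args:
  - 512.0
  - no
  - cbam
  - 6.0
- from: -1.0
  repeats: 1.0
  kind: ghost_conv
  args:
  - 256.0
  - 1.0
  - 1.0
- from: -1.0
  repeats: 1.0
  kind: upsample
  args: []
- from:
  - -1.0
  - 5.0
  repeats: 1.0
  kind: concat
  args: []
- from: -1.0
  repeats: 3.0
  kind: c3mb
  args:
  - 256.0
  - no
  - cbam
  - 6.0
- from: -1.0
  repeats: 1.0
  kind: ghost_conv
  args:
  - 256.0
  - 3.0
  - 2.0
- from:
  - -1.0
  - 15.0
  repeats: 1.0
  kind: concat
  args: []
- from: -1.0
  repeats: 3.0
  kind: c3mb
  args:
  - 512.0
  - no
  - cbam
  - 6.0
- from: -1.0
  repeats: 1.0
  kind: ghost_conv
  args:
  - 512.0
  - 3.0
  - 2.0
- from:
  - -1.0
  - 11.0
  repeats: 1.0
  kind: concat
  args: []
- from: -1.0
  repeats: 3.0
  kind: c3mb
  args:
  - 1024.0
  - no
  - cbam
  - 6.0
- from: -1.0
  repeats: 1.0
  kind: ghost_conv
  args:
  - 1024.0
  - 3.0
  - 2.0
- from:
  - 18.0
  - 21.0
  - 24.0
  - 25.0
  repeats: 1.0
  kind: detect
  args: []
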