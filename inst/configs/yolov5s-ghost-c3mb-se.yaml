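name: yolov5s-ghost-c3mb-se
nc: 4.0
depth_multiple: 0.33
width_multiple: 0.5
activation: silu
anchors:
- - 10.0
  - 13.0
  - 16.0
  - 30.0
  - 33.0
  - 23.0
- - 30.0
  - 61.0
  - 62.0
  - 45.0
  - 59.0
  - 119.0
- - 116.0
  - 90.0
  - 156.0
  - 198.0
  - 373.0
  - 326.0
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
  - se
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
  - se
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
  - se
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
  - se
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
  - se
  - 6.0
- from:
  - 18.0
  - 21.0
  - 24.0
  repeats: 1.0
  kind: detect
  args: []
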