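distance_universe:
- 0.0
- 720.0
distance_anchors:
  right:
    too_far: 150.0
    far: 300.0
    close: 450.0
    too_close: 600.0
  left:
    too_far: 150.0
    far: 300.0
    close: 450.0
    too_close: 600.0
iou_universe:
- 0.0
- 100.0
iou_anchors:
  too_far: 100.0
  far: 53.926991150442483
  close: 14.999999999999982
  too_close: 0.0
iou_sigmas:
  too_far: 19.565405410396011
  far: 16.530771101844806
  close: 6.369913502160135
  too_close: 6.369913502160135
output_universe:
- 0.0
- 100.0
output_sets:
  low:
  - 0.0
  - 0.0
  - 30.0
  ok:
  - 30.0
  - 50.0
  - 70.0
  high:
  - 70.0
  - 100.0
  - 100.0
nms_threshold: 0.5
resolution: 0.1
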