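# symmetric trapezoid with Tube A's included angle (29.05 degrees):
# exit opening 200 px wide at x = 400, entrance widened by 2*400*tan(14.525 deg)
tube_id: A
wall_left:
  - [0.0, 203.6330]
  - [400.0, 100.0]
wall_right:
  - [0.0, -203.6330]
  - [400.0, -100.0]
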