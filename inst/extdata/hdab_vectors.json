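{
  "hematoxylin": [0.650, 0.704, 0.286],
  "dab": [0.269, 0.568, 0.778],
  "background": [255, 255, 255]
}
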