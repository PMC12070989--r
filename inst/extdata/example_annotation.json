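{
  "version": "5.2.1",
  "flags": {},
  "shapes": [
    {
      "label": "CIN2",
      "points": [[20.0, 24.0], [58.0, 18.0], [74.0, 48.0], [52.0, 76.0], [22.0, 60.0]],
      "shape_type": "polygon"
    },
    {
      "label": "CIN2",
      "points": [[86.0, 84.0], [112.0, 88.0], [108.0, 114.0], [84.0, 110.0]],
      "shape_type": "polygon"
    }
  ],
  "imageHeight": 128,
  "imageWidth": 128
}
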