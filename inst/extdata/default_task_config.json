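{
  "screen": {
    "width_px": 1680,
    "height_px": 1050,
    "width_cm": 47.4,
    "height_cm": 29.6,
    "viewing_distance_cm": 50
  },
  "aois": {
    "face": [740, 100, 940, 330],
    "object_left": [200, 600, 480, 850],
    "object_right": [1200, 600, 1480, 850],
    "moving_object": [520, 620, 1160, 860]
  },
  "tasks": [
    {
      "task": "RJA",
      "segments_ms": { "looking_down": 2000, "interaction": 2000, "ja": 4000 },
      "trials": [
        { "target_side": "left" },
        { "target_side": "right" },
        { "target_side": "right" },
        { "target_side": "left" }
      ]
    },
    {
      "task": "IJA1",
      "segments_ms": { "looking_down": 2000, "interaction": 2000, "ja": 7000 },
      "trials": [
        { "target_side": "right" },
        { "target_side": "left" },
        { "target_side": "right" },
        { "target_side": "left" }
      ]
    },
    {
      "task": "IJA2",
      "segments_ms": { "looking_down": 2000, "interaction": 2000, "ja": 7000 },
      "trials": [
        { "target_side": "center" },
        { "target_side": "center" },
        { "target_side": "center" },
        { "target_side": "center" }
      ]
    }
  ]
}
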