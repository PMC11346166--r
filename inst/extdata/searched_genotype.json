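{
  "depth": 5,
  "encoders": [
    {"pattern": "1110", "filters": 128, "se": true, "se_ratio": 16},
    {"pattern": "0110", "filters": 256, "se": true, "se_ratio": 4},
    {"pattern": "0111", "filters": 64, "se": false, "se_ratio": null},
    {"pattern": "1110", "filters": 128, "se": true, "se_ratio": 8},
    {"pattern": "0010", "filters": 256, "se": false, "se_ratio": null}
  ],
  "decoders": [
    {"pattern": "0111", "filters": 8, "se": true, "se_ratio": 8},
    {"pattern": "0001", "filters": 128, "se": true, "se_ratio": 8},
    {"pattern": "1100", "filters": 64, "se": true, "se_ratio": 8},
    {"pattern": "0010", "filters": 128, "se": false, "se_ratio": null},
    {"pattern": "0010", "filters": 8, "se": true, "se_ratio": 4}
  ]
}
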