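{
  "ppr": {
    "sitting": 88.7,
    "standing": 84.6,
    "walking": 98.8
  },
  "split": {
    "sitting": {
      "standing": 33.3,
      "walking": 0
    },
    "standing": {
      "sitting": 46.2,
      "walking": 100
    },
    "walking": {
      "sitting": 53.8,
      "standing": 66.6
    }
  }
}
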