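{
  "perfect": {
    "seg": 1,
    "det": 1,
    "tra": 1,
    "counts": {
      "ns": 0,
      "fn": 0,
      "fp": 0,
      "ed": 0,
      "ea": 0,
      "ec": 0
    }
  },
  "broken_link": {
    "seg": 1,
    "det": 1,
    "tra": 0.977272727272727,
    "counts": {
      "ns": 0,
      "fn": 0,
      "fp": 0,
      "ed": 0,
      "ea": 1,
      "ec": 0
    }
  },
  "missing_cell": {
    "seg": 0.5,
    "det": 0.5,
    "tra": 0.5,
    "counts": {
      "ns": 0,
      "fn": 3,
      "fp": 0,
      "ed": 0,
      "ea": 2,
      "ec": 0
    }
  },
  "missed_division": {
    "seg": 1,
    "det": 1,
    "tra": 0.962962962962963,
    "counts": {
      "ns": 0,
      "fn": 0,
      "fp": 0,
      "ed": 0,
      "ea": 1,
      "ec": 1
    }
  },
  "overseg": {
    "seg": 0.8125,
    "det": 0.95,
    "tra": 0.953488372093023,
    "counts": {
      "ns": 0,
      "fn": 0,
      "fp": 1,
      "ed": 0,
      "ea": 0,
      "ec": 0
    }
  },
  "spurious": {
    "seg": 1,
    "det": 0.9,
    "tra": 0.848484848484849,
    "counts": {
      "ns": 0,
      "fn": 0,
      "fp": 3,
      "ed": 2,
      "ea": 0,
      "ec": 0
    }
  },
  "merged": {
    "seg": 0.5,
    "det": 0.75,
    "tra": 0.767441860465116,
    "counts": {
      "ns": 2,
      "fn": 0,
      "fp": 0,
      "ed": 0,
      "ea": 0,
      "ec": 0
    }
  }
}
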