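{
  "references": [
    "[CH2:1]=[CH2:2].[CH2:3]=[CH:4][CH:5]=[CH2:6]>>[CH2:1]1[CH2:2][CH2:3][CH:4]=[CH:5][CH2:6]1"
  ],
  "template": null,
  "alpha": 1.0,
  "threshold": 0.0,
  "stereo": false,
  "fragmentation": {
    "scheme": "IAB",
    "minLength": 2,
    "maxLength": 4,
    "formalCharge": true,
    "radicalsLonePairs": true
  }
}
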