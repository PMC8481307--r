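{
  "title": "brainprint pipeline report",
  "required": {
    "meta": { "mandatory": true, "type": "object" },
    "accuracies": { "mandatory": true, "type": "array" },
    "reliability_summary": { "mandatory": true, "type": "array" },
    "confounds": { "mandatory": true, "type": "array" },
    "empty_room": { "mandatory": false, "type": "array" },
    "pls": { "mandatory": false, "type": "object" }
  }
}
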