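{
  "nodes": ["A", "B"],
  "stimulus_nodes": ["A"],
  "observable_nodes": ["B"],
  "rules": {
    "B": "2*A(t-3)"
  }
}
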