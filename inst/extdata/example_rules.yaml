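# Minimal three-marker panel for the worked example.
rules:
  - {name: "CK+",   panel: 0, positive: [CK]}
  - {name: "CD3+",  panel: 0, positive: [CD3]}
  - {name: "CD68+", panel: 0, positive: [CD68]}
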