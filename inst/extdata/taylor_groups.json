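{
  "comment": "Taylor's ten overlapping physicochemical amino-acid groups",
  "groups": {
    "hydrophobic": ["A","G","C","T","I","V","L","K","H","F","Y","W","M"],
    "aromatic":    ["F","Y","W","H"],
    "aliphatic":   ["I","V","L"],
    "tiny":        ["A","S","G","C"],
    "small":       ["P","N","D","T","C","A","G","S","V"],
    "proline":     ["P"],
    "charged":     ["K","H","R","D","E"],
    "negative":    ["D","E"],
    "polar":       ["N","Q","S","D","E","C","T","K","R","H","Y","W"],
    "positive":    ["K","H","R"]
  }
}
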