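{
  "name": "four gene-pair DLBCL signature (synthetic pairing)",
  "provenance": "The seven published prognostic genes of the four-pair DLBCL signature (favorable: NEK6, RARRES2, CHRNA1; unfavorable: URI1, NIPA2, ZNF22, WDR12). The published gene-to-pair assignment is only available as figure panels, not machine-readable text, so THIS PAIRING IS A SYNTHETIC BEST-EFFORT RECONSTRUCTION suitable for exercising the scoring code, not a verified transcription. Replace the pairs before any scientific use.",
  "pairs": [
    { "upg": "URI1", "fpg": "NEK6" },
    { "upg": "NIPA2", "fpg": "RARRES2" },
    { "upg": "ZNF22", "fpg": "CHRNA1" },
    { "upg": "WDR12", "fpg": "NEK6" }
  ]
}
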