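{
  "comment": "Binding-site residues per channel and site. TASK-1: single lateral fenestration (chains A and B); Nav1.5: local-anesthetic site, domains III-IV; Kv1.5: central cavity (CC, chains A-D) and side pockets (SP, chains A-B).",
  "sites": [
    {
      "channel": "TASK-1",
      "site": "fenestration",
      "residues": [
        {"chain": "A", "aa": "Q", "resno": 126},
        {"chain": "A", "aa": "L", "resno": 171},
        {"chain": "A", "aa": "F", "resno": 194},
        {"chain": "A", "aa": "T", "resno": 198},
        {"chain": "A", "aa": "T", "resno": 199},
        {"chain": "A", "aa": "V", "resno": 234},
        {"chain": "A", "aa": "I", "resno": 235},
        {"chain": "A", "aa": "G", "resno": 236},
        {"chain": "A", "aa": "F", "resno": 238},
        {"chain": "A", "aa": "L", "resno": 239},
        {"chain": "A", "aa": "N", "resno": 240},
        {"chain": "B", "aa": "T", "resno": 93},
        {"chain": "B", "aa": "M", "resno": 111},
        {"chain": "B", "aa": "A", "resno": 114},
        {"chain": "B", "aa": "I", "resno": 118}
      ]
    },
    {
      "channel": "NaV1.5",
      "site": "LA",
      "residues": [
        {"chain": "A", "aa": "L", "resno": 1462},
        {"chain": "A", "aa": "I", "resno": 1466},
        {"chain": "A", "aa": "F", "resno": 1760},
        {"chain": "A", "aa": "Y", "resno": 1767}
      ]
    },
    {
      "channel": "KV1.5",
      "site": "CC",
      "residues": [
        {"chain": "A", "aa": "T", "resno": 480},
        {"chain": "A", "aa": "I", "resno": 508},
        {"chain": "A", "aa": "V", "resno": 512},
        {"chain": "A", "aa": "V", "resno": 516},
        {"chain": "B", "aa": "T", "resno": 480},
        {"chain": "B", "aa": "I", "resno": 508},
        {"chain": "B", "aa": "V", "resno": 512},
        {"chain": "B", "aa": "V", "resno": 516},
        {"chain": "C", "aa": "T", "resno": 480},
        {"chain": "C", "aa": "I", "resno": 508},
        {"chain": "C", "aa": "V", "resno": 512},
        {"chain": "C", "aa": "V", "resno": 516},
        {"chain": "D", "aa": "T", "resno": 480},
        {"chain": "D", "aa": "I", "resno": 508},
        {"chain": "D", "aa": "V", "resno": 512},
        {"chain": "D", "aa": "V", "resno": 516}
      ]
    },
    {
      "channel": "KV1.5",
      "site": "SP",
      "residues": [
        {"chain": "A", "aa": "L", "resno": 436},
        {"chain": "A", "aa": "F", "resno": 439},
        {"chain": "A", "aa": "F", "resno": 440},
        {"chain": "A", "aa": "I", "resno": 443},
        {"chain": "A", "aa": "I", "resno": 502},
        {"chain": "A", "aa": "L", "resno": 510},
        {"chain": "B", "aa": "L", "resno": 436},
        {"chain": "B", "aa": "F", "resno": 439},
        {"chain": "B", "aa": "F", "resno": 440},
        {"chain": "B", "aa": "I", "resno": 443},
        {"chain": "B", "aa": "I", "resno": 502},
        {"chain": "B", "aa": "L", "resno": 510}
      ]
    }
  ]
}
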