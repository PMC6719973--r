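{
  "optimum": "RGIFFYVFAAYKEI",
  "original": "RGISQAVHAAHAEI",
  "seed": 101,
  "noise": 0,
  "planted": {
    "4": {
      "residue": "PHE",
      "type": "lipophilic"
    },
    "5": {
      "residue": "PHE",
      "type": "lipophilic"
    },
    "6": {
      "residue": "TYR",
      "type": "acceptor"
    },
    "7": {
      "residue": "VAL",
      "type": "lipophilic"
    },
    "8": {
      "residue": "PHE",
      "type": "lipophilic"
    },
    "9": {
      "residue": "ALA",
      "type": "lipophilic"
    },
    "10": {
      "residue": "ALA",
      "type": "lipophilic"
    },
    "11": {
      "residue": "TYR",
      "type": "acceptor"
    },
    "12": {
      "residue": "LYS",
      "type": "charged-"
    }
  },
  "pocket_atoms": 83
}
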