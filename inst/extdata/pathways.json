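{
  "universe": ["HMDB0000122", "HMDB0000094", "HMDB0000254", "HMDB0000134",
               "HMDB0000156", "HMDB0000208", "HMDB0000243", "HMDB0000190",
               "HMDB0000673", "HMDB0000207", "HMDB0000215", "HMDB0000169"],
  "pathways": {
    "tca_cycle": {
      "name": "Citrate cycle (TCA cycle)",
      "compounds": ["HMDB0000094", "HMDB0000254", "HMDB0000134",
                    "HMDB0000156", "HMDB0000208", "HMDB0000243"]
    },
    "glycolysis": {
      "name": "Glycolysis / Gluconeogenesis",
      "compounds": ["HMDB0000122", "HMDB0000243", "HMDB0000190"]
    },
    "n_glycan_biosynthesis": {
      "name": "N-Glycan biosynthesis",
      "compounds": ["HMDB0000215", "HMDB0000169"]
    },
    "unsat_fa_biosynthesis": {
      "name": "Biosynthesis of unsaturated fatty acids",
      "compounds": ["HMDB0000673", "HMDB0000207"]
    }
  }
}
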