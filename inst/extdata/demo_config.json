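{
  "simulate": true,
  "design": {
    "treatments": ["T1", "T2", "T3", "T4", "T5", "T6", "T7", "T8", "T9", "T10"],
    "control": "CK",
    "seeds_per_dish": 30,
    "dishes_per_treatment": 4,
    "physio_bio_reps": 4,
    "physio_tech_reps": 3
  },
  "effects": "demo",
  "control": "CK",
  "alpha": 0.05,
  "seed": 20240601,
  "ri_level": "treatment",
  "normalization": "vector"
}
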