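[
  {"name": "vegetables",          "kind": "adequacy",    "cutoff": 200, "unit": "g/d"},
  {"name": "fruit",               "kind": "adequacy",    "cutoff": 200, "unit": "g/d"},
  {"name": "whole_grains",        "kind": "adequacy",    "cutoff": 90,  "unit": "g/d"},
  {"name": "legumes",             "kind": "adequacy",    "cutoff": 135, "unit": "g/w"},
  {"name": "nuts",                "kind": "adequacy",    "cutoff": 15,  "unit": "g/d"},
  {"name": "dairy",               "kind": "adequacy",    "cutoff": 300, "unit": "g/d"},
  {"name": "fish",                "kind": "adequacy",    "cutoff": 100, "unit": "g/w"},
  {"name": "tea",                 "kind": "adequacy",    "cutoff": 450, "unit": "g/d"},
  {"name": "grain_quality_ratio", "kind": "ratio",       "cutoff": 1,   "unit": "ratio"},
  {"name": "soft_fat_ratio",      "kind": "ratio",       "cutoff": 1,   "unit": "ratio"},
  {"name": "red_meat",            "kind": "moderation",  "cutoff": 375, "unit": "g/w"},
  {"name": "sugary_beverages",    "kind": "moderation",  "cutoff": 150, "unit": "g/d"},
  {"name": "alcohol",             "kind": "binary",      "cutoff": null, "unit": "any"},
  {"name": "salt",                "kind": "moderation",  "cutoff": 6,   "unit": "g/d"},
  {"name": "folic_acid",          "kind": "categorical", "cutoff": null, "unit": "category"}
]
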