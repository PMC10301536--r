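{
  "version": "1.0",
  "source": "published gender-specific mean soft-tissue volumes and percentage shares of the lower two-thirds (attractive orthognathic cohort, n=26 female / n=20 male)",
  "units": {"mean_volumes": "mm3", "printed_shares": "percent"},
  "female": {
    "mean_volumes": {"malar": 283005, "maxillary": 212433, "mandibular": 202279, "chin": 34340},
    "printed_shares": {"malar": 38.7, "maxillary": 29.0, "mandibular": 27.6, "chin": 4.7},
    "flags": []
  },
  "male": {
    "mean_volumes": {"malar": 300436, "maxillary": 230526, "mandibular": 242905, "chin": 49444},
    "printed_shares": {"malar": 37, "maxillary": 26, "mandibular": 30, "chin": 6},
    "flags": [
      "printed male shares sum to 99",
      "printed malar share (37) inconsistent with mean volumes (computed 36.5)",
      "printed maxillary share (26) inconsistent with mean volumes (computed 28.0)",
      "the discussion section attributes the 29/27.6 pair and ratio 1.05 to males, swapping the gender labels of the results section; values stored as printed in the results section"
    ]
  }
}
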