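{
  "version": "1.0",
  "east_asian": {
    "terms": [
      {"variant_id": "rs9269027", "effect_allele": "A", "weight": 0.69173},
      {"variant_id": "rs1974461", "effect_allele": "T", "weight": 1.23685},
      {"variant_id": "rs6707458", "effect_allele": "G", "weight": 0.36687},
      {"variant_id": "rs230540",  "effect_allele": "C", "weight": 0.25098},
      {"variant_id": "rs9405192", "effect_allele": "G", "weight": 0.39127}
    ],
    "interaction_terms": [
      {"variant_a": "rs9269027", "variant_b": "rs6707458", "weight": 0.48798}
    ],
    "control_mean": 1.6804,
    "control_sd": 1.0033
  },
  "european": {
    "terms": [
      {"variant_id": "rs9271541", "effect_allele": "C", "weight": 0.34945},
      {"variant_id": "rs9265949", "effect_allele": "T", "weight": 0.67919},
      {"variant_id": "rs2858309", "effect_allele": "C", "weight": 0.30707},
      {"variant_id": "rs6707458", "effect_allele": "G", "weight": 0.34601},
      {"variant_id": "rs230540",  "effect_allele": "C", "weight": 0.17450},
      {"variant_id": "rs9405192", "effect_allele": "G", "weight": 0.18343}
    ],
    "interaction_terms": [
      {"variant_a": "rs9271541", "variant_b": "rs6707458", "weight": 0.33782}
    ],
    "control_mean": 1.5089,
    "control_sd": 0.8202
  },
  "crs": {
    "east_asian": {
      "weight": 1.7712,
      "control_mean": 0.3724,
      "control_sd": 2.7503,
      "offset": 0.001
    },
    "european": {
      "weight": 0.4829,
      "control_mean": -1.4982,
      "control_sd": 1.4354,
      "offset": 0.001
    }
  }
}
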