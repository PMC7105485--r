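{
  "ethnicity": "east_asian",
  "n_cases": 1000,
  "n_controls": 2000,
  "seed": 20200330,
  "out_dir": "mnarch-demo-results",
  "stages": ["simulate", "grs", "serology", "crs", "assoc", "condition",
             "interact", "credible", "diagnose"]
}
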