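{
  "note": "Oracle-true effects of the default synthetic-data configuration, computed by direct simulation from the true structural models (not from fitted equations).",
  "generator": "true_effects(dgp_config(), oracle_n = 1e6, rng_seed = 20260101)",
  "true_tce": 0.142421622007107,
  "true_nde": 0.132278684903408,
  "true_nie": 0.010142937103699,
  "true_prop_mediated": 0.0712176772091026,
  "counterfactual_means": {
    "mu_11": 0.86660257627114,
    "mu_00": 0.724180954264033,
    "mu_10": 0.856459639167441
  },
  "oracle_n": 1000000
}
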