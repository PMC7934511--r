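{
  "selection": [
    {"method": "none", "k_fraction": 1},
    {"method": "chi2", "k_fraction": 0.5}
  ],
  "algorithms": [
    {"algorithm": "logistic_regression", "params": [{"lambda": 0.001}]},
    {"algorithm": "random_forest",
     "params": [{"n_estimators": 1000, "max_features": "sqrt"}]},
    {"algorithm": "gradient_boosting",
     "params": [{"n_estimators": 100, "max_depth": 3, "eta": 0.1}]},
    {"algorithm": "naive_bayes", "params": [{}]},
    {"algorithm": "knn", "params": [{"k": 11}]}
  ]
}
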