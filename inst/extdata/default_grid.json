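{
  "selection": [
    {"method": "none", "k_fraction": 1},
    {"method": "chi2", "k_fraction": 0.75},
    {"method": "chi2", "k_fraction": 0.5},
    {"method": "chi2", "k_fraction": 0.25},
    {"method": "rfe", "k_fraction": 0.5},
    {"method": "stability", "k_fraction": 0.5}
  ],
  "algorithms": [
    {"algorithm": "logistic_regression", "params": [{"lambda": 0.001}]},
    {"algorithm": "decision_tree",
     "params": [{"criterion": "gini"}, {"criterion": "information"}]},
    {"algorithm": "random_forest",
     "params": [{"n_estimators": 1000, "max_features": "sqrt"},
                {"n_estimators": 500, "max_features": "sqrt"}]},
    {"algorithm": "gradient_boosting",
     "params": [{"n_estimators": 100, "max_depth": 3, "eta": 0.1},
                {"n_estimators": 200, "max_depth": 2, "eta": 0.1}]},
    {"algorithm": "adaboost", "params": [{"n_estimators": 50}]},
    {"algorithm": "mlp",
     "params": [{"hidden_size": 8, "decay": 0.001},
                {"hidden_size": 16, "decay": 0.0001}]},
    {"algorithm": "naive_bayes", "params": [{}]},
    {"algorithm": "knn", "params": [{"k": 5}, {"k": 11}]},
    {"algorithm": "svm",
     "params": [{"kernel": "radial", "cost": 1},
                {"kernel": "linear", "cost": 1}]}
  ]
}
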