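{
  "comment": "Hyperparameter grids used for nested model selection. NB carries no tunable parameters.",
  "LR":   {"C": [1e-06, 1e-05, 1e-04, 1e-03, 1e-02, 1e-01, 1, 10, 100]},
  "MLP":  {"alpha": [1e-07, 1e-06, 1e-05, 1e-04, 1e-03, 1e-02],
           "n_neurons": [5, 10, 20, 30, 40, 50],
           "max_iter": [500, 1000, 1500]},
  "RF":   {"n_trees": [10, 100, 1000],
           "criterion": ["gini", "entropy"],
           "max_depth": [3, 4, 5, 6, 10],
           "min_samples": [2, 3, 4, 5, 6, 7, 8, 9]},
  "SVM":  {"C": [1e-04, 1e-03, 1e-02, 1e-01, 1, 10, 100],
           "gamma": [1e-04, 1e-03, 1e-02, 1e-01, 1, 10, 100]},
  "C4.5": {"max_depth": [1, 3, 5, 7, 9, 11, 13, 15, 17, 19],
           "min_samples": [10, 30, 50, 70, 90, 110, 130, 150, 170, 190, 210, 230, 250, 270, 290, 310, 330, 350, 370, 390, 410, 430, 450, 470, 490]},
  "NB":   {},
  "kNN":  {"k": [2, 3, 4, 5]},
  "GB":   {"n_trees": [10, 100, 1000],
           "learning_rate": [0.1, 0.5, 0.7, 1],
           "max_depth": [3, 4, 5, 6, 10],
           "min_samples": [2, 3, 4, 5, 6, 7, 8, 9]}
}
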