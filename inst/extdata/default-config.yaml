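# Pinned defaults for the echodml pipeline. Every tunable default of the
# package appears here so results stay reproducible even if library
# defaults drift.

schema:
  builtin: default
  confounding: 1.0          # scales all dependency-edge weights

plr:
  treatment: Mets           # designated treatment flag for simulation
  theta0: 0.5               # true effect on the latent outcome scale
  g0_form: linear           # linear | nonlinear_interactions
  m0_form: linear_logit     # linear_logit | nonlinear_logit
  outcome_link: latent_threshold  # latent_threshold | linear_probability | identity
  outcome_noise_sd: 1.0     # sd of the Gaussian disturbance U
  target_prevalence: 0.2    # marginal fraction of urgent records
  n_records: 5000
  seed: 1

label:
  threshold_days: 2         # urgent iff interval_days <= threshold

crossfit:
  n_folds: 5
  n_repetitions: 10
  seed: 1

prediction:
  threshold: 0.5            # urgency score cutoff

evaluation:
  n_folds: 5
  n_iterations: 3

effects:
  alpha: 0.05
  unreliable_floor: 10      # minimum treated rows for a reliable estimate

learners:
  nuisance: gradient_boosting
  naive_bayes:
    laplace: 1
  weighted_logistic: {}
  deep_learning:
    hidden: [16, 8]
    epochs: 150
    lr: 0.01
    l2: 1.0e-4
  decision_tree:
    max_depth: 6
    min_n: 20
  random_forest:
    n_trees: 100
    max_depth: 8
    min_n: 10
  gradient_boosting:
    n_trees: 150
    learn_rate: 0.1
    max_depth: 2
    min_n: 10
  svm:
    cost: 1
    maxit: 200
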