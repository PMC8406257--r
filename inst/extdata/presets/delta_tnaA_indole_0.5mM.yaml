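name: delta_tnaA_indole_0.5mM
fate_probs:
- 0.001
- 0.045
- 0.954
t0_ph:
  persister:
    means: 7.6
    sds: 0.2
    weights: 1.0
  vbnc:
    means: 7.6
    sds: 0.2
    weights: 1.0
  susceptible:
    means: 7.6
    sds: 0.2
    weights: 1.0
anchors:
  persister:
    time_h:
    - 0.0
    - 24.0
    ph:
    - 7.6
    - 7.6
  vbnc:
    time_h:
    - 0.0
    - 3.0
    - 24.0
    ph:
    - 7.6
    - 7.0
    - 7.0
  susceptible:
    time_h:
    - 0.0
    - 3.0
    - 24.0
    ph:
    - 7.6
    - 7.0
    - 7.0
traj_sd: 0.1
expression_mean: 1.0
expression_cv: 0.25
expression_24h_factor:
- 2.0
- 2.0
- 0.3
pi_fold:
- 1.0
- 1.0
- 3.0
susceptible_lysed_frac: 0.5
lysis_window:
- 1.0
- 6.0
division_window:
- 3.0
- 24.0
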