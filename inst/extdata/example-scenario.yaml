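# Example vaxgame scenario: analytic table, a behavioural run, and a short
# demonstration-scale Monte Carlo simulation.
#   run_scenario(system.file("extdata", "example-scenario.yaml", package = "vaxgame"))
seed: 1
out_dir: vaxgame-example
game:
  R0: [5, 10, 15, 20]
  r: 0.1
behavioral:
  r_v: 1
  r_i: 10
  horizon: 100
ibmc:
  "N": 300
  "L": 135
  p_vacc: 0.4
  t_end: 200
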