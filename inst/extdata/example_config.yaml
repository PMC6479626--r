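# Example scenario configuration for the fs-abm command line runner.
#
# The skyloo grid reproduces the four financing scenarios of the adoption
# study: start-up capital {MK10M, MK2M} x monthly repayment {MK9320, MK7000}.

environment:
  n_households: 3026
  owner_fraction: 0.5
  income_mean: 44000
  income_sd: 44000
  p_initial_skyloo: 0.003

network:
  k: 4
  p_rewire: 0.2

skyloo:
  build_cost: 200000
  operating_cost: 85000
  n_ticks: 2000

grid:
  high_9320: {startup_capital: 10000000, monthly_repayment: 9320}
  high_7000: {startup_capital: 10000000, monthly_repayment: 7000}
  low_9320:  {startup_capital: 2000000,  monthly_repayment: 9320}
  low_7000:  {startup_capital: 2000000,  monthly_repayment: 7000}
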