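# Small populations + networks used across tests; everything is generated
# in code under fixed seeds.

tiny_env <- function(n = 200, seed = 1, ...) {
  generate_households(environment_config(n_households = n, ...), seed = seed)
}

tiny_net <- function(n = 200, seed = 2, k = 4, p = 0.2) {
  build_small_world(n, k, p, seed = seed)
}

# a household row with all adoption multipliers exactly 1 under the default
# environment_config (flood mult 1 at proximity 2/3; land mult 1 at the
# range midpoint-of-scale 1050)
neutral_household <- function(tenure = "owner", income = 44000,
                              open_to_reuse = TRUE) {
  data.frame(tenure = tenure, income = income, open_to_reuse = open_to_reuse,
             flood_proximity = 2 / 3, land_size = 1050,
             stringsAsFactors = FALSE)
}
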