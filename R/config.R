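#' @keywords internal
"_PACKAGE"

## Validation helpers shared by the config constructors. Errors always name
## the offending field so scenario files fail loudly before any run.

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

check_prob <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_config(field, "must be a probability in [0, 1]")
  x
}

check_pos <- function(x, field, strict = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) && (if (strict) x > 0 else x >= 0)
  if (!ok) stop_config(field, if (strict) "must be > 0" else "must be >= 0")
  x
}

check_count <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != floor(x))
    stop_config(field, "must be a positive integer count")
  as.integer(x)
}

#' Configuration of the synthetic household environment
#'
#' Parameters of the synthetic urban household population and its spatial
#' covariates. The defaults describe a peri-urban Malawian study area:
#' 3026 households, a 50/50 owner/tenant split, household size around
#' 6 +/- 2 persons, monthly income with mean and standard deviation both
#' MK44,000 (a coefficient of variation of 1, hence the lognormal income
#' model used by [sample_income()]), 0.3% of households already owning a
#' Skyloo, and 64/148 of households open to reusing faecal sludge.
#'
#' The map is an abstract square of side `map_side`; a flood-prone strip
#' ("dambo") of width `flood_zone_width` runs along the x = 0 edge.
#' `flood_proximity` of a household is the perpendicular distance to the
#' strip, normalised to [0, 1] over the rest of the map (0 = inside the
#' strip). Plot sizes are uniform on `land_size_range`.
#'
#' `mult_high` and `mult_low` are the endpoints of the sliding-scale
#' adoption multipliers applied for flood proximity and plot size: a
#' household inside the flood strip (or on the smallest plot) is
#' `mult_high` times as receptive as the baseline, one at the far edge (or
#' on the largest plot) `mult_low` times.
#'
#' @param n_households number of households.
#' @param owner_fraction probability that a household owns its dwelling.
#' @param household_size_mean,household_size_sd moments of household size
#'   (persons); draws are rounded and floored at 1.
#' @param income_mean,income_sd moments of monthly income (MK).
#' @param p_initial_skyloo probability a household starts with a Skyloo
#'   already installed.
#' @param p_open_to_reuse probability a household is open to FS reuse.
#' @param map_side side of the square map (abstract length units).
#' @param flood_zone_width width of the flood-prone strip along one edge.
#' @param land_size_range length-2 numeric, range of plot sizes (area units).
#' @param mult_high,mult_low endpoints of the sliding-scale multipliers.
#' @return An object of class `environment_config` (a validated list).
#' @seealso [generate_households()]
#' @export
environment_config <- function(n_households = 3026,
                               owner_fraction = 0.5,
                               household_size_mean = 6,
                               household_size_sd = 2,
                               income_mean = 44000,
                               income_sd = 44000,
                               p_initial_skyloo = 0.003,
                               p_open_to_reuse = 64 / 148,
                               map_side = 1000,
                               flood_zone_width = 100,
                               land_size_range = c(150, 1500),
                               mult_high = 1.5,
                               mult_low = 0.75) {
  cfg <- list(
    n_households = check_count(n_households, "n_households"),
    owner_fraction = check_prob(owner_fraction, "owner_fraction"),
    household_size_mean = check_pos(household_size_mean, "household_size_mean"),
    household_size_sd = check_pos(household_size_sd, "household_size_sd", strict = FALSE),
    income_mean = check_pos(income_mean, "income_mean"),
    income_sd = check_pos(income_sd, "income_sd", strict = FALSE),
    p_initial_skyloo = check_prob(p_initial_skyloo, "p_initial_skyloo"),
    p_open_to_reuse = check_prob(p_open_to_reuse, "p_open_to_reuse"),
    map_side = check_pos(map_side, "map_side"),
    flood_zone_width = check_pos(flood_zone_width, "flood_zone_width"),
    land_size_range = land_size_range,
    mult_high = check_pos(mult_high, "mult_high"),
    mult_low = check_pos(mult_low, "mult_low")
  )
  if (!is.numeric(land_size_range) || length(land_size_range) != 2L ||
      any(land_size_range <= 0) || land_size_range[1] >= land_size_range[2])
    stop_config("land_size_range", "must be an increasing positive length-2 range")
  if (flood_zone_width >= map_side)
    stop_config("flood_zone_width", "must be smaller than map_side")
  if (mult_low > mult_high)
    stop_config("mult_low", "must not exceed mult_high")
  structure(cfg, class = "environment_config")
}

#' Configuration of the Skyloo adoption model
#'
#' One simulated tick is a day; a month is `month_length` ticks. The
#' business starts with `startup_capital`, builds at most `build_capacity`
#' Skyloos per day at `build_cost` each (issuing a loan repaid at
#' `monthly_repayment` with `monthly_interest` accruing on the balance),
#' and pays `operating_cost` every month. Awareness arrives through a
#' one-off marketing push to `initial_contacts` random households
#' (per-contact success `p_marketing`) and daily word of mouth along
#' network links from households that are installed or on the waiting list
#' (per-link daily success `p_neighbour`); both channels are scaled by the
#' tenant, flood and plot-size multipliers. An aware household adopts iff
#' it is open to reuse and the repayment does not exceed
#' `affordability_fraction` of its monthly income; adopters who wait more
#' than `wait_limit` days for construction abandon the technology.
#'
#' @param startup_capital business start-up capital, MK (scenarios
#'   10,000,000 and 2,000,000).
#' @param build_cost cost of one Skyloo including mason, MK.
#' @param build_capacity maximum builds per day.
#' @param operating_cost monthly business operating cost, MK.
#' @param monthly_repayment loan repayment, MK/month (scenarios 9320, 7000).
#' @param monthly_interest monthly interest rate on loan balances.
#' @param initial_contacts households reached by the marketing push.
#' @param p_marketing per-contact marketing success probability.
#' @param p_neighbour per-link word-of-mouth success probability, applied
#'   once per `neighbour_period` days.
#' @param neighbour_period days between word-of-mouth rounds. The default
#'   (30, i.e. 3% per link per month) reproduces the slow multi-year
#'   diffusion the adoption model is built around; set to 1 for daily
#'   trials.
#' @param tenant_multiplier receptiveness multiplier for tenants.
#' @param wait_limit days on the waiting list before un-adoption.
#' @param affordability_fraction maximum affordable repayment as a share of
#'   monthly income. The default 0.12 is calibrated so that the share of
#'   the modelled income distribution for which the MK9320 repayment is
#'   affordable matches the observed share of surveyed households
#'   effectively paying at least that much for a latrine (5/38, about
#'   13%).
#' @param spread_from statuses that propagate word of mouth; either
#'   `"adopters"` (installed or waiting households only) or `"aware"`
#'   (any household that has heard of the technology).
#' @param n_ticks run length in days.
#' @param month_length days per month.
#' @return An object of class `skyloo_config`.
#' @seealso [run_skyloo()]
#' @export
skyloo_config <- function(startup_capital = 10e6,
                          build_cost = 200000,
                          build_capacity = 1,
                          operating_cost = 85000,
                          monthly_repayment = 9320,
                          monthly_interest = 0.01,
                          initial_contacts = 300,
                          p_marketing = 0.25,
                          p_neighbour = 0.03,
                          neighbour_period = 30,
                          tenant_multiplier = 0.8,
                          wait_limit = 30,
                          affordability_fraction = 0.12,
                          spread_from = c("aware", "adopters"),
                          n_ticks = 2000,
                          month_length = 30) {
  spread_from <- match.arg(spread_from)
  cfg <- list(
    startup_capital = check_pos(startup_capital, "startup_capital", strict = FALSE),
    build_cost = check_pos(build_cost, "build_cost"),
    build_capacity = check_count(build_capacity, "build_capacity"),
    operating_cost = check_pos(operating_cost, "operating_cost", strict = FALSE),
    monthly_repayment = check_pos(monthly_repayment, "monthly_repayment"),
    monthly_interest = check_pos(monthly_interest, "monthly_interest", strict = FALSE),
    initial_contacts = check_count(initial_contacts, "initial_contacts"),
    p_marketing = check_prob(p_marketing, "p_marketing"),
    p_neighbour = check_prob(p_neighbour, "p_neighbour"),
    neighbour_period = check_count(neighbour_period, "neighbour_period"),
    tenant_multiplier = check_pos(tenant_multiplier, "tenant_multiplier"),
    wait_limit = check_pos(wait_limit, "wait_limit"),
    affordability_fraction = check_prob(affordability_fraction, "affordability_fraction"),
    spread_from = spread_from,
    n_ticks = check_count(n_ticks, "n_ticks"),
    month_length = check_count(month_length, "month_length")
  )
  structure(cfg, class = "skyloo_config")
}

#' Configuration of the municipal FS-site model
#'
#' Daily-step site operation. Each day each of `n_companies` vacuum-tanker
#' companies has a load of `load_volume` m3 with probability
#' `p_company_job` and disposes of it legally at the site with its current
#' propensity `p_legal_init` (adapted over time by the payoff-learning
#' rule), otherwise dumps it illegally (caught and fined with probability
#' `p_catch_illegal_dump`). The site guard is present with daily
#' probability `p_guard_present` and, when present, either enforces
#' (collects fees and fines for the council) or takes bribes, with an
#' adaptive corruption propensity starting at `p_guard_corrupt_init`.
#' Farmers attempt to acquire sludge with daily probability
#' `p_farmer_attempt`, stealing with adaptive propensity `p_steal_init`
#' (impossible once the site is `refurbished`: fence plus full-time guard)
#' or buying matured compost at `sludge_value` per 50 kg bag. Raw sludge
#' matures into saleable compost after `compost_lag` days at volumetric
#' yield `compost_yield`, and all matured bags are sold in bulk at each
#' six-month boundary.
#'
#' Tariffs are either a per-visit `dumping_fee` or a flat monthly
#' `permit_fee` (`tariff_mode = "monthly_permit"`); under the permit every
#' company renews at each month boundary (the first month is a start-up
#' grace period so a 2000-day run bills 66 renewals).
#'
#' @param dumping_fee per-visit disposal charge, MK (tested 6000-15000).
#' @param permit_fee monthly permit charge, MK (tested 40000-100000).
#' @param tariff_mode `"per_visit"` or `"monthly_permit"`.
#' @param sludge_value value of one 50 kg bag of sludge/compost, MK.
#' @param bribe bribe paid to the guard, MK.
#' @param bribe_multiplier scenario multiplier (1-8) applied to `bribe`.
#' @param fine_company fine for illegal dumping, MK (tested 2000-15000).
#' @param fine_farmer fine for stealing sludge, MK.
#' @param p_guard_present daily probability the guard is on site (0.65
#'   unrefurbished, 1.0 refurbished).
#' @param refurbished logical; fence present and guard full time.
#' @param compost_lag days from raw-sludge arrival to saleable compost.
#' @param n_companies,n_farmers agent counts.
#' @param load_volume tanker load, m3.
#' @param p_company_job daily probability a company has a load.
#' @param p_farmer_attempt daily probability a farmer seeks sludge.
#' @param bag_volume volume of one 50 kg bag, m3.
#' @param compost_yield volume fraction of raw sludge surviving composting.
#' @param p_catch_illegal_dump probability an illegal dump is caught.
#' @param p_legal_init initial company propensity for legal disposal.
#' @param p_steal_init initial farmer propensity for theft.
#' @param p_guard_corrupt_init initial guard propensity for bribery.
#' @param multiplier payoff-learning adjustment rate per MK of payoff
#'   difference.
#' @param n_ticks run length in days.
#' @param month_length days per month.
#' @return An object of class `municipal_config`.
#' @seealso [run_municipal()], [adjust_probability()]
#' @export
municipal_config <- function(dumping_fee = 9000,
                             permit_fee = 70000,
                             tariff_mode = c("per_visit", "monthly_permit"),
                             sludge_value = 5000,
                             bribe = 3000,
                             bribe_multiplier = 1,
                             fine_company = 2000,
                             fine_farmer = 20000,
                             p_guard_present = 0.65,
                             refurbished = FALSE,
                             compost_lag = 180,
                             n_companies = 5,
                             n_farmers = 15,
                             load_volume = 3,
                             p_company_job = 0.2,
                             p_farmer_attempt = 0.1,
                             bag_volume = 0.05,
                             compost_yield = 0.5,
                             p_catch_illegal_dump = 0.1,
                             p_legal_init = 0.01,
                             p_steal_init = 0.5,
                             p_guard_corrupt_init = 0.5,
                             multiplier = 1e-6,
                             n_ticks = 2000,
                             month_length = 30) {
  tariff_mode <- match.arg(tariff_mode)
  refurbished <- isTRUE(refurbished)
  if (refurbished) p_guard_present <- 1.0
  cfg <- list(
    dumping_fee = check_pos(dumping_fee, "dumping_fee", strict = FALSE),
    permit_fee = check_pos(permit_fee, "permit_fee", strict = FALSE),
    tariff_mode = tariff_mode,
    sludge_value = check_pos(sludge_value, "sludge_value", strict = FALSE),
    bribe = check_pos(bribe, "bribe", strict = FALSE) *
      check_pos(bribe_multiplier, "bribe_multiplier"),
    fine_company = check_pos(fine_company, "fine_company", strict = FALSE),
    fine_farmer = check_pos(fine_farmer, "fine_farmer", strict = FALSE),
    p_guard_present = check_prob(p_guard_present, "p_guard_present"),
    refurbished = refurbished,
    compost_lag = check_pos(compost_lag, "compost_lag"),
    n_companies = check_count(n_companies, "n_companies"),
    n_farmers = check_count(n_farmers, "n_farmers"),
    load_volume = check_pos(load_volume, "load_volume"),
    p_company_job = check_prob(p_company_job, "p_company_job"),
    p_farmer_attempt = check_prob(p_farmer_attempt, "p_farmer_attempt"),
    bag_volume = check_pos(bag_volume, "bag_volume"),
    compost_yield = check_prob(compost_yield, "compost_yield"),
    p_catch_illegal_dump = check_prob(p_catch_illegal_dump, "p_catch_illegal_dump"),
    p_legal_init = check_prob(p_legal_init, "p_legal_init"),
    p_steal_init = check_prob(p_steal_init, "p_steal_init"),
    p_guard_corrupt_init = check_prob(p_guard_corrupt_init, "p_guard_corrupt_init"),
    multiplier = check_pos(multiplier, "multiplier", strict = FALSE),
    n_ticks = check_count(n_ticks, "n_ticks"),
    month_length = check_count(month_length, "month_length")
  )
  structure(cfg, class = "municipal_config")
}

#' Read a scenario-configuration file
#'
#' Reads a YAML document with any of the sections `environment`, `network`,
#' `skyloo`, `municipal` and `grid`, and turns each into the corresponding
#' validated configuration object. Unknown keys in a section are a
#' configuration error.
#'
#' @param path path to a YAML file.
#' @return A list with elements `environment` ([environment_config()]),
#'   `network` (list of `k`, `p_rewire`), `skyloo` ([skyloo_config()]),
#'   `municipal` ([municipal_config()]) and `grid` (raw list), each present
#'   only if the file has the section.
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path, call. = FALSE)
  doc <- yaml::read_yaml(path)
  out <- list()
  apply_section <- function(section, constructor) {
    vals <- doc[[section]]
    if (is.null(vals)) return(NULL)
    known <- names(formals(constructor))
    bad <- setdiff(names(vals), known)
    if (length(bad))
      stop_config(paste0(section, ".", bad[1]), "is not a recognised parameter")
    do.call(constructor, vals)
  }
  out$environment <- apply_section("environment", environment_config)
  out$skyloo <- apply_section("skyloo", skyloo_config)
  out$municipal <- apply_section("municipal", municipal_config)
  if (!is.null(doc$network)) {
    net <- doc$network
    bad <- setdiff(names(net), c("k", "p_rewire"))
    if (length(bad)) stop_config(paste0("network.", bad[1]), "is not a recognised parameter")
    out$network <- list(k = net$k %||% 4, p_rewire = net$p_rewire %||% 0.2)
  }
  out$grid <- doc$grid
  out[!vapply(out, is.null, logical(1))]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
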