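## Household status codes used by the Skyloo simulation state.
## naive -> aware -> adopter-waiting -> {installed | unadopted}
ST_NAIVE <- 0L
ST_AWARE <- 1L     # aware but not adopting (not open, or cannot afford)
ST_WAITING <- 2L   # decided to adopt, on the business waiting list
ST_INSTALLED <- 3L
ST_UNADOPTED <- 4L

status_labels <- c("naive", "aware", "adopter-waiting", "installed", "unadopted")

#' Per-household exposure success probability
#'
#' Probability that one exposure event (a marketing contact or one day of
#' word of mouth along one network link) makes a naive household aware.
#' The channel base rate (`p_marketing` or `p_neighbour`) is scaled by the
#' tenant multiplier (tenants are harder to convince: landlord permission)
#' and by the flood-proximity and plot-size sliding-scale multipliers,
#' then clipped to [0, 1].
#'
#' @param households rows of a [generate_households()] data frame.
#' @param channel `"marketing"` or `"neighbour"`.
#' @param cfg a [skyloo_config()].
#' @param env_cfg the [environment_config()] the households were drawn
#'   from (defaults to the config attached to `households`).
#' @return Numeric vector of probabilities, one per row.
#' @export
exposure_prob <- function(households, channel = c("marketing", "neighbour"),
                          cfg = skyloo_config(),
                          env_cfg = attr(households, "config")) {
  channel <- match.arg(channel)
  if (is.null(env_cfg)) env_cfg <- environment_config()
  base <- if (channel == "marketing") cfg$p_marketing else cfg$p_neighbour
  tm <- ifelse(households$tenure == "tenant", cfg$tenant_multiplier, 1)
  p <- base * tm *
    flood_multiplier(households$flood_proximity, env_cfg) *
    land_multiplier(households$land_size, env_cfg)
  pmin(pmax(p, 0), 1)
}

#' Run one exposure trial per household
#'
#' Bernoulli draw at the [exposure_prob()] rate. Households that are
#' already aware stay aware (the draw is only meaningful for naive ones;
#' callers pass `already_aware` to make the trial a no-op for them).
#'
#' @inheritParams exposure_prob
#' @param already_aware logical vector; `TRUE` rows are returned as aware
#'   without a draw.
#' @return Logical vector: aware after the trial.
#' @export
exposure_trial <- function(households, channel = c("marketing", "neighbour"),
                           cfg = skyloo_config(),
                           env_cfg = attr(households, "config"),
                           already_aware = FALSE) {
  p <- exposure_prob(households, channel, cfg, env_cfg)
  already_aware | (stats::runif(nrow(households)) < p)
}

#' Adoption decision of an aware household
#'
#' A household that has become aware adopts if and only if it is open to
#' faecal-sludge reuse and the monthly loan repayment is affordable, i.e.
#' does not exceed `cfg$affordability_fraction` of its monthly income.
#' The decision is deterministic given the household's covariates.
#'
#' @param households rows of a [generate_households()] data frame.
#' @param cfg a [skyloo_config()].
#' @return Logical vector: adopt or not.
#' @examples
#' hh <- data.frame(open_to_reuse = TRUE, income = 44000)
#' adoption_decision(hh, skyloo_config(monthly_repayment = 9320))  # TRUE
#' @export
adoption_decision <- function(households, cfg = skyloo_config()) {
  households$open_to_reuse &
    cfg$monthly_repayment <= cfg$affordability_fraction * households$income
}

## ---- internal state machinery -------------------------------------------

skyloo_init_state <- function(env, network, cfg) {
  n <- nrow(env)
  env_cfg <- attr(env, "config")
  if (is.null(env_cfg)) env_cfg <- environment_config(n_households = n)
  status <- rep(ST_NAIVE, n)
  status[env$has_skyloo] <- ST_INSTALLED
  list(
    n = n,
    status = status,
    wait_start = rep(NA_integer_, n),
    eligible = adoption_decision(env, cfg),
    mult = ifelse(env$tenure == "tenant", cfg$tenant_multiplier, 1) *
      flood_multiplier(env$flood_proximity, env_cfg) *
      land_multiplier(env$land_size, env_cfg),
    ever_aware = env$has_skyloo,
    adj = network$adjacency,
    queue = integer(0),
    f_src = integer(0),   # frontier: informed -> naive edges
    f_tgt = integer(0),
    loan_household = integer(0),
    loan_balance = numeric(0),
    loan_payment = numeric(0),
    loan_open = integer(0),
    cash = cfg$startup_capital,
    total_repaid = 0,
    total_built = 0,
    total_opex = 0,
    n_builds = 0L
  )
}

informed_statuses <- function(cfg) {
  if (cfg$spread_from == "adopters") c(ST_WAITING, ST_INSTALLED)
  else c(ST_AWARE, ST_WAITING, ST_INSTALLED, ST_UNADOPTED)
}

## add frontier edges from newly informed nodes to their naive neighbours
frontier_add <- function(state, nodes) {
  for (v in nodes) {
    nb <- state$adj[[v]]
    nb <- nb[state$status[nb] == ST_NAIVE]
    if (length(nb)) {
      state$f_src <- c(state$f_src, rep.int(v, length(nb)))
      state$f_tgt <- c(state$f_tgt, nb)
    }
  }
  state
}

## households in `ids` have just become aware at tick t: remove them as
## frontier targets, apply the adoption decision, extend the frontier
process_new_aware <- function(state, ids, t, cfg) {
  if (!length(ids)) return(state)
  keep <- !(state$f_tgt %in% ids)
  state$f_src <- state$f_src[keep]
  state$f_tgt <- state$f_tgt[keep]
  state$ever_aware[ids] <- TRUE
  adopt <- state$eligible[ids]
  waiters <- ids[adopt]
  state$status[waiters] <- ST_WAITING
  state$wait_start[waiters] <- t
  state$queue <- c(state$queue, waiters)
  state$status[ids[!adopt]] <- ST_AWARE
  newly_informed <- if (cfg$spread_from == "adopters") waiters else ids
  frontier_add(state, newly_informed)
}

## one day of word of mouth along the informed -> naive frontier
neighbour_exposure_step <- function(state, t, cfg) {
  m <- length(state$f_tgt)
  if (m == 0L || cfg$p_neighbour == 0) return(state)
  p <- pmin(cfg$p_neighbour * state$mult[state$f_tgt], 1)
  hit <- stats::runif(m) < p
  process_new_aware(state, unique(state$f_tgt[hit]), t, cfg)
}

## serve the waiting list: up to build_capacity builds, each gated on cash
business_build_step <- function(state, t, cfg) {
  built <- 0L
  while (built < cfg$build_capacity && length(state$queue) &&
         state$cash >= cfg$build_cost) {
    h <- state$queue[1L]
    state$queue <- state$queue[-1L]
    state$cash <- state$cash - cfg$build_cost
    state$total_built <- state$total_built + cfg$build_cost
    state$n_builds <- state$n_builds + 1L
    state$status[h] <- ST_INSTALLED
    state$loan_household <- c(state$loan_household, h)
    state$loan_balance <- c(state$loan_balance, cfg$build_cost)
    state$loan_payment <- c(state$loan_payment, cfg$monthly_repayment)
    state$loan_open <- c(state$loan_open, t)
    built <- built + 1L
  }
  state
}

## waiting households past the limit abandon the technology for good
unadopt_sweep <- function(state, t, cfg) {
  if (!length(state$queue)) return(state)
  expired <- state$queue[t - state$wait_start[state$queue] > cfg$wait_limit]
  if (!length(expired)) return(state)
  state$status[expired] <- ST_UNADOPTED
  state$queue <- setdiff(state$queue, expired)
  if (cfg$spread_from == "adopters") {
    keep <- !(state$f_src %in% expired)
    state$f_src <- state$f_src[keep]
    state$f_tgt <- state$f_tgt[keep]
  }
  state
}

## month boundary: loans accrue interest and repay, operating cost debited.
## Loans opened this very tick start repaying at the next boundary
## ("repayments beginning the next month").
monthly_settlement <- function(state, t, cfg) {
  due <- state$loan_balance > 0 & state$loan_open < t
  if (any(due)) {
    bal <- state$loan_balance[due] * (1 + cfg$monthly_interest)
    pay <- pmin(state$loan_payment[due], bal)
    state$loan_balance[due] <- bal - pay
    received <- sum(pay)
    state$cash <- state$cash + received
    state$total_repaid <- state$total_repaid + received
  }
  state$cash <- state$cash - cfg$operating_cost
  state$total_opex <- state$total_opex + cfg$operating_cost
  state
}

#' Simulate Skyloo adoption and business finance
#'
#' Daily-step simulation over `cfg$n_ticks` days (default 2000, about 5.5
#' years). At tick 0 the business markets to `cfg$initial_contacts`
#' random households; every subsequent day word of mouth spreads along the
#' contact network, aware households decide whether to adopt, the business
#' builds for the head of the waiting list (one per day, cash permitting,
#' issuing a loan), households waiting longer than `cfg$wait_limit` days
#' un-adopt, and at every 30-day boundary loans repay and the operating
#' cost falls due.
#'
#' @param env household population from [generate_households()].
#' @param network contact network from [build_small_world()]; must have
#'   one node per household.
#' @param cfg a [skyloo_config()].
#' @param seed optional integer seed; the run is deterministic given
#'   `env`, `network`, `cfg` and `seed`.
#' @return An object of class `skyloo_run`: list with
#'   \describe{
#'     \item{series}{data frame, one row per tick 0..n_ticks: counts
#'       `installed`, `waiting`, `aware`, `unadopted`, `naive`, business
#'       `cash`, and business `capital` (cash plus the outstanding loan
#'       book -- issuing a loan converts cash into a receivable, so
#'       `capital` is the business's worth while `cash` is its liquidity).}
#'     \item{households}{final per-household `id` and `status`.}
#'     \item{ledger}{`startup_capital`, `total_repaid`, `total_built`,
#'       `total_opex`, `final_cash` (the exact cash identity),
#'       `n_builds`, `n_open_loans`, `outstanding_balance`.}
#'     \item{config, seed}{inputs echoed back.}
#'   }
#' @examples
#' env <- generate_households(environment_config(n_households = 200), seed = 1)
#' net <- build_small_world(200, 4, 0.2, seed = 2)
#' r <- run_skyloo(env, net, skyloo_config(n_ticks = 120), seed = 3)
#' tail(r$series, 1)
#' @export
run_skyloo <- function(env, network, cfg = skyloo_config(), seed = NULL) {
  stopifnot(inherits(cfg, "skyloo_config"), inherits(network, "fsabm_network"))
  if (nrow(env) != network$n)
    stop("environment and network sizes differ", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  env_cfg <- attr(env, "config")
  state <- skyloo_init_state(env, network, cfg)

  # pre-installed households seed the word of mouth
  state <- frontier_add(state, which(env$has_skyloo))

  n_ticks <- cfg$n_ticks
  series <- matrix(0, nrow = n_ticks + 1L, ncol = 7L,
                   dimnames = list(NULL, c("installed", "waiting", "aware",
                                           "unadopted", "naive", "cash",
                                           "capital")))
  snapshot <- function(state) {
    c(sum(state$status == ST_INSTALLED), sum(state$status == ST_WAITING),
      sum(state$status == ST_AWARE), sum(state$status == ST_UNADOPTED),
      sum(state$status == ST_NAIVE), state$cash,
      state$cash + sum(state$loan_balance))
  }

  # tick 0: one-off marketing push
  contacts <- sample.int(state$n, min(cfg$initial_contacts, state$n))
  naive_contacts <- contacts[state$status[contacts] == ST_NAIVE]
  if (length(naive_contacts)) {
    p <- pmin(cfg$p_marketing * state$mult[naive_contacts], 1)
    hits <- naive_contacts[stats::runif(length(naive_contacts)) < p]
    state <- process_new_aware(state, hits, 0L, cfg)
  }
  series[1L, ] <- snapshot(state)

  for (t in seq_len(n_ticks)) {
    if (t %% cfg$neighbour_period == 0L)
      state <- neighbour_exposure_step(state, t, cfg)
    state <- business_build_step(state, t, cfg)
    state <- unadopt_sweep(state, t, cfg)
    if (t %% cfg$month_length == 0L) state <- monthly_settlement(state, t, cfg)
    series[t + 1L, ] <- snapshot(state)
  }

  structure(list(
    series = data.frame(tick = 0:n_ticks, series),
    households = data.frame(
      id = seq_len(state$n),
      status = factor(status_labels[state$status + 1L], levels = status_labels),
      ever_aware = state$ever_aware,
      eligible = state$eligible
    ),
    ledger = list(
      startup_capital = cfg$startup_capital,
      total_repaid = state$total_repaid,
      total_built = state$total_built,
      total_opex = state$total_opex,
      final_cash = state$cash,
      n_builds = state$n_builds,
      n_open_loans = sum(state$loan_balance > 0),
      outstanding_balance = sum(state$loan_balance),
      final_capital = state$cash + sum(state$loan_balance)
    ),
    config = cfg,
    env_config = env_cfg,
    seed = seed
  ), class = "skyloo_run")
}

#' @export
print.skyloo_run <- function(x, ...) {
  last <- x$series[nrow(x$series), ]
  cat(sprintf("Skyloo adoption run: %d households, %d ticks\n",
              nrow(x$households), max(x$series$tick)))
  cat(sprintf("  installed %d | waiting %d | unadopted %d | aware %d | naive %d\n",
              last$installed, last$waiting, last$unadopted, last$aware, last$naive))
  cat(sprintf("  business cash MK%s (startup MK%s)\n",
              format(round(last$cash), big.mark = ","),
              format(x$ledger$startup_capital, big.mark = ",")))
  invisible(x)
}

#' @export
summary.skyloo_run <- function(object, ...) {
  out <- c(object$ledger,
           final_installed = object$series$installed[nrow(object$series)],
           final_unadopted = object$series$unadopted[nrow(object$series)])
  class(out) <- "summary.skyloo_run"
  out
}

#' @export
print.summary.skyloo_run <- function(x, ...) {
  cat("Skyloo run summary\n")
  for (nm in names(x))
    cat(sprintf("  %-20s %s\n", nm, format(x[[nm]], big.mark = ",")))
  invisible(x)
}

#' Plot adoption and cash trajectories of a Skyloo run
#'
#' @param x a `skyloo_run`.
#' @param which `"adoption"` or `"cash"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.skyloo_run <- function(x, which = c("adoption", "cash"), ...) {
  which <- match.arg(which)
  s <- x$series
  if (which == "adoption") {
    graphics::plot(s$tick, s$installed, type = "l", xlab = "day",
                   ylab = "households with Skyloo installed", ...)
  } else {
    graphics::plot(s$tick, s$cash / 1e6, type = "l", xlab = "day",
                   ylab = "business cash (MK millions)", ...)
    graphics::abline(h = x$ledger$startup_capital / 1e6, lty = 3)
  }
  invisible(x)
}
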