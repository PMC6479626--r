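#' Payoff-learning probability update
#'
#' Adaptive propensity rule used by every agent at the municipal site:
#' after an action, the probability of the action just performed moves
#' towards the better-paying alternative by `multiplier` per MK of
#' difference between the realized payoff and the counterfactual payoff
#' of the alternative action, and is clamped to [0, 1]. The multiplier is
#' deliberately tiny (1e-6) so behaviour drifts slowly over the ~5.5-year
#' run.
#'
#' @param p current probability of the focal action.
#' @param actual realized payoff of the action taken, MK.
#' @param potential counterfactual payoff of the alternative, MK.
#' @param multiplier adjustment rate per MK of payoff difference.
#' @return Updated probability in [0, 1].
#' @examples
#' adjust_probability(0.5, actual = 1000, potential = 5000)  # 0.496
#' @export
adjust_probability <- function(p, actual, potential, multiplier = 1e-6) {
  min(max(p + multiplier * (actual - potential), 0), 1)
}

## ---- internal state ------------------------------------------------------

municipal_init_state <- function(cfg) {
  list(
    p_legal = rep(cfg$p_legal_init, cfg$n_companies),
    p_steal = rep(cfg$p_steal_init, cfg$n_farmers),
    p_corrupt = cfg$p_guard_corrupt_init,
    # raw-sludge inventory, FIFO by arrival tick
    raw_tick = integer(0),
    raw_vol = numeric(0),
    mature_ptr = 1L,          # entries before this index have composted
    compost_pool = 0,         # matured volume not yet bagged
    compost_bags = 0L,
    # cumulative volumes
    legal_m3 = 0, illegal_m3 = 0, stolen_m3 = 0, matured_m3 = 0,
    # money ledgers
    council_cash = 0,
    fees = 0, fines_company = 0, fines_farmer = 0,
    permits = 0, bag_sales = 0, bulk_sales = 0,
    guard_bribes = 0,
    bags_sold = 0L
  )
}

## guard's personal payoff update: bribes are the only personal income;
## fees and fines are collected for the council
guard_update <- function(state, stance_corrupt, bribe_taken, cfg) {
  if (stance_corrupt) {
    state$p_corrupt <- adjust_probability(state$p_corrupt, bribe_taken, 0,
                                          cfg$multiplier)
  } else {
    p_enforce <- adjust_probability(1 - state$p_corrupt, 0, cfg$bribe,
                                    cfg$multiplier)
    state$p_corrupt <- 1 - p_enforce
  }
  state
}

## one tanker-load disposal decision by company i
company_disposal_event <- function(state, i, guard_present, guard_corrupt,
                                   t, cfg) {
  legal <- stats::runif(1) < state$p_legal[i]
  permit_mode <- cfg$tariff_mode == "monthly_permit"

  # gate cost a legal visit would incur under today's guard state
  legal_cost <- if (permit_mode) 0
    else if (guard_present && !guard_corrupt) cfg$dumping_fee
    else if (guard_present && guard_corrupt) cfg$bribe
    else 0

  if (legal) {
    if (!permit_mode && guard_present && !guard_corrupt) {
      state$fees <- state$fees + cfg$dumping_fee
      state$council_cash <- state$council_cash + cfg$dumping_fee
    } else if (!permit_mode && guard_present && guard_corrupt) {
      state$guard_bribes <- state$guard_bribes + cfg$bribe
    }
    state$legal_m3 <- state$legal_m3 + cfg$load_volume
    state$raw_tick <- c(state$raw_tick, t)
    state$raw_vol <- c(state$raw_vol, cfg$load_volume)
    actual <- -legal_cost
    # counterfactual: dumping illegally, fresh catch draw
    potential <- if (stats::runif(1) < cfg$p_catch_illegal_dump)
      -cfg$fine_company else 0
    state$p_legal[i] <- adjust_probability(state$p_legal[i], actual,
                                           potential, cfg$multiplier)
    if (!permit_mode && guard_present)
      state <- guard_update(state, guard_corrupt,
                            if (guard_corrupt) cfg$bribe else 0, cfg)
  } else {
    caught <- stats::runif(1) < cfg$p_catch_illegal_dump
    if (caught) {
      state$fines_company <- state$fines_company + cfg$fine_company
      state$council_cash <- state$council_cash + cfg$fine_company
    }
    state$illegal_m3 <- state$illegal_m3 + cfg$load_volume
    actual <- if (caught) -cfg$fine_company else 0
    potential <- -legal_cost
    p_illegal <- adjust_probability(1 - state$p_legal[i], actual,
                                    potential, cfg$multiplier)
    state$p_legal[i] <- 1 - p_illegal
  }
  state
}

## remove up to `vol` m3 from the un-matured raw inventory (FIFO)
take_raw <- function(state, vol) {
  taken <- 0
  idx <- state$mature_ptr
  while (taken < vol && idx <= length(state$raw_vol)) {
    avail <- state$raw_vol[idx]
    grab <- min(avail, vol - taken)
    state$raw_vol[idx] <- avail - grab
    taken <- taken + grab
    idx <- idx + 1L
  }
  list(state = state, taken = taken)
}

## un-matured raw volume currently on site
raw_available <- function(state) {
  if (state$mature_ptr > length(state$raw_vol)) 0
  else sum(state$raw_vol[state$mature_ptr:length(state$raw_vol)])
}

## one acquisition attempt by farmer j: steal or buy one 50 kg bag
farmer_acquisition_event <- function(state, j, guard_present, guard_corrupt,
                                     t, cfg) {
  steal <- stats::runif(1) < state$p_steal[j]

  # value (MK) a theft attempt would yield under today's guard state
  steal_outcome <- function() {
    if (cfg$refurbished) {
      # fence: removal impossible; an enforcing guard catches and fines
      if (!guard_corrupt) list(vol = 0, payoff = -cfg$fine_farmer, fined = TRUE,
                               bribe = 0)
      else list(vol = 0, payoff = 0, fined = FALSE, bribe = 0)
    } else if (!guard_present) {
      v <- min(cfg$bag_volume, raw_available(state))
      list(vol = v, payoff = cfg$sludge_value * v / cfg$bag_volume,
           fined = FALSE, bribe = 0)
    } else if (guard_corrupt) {
      v <- min(cfg$bag_volume, raw_available(state))
      list(vol = v, payoff = cfg$sludge_value * v / cfg$bag_volume - cfg$bribe,
           fined = FALSE, bribe = cfg$bribe)
    } else {
      list(vol = 0, payoff = -cfg$fine_farmer, fined = TRUE, bribe = 0)
    }
  }

  # buying nets value - price = 0 (or 0 if no stock): the counterfactual
  # payoff of the legal route is always 0
  if (steal) {
    out <- steal_outcome()
    if (out$vol > 0) {
      tr <- take_raw(state, out$vol)
      state <- tr$state
      state$stolen_m3 <- state$stolen_m3 + tr$taken
    }
    if (out$fined) {
      state$fines_farmer <- state$fines_farmer + cfg$fine_farmer
      state$council_cash <- state$council_cash + cfg$fine_farmer
    }
    if (out$bribe > 0) state$guard_bribes <- state$guard_bribes + out$bribe
    state$p_steal[j] <- adjust_probability(state$p_steal[j], out$payoff, 0,
                                           cfg$multiplier)
    if (guard_present && !cfg$refurbished)
      state <- guard_update(state, guard_corrupt, out$bribe, cfg)
  } else {
    if (state$compost_bags >= 1L) {
      state$compost_bags <- state$compost_bags - 1L
      state$bag_sales <- state$bag_sales + cfg$sludge_value
      state$council_cash <- state$council_cash + cfg$sludge_value
    }
    potential <- steal_outcome()$payoff
    p_buy <- adjust_probability(1 - state$p_steal[j], 0, potential,
                                cfg$multiplier)
    state$p_steal[j] <- 1 - p_buy
  }
  state
}

## maturation of raw sludge into saleable bags, plus the six-monthly bulk
## compost sale
compost_step <- function(state, t, cfg) {
  while (state$mature_ptr <= length(state$raw_tick) &&
         state$raw_tick[state$mature_ptr] <= t - cfg$compost_lag) {
    v <- state$raw_vol[state$mature_ptr]
    state$raw_vol[state$mature_ptr] <- 0
    state$matured_m3 <- state$matured_m3 + v
    state$compost_pool <- state$compost_pool + v
    state$mature_ptr <- state$mature_ptr + 1L
  }
  new_bags <- floor(state$compost_pool * cfg$compost_yield / cfg$bag_volume)
  if (new_bags >= 1) {
    state$compost_bags <- state$compost_bags + as.integer(new_bags)
    state$compost_pool <- state$compost_pool -
      new_bags * cfg$bag_volume / cfg$compost_yield
  }
  if (t %% cfg$compost_lag == 0L && state$compost_bags > 0L) {
    sale <- state$compost_bags * cfg$sludge_value
    state$bulk_sales <- state$bulk_sales + sale
    state$council_cash <- state$council_cash + sale
    state$bags_sold <- state$bags_sold + state$compost_bags
    state$compost_bags <- 0L
  }
  state
}

## monthly permit renewal: every company renews at each month boundary
renew_permit <- function(state, t, cfg) {
  if (cfg$tariff_mode != "monthly_permit") return(state)
  amount <- cfg$n_companies * cfg$permit_fee
  state$permits <- state$permits + amount
  state$council_cash <- state$council_cash + amount
  state
}

#' Simulate the municipal FS disposal site
#'
#' Daily-step simulation over `cfg$n_ticks` days. Each day the guard is on
#' site with probability `cfg$p_guard_present` and, when present, takes a
#' corrupt or enforcing stance from his adaptive corruption propensity;
#' each company with a tanker load chooses legal disposal (paying the
#' per-visit fee, a bribe, or nothing depending on tariff mode and guard
#' state) or illegal dumping (fined if caught); each farmer seeking
#' sludge chooses theft (impossible at the refurbished, fenced site) or a
#' legal compost purchase. After every interaction the acting agent -- and
#' the guard, where involved -- updates its propensity with
#' [adjust_probability()] using the realized payoff against the
#' counterfactual payoff of the alternative action under the same guard
#' state. Raw sludge matures into compost after `cfg$compost_lag` days and
#' matured bags are bulk-sold at every six-month boundary; under the
#' monthly-permit tariff every company renews at each 30-day boundary
#' (the first month is a grace period, so a 2000-day run bills 66
#' renewals).
#'
#' @param cfg a [municipal_config()].
#' @param seed optional integer seed.
#' @return An object of class `municipal_run`: list with
#'   \describe{
#'     \item{series}{data frame, one row per tick 0..n_ticks: cumulative
#'       `legal_m3`, `illegal_m3`, `stolen_m3`, `council_cash`,
#'       `guard_bribes`, and current `compost_bags`.}
#'     \item{ledger}{money components (`fees`, `fines_company`,
#'       `fines_farmer`, `permits`, `bag_sales`, `bulk_sales`,
#'       `council_cash`, `guard_bribes`) and volume components
#'       (`legal_m3`, `illegal_m3`, `stolen_m3`, `matured_m3`,
#'       `raw_m3`, `compost_pool_m3`, `bags_sold`).}
#'     \item{propensities}{final `p_legal` (per company), `p_steal`
#'       (per farmer) and guard `p_corrupt`.}
#'     \item{config, seed}{inputs echoed back.}
#'   }
#' @examples
#' r <- run_municipal(municipal_config(n_ticks = 400), seed = 1)
#' tail(r$series, 1)
#' @export
run_municipal <- function(cfg = municipal_config(), seed = NULL) {
  stopifnot(inherits(cfg, "municipal_config"))
  if (!is.null(seed)) set.seed(seed)
  state <- municipal_init_state(cfg)
  n_ticks <- cfg$n_ticks
  series <- matrix(0, nrow = n_ticks + 1L, ncol = 6L,
                   dimnames = list(NULL, c("legal_m3", "illegal_m3", "stolen_m3",
                                           "council_cash", "guard_bribes",
                                           "compost_bags")))
  for (t in seq_len(n_ticks)) {
    guard_present <- cfg$refurbished ||
      stats::runif(1) < cfg$p_guard_present
    guard_corrupt <- guard_present && stats::runif(1) < state$p_corrupt

    jobs <- which(stats::runif(cfg$n_companies) < cfg$p_company_job)
    for (i in jobs)
      state <- company_disposal_event(state, i, guard_present, guard_corrupt,
                                      t, cfg)
    attempts <- which(stats::runif(cfg$n_farmers) < cfg$p_farmer_attempt)
    for (j in attempts)
      state <- farmer_acquisition_event(state, j, guard_present, guard_corrupt,
                                        t, cfg)
    state <- compost_step(state, t, cfg)
    if (t %% cfg$month_length == 0L) state <- renew_permit(state, t, cfg)
    series[t + 1L, ] <- c(state$legal_m3, state$illegal_m3, state$stolen_m3,
                          state$council_cash, state$guard_bribes,
                          state$compost_bags)
  }

  structure(list(
    series = data.frame(tick = 0:n_ticks, series),
    ledger = list(
      fees = state$fees, fines_company = state$fines_company,
      fines_farmer = state$fines_farmer, permits = state$permits,
      bag_sales = state$bag_sales, bulk_sales = state$bulk_sales,
      council_cash = state$council_cash, guard_bribes = state$guard_bribes,
      legal_m3 = state$legal_m3, illegal_m3 = state$illegal_m3,
      stolen_m3 = state$stolen_m3, matured_m3 = state$matured_m3,
      raw_m3 = sum(state$raw_vol),
      compost_pool_m3 = state$compost_pool,
      bags_sold = state$bags_sold
    ),
    propensities = list(p_legal = state$p_legal, p_steal = state$p_steal,
                        p_corrupt = state$p_corrupt),
    config = cfg,
    seed = seed
  ), class = "municipal_run")
}

#' @export
print.municipal_run <- function(x, ...) {
  l <- x$ledger
  cat(sprintf("Municipal FS-site run: %d ticks (%s, %s site)\n",
              max(x$series$tick), x$config$tariff_mode,
              if (x$config$refurbished) "refurbished" else "unrefurbished"))
  cat(sprintf("  volumes (m3): legal %.1f | illegal %.1f | stolen %.2f\n",
              l$legal_m3, l$illegal_m3, l$stolen_m3))
  cat(sprintf("  council cash MK%s | guard bribes MK%s\n",
              format(round(l$council_cash), big.mark = ","),
              format(round(l$guard_bribes), big.mark = ",")))
  invisible(x)
}

#' @export
summary.municipal_run <- function(object, ...) {
  out <- object$ledger
  out$mean_p_legal <- mean(object$propensities$p_legal)
  out$mean_p_steal <- mean(object$propensities$p_steal)
  out$p_corrupt <- object$propensities$p_corrupt
  class(out) <- "summary.municipal_run"
  out
}

#' @export
print.summary.municipal_run <- function(x, ...) {
  cat("Municipal FS-site run summary\n")
  for (nm in names(x))
    cat(sprintf("  %-18s %s\n", nm, format(x[[nm]], big.mark = ",")))
  invisible(x)
}

#' Plot council cash flow or disposal volumes of a municipal run
#'
#' @param x a `municipal_run`.
#' @param which `"cash"` or `"volumes"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.municipal_run <- function(x, which = c("cash", "volumes"), ...) {
  which <- match.arg(which)
  s <- x$series
  if (which == "cash") {
    graphics::plot(s$tick, s$council_cash / 1e6, type = "l", xlab = "day",
                   ylab = "council cash (MK millions)", ...)
  } else {
    graphics::matplot(s$tick, cbind(s$legal_m3, s$illegal_m3, s$stolen_m3),
                      type = "l", lty = 1, xlab = "day",
                      ylab = "cumulative volume (m3)", ...)
    graphics::legend("topleft", c("legal", "illegal", "stolen"),
                     col = 1:3, lty = 1, bty = "n")
  }
  invisible(x)
}
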