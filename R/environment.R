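#' Draw a monthly household income
#'
#' Incomes are modelled as lognormal, moment-matched to the requested mean
#' and standard deviation: `sdlog^2 = log(1 + (sd/mean)^2)`,
#' `meanlog = log(mean) - sdlog^2/2`. With mean = SD = MK44,000 (coefficient
#' of variation 1) this gives `sdlog^2 = log 2` and a median of
#' `mean/sqrt(2)` (about MK31,100), the right-skewed shape expected of an
#' urban income distribution; a normal with these moments would put ~16% of
#' households at negative income. With `sd = 0` the draw is degenerate at
#' `mean`.
#'
#' @param mean,sd target moments, MK/month; `mean > 0`, `sd >= 0`.
#' @param n number of draws.
#' @return Numeric vector of `n` non-negative incomes.
#' @examples
#' set.seed(1)
#' mean(sample_income(44000, 44000, 1e4))
#' @export
sample_income <- function(mean, sd, n = 1) {
  if (!is.numeric(mean) || length(mean) != 1L || is.na(mean) || mean <= 0)
    stop_config("income_mean", "must be > 0")
  if (!is.numeric(sd) || length(sd) != 1L || is.na(sd) || sd < 0)
    stop_config("income_sd", "must be >= 0")
  if (sd == 0) return(rep(mean, n))
  s2 <- log(1 + (sd / mean)^2)
  stats::rlnorm(n, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

## Linear sliding scale from `high` at x = 0 to `low` at x = 1.
sliding_scale <- function(x, high, low) high + (low - high) * x

#' Flood-proximity adoption multiplier
#'
#' Households near flood-prone land are more receptive to a raised dry
#' toilet (pit latrines there flood or collapse). The multiplier slides
#' linearly from `cfg$mult_high` for a household inside the flood strip
#' (`flood_proximity = 0`) down to `cfg$mult_low` at the far edge of the
#' map (`flood_proximity = 1`).
#'
#' @param flood_proximity normalised distance to the flood strip, in [0, 1].
#' @param cfg an [environment_config()].
#' @return Multiplier(s) in `[cfg$mult_low, cfg$mult_high]`.
#' @export
flood_multiplier <- function(flood_proximity, cfg = environment_config()) {
  if (!is.numeric(flood_proximity) || anyNA(flood_proximity) ||
      any(flood_proximity < 0 | flood_proximity > 1))
    stop("flood_proximity must lie in [0, 1]", call. = FALSE)
  sliding_scale(flood_proximity, cfg$mult_high, cfg$mult_low)
}

#' Plot-size adoption multiplier
#'
#' Small plots leave no room to dig replacement pit latrines, making a
#' permanent above-ground toilet more attractive. Linear slide from
#' `cfg$mult_high` at the smallest plot in `cfg$land_size_range` to
#' `cfg$mult_low` at the largest; plots outside the range are clamped.
#'
#' @param land_size plot area(s), same units as `cfg$land_size_range`; > 0.
#' @param cfg an [environment_config()].
#' @return Multiplier(s) in `[cfg$mult_low, cfg$mult_high]`.
#' @export
land_multiplier <- function(land_size, cfg = environment_config()) {
  if (!is.numeric(land_size) || anyNA(land_size) || any(land_size <= 0))
    stop("land_size must be > 0", call. = FALSE)
  r <- cfg$land_size_range
  x <- pmin(pmax((land_size - r[1]) / (r[2] - r[1]), 0), 1)
  sliding_scale(x, cfg$mult_high, cfg$mult_low)
}

#' Generate a synthetic household population
#'
#' Emulates what a field survey plus GIS would provide: per-household
#' tenure, size, income, plot size, location and distance to flood-prone
#' land, openness to faecal-sludge reuse, and whether a Skyloo is already
#' installed. Locations are uniform on the square map; `flood_proximity`
#' is the perpendicular distance to the flood strip along the x = 0 edge,
#' normalised to [0, 1] (0 = inside the strip).
#'
#' @param cfg an [environment_config()].
#' @param seed optional integer seed; if given, the population is a pure
#'   function of `cfg` and `seed`.
#' @return A `data.frame` with one row per household and columns `id`,
#'   `x`, `y`, `tenure` (`"owner"`/`"tenant"`), `size`, `income`,
#'   `land_size`, `flood_proximity`, `open_to_reuse`, `has_skyloo`.
#' @examples
#' hh <- generate_households(environment_config(n_households = 100), seed = 1)
#' table(hh$tenure)
#' @export
generate_households <- function(cfg = environment_config(), seed = NULL) {
  stopifnot(inherits(cfg, "environment_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- cfg$n_households
  x <- stats::runif(n, 0, cfg$map_side)
  y <- stats::runif(n, 0, cfg$map_side)
  fp <- pmin(pmax((x - cfg$flood_zone_width) /
                    (cfg$map_side - cfg$flood_zone_width), 0), 1)
  out <- data.frame(
    id = seq_len(n),
    x = x, y = y,
    tenure = ifelse(stats::runif(n) < cfg$owner_fraction, "owner", "tenant"),
    size = pmax(1L, as.integer(round(stats::rnorm(
      n, cfg$household_size_mean, cfg$household_size_sd)))),
    income = sample_income(cfg$income_mean, cfg$income_sd, n),
    land_size = stats::runif(n, cfg$land_size_range[1], cfg$land_size_range[2]),
    flood_proximity = fp,
    open_to_reuse = stats::runif(n) < cfg$p_open_to_reuse,
    has_skyloo = stats::runif(n) < cfg$p_initial_skyloo,
    stringsAsFactors = FALSE
  )
  attr(out, "config") <- cfg
  out
}

#' Write a household population to a delimited file
#'
#' @param households output of [generate_households()].
#' @param path file to write (headered CSV, one household per row).
#' @return `path`, invisibly.
#' @export
write_households <- function(households, path) {
  utils::write.csv(households, path, row.names = FALSE)
  invisible(path)
}
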