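# Parameter derivation arithmetic: period-to-month probability conversion,
# hazard-ratio adjustment, CPI inflation / currency conversion, discount-rate
# derivation, and moment matching of beta/gamma distributions for the PSA.

#' Convert an event proportion over a period to a one-month probability
#'
#' Converts `events / at_risk` observed over `period` months into a constant
#' one-month transition probability via the exponential-rate identity: the
#' period rate is `-log(1 - events/at_risk) / period` and the monthly
#' probability is `1 - exp(-rate)`, i.e. `1 - (1 - events/at_risk)^(1/period)`.
#' Compounding the result over the period recovers the observed proportion
#' exactly.
#'
#' @param events Number of events observed (non-negative, less than `at_risk`).
#' @param at_risk Number of subjects at risk (positive).
#' @param period Length of the observation period in months (positive).
#' @return One-month transition probability in `[0, 1)`.
#' @examples
#' monthly_prob_from_period(10, 440, 2)    # 0.0114 (4 d.p.)
#' monthly_prob_from_period(558, 4187, 27) # 0.0053 (4 d.p.)
#' @export
monthly_prob_from_period <- function(events, at_risk, period) {
  if (at_risk <= 0) stop("`at_risk` must be positive")
  if (events < 0) stop("`events` must be non-negative")
  if (events >= at_risk) {
    stop("`events` must be smaller than `at_risk` (period proportion < 1)")
  }
  if (period <= 0) stop("`period` must be positive (months)")
  1 - exp(log(1 - events / at_risk) / period)
}

#' Period-to-month conversion with a hazard ratio applied to the event count
#'
#' Scales the reference-arm event count by a hazard ratio *before* the
#' rate-based period-to-month conversion, i.e. computes
#' `1 - exp(log(1 - hr * events / at_risk) / period)`.  Applying the ratio to
#' the event count (rather than multiplying the converted rate) mirrors how
#' treated-arm probabilities are derived from a reference arm's count data.
#'
#' @inheritParams monthly_prob_from_period
#' @param hr Hazard ratio applied to the event count (non-negative;
#'   `hr * events` must stay below `at_risk`).
#' @return One-month transition probability in `[0, 1)`.
#' @examples
#' monthly_prob_with_hazard_ratio(392, 1157, 12, 0.79) # 0.0256 (4 d.p.)
#' monthly_prob_with_hazard_ratio(392, 1157, 12, 1)    # 0.0339 (4 d.p.)
#' @export
monthly_prob_with_hazard_ratio <- function(events, at_risk, period, hr) {
  if (hr < 0) stop("`hr` must be non-negative")
  monthly_prob_from_period(hr * events, at_risk, period)
}

#' Healthcare consumer-price-index chain with an exchange rate
#'
#' Bundles an ordered chain of annual healthcare CPI multipliers with the
#' CNY-per-USD exchange rate used to express all model costs in USD.
#'
#' @param multipliers Numeric vector of annual CPI multipliers (each > 0),
#'   ordered from the earliest to the latest year.
#' @param exchange_rate CNY per USD (> 0).
#' @param years Optional integer vector of calendar years labelling the
#'   multipliers.
#' @return An object of class `cpi_chain`.
#' @export
cpi_chain <- function(multipliers, exchange_rate, years = NULL) {
  if (length(multipliers) < 1 || any(multipliers <= 0)) {
    stop("`multipliers` must be a non-empty vector of positive values")
  }
  if (exchange_rate <= 0) stop("`exchange_rate` must be positive")
  if (!is.null(years) && length(years) != length(multipliers)) {
    stop("`years` must match `multipliers` in length")
  }
  structure(
    list(
      multipliers = as.numeric(multipliers),
      exchange_rate = exchange_rate,
      years = years
    ),
    class = "cpi_chain"
  )
}

#' Inflate a historical CNY cost and convert it to USD
#'
#' Multiplies a cost denominated in CNY through the full CPI chain and divides
#' by the exchange rate.  The operation is multiplicative: chaining two CPI
#' sub-chains equals applying their concatenation.
#'
#' @param cost_cny Cost in CNY at the start of the CPI chain (> 0).
#' @param cpi A [cpi_chain()].
#' @return Cost in USD at the end of the chain.
#' @examples
#' chain <- cpi_chain(c(1.027, 1.038, 1.06, 1.043, 1.024, 1.018, 1.004), 6.4515)
#' inflate_and_convert_cost(12351, chain) # 2361.5 (1 d.p.)
#' @export
inflate_and_convert_cost <- function(cost_cny, cpi) {
  stopifnot(inherits(cpi, "cpi_chain"))
  if (cost_cny <= 0) stop("`cost_cny` must be positive")
  cost_cny * prod(cpi$multipliers) / cpi$exchange_rate
}

#' Derive the annual discount rate from a CPI chain
#'
#' Returns the geometric mean of the CPI multipliers minus one.  The base-case
#' model uses this value rounded to two decimals (0.03 for the packaged
#' 2015-2021 healthcare chain).
#'
#' @param cpi A [cpi_chain()].
#' @return Annual discount rate as a fraction.
#' @export
derive_discount_rate <- function(cpi) {
  stopifnot(inherits(cpi, "cpi_chain"))
  prod(cpi$multipliers)^(1 / length(cpi$multipliers)) - 1
}

#' Moment-match a beta distribution to a mean and standard deviation
#'
#' Solves for the beta shape parameters reproducing the given first two
#' moments: with `k = mean (1 - mean) / sd^2 - 1`, `shape1 = mean k` and
#' `shape2 = (1 - mean) k`.
#'
#' @param mean Target mean, in (0, 1).
#' @param sd Target standard deviation; `sd^2` must be below
#'   `mean * (1 - mean)`.
#' @return A `distribution_spec` list with fields `family`, `mean`, `sd`,
#'   `shape1`, `shape2`.
#' @export
moment_match_beta <- function(mean, sd) {
  if (mean <= 0 || mean >= 1) stop("beta `mean` must lie in (0, 1)")
  if (sd <= 0) stop("`sd` must be positive")
  if (sd^2 >= mean * (1 - mean)) {
    stop("`sd` too large for a beta distribution with this mean")
  }
  k <- mean * (1 - mean) / sd^2 - 1
  structure(
    list(family = "beta", mean = mean, sd = sd,
         shape1 = mean * k, shape2 = (1 - mean) * k),
    class = "distribution_spec"
  )
}

#' Moment-match a gamma distribution to a mean and standard deviation
#'
#' `shape = (mean/sd)^2`, `scale = sd^2/mean`; the resulting distribution has
#' exactly the requested first two moments.
#'
#' @param mean Target mean (> 0).
#' @param sd Target standard deviation (> 0).
#' @return A `distribution_spec` list with fields `family`, `mean`, `sd`,
#'   `shape`, `scale`.
#' @export
moment_match_gamma <- function(mean, sd) {
  if (mean <= 0 || sd <= 0) stop("gamma `mean` and `sd` must be positive")
  structure(
    list(family = "gamma", mean = mean, sd = sd,
         shape = (mean / sd)^2, scale = sd^2 / mean),
    class = "distribution_spec"
  )
}

#' Draw from a moment-matched distribution spec
#'
#' @param spec A `distribution_spec` from [moment_match_beta()] or
#'   [moment_match_gamma()].
#' @param n Number of draws.
#' @return Numeric vector of draws (uses the current RNG state).
#' @export
draw_distribution <- function(spec, n = 1) {
  stopifnot(inherits(spec, "distribution_spec"))
  switch(spec$family,
    beta = stats::rbeta(n, spec$shape1, spec$shape2),
    gamma = stats::rgamma(n, shape = spec$shape, scale = spec$scale),
    stop("unknown distribution family: ", spec$family)
  )
}

#' Age-banded monthly non-cardiovascular mortality table
#'
#' @param age_breaks Lower bounds of the age bands, in years, strictly
#'   increasing (the last band is open-ended).
#' @param monthly_prob Monthly non-cardiovascular death probability per band,
#'   each in (0, 1) and non-decreasing with age.
#' @return An object of class `life_table`.
#' @export
life_table <- function(age_breaks, monthly_prob) {
  if (length(age_breaks) != length(monthly_prob)) {
    stop("`age_breaks` and `monthly_prob` must have the same length")
  }
  if (any(diff(age_breaks) <= 0)) stop("`age_breaks` must be strictly increasing")
  if (any(monthly_prob < 0 | monthly_prob >= 1)) {
    stop("life-table probabilities must lie in [0, 1)")
  }
  if (any(diff(monthly_prob) < 0)) {
    stop("life-table probabilities must be non-decreasing with age")
  }
  structure(
    list(age_breaks = as.numeric(age_breaks),
         monthly_prob = as.numeric(monthly_prob)),
    class = "life_table"
  )
}

#' Monthly non-cardiovascular mortality at a given age
#'
#' Band lookup in a [life_table()]; ages at or beyond the last band's lower
#' bound clamp to the last band.
#'
#' @param age Age in years (at or above the first band's lower bound).
#' @param table A [life_table()].
#' @return Monthly probability of non-cardiovascular death.
#' @examples
#' lt <- life_table(c(60, 65, 70, 75, 80, 85),
#'                  c(0.0004, 0.0007, 0.0010, 0.0017, 0.0026, 0.0054))
#' noncv_mortality(62, lt)  # 0.0004
#' noncv_mortality(120, lt) # 0.0054
#' @export
noncv_mortality <- function(age, table) {
  stopifnot(inherits(table, "life_table"))
  if (age < table$age_breaks[1]) {
    stop("`age` below the first life-table band (", table$age_breaks[1], ")")
  }
  table$monthly_prob[findInterval(age, table$age_breaks)]
}

# ---- parameter set ---------------------------------------------------------

.prob_params <- c(
  "p_cvd_early_sv", "p_cvd_early_ena", "p_cvd_late_sv", "p_cvd_late_ena",
  "p_hosp_early_sv", "p_hosp_early_ena", "p_hosp_late_sv", "p_hosp_late_ena"
)
.cost_params <- c("cost_sv_month", "cost_ena_month", "cost_hosp_event")
.utility_params <- c("u_sv_month", "u_ena_month")

#' Construct a model parameter set
#'
#' Gathers every scalar input of the decision model: monthly transition
#' probabilities for cardiovascular death and hospitalization in the
#' vulnerable (first two post-discharge months) and stable (three or more
#' non-hospitalized months) phases for both drugs, monthly costs and
#' utilities, the per-event hospitalization cost and utility decrement, the
#' annual discount rate, the willingness-to-pay threshold, the starting age
#' and the horizon in monthly cycles.  `cost_ena_month` is the background
#' "enalapril + standard care" cost accrued during every non-hospitalized
#' alive month in all strategies; `cost_sv_month` is the additional
#' sacubitril-valsartan acquisition cost accrued in months where it is the
#' active drug.
#'
#' @param p_cvd_early_sv,p_cvd_early_ena Monthly cardiovascular-death
#'   probability within 2 months of discharge, per drug.
#' @param p_cvd_late_sv,p_cvd_late_ena Monthly cardiovascular-death
#'   probability in the stable phase.
#' @param p_hosp_early_sv,p_hosp_early_ena Monthly readmission probability in
#'   the vulnerable phase.
#' @param p_hosp_late_sv,p_hosp_late_ena Monthly hospitalization probability
#'   in the stable phase.
#' @param cost_sv_month,cost_ena_month Monthly costs, USD.
#' @param cost_hosp_event Cost per hospitalization event, USD.
#' @param u_sv_month,u_ena_month Monthly utilities (QALY per month).
#' @param u_hosp_event Utility decrement per hospitalization event (negative).
#' @param discount_annual Annual discount rate (fraction).
#' @param wtp Willingness-to-pay threshold, USD per QALY.
#' @param start_age Cohort starting age, years.
#' @param horizon_cycles Model horizon in monthly cycles.
#' @param uncertainty Optional data frame with columns `parameter`, `low`,
#'   `high`, `sd`, `family` describing one-way ranges and PSA distributions.
#' @return An object of class `parameter_set` (a named list).
#' @export
parameter_set <- function(p_cvd_early_sv, p_cvd_early_ena,
                          p_cvd_late_sv, p_cvd_late_ena,
                          p_hosp_early_sv, p_hosp_early_ena,
                          p_hosp_late_sv, p_hosp_late_ena,
                          cost_sv_month, cost_ena_month, cost_hosp_event,
                          u_sv_month, u_ena_month, u_hosp_event,
                          discount_annual, wtp,
                          start_age = 60, horizon_cycles = 480,
                          uncertainty = NULL) {
  params <- structure(
    list(
      p_cvd_early_sv = p_cvd_early_sv, p_cvd_early_ena = p_cvd_early_ena,
      p_cvd_late_sv = p_cvd_late_sv, p_cvd_late_ena = p_cvd_late_ena,
      p_hosp_early_sv = p_hosp_early_sv, p_hosp_early_ena = p_hosp_early_ena,
      p_hosp_late_sv = p_hosp_late_sv, p_hosp_late_ena = p_hosp_late_ena,
      cost_sv_month = cost_sv_month, cost_ena_month = cost_ena_month,
      cost_hosp_event = cost_hosp_event,
      u_sv_month = u_sv_month, u_ena_month = u_ena_month,
      u_hosp_event = u_hosp_event,
      discount_annual = discount_annual, wtp = wtp,
      start_age = start_age, horizon_cycles = horizon_cycles,
      uncertainty = uncertainty
    ),
    class = "parameter_set"
  )
  validate_parameter_set(params)
  params
}

#' Validate a parameter set against the model invariants
#'
#' Checks that all transition probabilities lie in (0, 1) and that competing
#' exit probabilities from each state sum to less than 1, that costs are
#' positive, monthly utilities lie in (0, 1/12], the hospitalization utility
#' decrement is negative, the discount rate is non-negative, and that any
#' uncertainty ranges bracket the base value.
#'
#' @param params A [parameter_set()].
#' @param check_ranges Also check that one-way ranges bracket the base value
#'   (on by default; turned off when validating Monte Carlo draws, whose
#'   values legitimately fall outside the deterministic ranges).
#' @return `params`, invisibly; errors name the offending field.
#' @export
validate_parameter_set <- function(params, check_ranges = TRUE) {
  stopifnot(inherits(params, "parameter_set"))
  for (nm in .prob_params) {
    v <- params[[nm]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v >= 1) {
      stop("`", nm, "` must be a probability in [0, 1)")
    }
  }
  for (nm in .cost_params) {
    v <- params[[nm]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0) {
      stop("`", nm, "` must be a positive cost")
    }
  }
  for (nm in .utility_params) {
    v <- params[[nm]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0 || v > 1 / 12) {
      stop("`", nm, "` must be a monthly utility in (0, 1/12]")
    }
  }
  if (!is.numeric(params$u_hosp_event) || params$u_hosp_event >= 0) {
    stop("`u_hosp_event` must be a negative utility decrement")
  }
  if (params$discount_annual < 0) stop("`discount_annual` must be >= 0")
  if (params$wtp <= 0) stop("`wtp` must be positive")
  if (params$horizon_cycles < 1) stop("`horizon_cycles` must be >= 1")
  # competing exits: vulnerable-phase states may die of CV causes or be
  # readmitted within the same cycle; stable states additionally face
  # background mortality (bounded by the largest life-table band, < 1 here
  # because each term is a probability and the sum is checked directly)
  for (d in c("sv", "ena")) {
    s_early <- params[[paste0("p_cvd_early_", d)]] +
      params[[paste0("p_hosp_early_", d)]]
    if (s_early >= 1) {
      stop("competing vulnerable-phase probabilities for `", d,
           "` sum to ", signif(s_early, 4), " (must be < 1)")
    }
    s_late <- params[[paste0("p_cvd_late_", d)]] +
      params[[paste0("p_hosp_late_", d)]]
    if (s_late >= 1) {
      stop("competing stable-phase probabilities for `", d,
           "` sum to ", signif(s_late, 4),
           " (must be < 1 before background mortality)")
    }
  }
  if (check_ranges && !is.null(params$uncertainty)) {
    u <- params$uncertainty
    need <- c("parameter", "low", "high", "sd", "family")
    if (!all(need %in% names(u))) {
      stop("`uncertainty` must have columns ", paste(need, collapse = ", "))
    }
    for (i in seq_len(nrow(u))) {
      nm <- u$parameter[i]
      if (is.null(params[[nm]])) stop("uncertainty row for unknown parameter `", nm, "`")
      base <- params[[nm]]
      if (!is.na(u$low[i]) && !is.na(u$high[i]) &&
          (u$low[i] > base || base > u$high[i])) {
        stop("range for `", nm, "` does not bracket the base value")
      }
    }
  }
  invisible(params)
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("Markov model parameter set\n")
  cat(sprintf("  start age %g y, horizon %d monthly cycles, discount %.3f/y, WTP %.1f USD/QALY\n",
              x$start_age, x$horizon_cycles, x$discount_annual, x$wtp))
  scalars <- setdiff(names(x), "uncertainty")
  df <- data.frame(value = unlist(x[scalars]))
  print(df, ...)
  if (!is.null(x$uncertainty)) {
    cat("  uncertainty:", sum(!is.na(x$uncertainty$low)), "ranged parameters,",
        sum(!is.na(x$uncertainty$family)), "with PSA distributions\n")
  }
  invisible(x)
}
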