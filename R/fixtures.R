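# Packaged base-case inputs, configuration file round-tripping, and the
# synthetic parameter-set generator used for property testing.

#' Read model inputs from a configuration file
#'
#' Parses the flat YAML configuration holding the parameter table (base
#' values, one-way ranges, SDs and distribution families), the model
#' settings, the age-banded life table and the CPI chain.
#'
#' @param path Path to a YAML configuration file (see
#'   `system.file("extdata", "base_case.yaml", package = "svcea")` for the
#'   packaged base case).
#' @return List with elements `params` (a [parameter_set()]), `lt` (a
#'   [life_table()]) and `cpi` (a [cpi_chain()]).
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  cfg <- yaml::read_yaml(path)
  for (section in c("settings", "parameters", "life_table", "cpi")) {
    if (is.null(cfg[[section]])) {
      stop("configuration is missing the `", section, "` section")
    }
  }
  pars <- cfg$parameters
  need <- c(.prob_params, .cost_params, .utility_params, "u_hosp_event",
            "discount_annual")
  missing <- setdiff(need, names(pars))
  if (length(missing)) {
    stop("configuration is missing parameter key(s): ",
         paste(missing, collapse = ", "))
  }
  base_of <- function(nm) {
    v <- pars[[nm]]$base
    if (is.null(v)) stop("parameter `", nm, "` has no `base` value")
    v
  }
  uncertainty <- do.call(rbind, lapply(names(pars), function(nm) {
    p <- pars[[nm]]
    data.frame(
      parameter = nm,
      low = if (is.null(p$low)) NA_real_ else p$low,
      high = if (is.null(p$high)) NA_real_ else p$high,
      sd = if (is.null(p$sd)) NA_real_ else p$sd,
      family = if (is.null(p$family)) NA_character_ else p$family
    )
  }))
  for (st in c("start_age", "horizon_cycles", "wtp_usd_per_qaly")) {
    if (is.null(cfg$settings[[st]])) stop("settings key `", st, "` is missing")
  }
  params <- parameter_set(
    p_cvd_early_sv = base_of("p_cvd_early_sv"),
    p_cvd_early_ena = base_of("p_cvd_early_ena"),
    p_cvd_late_sv = base_of("p_cvd_late_sv"),
    p_cvd_late_ena = base_of("p_cvd_late_ena"),
    p_hosp_early_sv = base_of("p_hosp_early_sv"),
    p_hosp_early_ena = base_of("p_hosp_early_ena"),
    p_hosp_late_sv = base_of("p_hosp_late_sv"),
    p_hosp_late_ena = base_of("p_hosp_late_ena"),
    cost_sv_month = base_of("cost_sv_month"),
    cost_ena_month = base_of("cost_ena_month"),
    cost_hosp_event = base_of("cost_hosp_event"),
    u_sv_month = base_of("u_sv_month"),
    u_ena_month = base_of("u_ena_month"),
    u_hosp_event = base_of("u_hosp_event"),
    discount_annual = base_of("discount_annual"),
    wtp = cfg$settings$wtp_usd_per_qaly,
    start_age = cfg$settings$start_age,
    horizon_cycles = cfg$settings$horizon_cycles,
    uncertainty = uncertainty
  )
  lt <- life_table(cfg$life_table$age_breaks, cfg$life_table$monthly_prob)
  cpi <- cpi_chain(cfg$cpi$multipliers, cfg$cpi$exchange_rate_cny_per_usd,
                   years = cfg$cpi$years)
  list(params = params, lt = lt, cpi = cpi)
}

#' Write model inputs to a configuration file
#'
#' Serializes a parameter set, life table and CPI chain to the same YAML
#' layout read by [read_model_config()]; reading the file back recovers the
#' values exactly.
#'
#' @param params A [parameter_set()].
#' @param lt A [life_table()].
#' @param cpi A [cpi_chain()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_config <- function(params, lt, cpi, path) {
  u <- params$uncertainty
  par_entry <- function(nm) {
    entry <- list(base = params[[nm]])
    if (!is.null(u) && nm %in% u$parameter) {
      row <- u[u$parameter == nm, ]
      entry$low <- if (is.na(row$low)) NULL else row$low
      entry$high <- if (is.na(row$high)) NULL else row$high
      entry$sd <- if (is.na(row$sd)) NULL else row$sd
      entry$family <- if (is.na(row$family)) NULL else row$family
    }
    entry
  }
  par_names <- unique(c(.prob_params, .cost_params, .utility_params,
                        "u_hosp_event", "discount_annual",
                        if (!is.null(u)) u$parameter))
  cfg <- list(
    settings = list(
      start_age = params$start_age,
      horizon_cycles = params$horizon_cycles,
      discount_annual = params$discount_annual,
      wtp_usd_per_qaly = params$wtp
    ),
    parameters = stats::setNames(lapply(par_names, par_entry), par_names),
    life_table = list(age_breaks = lt$age_breaks,
                      monthly_prob = lt$monthly_prob),
    cpi = list(years = cpi$years, multipliers = cpi$multipliers,
               exchange_rate_cny_per_usd = cpi$exchange_rate)
  )
  write_atomically(path, function(tmp) {
    yaml::write_yaml(cfg, tmp, precision = 15)
  })
  invisible(path)
}

#' Packaged base-case inputs
#'
#' Loads the base-case parameter table, life table and CPI chain shipped
#' with the package.
#'
#' @return As [read_model_config()].
#' @examples
#' inputs <- base_case_inputs()
#' inputs$params$p_hosp_early_ena # 0.0717
#' @export
base_case_inputs <- function() {
  read_model_config(system.file("extdata", "base_case.yaml",
                                package = "svcea", mustWork = TRUE))
}

# ---- synthetic parameter sets ---------------------------------------------

#' Specification for synthetic parameter-set generation
#'
#' Describes the sampling ranges and structural constraints for random but
#' structurally valid parameter sets: stable-phase risks are drawn first and
#' vulnerable-phase risks are obtained by scaling them up (the early
#' post-discharge months carry more risk), and, when
#' `treated_better = TRUE`, the sacubitril-valsartan risks are a downscaled
#' copy of the enalapril risks while its utility is at least as high.
#'
#' @param seed Integer seed.
#' @param treated_better Enforce treated risk < reference risk (and treated
#'   utility >= reference utility).
#' @param p_cvd_late_range,p_hosp_late_range Ranges for the stable-phase
#'   monthly probabilities (reference drug).
#' @param early_ratio_range Multiplier range taking stable-phase to
#'   vulnerable-phase risk.
#' @param effect_range Range of the treated:reference risk ratio used when
#'   `treated_better` is set.
#' @param cost_month_range,cost_event_range Monthly and per-event cost
#'   ranges, USD.
#' @param u_month_range Monthly utility range.
#' @param u_event_range Range of the (negative) per-event utility decrement.
#' @param rel_sd Relative SD given to every distributed parameter.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1, treated_better = TRUE,
                           p_cvd_late_range = c(0.002, 0.012),
                           p_hosp_late_range = c(0.01, 0.06),
                           early_ratio_range = c(1.2, 3),
                           effect_range = c(0.55, 0.95),
                           cost_month_range = c(15, 200),
                           cost_event_range = c(800, 6000),
                           u_month_range = c(0.05, 0.08),
                           u_event_range = c(-0.15, -0.05),
                           rel_sd = 0.15) {
  structure(
    list(seed = seed, treated_better = treated_better,
         p_cvd_late_range = p_cvd_late_range,
         p_hosp_late_range = p_hosp_late_range,
         early_ratio_range = early_ratio_range,
         effect_range = effect_range,
         cost_month_range = cost_month_range,
         cost_event_range = cost_event_range,
         u_month_range = u_month_range, u_event_range = u_event_range,
         rel_sd = rel_sd),
    class = "synthetic_spec"
  )
}

#' Generate a synthetic, structurally valid parameter set
#'
#' Seeded draw honouring the structural flags of the [synthetic_spec()];
#' the result always passes [validate_parameter_set()].
#'
#' @param spec A [synthetic_spec()].
#' @return A [parameter_set()] with an uncertainty table (ranges at +/- 20%
#'   of base, clipped to the parameter's domain; beta SDs capped below the
#'   feasibility bound).
#' @export
synthetic_parameter_set <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  runifr <- function(r) stats::runif(1, r[1], r[2])
  p_cvd_late_ena <- runifr(spec$p_cvd_late_range)
  p_hosp_late_ena <- runifr(spec$p_hosp_late_range)
  effect <- if (spec$treated_better) runifr(spec$effect_range) else
    stats::runif(1, 0.7, 1.3)
  p_cvd_late_sv <- p_cvd_late_ena * effect
  p_hosp_late_sv <- p_hosp_late_ena * effect
  ratio <- runifr(spec$early_ratio_range)
  p_cvd_early_ena <- min(p_cvd_late_ena * ratio, 0.3)
  p_hosp_early_ena <- min(p_hosp_late_ena * ratio, 0.3)
  p_cvd_early_sv <- p_cvd_early_ena * effect
  p_hosp_early_sv <- p_hosp_early_ena * effect
  cost_ena <- runifr(spec$cost_month_range)
  cost_sv <- if (spec$treated_better) {
    # a pricier treated drug keeps the trade-off non-trivial
    cost_ena * stats::runif(1, 1, 3)
  } else {
    runifr(spec$cost_month_range)
  }
  u_ena <- runifr(spec$u_month_range)
  u_sv <- if (spec$treated_better) {
    stats::runif(1, u_ena, min(spec$u_month_range[2], 1 / 12))
  } else {
    runifr(spec$u_month_range)
  }
  prob_names <- .prob_params
  values <- list(
    p_cvd_early_sv = p_cvd_early_sv, p_cvd_early_ena = p_cvd_early_ena,
    p_cvd_late_sv = p_cvd_late_sv, p_cvd_late_ena = p_cvd_late_ena,
    p_hosp_early_sv = p_hosp_early_sv, p_hosp_early_ena = p_hosp_early_ena,
    p_hosp_late_sv = p_hosp_late_sv, p_hosp_late_ena = p_hosp_late_ena,
    cost_sv_month = cost_sv, cost_ena_month = cost_ena,
    cost_hosp_event = runifr(spec$cost_event_range),
    u_sv_month = u_sv, u_ena_month = u_ena,
    u_hosp_event = runifr(spec$u_event_range)
  )
  uncertainty <- do.call(rbind, lapply(names(values), function(nm) {
    base <- values[[nm]]
    fam <- if (nm %in% .cost_params) "gamma" else "beta"
    sd <- abs(base) * spec$rel_sd
    if (fam == "beta") {
      # keep the beta moment match feasible
      cap <- sqrt(abs(base) * (1 - abs(base))) * 0.5
      sd <- min(sd, cap)
    }
    lo <- base - abs(base) * 0.2
    hi <- base + abs(base) * 0.2
    if (nm %in% .utility_params) hi <- min(hi, 1 / 12)
    if (nm %in% prob_names) hi <- min(hi, 0.999)
    data.frame(parameter = nm, low = min(lo, hi), high = max(lo, hi),
               sd = sd, family = fam)
  }))
  uncertainty <- rbind(uncertainty, data.frame(
    parameter = "discount_annual", low = 0, high = 0.06,
    sd = NA_real_, family = NA_character_
  ))
  parameter_set(
    p_cvd_early_sv = values$p_cvd_early_sv,
    p_cvd_early_ena = values$p_cvd_early_ena,
    p_cvd_late_sv = values$p_cvd_late_sv,
    p_cvd_late_ena = values$p_cvd_late_ena,
    p_hosp_early_sv = values$p_hosp_early_sv,
    p_hosp_early_ena = values$p_hosp_early_ena,
    p_hosp_late_sv = values$p_hosp_late_sv,
    p_hosp_late_ena = values$p_hosp_late_ena,
    cost_sv_month = values$cost_sv_month,
    cost_ena_month = values$cost_ena_month,
    cost_hosp_event = values$cost_hosp_event,
    u_sv_month = values$u_sv_month, u_ena_month = values$u_ena_month,
    u_hosp_event = values$u_hosp_event,
    discount_annual = 0.03, wtp = 37654.5,
    start_age = 60, horizon_cycles = 480,
    uncertainty = uncertainty
  )
}
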