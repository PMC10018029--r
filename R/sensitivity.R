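# One-way (tornado) deterministic sensitivity analysis and probabilistic
# sensitivity analysis (Monte Carlo over the parameter distributions, CE
# scatter, acceptability curve and its 0.5 crossing).

.default_strategies <- function() {
  list(reference = strategy_spec("enalapril"),
       comparator = strategy_spec("sv_early"))
}

#' One-way sensitivity analysis for a single parameter
#'
#' Re-runs the comparator-versus-reference base case twice with the named
#' parameter set to its lower and upper bound (all other parameters at base)
#' and records the ICER at each bound.
#'
#' @param params A [parameter_set()] whose `uncertainty` table carries the
#'   parameter's `low`/`high` range.
#' @param lt A [life_table()].
#' @param parameter_name Name of the parameter to vary.
#' @param strategies List with elements `reference` and `comparator`, both
#'   [strategy_spec()]s; defaults to enalapril vs early initiation.
#' @return A one-row data frame (`tornado_entry`): `parameter`, `low`,
#'   `high`, `icer_low`, `icer_high`, `width`.
#' @export
one_way <- function(params, lt, parameter_name,
                    strategies = .default_strategies()) {
  u <- params$uncertainty
  if (is.null(u) || !parameter_name %in% u$parameter) {
    stop("unknown or unranged parameter `", parameter_name, "`")
  }
  row <- u[u$parameter == parameter_name, ]
  if (is.na(row$low) || is.na(row$high)) {
    stop("parameter `", parameter_name, "` has no one-way range")
  }
  icer_at <- function(value) {
    p <- params
    p[[parameter_name]] <- value
    validate_parameter_set(p)
    ref <- run_strategy(strategies$reference, p, lt)
    cmp <- run_strategy(strategies$comparator, p, lt)
    compute_icer(ref, cmp)$icer
  }
  icer_low <- icer_at(row$low)
  icer_high <- icer_at(row$high)
  data.frame(parameter = parameter_name, low = row$low, high = row$high,
             icer_low = icer_low, icer_high = icer_high,
             width = abs(icer_high - icer_low))
}

#' Tornado table: one-way analysis over every ranged parameter
#'
#' Runs [one_way()] for each parameter carrying a range and sorts the
#' entries by descending bar width.
#'
#' @inheritParams one_way
#' @return A data frame of tornado entries, widest first.
#' @export
tornado <- function(params, lt, strategies = .default_strategies()) {
  u <- params$uncertainty
  if (is.null(u)) stop("parameter set has no uncertainty table")
  ranged <- u$parameter[!is.na(u$low) & !is.na(u$high)]
  if (length(ranged) < 1) stop("no ranged parameters")
  entries <- do.call(rbind, lapply(ranged, function(nm) {
    one_way(params, lt, nm, strategies)
  }))
  entries[order(-entries$width), , drop = FALSE]
}

#' Draw one parameter set from the PSA distributions
#'
#' For every uncertainty row with a distribution family and SD, replaces the
#' base value by a random draw: beta distributions (moment-matched to the
#' base value and SD) for probabilities and monthly utilities; gamma for
#' costs; the hospitalization utility decrement is drawn as a beta on its
#' magnitude and negated.  Parameters without a distribution (the discount
#' rate, the life table, the starting age) stay at base.  Uses the current
#' RNG state; seed outside for reproducibility.
#'
#' @param params A [parameter_set()] with an `uncertainty` table.
#' @return A new `parameter_set` (not revalidated: structural validity of a
#'   draw is checked, and invalid draws rejected, by [run_psa()]).
#' @export
draw_parameters <- function(params) {
  u <- params$uncertainty
  if (is.null(u)) stop("parameter set has no uncertainty table")
  drawn <- params
  for (i in seq_len(nrow(u))) {
    if (is.na(u$family[i]) || is.na(u$sd[i]) || u$sd[i] == 0) next
    nm <- u$parameter[i]
    base <- params[[nm]]
    drawn[[nm]] <- switch(u$family[i],
      beta = draw_distribution(moment_match_beta(abs(base), u$sd[i])) *
        sign(base),
      gamma = draw_distribution(moment_match_gamma(base, u$sd[i])),
      stop("unknown distribution family `", u$family[i], "` for `", nm, "`")
    )
  }
  drawn
}

#' Probabilistic sensitivity analysis
#'
#' Draws `n_iterations` parameter sets from the PSA distributions and runs
#' the full cohort model for the comparator and reference strategies on each
#' draw.  Structurally invalid draws (competing probabilities summing to 1 or
#' more, utilities outside their domain) are rejected and redrawn, with the
#' rejection count reported.  Acceptability at the base willingness-to-pay
#' threshold is the fraction of draws with positive incremental net monetary
#' benefit.
#'
#' @param params A [parameter_set()] with PSA distributions.
#' @param lt A [life_table()].
#' @param n_iterations Number of Monte Carlo iterations (>= 1).
#' @param seed Integer seed for the draw stream.
#' @param strategies List with `reference` and `comparator`
#'   [strategy_spec()]s; defaults to enalapril vs early initiation.
#' @return An object of class `psa_result`: data frame `samples` with one
#'   row per iteration (`cost_ref`, `qaly_ref`, `cost_cmp`, `qaly_cmp`,
#'   `d_cost`, `d_effect`), plus `acceptability` at `params$wtp`, `wtp`,
#'   `n_iterations`, `n_rejected` and `seed`.
#' @export
run_psa <- function(params, lt, n_iterations = 10000, seed = 1,
                    strategies = .default_strategies()) {
  if (n_iterations < 1) stop("`n_iterations` must be >= 1")
  validate_parameter_set(params)
  set.seed(seed)
  out <- matrix(NA_real_, n_iterations, 6,
                dimnames = list(NULL, c("cost_ref", "qaly_ref", "cost_cmp",
                                        "qaly_cmp", "d_cost", "d_effect")))
  n_rejected <- 0L
  for (j in seq_len(n_iterations)) {
    repeat {
      p <- draw_parameters(params)
      ok <- tryCatch({
        validate_parameter_set(p, check_ranges = FALSE)
        TRUE
      }, error = function(e) FALSE)
      if (ok) break
      n_rejected <- n_rejected + 1L
      if (n_rejected > 100 * n_iterations) {
        stop("PSA rejection rate too high; check the distribution inputs")
      }
    }
    ref <- run_strategy(strategies$reference, p, lt)
    cmp <- run_strategy(strategies$comparator, p, lt)
    out[j, ] <- c(ref$cost, ref$qaly, cmp$cost, cmp$qaly,
                  cmp$cost - ref$cost, cmp$qaly - ref$qaly)
  }
  samples <- as.data.frame(out)
  acceptability <- mean(params$wtp * samples$d_effect - samples$d_cost > 0)
  structure(
    list(samples = samples, acceptability = acceptability, wtp = params$wtp,
         n_iterations = n_iterations, n_rejected = n_rejected, seed = seed,
         reference = strategies$reference$name,
         comparator = strategies$comparator$name),
    class = "psa_result"
  )
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value on the grid, the acceptability is the
#' fraction of PSA samples in which the comparator has positive incremental
#' net monetary benefit, `wtp * dE - dC > 0`.
#'
#' @param psa A [run_psa()] result.
#' @param wtp_grid Ascending numeric vector of WTP values (USD/QALY).
#' @return Data frame with columns `wtp` and `acceptability`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 50000, by = 100)) {
  stopifnot(inherits(psa, "psa_result"))
  if (length(wtp_grid) < 1 || is.unsorted(wtp_grid)) {
    stop("`wtp_grid` must be a non-empty ascending vector")
  }
  acc <- vapply(wtp_grid, function(w) {
    mean(w * psa$samples$d_effect - psa$samples$d_cost > 0)
  }, numeric(1))
  data.frame(wtp = wtp_grid, acceptability = acc)
}

#' Willingness-to-pay value where acceptability reaches one half
#'
#' Bisection on the WTP axis for the smallest threshold at which the
#' comparator's acceptability reaches 0.5 (the point where the two strategies
#' are equally likely to be preferred), resolved to a 0.1 USD grid.
#'
#' @param psa A [run_psa()] result.
#' @param lower,upper Search interval in USD/QALY.
#' @return The crossing WTP in USD/QALY, or `NA` if acceptability does not
#'   cross 0.5 on the interval.
#' @export
ceac_crossing <- function(psa, lower = 0, upper = 50000) {
  stopifnot(inherits(psa, "psa_result"))
  acc_at <- function(w) mean(w * psa$samples$d_effect - psa$samples$d_cost > 0)
  if (acc_at(lower) >= 0.5 || acc_at(upper) < 0.5) return(NA_real_)
  lo <- lower
  hi <- upper
  while (hi - lo > 0.05) {
    mid <- (lo + hi) / 2
    if (acc_at(mid) >= 0.5) hi <- mid else lo <- mid
  }
  round((lo + hi) / 2, 1)
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("PSA: %d iterations (%d draws rejected), seed %d\n",
              x$n_iterations, x$n_rejected, x$seed))
  cat(sprintf("  %s vs %s: acceptability %.1f%% at WTP %.1f USD/QALY\n",
              x$comparator, x$reference, 100 * x$acceptability, x$wtp))
  invisible(x)
}
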