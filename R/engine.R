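# Markov cohort engine: expanded state space, strategy drug maps,
# age-dependent transition matrices, cohort trace propagation, and
# half-cycle-corrected discounted accrual.
#
# The clinical state space has four transition states - hospitalized HF and
# the first, second, and third-or-later non-hospitalized months - and two
# absorbing death states.  The third non-hospitalized month is the stable
# state (self-looping); the first two post-discharge months are tunnel states
# occupied for at most one cycle per visit.  Alive non-stable states carry a
# phase tag (pre / post first stabilization) so that late-initiation
# switching history can be encoded in the transition structure.

.states <- c("HOSP_pre", "POST1_pre", "POST2_pre",
             "HOSP_post", "POST1_post", "POST2_post",
             "STABLE", "CV_DEATH", "NONCV_DEATH")
.alive_states <- .states[1:7]
.dead_states <- .states[8:9]
.nonhosp_alive <- c("POST1_pre", "POST2_pre", "POST1_post", "POST2_post",
                    "STABLE")

#' Expanded health-state labels
#'
#' Returns the nine expanded model states: the hospitalized state and the two
#' post-discharge tunnel months, each tagged `pre` (before the first entry
#' into the stable state) or `post` (after it), the stable state, and the two
#' absorbing death states.
#'
#' @return Character vector of state labels.
#' @export
health_states <- function() .states

#' Strategy specification: which drug is active in which state
#'
#' Builds the rule mapping expanded states to the active drug (`"sv"` for
#' sacubitril-valsartan, `"ena"` for enalapril):
#' \describe{
#'   \item{`enalapril`}{enalapril in every alive state.}
#'   \item{`sv_early`}{sacubitril-valsartan in every alive state, initiated
#'     during the index admission.}
#'   \item{`sv_late`}{enalapril until the cohort first completes three
#'     consecutive non-hospitalized months (entry into the stable state),
#'     sacubitril-valsartan in the stable state thereafter.  By default a
#'     subsequent hospitalization episode reverts the vulnerable-phase risks,
#'     utilities and costs to the enalapril values until re-stabilization
#'     (`relapse_drug = "ena"`); set `relapse_drug = "sv"` to keep
#'     sacubitril-valsartan parameters through post-switch hospitalization
#'     episodes instead.}
#' }
#'
#' @param name One of `"enalapril"`, `"sv_early"`, `"sv_late"`.
#' @param relapse_drug Drug governing post-switch vulnerable-phase states in
#'   the `sv_late` strategy (ignored otherwise).
#' @return An object of class `strategy_spec` with the per-state drug map.
#' @export
strategy_spec <- function(name = c("enalapril", "sv_early", "sv_late"),
                          relapse_drug = c("ena", "sv")) {
  name <- match.arg(name)
  relapse_drug <- match.arg(relapse_drug)
  pre <- c("HOSP_pre", "POST1_pre", "POST2_pre")
  post <- c("HOSP_post", "POST1_post", "POST2_post")
  drug_map <- switch(name,
    enalapril = stats::setNames(rep("ena", 7), .alive_states),
    sv_early = stats::setNames(rep("sv", 7), .alive_states),
    sv_late = c(
      stats::setNames(rep("ena", 3), pre),
      stats::setNames(rep(relapse_drug, 3), post),
      STABLE = "sv"
    )
  )
  structure(list(name = name, drug_map = drug_map[.alive_states]),
            class = "strategy_spec")
}

#' Resolve the active drug for a strategy in a given state
#'
#' @param strategy A [strategy_spec()].
#' @param state An alive expanded state label (see [health_states()]).
#' @return `"sv"` or `"ena"`.
#' @export
resolve_active_drug <- function(strategy, state) {
  stopifnot(inherits(strategy, "strategy_spec"))
  if (state %in% .dead_states) {
    stop("no active drug in the absorbing state `", state, "`")
  }
  if (!state %in% .alive_states) stop("unknown state `", state, "`")
  unname(strategy$drug_map[state])
}

#' One transition-probability row of the expanded Markov model
#'
#' Exit probabilities from `state` for one monthly cycle at the given age:
#' \itemize{
#'   \item hospitalized: cardiovascular death with the vulnerable-phase
#'     probability of the active drug, otherwise to the first post-discharge
#'     month (same phase);
#'   \item post-discharge months 1 and 2: cardiovascular death or readmission
#'     (vulnerable-phase probabilities; readmission stays within the phase),
#'     otherwise on to the next tunnel month or, from month 2, into the
#'     stable state;
#'   \item stable: cardiovascular death (stable-phase probability),
#'     age-dependent non-cardiovascular death, hospitalization (stable-phase
#'     probability, entering the post-switch hospitalized state), otherwise
#'     remain stable;
#'   \item death states: absorbing.
#' }
#' Non-cardiovascular death applies only from the stable state: deaths within
#' the two vulnerable post-discharge months are counted as cardiovascular.
#'
#' @param strategy A [strategy_spec()].
#' @param state An expanded state label.
#' @param age Age in years (for the life-table lookup).
#' @param params A [parameter_set()].
#' @param lt A [life_table()].
#' @return Named probability vector over all expanded states, summing to 1.
#' @export
transition_row <- function(strategy, state, age, params, lt) {
  row <- stats::setNames(numeric(length(.states)), .states)
  if (state %in% .dead_states) {
    row[state] <- 1
    return(row)
  }
  if (!state %in% .alive_states) stop("unknown state `", state, "`")
  drug <- resolve_active_drug(strategy, state)
  if (state == "STABLE") {
    p_cvd <- params[[paste0("p_cvd_late_", drug)]]
    p_hosp <- params[[paste0("p_hosp_late_", drug)]]
    p_ncd <- noncv_mortality(age, lt)
    rest <- 1 - p_cvd - p_ncd - p_hosp
    if (rest < 0) {
      stop("competing exit probabilities from STABLE exceed 1 (",
           signif(p_cvd + p_ncd + p_hosp, 4), ")")
    }
    row["CV_DEATH"] <- p_cvd
    row["NONCV_DEATH"] <- p_ncd
    row["HOSP_post"] <- p_hosp
    row["STABLE"] <- rest
    return(row)
  }
  phase <- sub("^.*_", "", state)
  p_cvd <- params[[paste0("p_cvd_early_", drug)]]
  p_hosp <- params[[paste0("p_hosp_early_", drug)]]
  if (startsWith(state, "HOSP")) {
    row["CV_DEATH"] <- p_cvd
    row[paste0("POST1_", phase)] <- 1 - p_cvd
  } else {
    rest <- 1 - p_cvd - p_hosp
    if (rest < 0) {
      stop("competing exit probabilities from ", state, " exceed 1 (",
           signif(p_cvd + p_hosp, 4), ")")
    }
    row["CV_DEATH"] <- p_cvd
    row[paste0("HOSP_", phase)] <- p_hosp
    if (startsWith(state, "POST1")) {
      row[paste0("POST2_", phase)] <- rest
    } else {
      row["STABLE"] <- rest
    }
  }
  row
}

#' Full transition matrix at a given age
#'
#' @inheritParams transition_row
#' @return A 9 x 9 row-stochastic matrix over [health_states()].
#' @export
transition_matrix <- function(strategy, age, params, lt) {
  P <- t(vapply(.states, transition_row, numeric(length(.states)),
                strategy = strategy, age = age, params = params, lt = lt))
  dimnames(P) <- list(.states, .states)
  P
}

#' Run the cohort trace for one strategy
#'
#' Starts the whole cohort in the pre-switch hospitalized state (the index
#' admission) and propagates it through the age-dependent transition matrix
#' for `horizon` monthly cycles; age advances by one year every 12 cycles for
#' the life-table lookup.  Records, per cycle, the fraction of the cohort
#' newly entering a hospitalized state (the inflow; cycle 0 inflow is 1, the
#' index admission - the hospitalized state is left after exactly one cycle,
#' so its occupancy at any cycle equals the new inflow at that cycle).
#'
#' @param strategy A [strategy_spec()].
#' @param params A [parameter_set()].
#' @param lt A [life_table()].
#' @param horizon Number of monthly cycles (defaults to
#'   `params$horizon_cycles`).
#' @return An object of class `cohort_trace`: list with `trace` (a
#'   `(horizon + 1) x 9` occupancy matrix, rows = cycles `0..horizon`),
#'   `inflow` (new-hospitalization fraction per cycle), `strategy`,
#'   `start_age` and `horizon`.
#' @export
run_cohort <- function(strategy, params, lt, horizon = params$horizon_cycles) {
  stopifnot(inherits(strategy, "strategy_spec"))
  validate_parameter_set(params, check_ranges = FALSE)
  if (horizon < 1) stop("`horizon` must be >= 1")
  ages <- params$start_age + (seq_len(horizon) - 1) %/% 12
  # the matrix changes only when the life-table band changes
  bands <- findInterval(ages, lt$age_breaks)
  if (any(bands < 1)) stop("cohort age below the first life-table band")
  mats <- lapply(sort(unique(bands)), function(b) {
    transition_matrix(strategy, lt$age_breaks[b], params, lt)
  })
  names(mats) <- as.character(sort(unique(bands)))
  trace <- matrix(0, horizon + 1, length(.states),
                  dimnames = list(NULL, .states))
  trace[1, "HOSP_pre"] <- 1
  v <- trace[1, ]
  for (t in seq_len(horizon)) {
    v <- as.vector(v %*% mats[[as.character(bands[t])]])
    trace[t + 1, ] <- v
  }
  inflow <- trace[, "HOSP_pre"] + trace[, "HOSP_post"]
  structure(
    list(trace = trace, inflow = inflow, strategy = strategy,
         start_age = params$start_age, horizon = horizon),
    class = "cohort_trace"
  )
}

#' Accrue discounted costs, QALYs and life-years over a cohort trace
#'
#' Occupancy-based accruals (monthly drug and background costs, monthly
#' utilities, and life-years at 1/12 per alive month) use half-cycle-corrected
#' occupancy - the trapezoidal average of consecutive trace rows - and the
#' mid-cycle discount factor `(1 + r)^(-(t + 0.5)/12)`.  Event-based accruals
#' (the hospitalization cost and utility decrement per unit of new
#' hospitalization inflow, including the index admission at cycle 0) use the
#' inflow cycle's start-of-cycle factor `(1 + r)^(-t/12)`.  The background
#' `cost_ena_month` accrues in every non-hospitalized alive month regardless
#' of strategy; `cost_sv_month` is added in non-hospitalized months whose
#' active drug is sacubitril-valsartan.  Utilities accrue in all alive months
#' (including hospitalized ones) at the active drug's monthly utility.
#'
#' @param cohort A [run_cohort()] result.
#' @param params The [parameter_set()] used to run it.
#' @return An object of class `run_result`: discounted `cost`, `qaly`, `ly`,
#'   the event/occupancy decomposition (`cost_events`, `cost_occupancy`,
#'   `qaly_events`, `qaly_occupancy`), discounted and undiscounted expected
#'   hospitalization counts, and undiscounted totals under `undiscounted`.
#' @export
accrue <- function(cohort, params) {
  stopifnot(inherits(cohort, "cohort_trace"))
  strategy <- cohort$strategy
  H <- cohort$horizon
  r <- params$discount_annual

  state_cost <- stats::setNames(numeric(length(.states)), .states)
  state_cost[.nonhosp_alive] <- params$cost_ena_month
  sv_states <- .nonhosp_alive[strategy$drug_map[.nonhosp_alive] == "sv"]
  state_cost[sv_states] <- state_cost[sv_states] + params$cost_sv_month
  state_u <- stats::setNames(numeric(length(.states)), .states)
  state_u[.alive_states] <- ifelse(strategy$drug_map == "sv",
                                   params$u_sv_month, params$u_ena_month)
  alive <- as.numeric(.states %in% .alive_states)

  occ <- (cohort$trace[1:H, , drop = FALSE] +
          cohort$trace[2:(H + 1), , drop = FALSE]) / 2
  t0 <- 0:(H - 1)
  disc_occ <- (1 + r)^(-(t0 + 0.5) / 12)
  disc_ev <- (1 + r)^(-t0 / 12)
  inflow <- cohort$inflow[1:H]

  occ_cost_cycle <- as.vector(occ %*% state_cost)
  occ_qaly_cycle <- as.vector(occ %*% state_u)
  occ_ly_cycle <- as.vector(occ %*% alive) / 12

  ev_disc <- sum(inflow * disc_ev)
  ev_undisc <- sum(inflow)

  structure(
    list(
      strategy = strategy$name,
      cost = sum(occ_cost_cycle * disc_occ) + ev_disc * params$cost_hosp_event,
      qaly = sum(occ_qaly_cycle * disc_occ) + ev_disc * params$u_hosp_event,
      ly = sum(occ_ly_cycle * disc_occ),
      cost_events = ev_disc * params$cost_hosp_event,
      cost_occupancy = sum(occ_cost_cycle * disc_occ),
      qaly_events = ev_disc * params$u_hosp_event,
      qaly_occupancy = sum(occ_qaly_cycle * disc_occ),
      hosp_events_discounted = ev_disc,
      hosp_events = ev_undisc,
      undiscounted = list(
        cost = sum(occ_cost_cycle) + ev_undisc * params$cost_hosp_event,
        qaly = sum(occ_qaly_cycle) + ev_undisc * params$u_hosp_event,
        ly = sum(occ_ly_cycle)
      )
    ),
    class = "run_result"
  )
}

#' Run one strategy end to end
#'
#' Convenience wrapper: [run_cohort()] followed by [accrue()].
#'
#' @inheritParams run_cohort
#' @return A `run_result` (see [accrue()]).
#' @export
run_strategy <- function(strategy, params, lt,
                         horizon = params$horizon_cycles) {
  accrue(run_cohort(strategy, params, lt, horizon), params)
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf("%s: cost %.1f USD (events %.1f + occupancy %.1f), %.3f QALY, %.3f LY\n",
              x$strategy, x$cost, x$cost_events, x$cost_occupancy,
              x$qaly, x$ly))
  cat(sprintf("  discounted hospitalization events: %.3f (undiscounted %.3f)\n",
              x$hosp_events_discounted, x$hosp_events))
  invisible(x)
}

#' @export
print.cohort_trace <- function(x, ...) {
  alive <- sum(x$trace[x$horizon + 1, .alive_states])
  cat(sprintf("cohort trace: strategy %s, %d cycles from age %g; alive at horizon %.4g\n",
              x$strategy$name, x$horizon, x$start_age, alive))
  invisible(x)
}
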