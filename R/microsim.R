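# Individual-level micro-simulation oracle.  Trajectories are simulated
# patient by patient through the same transition rows as the cohort engine
# (shared at the transition_row level only); the accrual arithmetic below is
# written independently of accrue() so that agreement between the two routes
# is a meaningful check, not a tautology.

#' Micro-simulation estimate of a strategy's outcomes
#'
#' Simulates `n_patients` independent trajectories through the expanded
#' state space by per-cycle categorical draws from [transition_row()], then
#' accrues discounted cost, QALY and life-years per patient: half-cycle
#' (trapezoidal) occupancy accrual at the mid-cycle discount factor, and
#' per-event hospitalization accruals (index admission included) at the
#' entry cycle's start-of-cycle factor.  Returns the sample means with their
#' Monte Carlo standard errors.
#'
#' @param strategy A [strategy_spec()].
#' @param params A [parameter_set()].
#' @param lt A [life_table()].
#' @param n_patients Number of simulated patients (>= 1).
#' @param horizon Number of monthly cycles (defaults to
#'   `params$horizon_cycles`).
#' @param seed Integer seed.
#' @return List with `cost`, `qaly`, `ly` (means), `se` (named vector of
#'   standard errors), `n_patients` and `horizon`.
#' @export
micro_simulation_oracle <- function(strategy, params, lt, n_patients = 1e5,
                                    horizon = params$horizon_cycles,
                                    seed = 1) {
  stopifnot(inherits(strategy, "strategy_spec"))
  validate_parameter_set(params)
  if (n_patients < 1) stop("`n_patients` must be >= 1")
  set.seed(seed)
  states <- health_states()
  n_state <- length(states)
  alive_idx <- which(!states %in% c("CV_DEATH", "NONCV_DEATH"))
  hosp_idx <- which(states %in% c("HOSP_pre", "HOSP_post"))

  # per-state reward vectors (independent of the engine's accrual code)
  cost_month <- numeric(n_state)
  u_month <- numeric(n_state)
  for (i in alive_idx) {
    s <- states[i]
    drug <- resolve_active_drug(strategy, s)
    u_month[i] <- if (drug == "sv") params$u_sv_month else params$u_ena_month
    if (!s %in% c("HOSP_pre", "HOSP_post")) {
      cost_month[i] <- params$cost_ena_month +
        if (drug == "sv") params$cost_sv_month else 0
    }
  }
  ly_month <- as.numeric(seq_len(n_state) %in% alive_idx) / 12
  r <- params$discount_annual

  state <- rep(1L, n_patients) # everyone starts in the index admission
  cost <- rep(params$cost_hosp_event, n_patients) # cycle-0 event, factor 1
  qaly <- rep(params$u_hosp_event, n_patients)
  ly <- numeric(n_patients)

  for (t in 0:(horizon - 1)) {
    age <- params$start_age + t %/% 12
    cum_rows <- lapply(seq_len(n_state), function(i) {
      cumsum(transition_row(strategy, states[i], age, params, lt))
    })
    new_state <- state
    for (i in unique(state)) {
      if (!i %in% alive_idx) next
      sel <- which(state == i)
      u <- stats::runif(length(sel))
      new_state[sel] <- findInterval(u, cum_rows[[i]],
                                     left.open = TRUE) + 1L
    }
    d_occ <- (1 + r)^(-(t + 0.5) / 12)
    d_ev <- (1 + r)^(-(t + 1) / 12)
    cost <- cost + d_occ * (cost_month[state] + cost_month[new_state]) / 2
    qaly <- qaly + d_occ * (u_month[state] + u_month[new_state]) / 2
    ly <- ly + d_occ * (ly_month[state] + ly_month[new_state]) / 2
    if (t < horizon - 1) {
      entered <- new_state %in% hosp_idx
      cost[entered] <- cost[entered] + d_ev * params$cost_hosp_event
      qaly[entered] <- qaly[entered] + d_ev * params$u_hosp_event
    }
    state <- new_state
  }
  se <- c(cost = stats::sd(cost), qaly = stats::sd(qaly), ly = stats::sd(ly)) /
    sqrt(n_patients)
  list(cost = mean(cost), qaly = mean(qaly), ly = mean(ly), se = se,
       n_patients = n_patients, horizon = horizon)
}
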