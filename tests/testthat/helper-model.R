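# Shared fixtures: the packaged base-case inputs and a few small builders.

.inputs <- base_case_inputs()
.params <- .inputs$params
.lt <- .inputs$lt
.cpi <- .inputs$cpi

# minimal run_result for unit-testing the economics layer in isolation
make_run <- function(cost, qaly, ly = qaly, strategy = "x") {
  structure(
    list(strategy = strategy, cost = cost, qaly = qaly, ly = ly,
         cost_events = 0, cost_occupancy = cost,
         qaly_events = 0, qaly_occupancy = qaly,
         hosp_events_discounted = 0, hosp_events = 0,
         undiscounted = list(cost = cost, qaly = qaly, ly = ly)),
    class = "run_result"
  )
}

# parameter set with every PSA distribution collapsed (sd = 0): draws
# return the base values exactly
degenerate_psa_params <- function(params = .params) {
  params$uncertainty$sd <- 0
  params
}

# all-zero transition risks: nobody ever dies or is readmitted
immortal_params <- function(u = 0.06, discount = 0) {
  parameter_set(
    p_cvd_early_sv = 0, p_cvd_early_ena = 0,
    p_cvd_late_sv = 0, p_cvd_late_ena = 0,
    p_hosp_early_sv = 0, p_hosp_early_ena = 0,
    p_hosp_late_sv = 0, p_hosp_late_ena = 0,
    cost_sv_month = 10, cost_ena_month = 20, cost_hosp_event = 1000,
    u_sv_month = u, u_ena_month = u, u_hosp_event = -0.1,
    discount_annual = discount, wtp = 37654.5,
    start_age = 60, horizon_cycles = 480
  )
}

immortal_lt <- function() life_table(c(60, 85), c(0, 0))
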