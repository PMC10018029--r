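# Cohort engine: strategy drug maps, transition structure, trace
# propagation, and half-cycle-corrected accrual.

strategies <- list(
  enalapril = strategy_spec("enalapril"),
  sv_early = strategy_spec("sv_early"),
  sv_late = strategy_spec("sv_late")
)

test_that("strategies resolve the active drug by state and phase", {
  expect_equal(resolve_active_drug(strategies$enalapril, "STABLE"), "ena")
  expect_equal(resolve_active_drug(strategies$sv_early, "HOSP_pre"), "sv")
  # late initiation: enalapril during the index admission, switch in STABLE
  expect_equal(resolve_active_drug(strategies$sv_late, "HOSP_pre"), "ena")
  expect_equal(resolve_active_drug(strategies$sv_late, "STABLE"), "sv")
  # default relapse behaviour: hospitalization episodes after the switch
  # fall back to enalapril-phase parameters until re-stabilization
  expect_equal(resolve_active_drug(strategies$sv_late, "HOSP_post"), "ena")
  alt <- strategy_spec("sv_late", relapse_drug = "sv")
  expect_equal(resolve_active_drug(alt, "HOSP_post"), "sv")
  expect_equal(resolve_active_drug(alt, "HOSP_pre"), "ena")
  expect_error(resolve_active_drug(strategies$sv_late, "CV_DEATH"),
               "absorbing")
  expect_error(resolve_active_drug(strategies$sv_late, "LIMBO"), "unknown")
})

test_that("transition rows match the base-case probabilities", {
  row <- transition_row(strategies$enalapril, "HOSP_pre", 62, .params, .lt)
  expect_equal(unname(row["CV_DEATH"]), 0.0172)
  expect_equal(unname(row["POST1_pre"]), 1 - 0.0172)
  row <- transition_row(strategies$sv_early, "STABLE", 62, .params, .lt)
  expect_equal(unname(row["CV_DEATH"]), 0.0053)
  expect_equal(unname(row["NONCV_DEATH"]), 0.0004)
  expect_equal(unname(row["HOSP_post"]), 0.0256)
  expect_equal(unname(row["STABLE"]), 1 - 0.0053 - 0.0004 - 0.0256)
  # non-CV death only applies from the stable state
  for (s in c("HOSP_pre", "POST1_pre", "POST2_pre")) {
    r <- transition_row(strategies$enalapril, s, 90, .params, .lt)
    expect_equal(unname(r["NONCV_DEATH"]), 0)
  }
  # every row is a probability vector summing to one
  for (strat in strategies) {
    for (s in health_states()) {
      for (age in c(60, 72, 91)) {
        r <- transition_row(strat, s, age, .params, .lt)
        expect_true(all(r >= 0))
        expect_equal(sum(r), 1, tolerance = 1e-15)
      }
    }
  }
})

test_that("late-initiation routing crosses the phase switch at stabilization", {
  # surviving the second post-discharge month enters the stable state
  row <- transition_row(strategies$sv_late, "POST2_pre", 62, .params, .lt)
  expect_equal(unname(row["STABLE"]),
               1 - .params$p_cvd_early_ena - .params$p_hosp_early_ena)
  # readmission before stabilization stays in the pre-switch phase
  row <- transition_row(strategies$sv_late, "POST1_pre", 62, .params, .lt)
  expect_equal(unname(row["HOSP_pre"]), .params$p_hosp_early_ena)
  expect_equal(unname(row["HOSP_post"]), 0)
  # hospitalization out of the stable state enters the post-switch phase
  row <- transition_row(strategies$sv_late, "STABLE", 62, .params, .lt)
  expect_equal(unname(row["HOSP_post"]), .params$p_hosp_late_sv)
  # with relapse_drug = "sv" the post-switch tunnels use the treated risks
  alt <- strategy_spec("sv_late", relapse_drug = "sv")
  row <- transition_row(alt, "POST1_post", 62, .params, .lt)
  expect_equal(unname(row["CV_DEATH"]), .params$p_cvd_early_sv)
  row <- transition_row(strategies$sv_late, "POST1_post", 62, .params, .lt)
  expect_equal(unname(row["CV_DEATH"]), .params$p_cvd_early_ena)
})

test_that("two propagation cycles match hand matrix multiplication", {
  cohort <- run_cohort(strategies$enalapril, .params, .lt, horizon = 2)
  expect_equal(unname(cohort$trace[1, "HOSP_pre"]), 1)
  expect_equal(sum(cohort$trace[1, ]), 1)
  # hand-propagated, written out from the transition definitions:
  p_cvd <- 0.0172; p_hosp <- 0.0717
  expect_equal(unname(cohort$trace[2, "CV_DEATH"]), p_cvd)
  expect_equal(unname(cohort$trace[2, "POST1_pre"]), 1 - p_cvd)
  expect_equal(unname(cohort$trace[3, "CV_DEATH"]),
               p_cvd + (1 - p_cvd) * p_cvd)
  expect_equal(unname(cohort$trace[3, "HOSP_pre"]), (1 - p_cvd) * p_hosp)
  expect_equal(unname(cohort$trace[3, "POST2_pre"]),
               (1 - p_cvd) * (1 - p_cvd - p_hosp))
  # the index admission is the cycle-0 inflow
  expect_equal(unname(cohort$inflow[1]), 1)
})

test_that("traces conserve mass and absorb monotonically", {
  sets <- c(list(.params),
            lapply(c(11, 12), function(s) {
              synthetic_parameter_set(synthetic_spec(seed = s))
            }))
  for (p in sets) {
    for (strat in strategies) {
      cohort <- run_cohort(strat, p, .lt, horizon = 120)
      sums <- rowSums(cohort$trace)
      expect_true(all(abs(sums - 1) < 1e-12))
      expect_true(all(cohort$trace >= 0))
      for (dead in c("CV_DEATH", "NONCV_DEATH")) {
        expect_true(all(diff(cohort$trace[, dead]) >= -1e-15))
      }
      # tunnel property: month-1 occupancy never exceeds the previous
      # cycle's hospitalized survivors
      hosp <- cohort$trace[, "HOSP_pre"] + cohort$trace[, "HOSP_post"]
      post1 <- cohort$trace[, "POST1_pre"] + cohort$trace[, "POST1_post"]
      expect_true(all(post1[-1] <= hosp[-121] + 1e-15))
      # inflow equals hospitalized occupancy (one-cycle tunnel)
      expect_equal(unname(cohort$inflow), unname(hosp))
    }
  }
})

test_that("background mortality empties the cohort over a lifetime horizon", {
  cohort <- run_cohort(strategies$enalapril, .params, .lt)
  alive <- sum(cohort$trace[481, setdiff(health_states(),
                                         c("CV_DEATH", "NONCV_DEATH"))])
  expect_lt(alive, 0.01)
})

test_that("lowering any event risk never decreases QALY or LY", {
  base <- run_strategy(strategies$enalapril, .params, .lt, horizon = 240)
  for (nm in c("p_cvd_early_ena", "p_cvd_late_ena", "p_hosp_early_ena",
               "p_hosp_late_ena")) {
    p <- .params
    p[[nm]] <- p[[nm]] * 0.5
    better <- accrue(run_cohort(strategies$enalapril, p, .lt, horizon = 240), p)
    expect_gte(better$qaly, base$qaly)
    expect_gte(better$ly, base$ly)
  }
})

test_that("accrual matches the one-cycle closed form at zero discount", {
  p <- .params
  p$discount_annual <- 0
  res <- run_strategy(strategies$enalapril, p, .lt, horizon = 1)
  # occupancy: trapezoid between all-HOSP and the cycle-1 row
  survivors <- 1 - p$p_cvd_early_ena
  expect_equal(res$qaly_occupancy,
               (p$u_ena_month + survivors * p$u_ena_month) / 2)
  expect_equal(res$cost_occupancy, survivors * p$cost_ena_month / 2)
  expect_equal(res$ly, (1 + survivors) / 2 / 12)
  # events: the index admission only
  expect_equal(res$cost_events, p$cost_hosp_event)
  expect_equal(res$qaly_events, p$u_hosp_event)
})

test_that("accrual decomposes exactly and discounting never gains", {
  for (strat in strategies) {
    res <- run_strategy(strat, .params, .lt)
    expect_identical(res$cost, res$cost_events + res$cost_occupancy)
    expect_identical(res$qaly, res$qaly_events + res$qaly_occupancy)
    expect_lte(res$cost, res$undiscounted$cost)
    expect_lte(res$qaly, res$undiscounted$qaly)
    expect_lte(res$ly, res$undiscounted$ly)
  }
})

test_that("event accruals equal the inflow-weighted discount sum", {
  cohort <- run_cohort(strategies$sv_early, .params, .lt)
  res <- accrue(cohort, .params)
  # independent summation straight from the trace
  t0 <- 0:(cohort$horizon - 1)
  expected_events <- sum((cohort$trace[t0 + 1, "HOSP_pre"] +
                          cohort$trace[t0 + 1, "HOSP_post"]) *
                         (1 + .params$discount_annual)^(-t0 / 12))
  expect_equal(res$cost_events / .params$cost_hosp_event, expected_events,
               tolerance = 1e-12)
  expect_equal(res$hosp_events_discounted, expected_events,
               tolerance = 1e-12)
})

test_that("base-case strategy orderings hold strictly", {
  ena <- run_strategy(strategies$enalapril, .params, .lt)
  sve <- run_strategy(strategies$sv_early, .params, .lt)
  svl <- run_strategy(strategies$sv_late, .params, .lt)
  expect_true(sve$qaly > svl$qaly && svl$qaly > ena$qaly)
  expect_true(sve$ly > svl$ly && svl$ly > ena$ly)
  expect_true(sve$cost > svl$cost && svl$cost > ena$cost)
})
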