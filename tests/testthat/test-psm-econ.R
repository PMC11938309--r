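params <- econ_params()
grid <- cycle_grid(params)
np <- length(grid)

test_that("econ_params validates Table-style constraints", {
  expect_error(econ_params(utilities = list(pfs = 1.2, pd = 0.5)), "utilities")
  expect_error(econ_params(annual_discount = 0.2), "discount")
  expect_error(econ_params(pd_treatment_mix = list(chemotherapy = 0.5,
                                                   targeted = 0.2, tcm = 0.1,
                                                   supportive = 0.1)),
               "sums")
  expect_error(econ_params(ae_disutilities = list(anaemia = 0.074)), "<= 0")
})

test_that("the cycle grid covers exactly the five-year horizon", {
  expect_equal(grid[1], 0)
  expect_equal(max(grid), 60)
  expect_equal(grid[2], 21 / (365.25 / 12))
})

test_that("drug costs follow vial-level rounding and schedules", {
  sint <- strategy_def("s", list(list(drug = "sintilimab", dose_rule = "flat",
                                      dose = 200, interval_days = 21)))
  expect_equal(drug_cost_per_cycle(sint, params), 153.74)
  ## 250 mg flat from 200 mg vials: two vials, no sharing
  two <- strategy_def("x", list(list(drug = "sintilimab", dose_rule = "flat",
                                     dose = 250, interval_days = 21)))
  expect_equal(drug_cost_per_cycle(two, params), 2 * 153.74)
  ## serplulimab 3 mg/kg two-weekly: 195 mg -> 2 x 100 mg vials,
  ## 1.5 administrations per 21-day cycle
  serp <- strategy_def("s", list(list(drug = "serplulimab",
                                      dose_rule = "mg_kg", dose = 3,
                                      interval_days = 14)))
  expect_equal(drug_cost_per_cycle(serp, params), 2 * 795.45 * 1.5)
  expect_error(drug_cost_per_cycle(
    strategy_def("u", list(list(drug = "nivolumab", dose_rule = "flat",
                                dose = 1, interval_days = 21))), params),
    "unknown drug")
  expect_error(strategy_def("b", list(list(drug = "sintilimab",
                                           dose_rule = "flat", dose = 1,
                                           interval_days = 7))), "interval")
})

test_that("trace memberships are clamped and always sum to one", {
  tr <- build_trace(rep(1, np), rep(1, np), params)
  expect_true(all(tr$state$p_pd == 0))
  expect_true(all(tr$state$p_death == 0))
  expect_equal(tr$clamp_count, 0)

  s_os <- exp(-0.04 * grid); s_pfs <- exp(-0.09 * grid)
  tr2 <- build_trace(s_pfs, s_os, params)
  expect_lt(max(abs(with(tr2$state, p_pfs + p_pd + p_death) - 1)), 1e-12)

  ## one crossing cycle: PD clamped to zero there, counter reports it
  s_bad <- s_os; s_bad[10] <- s_os[10] + 0.01
  tr3 <- build_trace(s_bad, s_os, params)
  expect_equal(tr3$clamp_count, 1)
  expect_equal(tr3$state$p_pd[10], 0)
  expect_lt(max(abs(with(tr3$state, p_pfs + p_pd + p_death) - 1)), 1e-12)
  expect_error(build_trace(rep(1, 10), rep(1, 10), params), "cycle_grid")
})

test_that("a healthy cohort accrues exactly five undiscounted years", {
  p0 <- econ_params(annual_discount = 0, utilities = list(pfs = 1, pd = 1),
                    ae_incidence = list(default = list()))
  tr <- build_trace(rep(1, np), rep(1, np), p0)
  acc <- accrue(tr, default_strategies()$chemotherapy, p0)
  expect_equal(acc$total_qaly, 5, tolerance = 1e-10)
  expect_equal(acc$total_ly, 5, tolerance = 1e-10)
})

test_that("accrued cost matches the geometric-sum oracle", {
  p0 <- econ_params(annual_discount = 0,
                    ae_incidence = list(default = list()))
  lam <- 0.05
  s <- exp(-lam * grid)
  tr <- build_trace(s, s, p0)
  strat <- default_strategies()$chemotherapy
  acc <- accrue(tr, strat, p0)
  per_cycle <- drug_cost_per_cycle(strat, p0) +
    with(p0$per_cycle_costs, routine_followup + administration +
           laboratory_radiology + supportive_care + hospitalization)
  ## closed form: (C / cycle) * integral of exp(-lam t); the half-cycle
  ## correction makes the discrete sum a trapezoid rule for it
  oracle <- per_cycle * (1 - exp(-lam * 60)) / lam / (21 / (365.25 / 12))
  expect_lt(abs(acc$total_cost - oracle) / oracle, 0.005)
})

test_that("adverse-event machinery is excercised once and only once", {
  s <- exp(-0.05 * grid)
  strat <- default_strategies()$sintilimab
  with_ae <- accrue(build_trace(s, s, params), strat, params)
  p_no <- econ_params(ae_incidence = list(default = list()))
  no_ae <- accrue(build_trace(s, s, p_no), strat, p_no)
  inc <- params$ae_incidence$default
  expect_equal(with_ae$total_cost - no_ae$total_cost,
               sum(unlist(inc) * unlist(params$ae_costs[names(inc)])))
  ## zero incidence: identical results with the machinery on or off
  p_zero <- econ_params(ae_incidence = list(
    default = lapply(params$ae_incidence$default, function(x) 0)))
  zero_ae <- accrue(build_trace(s, s, p_zero), strat, p_zero)
  expect_equal(zero_ae$total_cost, no_ae$total_cost)
  expect_equal(zero_ae$total_qaly, no_ae$total_qaly)
  ## unknown AE category errors instead of silently costing zero
  p_bad <- econ_params(ae_incidence = list(default = list(rash = 0.1)))
  expect_error(accrue(build_trace(s, s, p_bad), strat, p_bad), "rash")
})

test_that("icer_table reproduces the reported incremental analysis", {
  tab <- icer_table(escc_base_case_totals(), "chemotherapy", params)
  tor <- tab[tab$strategy == "toripalimab", ]
  expect_equal(tor$inc_cost, 33743.55 - 14025.37)
  expect_equal(tor$inc_qaly, 1.27 - 0.66)
  expect_equal(attr(tab, "n_below_wtp"), 3)
  ## ranking: ascending ICER among gainers
  ranked <- tab[!is.na(tab$rank), ]
  expect_equal(ranked$strategy[order(ranked$rank)][1:3],
               c("sintilimab", "toripalimab", "tislelizumab"))
  ## an identical strategy is flagged, not divided
  same <- rbind(escc_base_case_totals(),
                data.frame(strategy = "copy", cost = 14025.37, qaly = 0.66,
                           ly = 0.96))
  tab2 <- icer_table(same, "chemotherapy", params)
  expect_true(tab2$dominated_or_equal[tab2$strategy == "copy"])
  expect_true(is.na(tab2$icer[tab2$strategy == "copy"]))
  expect_error(icer_table(escc_base_case_totals(), "nope", params), "absent")
})

test_that("ICERs scale exactly with a global currency factor", {
  k <- 7.02
  scale_costs <- function(p, k) {
    p$unit_costs <- lapply(p$unit_costs, function(u) {
      u$price <- u$price * k; u })
    p$per_cycle_costs <- lapply(p$per_cycle_costs, function(v) v * k)
    p$ae_costs <- lapply(p$ae_costs, function(v) v * k)
    p$wtp_per_qaly <- p$wtp_per_qaly * k
    p
  }
  s_pfs <- exp(-0.08 * grid); s_os <- exp(-0.05 * grid)
  strategies <- default_strategies()[c("chemotherapy", "sintilimab")]
  run_all <- function(p) {
    totals <- do.call(rbind, lapply(strategies, function(s)
      run_strategy(s, s_pfs, s_os, p)))
    icer_table(totals, "chemotherapy", p)
  }
  base <- run_all(params)
  scaled <- run_all(scale_costs(params, k))
  expect_equal(scaled$icer[scaled$strategy == "sintilimab"],
               k * base$icer[base$strategy == "sintilimab"],
               tolerance = 1e-12)
  expect_equal(scaled$below_wtp, base$below_wtp)
})

test_that("raising the PFS utility never lowers any strategy's QALYs", {
  s_pfs <- exp(-0.08 * grid); s_os <- exp(-0.05 * grid)
  for (strat in default_strategies()[c("chemotherapy", "toripalimab")]) {
    lo <- run_strategy(strat, s_pfs, s_os,
                       econ_params(utilities = list(pfs = 0.70, pd = 0.581)))
    hi <- run_strategy(strat, s_pfs, s_os,
                       econ_params(utilities = list(pfs = 0.80, pd = 0.581)))
    expect_gte(hi$qaly, lo$qaly)
  }
})

test_that("zero discount reproduces undiscounted sums", {
  p0 <- econ_params(annual_discount = 0,
                    ae_incidence = list(default = list()))
  s_pfs <- exp(-0.08 * grid); s_os <- exp(-0.05 * grid)
  tr <- build_trace(s_pfs, s_os, p0)
  acc <- accrue(tr, default_strategies()$chemotherapy, p0)
  avg <- function(v) (v[-1] + v[-length(v)]) / 2
  ly_raw <- sum((avg(s_pfs) + avg(pmax(0, s_os - s_pfs))) * diff(grid) / 12)
  expect_equal(acc$total_ly, ly_raw, tolerance = 1e-10)
})
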