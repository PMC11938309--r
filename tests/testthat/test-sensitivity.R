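params <- econ_params()

## a fast analytic stand-in model: totals respond to utilities and one
## drug price the way the real pipeline does, at negligible cost
toy_model <- function(p) {
  q_chemo <- 0.60 * p$utilities$pfs / 0.741
  q_drug <- 1.00 * (0.6 * p$utilities$pfs + 0.4 * p$utilities$pd) /
    (0.6 * 0.741 + 0.4 * 0.581)
  c_drug <- 14000 + 60 * p$unit_costs$sintilimab$price
  data.frame(strategy = c("chemotherapy", "drug"),
             cost = c(12000, c_drug),
             qaly = c(q_chemo, q_drug),
             ly = c(0.9, 1.4))
}

test_that("dsa_spec applies the +/-20% and price-only-downward rules", {
  sp <- dsa_spec(params)
  u <- sp[sp$path == "utilities.pfs", ]
  expect_equal(u$low, 0.741 * 0.8)
  expect_equal(u$high, 0.741 * 1.2)
  pr <- sp[sp$path == "unit_costs.sintilimab.price", ]
  expect_equal(pr$low, 153.74 * 0.8)
  expect_equal(pr$high, 153.74)
  expect_true(all(sp$low <= sp$high))
})

test_that("one_way produces a sorted tornado with sane directions", {
  sp <- dsa_spec(params, c("utilities.pfs", "utilities.pd",
                           "unit_costs.sintilimab.price"))
  tw <- one_way(toy_model, params, sp, "drug", "chemotherapy")
  expect_true(all(diff(tw$span) <= 0))
  ## raising the intervention's price raises its ICER
  pr <- tw[tw$path == "unit_costs.sintilimab.price", ]
  expect_gt(pr$icer_high, pr$icer_low)
  ## a degenerate parameter has span zero
  sp0 <- dsa_spec(params, "utilities.pfs")
  sp0$low <- sp0$high <- sp0$baseline
  tw0 <- one_way(toy_model, params, sp0, "drug", "chemotherapy")
  expect_equal(tw0$span, 0)
})

test_that("a perturbation that removes the QALY gain is flagged dominated", {
  dom_model <- function(p) {
    data.frame(strategy = c("chemotherapy", "drug"),
               cost = c(12000, 20000),
               qaly = c(0.6, 0.6 + (p$utilities$pfs - 0.70) * 10),
               ly = c(1, 1))
  }
  sp <- dsa_spec(params, "utilities.pfs")
  sp$low <- 0.65; sp$high <- 0.85
  tw <- one_way(dom_model, params, sp, "drug", "chemotherapy")
  expect_true(tw$dominated_low)
  expect_false(tw$dominated_high)
})

test_that("moment-matched samplers hit their targets", {
  spec <- psa_spec(params, n_draws = 100000, seed = 5)
  ## pull one gamma cost column directly
  draws <- sample_params(spec)
  x <- draws[["per_cycle_costs.laboratory_radiology"]]
  m <- 379.15; se <- 0.2 * m / 1.96
  expect_gt(mean(x), m - 0.01 * m); expect_lt(mean(x), m + 0.01 * m)
  expect_gt(sd(x), se * 0.975); expect_lt(sd(x), se * 1.025)
  ## beta utilities stay inside [0, 1] and centre on the baseline
  u <- draws[["utilities.pfs"]]
  expect_true(all(u >= 0 & u <= 1))
  expect_lt(abs(mean(u) - 0.741), 3 * sd(u) / sqrt(length(u)))
  ## disutilities are negative beta magnitudes
  d <- draws[["ae_disutilities.anaemia"]]
  expect_true(all(d <= 0))
  ## Dirichlet rows sum to one
  mix <- as.matrix(draws[, grep("^pd_treatment_mix", names(draws))])
  expect_lt(max(abs(rowSums(mix) - 1)), 1e-12)
  ## discount draws respect the [0, 0.08] support
  expect_true(all(draws[["annual_discount"]] >= 0 &
                    draws[["annual_discount"]] <= 0.08))
})

test_that("gamma draws at the stated acceptance scale match mean and SD", {
  x <- esccea:::sample_gamma(100000, 100, 20)
  expect_gt(mean(x), 99); expect_lt(mean(x), 101)
  expect_gt(sd(x), 19.5); expect_lt(sd(x), 20.5)
  expect_error(esccea:::sample_gamma(10, 100, 0), "SE")
})

test_that("degenerate SEs collapse every draw onto the mean", {
  x <- esccea:::sample_gamma(1000, 50, 50 * 1e-9)
  expect_lt(max(abs(x - 50) / 50), 1e-6)
  y <- esccea:::sample_beta_scaled(1000, 0.741, 0.741 * 1e-9)
  expect_lt(max(abs(y - 0.741) / 0.741), 1e-6)
})

test_that("sampling is reproducible from the spec seed", {
  s1 <- sample_params(psa_spec(params, n_draws = 50, seed = 9))
  s2 <- sample_params(psa_spec(params, n_draws = 50, seed = 9))
  expect_identical(s1, s2)
  s3 <- sample_params(psa_spec(params, n_draws = 50, seed = 10))
  expect_false(identical(s1, s3))
})

test_that("contrast coefficients are sampled from their reported intervals", {
  ct <- escc_fp_contrasts()
  spec <- psa_spec(params, ct, n_draws = 20000, seed = 3)
  draws <- sample_params(spec)
  x <- draws[["contrast.PFS.toripalimab.d0"]]
  se <- (-0.52 - (-1.30)) / (2 * 1.96)
  expect_lt(abs(mean(x) + 0.91), 3 * se / sqrt(length(x)) + 0.01)
  expect_lt(abs(sd(x) - se) / se, 0.05)
})

test_that("run_psa counts strictly positive net benefit, reproducibly", {
  ## three hand-crafted draws with known incrementals via a lookup model
  lookup <- data.frame(dc = c(1000, 5000, -200), dq = c(0.5, 0.1, 0.02))
  i <- 0
  hand_model <- function(p) {
    i <<- i + 1
    data.frame(strategy = c("chemotherapy", "drug"),
               cost = c(0, lookup$dc[i]), qaly = c(0, lookup$dq[i]),
               ly = c(1, 1))
  }
  draws <- data.frame(body_weight = c(65, 65, 65))
  res <- run_psa(hand_model, draws, params, "chemotherapy", wtp = 10000,
                 contrasts = NULL)
  ## NMB: 10000*0.5-1000 > 0; 10000*0.1-5000 < 0; 10000*0.02+200 > 0
  expect_equal(unname(res$prob_ce[["drug"]]), 2 / 3)
  ## degenerate distributions reproduce the base case deterministically
  base_model <- function(p) toy_model(params)
  resb <- run_psa(base_model, data.frame(body_weight = 65), params, "chemotherapy",
                  wtp = params$wtp_per_qaly)
  nmb <- params$wtp_per_qaly *
    (toy_model(params)$qaly[2] - toy_model(params)$qaly[1]) -
    (toy_model(params)$cost[2] - toy_model(params)$cost[1])
  expect_equal(unname(resb$prob_ce[["drug"]]), as.numeric(nmb > 0))
})

test_that("failures are tolerated up to 5% and reported", {
  flaky <- local({
    i <- 0
    function(p) {
      i <<- i + 1
      if (i == 2) stop("boom")
      data.frame(strategy = c("chemotherapy", "drug"), cost = c(0, 100),
                 qaly = c(0, 0.5), ly = c(1, 1))
    }
  })
  res <- run_psa(flaky, data.frame(body_weight = rep(65, 50)), params, "chemotherapy")
  expect_equal(res$n_failed, 1)
  always_fails <- function(p) stop("boom")
  expect_error(run_psa(always_fails, data.frame(body_weight = rep(65, 10)), params,
                       "chemotherapy"), "5%")
})

test_that("the CEAC is monotone for always-gaining strategies and strict at ties", {
  scatter <- data.frame(draw = 1:4, strategy = "drug",
                        inc_cost = c(1000, 2000, 1500, 800),
                        inc_qaly = c(0.1, 0.2, 0.05, 0.4))
  psa <- structure(list(scatter = scatter, reference = "chemotherapy"),
                   class = "psa_result")
  cc <- ceac(psa, c(0, 5000, 10000, 1e6))
  expect_true(all(diff(cc$drug) >= 0))
  expect_true(all(cc$drug >= 0 & cc$drug <= 1))
  ## a draw whose ICER equals the WTP exactly is NOT cost-effective
  one <- structure(list(scatter = data.frame(draw = 1, strategy = "drug",
                                             inc_cost = 1000,
                                             inc_qaly = 0.1),
                        reference = "chemotherapy"),
                   class = "psa_result")
  cc1 <- ceac(one, 10000)
  expect_equal(cc1$drug, 0)
  expect_equal(ceac(one, 10001)$drug, 1)
})
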