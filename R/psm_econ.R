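## Three-state partitioned survival model (progression-free, progressed,
## dead) for first-line advanced ESCC: state occupancy read directly off
## the PFS and OS curves, 21-day cycles over a 5-year horizon with
## half-cycle correction and 5% annual discounting, drug acquisition costed
## at vial level (65 kg / 1.72 m2 reference patient), one-off adverse-event
## costs and disutilities, and ICER ranking against the chemotherapy
## reference at the Chinese willingness-to-pay threshold.

DAYS_PER_YEAR <- 365.25
DAYS_PER_MONTH <- DAYS_PER_YEAR / 12

#' Economic model parameters
#'
#' Builds the full parameter set of the economic model: unit drug prices
#' (USD per vial, 2022 prices), per-21-day-cycle resource costs, one-off
#' adverse-event costs and disutilities, health-state utilities, the
#' post-progression treatment mix, dosing anthropometrics (65 kg, 1.72 m2),
#' discounting and the willingness-to-pay threshold (three times 2022
#' Chinese per-capita GDP, $36,598.19/QALY; 1 CNY = 0.14235 USD).
#' Any element can be overridden.
#'
#' @param ... named overrides of the defaults (nested lists are replaced
#'   wholesale).
#' @return list of class \code{econ_params}.
#' @export
econ_params <- function(...) {
  p <- list(
    cycle_days = 21,
    horizon_years = 5,
    annual_discount = 0.05,
    discount_lys = TRUE,
    wtp_per_qaly = 36598.19,
    cny_to_usd = 0.14235,
    body_weight = 65,
    bsa = 1.72,
    unit_costs = list(
      toripalimab = list(price = 299.07, vial_mg = 240),
      camrelizumab = list(price = 366.78, vial_mg = 200),
      pembrolizumab = list(price = 2550.63, vial_mg = 100),
      serplulimab = list(price = 795.45, vial_mg = 100),
      sintilimab = list(price = 153.74, vial_mg = 200),
      tislelizumab = list(price = 392.17, vial_mg = 200),
      fluorouracil = list(price = 4.59, vial_mg = 250),
      cisplatin = list(price = 3.99, vial_mg = 50),
      anlotinib = list(price = 5.21, vial_mg = 10),
      paclitaxel_liposome = list(price = 173.52, vial_mg = 30)),
    per_cycle_costs = list(
      routine_followup = 78.23,
      administration = 1.95,
      laboratory_radiology = 379.15,
      supportive_care = 177.87,
      hospitalization = 159.72,
      herbal = 213.53),
    ae_costs = list(anaemia = 203.13, leukopenia = 472.07,
                    neutropenia = 472.07, nausea = 20.50, vomiting = 20.50,
                    hypokalaemia = 17.04, pneumonia = 706.82),
    utilities = list(pfs = 0.741, pd = 0.581),
    ae_disutilities = list(anaemia = -0.074, leukopenia = -0.090,
                           neutropenia = -0.090, nausea = -0.048,
                           vomiting = -0.048, hypokalaemia = -0.040,
                           pneumonia = -0.008),
    ## grade >=3 incidences are trial-report territory; these defaults are a
    ## synthetic assumption shared across strategies, overridable per
    ## strategy by name (fallback key "default")
    ae_incidence = list(default = list(anaemia = 0.12, leukopenia = 0.09,
                                       neutropenia = 0.20, nausea = 0.05,
                                       vomiting = 0.05, hypokalaemia = 0.06,
                                       pneumonia = 0.03)),
    pd_treatment_mix = list(chemotherapy = 0.30, targeted = 0.20,
                            tcm = 0.30, supportive = 0.20),
    ## post-progression regimens (assumption, configurable)
    pd_doses = list(
      paclitaxel_mg_m2 = 175,          # liposomal paclitaxel q3w
      anlotinib_mg_day = 12, anlotinib_days_per_cycle = 14))
  over <- list(...)
  for (nm in names(over)) p[[nm]] <- over[[nm]]
  p <- structure(p, class = "econ_params")
  validate_econ_params(p)
  p
}

#' Validate economic parameters
#'
#' @param p an \code{econ_params}.
#' @return invisibly \code{p}; errors describe each violated constraint.
#' @export
validate_econ_params <- function(p) {
  probs <- character(0)
  costs <- c(unlist(lapply(p$unit_costs, `[[`, "price")),
             unlist(p$per_cycle_costs), unlist(p$ae_costs))
  if (any(costs < 0)) probs <- c(probs, "negative cost entries")
  u <- unlist(p$utilities)
  if (any(u < 0 | u > 1)) probs <- c(probs, "utilities outside [0, 1]")
  if (any(unlist(p$ae_disutilities) > 0))
    probs <- c(probs, "AE disutilities must be <= 0")
  mix <- unlist(p$pd_treatment_mix)
  if (abs(sum(mix) - 1) > 1e-9)
    probs <- c(probs, sprintf("pd_treatment_mix sums to %.4f, not 1", sum(mix)))
  if (p$annual_discount < 0 || p$annual_discount > 0.08)
    probs <- c(probs, "discount rate outside [0, 0.08]")
  if (length(probs)) stop("invalid econ_params: ", paste(probs, collapse = "; "),
                          call. = FALSE)
  invisible(p)
}

#' Define a treatment strategy
#'
#' @param name strategy label.
#' @param components list of drug components, each a list with \code{drug},
#'   \code{dose_rule} (\code{"flat"}, \code{"mg_kg"} or \code{"mg_m2"}),
#'   \code{dose}, and \code{interval_days} (14 or 21).
#' @param duration \code{"until_progression"} (drug cost accrues on the
#'   PFS state) or a fixed number of cycles.
#' @return list of class \code{strategy_def}.
#' @export
strategy_def <- function(name, components, duration = "until_progression") {
  for (comp in components) {
    stopifnot(all(c("drug", "dose_rule", "dose", "interval_days") %in%
                    names(comp)))
    if (!comp$interval_days %in% c(14, 21))
      stop("administration interval must be 14 or 21 days", call. = FALSE)
    if (!comp$dose_rule %in% c("flat", "mg_kg", "mg_m2"))
      stop("unknown dose rule: ", comp$dose_rule, call. = FALSE)
  }
  structure(list(name = name, components = components, duration = duration),
            class = "strategy_def")
}

## 5-FU + cisplatin backbone (the common comparator regimen: 5-FU
## 800 mg/m2/day days 1-5 plus cisplatin 80 mg/m2, every 3 weeks).
chemo_backbone <- function() {
  list(list(drug = "fluorouracil", dose_rule = "mg_m2", dose = 4000,
            interval_days = 21),
       list(drug = "cisplatin", dose_rule = "mg_m2", dose = 80,
            interval_days = 21))
}

#' Default strategy set: chemotherapy and the six PD-1 combinations
#'
#' Chemotherapy is the 5-FU + cisplatin backbone; each combination adds
#' one PD-1 inhibitor (toripalimab 240 mg, camrelizumab 200 mg,
#' pembrolizumab 200 mg, sintilimab 200 mg and tislelizumab 200 mg flat
#' every 3 weeks; serplulimab 3 mg/kg every 2 weeks).
#'
#' @return named list of \code{strategy_def} objects.
#' @export
default_strategies <- function() {
  pd1 <- list(
    toripalimab = list(drug = "toripalimab", dose_rule = "flat", dose = 240,
                       interval_days = 21),
    camrelizumab = list(drug = "camrelizumab", dose_rule = "flat", dose = 200,
                        interval_days = 21),
    pembrolizumab = list(drug = "pembrolizumab", dose_rule = "flat",
                         dose = 200, interval_days = 21),
    serplulimab = list(drug = "serplulimab", dose_rule = "mg_kg", dose = 3,
                       interval_days = 14),
    sintilimab = list(drug = "sintilimab", dose_rule = "flat", dose = 200,
                      interval_days = 21),
    tislelizumab = list(drug = "tislelizumab", dose_rule = "flat", dose = 200,
                        interval_days = 21))
  out <- list(chemotherapy = strategy_def("chemotherapy", chemo_backbone()))
  for (nm in names(pd1))
    out[[nm]] <- strategy_def(nm, c(list(pd1[[nm]]), chemo_backbone()))
  out
}

#' Drug acquisition cost per 21-day model cycle
#'
#' Per administration the required dose is resolved (flat, per kg at the
#' reference 65 kg, or per m2 at 1.72 m2), rounded up to whole vials with
#' no vial sharing, and priced; 14-day schedules contribute 1.5
#' administrations per 21-day model cycle.
#'
#' @param strategy a \code{strategy_def}.
#' @param params an \code{econ_params}.
#' @return USD per model cycle.
#' @export
drug_cost_per_cycle <- function(strategy, params) {
  total <- 0
  for (comp in strategy$components) {
    uc <- params$unit_costs[[comp$drug]]
    if (is.null(uc)) stop("unknown drug: ", comp$drug, call. = FALSE)
    if (uc$vial_mg <= 0) stop("zero vial strength for ", comp$drug, call. = FALSE)
    mg <- switch(comp$dose_rule,
                 flat = comp$dose,
                 mg_kg = comp$dose * params$body_weight,
                 mg_m2 = comp$dose * params$bsa)
    vials <- ceiling(mg / uc$vial_mg)
    per_admin <- vials * uc$price
    total <- total + per_admin * params$cycle_days / comp$interval_days
  }
  total
}

## Post-progression per-cycle cost: a mixture over the PD treatment
## components (later-line chemotherapy, targeted therapy, traditional
## Chinese medicine, supportive care).
pd_cost_per_cycle <- function(params) {
  uc <- params$unit_costs
  pdd <- params$pd_doses
  pac_mg <- pdd$paclitaxel_mg_m2 * params$bsa
  chemo <- ceiling(pac_mg / uc$paclitaxel_liposome$vial_mg) *
    uc$paclitaxel_liposome$price
  anl_mg <- pdd$anlotinib_mg_day * pdd$anlotinib_days_per_cycle
  targeted <- ceiling(anl_mg / uc$anlotinib$vial_mg) * uc$anlotinib$price
  mix <- params$pd_treatment_mix
  mix$chemotherapy * chemo + mix$targeted * targeted +
    mix$tcm * params$per_cycle_costs$herbal +
    mix$supportive * params$per_cycle_costs$supportive_care
}

#' Model cycle grid
#'
#' @param params an \code{econ_params}.
#' @return times in months from 0 to the horizon in 21-day steps; the
#'   final (possibly partial) step is truncated exactly at the horizon.
#' @export
cycle_grid <- function(params) {
  cyc_m <- params$cycle_days / DAYS_PER_MONTH
  hor_m <- params$horizon_years * 12
  g <- seq(0, hor_m, by = cyc_m)
  if (max(g) < hor_m - 1e-9) g <- c(g, hor_m)
  g
}

#' Build the partitioned-survival state-occupancy trace
#'
#' State membership at each cycle boundary: progression-free
#' \code{min(S_pfs, S_os)}, progressed \code{max(0, S_os - S_pfs)}
#' (clamped, with the clamp count reported), dead \code{1 - S_os}; the
#' memberships sum to 1 by construction. Accrual uses the half-cycle
#' correction (endpoint averages) and the discount factor is evaluated at
#' each cycle midpoint.
#'
#' @param s_pfs,s_os survival probabilities on \code{\link{cycle_grid}}.
#' @param params an \code{econ_params}.
#' @return list of class \code{psm_trace}: \code{state} (data.frame of
#'   cycle, time_months, time_years, p_pfs, p_pd, p_death),
#'   \code{clamp_count}, and per-interval discount factors.
#' @export
build_trace <- function(s_pfs, s_os, params) {
  grid <- cycle_grid(params)
  if (length(s_pfs) != length(grid) || length(s_os) != length(grid))
    stop("survival curves must be evaluated on cycle_grid(params) (",
         length(grid), " points)", call. = FALSE)
  clamp_count <- sum(s_pfs > s_os + 1e-12)
  p_pfs <- pmin(s_pfs, s_os)
  p_pd <- pmax(0, s_os - s_pfs)
  p_death <- 1 - s_os
  t_years <- grid / 12
  n_int <- length(grid) - 1
  t_mid <- (t_years[-1] + t_years[-length(t_years)]) / 2
  disc <- (1 + params$annual_discount)^(-t_mid)
  structure(list(
    state = data.frame(cycle = seq_along(grid) - 1, time_months = grid,
                       time_years = t_years, p_pfs = p_pfs, p_pd = p_pd,
                       p_death = p_death),
    discount = disc, clamp_count = clamp_count, n_intervals = n_int),
    class = "psm_trace")
}

#' @export
print.psm_trace <- function(x, ...) {
  cat("Partitioned-survival trace:", x$n_intervals, "cycles,",
      x$clamp_count, "clamped PD memberships\n")
  invisible(x)
}

#' Accrue discounted costs, QALYs and life years over a trace
#'
#' Progression-free cycles cost the strategy's drugs plus administration,
#' laboratory/radiology, supportive care, hospitalization and routine
#' follow-up; progressed cycles cost the post-progression treatment
#' mixture (patients continue active treatment after progression).
#' Adverse-event costs and disutilities are applied once, at model start,
#' to the whole cohort. Utility-weighted (QALY) and unweighted (LY)
#' survival accrue by half-cycle-corrected interval averages with midpoint
#' discounting.
#'
#' @param trace a \code{psm_trace}.
#' @param strategy a \code{strategy_def}.
#' @param params an \code{econ_params}.
#' @return list: \code{total_cost}, \code{total_qaly}, \code{total_ly}
#'   (discounted, USD / QALY / years) and the per-cycle accrual table.
#' @export
accrue <- function(trace, strategy, params) {
  st <- trace$state
  n <- trace$n_intervals
  need <- c("routine_followup", "administration", "laboratory_radiology",
            "supportive_care", "hospitalization", "herbal")
  missing_cat <- setdiff(need, names(params$per_cycle_costs))
  if (length(missing_cat))
    stop("missing per-cycle cost categories: ",
         paste(missing_cat, collapse = ", "), call. = FALSE)
  pcc <- params$per_cycle_costs
  pfs_fixed <- pcc$routine_followup + pcc$administration +
    pcc$laboratory_radiology + pcc$supportive_care + pcc$hospitalization
  pfs_cost <- drug_cost_per_cycle(strategy, params) + pfs_fixed
  pd_cost <- pd_cost_per_cycle(params)
  avg <- function(v) (v[-1] + v[-length(v)]) / 2
  p_pfs <- avg(st$p_pfs); p_pd <- avg(st$p_pd)
  dt_years <- diff(st$time_years)
  cycle_scale <- dt_years * DAYS_PER_YEAR / params$cycle_days
  disc <- trace$discount
  cost_c <- (p_pfs * pfs_cost + p_pd * pd_cost) * cycle_scale * disc
  u <- params$utilities
  qaly_c <- (u$pfs * p_pfs + u$pd * p_pd) * dt_years * disc
  ly_disc <- if (isTRUE(params$discount_lys)) disc else 1
  ly_c <- (p_pfs + p_pd) * dt_years * ly_disc
  ## one-off adverse-event burden at model start
  inc <- params$ae_incidence[[strategy$name]] %||% params$ae_incidence$default
  ae_cost <- sum(vapply(names(inc), function(ae) {
    if (is.null(params$ae_costs[[ae]]))
      stop("no cost for adverse event '", ae, "'", call. = FALSE)
    inc[[ae]] * params$ae_costs[[ae]]
  }, numeric(1)))
  ae_dis <- sum(vapply(names(inc), function(ae) {
    if (is.null(params$ae_disutilities[[ae]]))
      stop("no disutility for adverse event '", ae, "'", call. = FALSE)
    inc[[ae]] * params$ae_disutilities[[ae]]
  }, numeric(1)))
  list(total_cost = sum(cost_c) + ae_cost,
       total_qaly = sum(qaly_c) + ae_dis,
       total_ly = sum(ly_c),
       per_cycle = data.frame(cycle = seq_len(n), cost = cost_c,
                              qaly = qaly_c, ly = ly_c, discount = disc),
       ae_cost = ae_cost, ae_disutility = ae_dis)
}

#' Evaluate one strategy over given PFS/OS curves
#'
#' @param strategy a \code{strategy_def}.
#' @param s_pfs,s_os survival on \code{\link{cycle_grid}}.
#' @param params an \code{econ_params}.
#' @return one-row data.frame: strategy, cost, qaly, ly.
#' @export
run_strategy <- function(strategy, s_pfs, s_os, params) {
  tr <- build_trace(s_pfs, s_os, params)
  acc <- accrue(tr, strategy, params)
  data.frame(strategy = strategy$name, cost = acc$total_cost,
             qaly = acc$total_qaly, ly = acc$total_ly,
             stringsAsFactors = FALSE)
}

#' Incremental cost-effectiveness table
#'
#' Computes incremental cost and QALYs versus the reference, the ICER,
#' the rank (ascending ICER among strategies with positive incremental
#' QALYs), and a below-willingness-to-pay flag. Strategies with
#' non-positive incremental QALYs are flagged and excluded from ranking
#' rather than divided.
#'
#' @param totals data.frame with \code{strategy}, \code{cost},
#'   \code{qaly} (and optionally \code{ly}).
#' @param reference strategy label of the comparator.
#' @param params an \code{econ_params} (supplies the WTP threshold).
#' @return data.frame of class \code{ce_result} with incrementals, ICER,
#'   \code{rank}, \code{below_wtp} and \code{dominated_or_equal} flags;
#'   attribute \code{n_below_wtp}.
#' @export
icer_table <- function(totals, reference, params = econ_params()) {
  stopifnot(all(c("strategy", "cost", "qaly") %in% names(totals)))
  if (!reference %in% totals$strategy)
    stop("reference strategy '", reference, "' absent", call. = FALSE)
  ref <- totals[totals$strategy == reference, ]
  out <- totals
  out$inc_cost <- out$cost - ref$cost
  out$inc_qaly <- out$qaly - ref$qaly
  is_ref <- out$strategy == reference
  pos <- out$inc_qaly > 0 & !is_ref
  out$icer <- ifelse(pos, out$inc_cost / out$inc_qaly, NA_real_)
  out$dominated_or_equal <- !pos & !is_ref
  out$rank <- NA_integer_
  out$rank[pos] <- rank(out$icer[pos], ties.method = "first")
  out$below_wtp <- pos & out$icer < params$wtp_per_qaly
  attr(out, "n_below_wtp") <- sum(out$below_wtp)
  attr(out, "reference") <- reference
  attr(out, "wtp") <- params$wtp_per_qaly
  class(out) <- c("ce_result", "data.frame")
  out
}

#' @export
print.ce_result <- function(x, ...) {
  cat("Cost-effectiveness vs '", attr(x, "reference"), "' (WTP ",
      format(attr(x, "wtp"), big.mark = ","), "/QALY); ",
      attr(x, "n_below_wtp"), " strategies below threshold\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 6)
  invisible(x)
}

#' Build a cost-effectiveness model closure
#'
#' Binds reference-arm PFS/OS survival fits, FP contrasts per endpoint and
#' treatment, and the strategy set into a single function of the economic
#' parameters: every call projects each comparator's curves from the
#' reference via \code{\link{apply_contrast}}, runs the partitioned
#' survival model and returns the per-strategy totals. This is the "model"
#' handed to the deterministic and probabilistic sensitivity analyses.
#'
#' @param fit_pfs,fit_os \code{surv_fit} objects for the reference arm.
#' @param contrasts data.frame with columns treatment, endpoint
#'   (\code{"PFS"}/\code{"OS"}), p, d0, d1 (CI columns optional).
#' @param strategies named list of \code{strategy_def}; names other than
#'   the reference must appear in \code{contrasts$treatment}.
#' @param reference strategy evaluated directly from the reference fits.
#' @param t_floor passed to \code{\link{apply_contrast}}.
#' @return function \code{(params, contrasts = <bound>)} returning the
#'   totals data.frame.
#' @export
ce_model <- function(fit_pfs, fit_os, contrasts, strategies,
                     reference = "chemotherapy", t_floor = 1) {
  force(fit_pfs); force(fit_os); force(strategies); force(reference)
  bound_contrasts <- contrasts
  function(params, contrasts = bound_contrasts) {
    grid <- cycle_grid(params)
    ref_pfs <- predict(fit_pfs, grid)$survival
    ref_os <- predict(fit_os, grid)$survival
    rows <- lapply(strategies, function(strat) {
      if (strat$name == reference) {
        s_p <- ref_pfs; s_o <- ref_os
      } else {
        cp <- contrasts[contrasts$treatment == strat$name &
                          toupper(contrasts$endpoint) == "PFS", ]
        co <- contrasts[contrasts$treatment == strat$name &
                          toupper(contrasts$endpoint) == "OS", ]
        if (nrow(cp) != 1 || nrow(co) != 1)
          stop("need one PFS and one OS contrast for ", strat$name,
               call. = FALSE)
        s_p <- apply_contrast(fit_pfs, as.list(cp), grid, t_floor)$survival
        s_o <- apply_contrast(fit_os, as.list(co), grid, t_floor)$survival
      }
      run_strategy(strat, s_p, s_o, params)
    })
    do.call(rbind, c(rows, make.row.names = FALSE))
  }
}
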