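# Shared simulation fixtures, built in code at test time.

# Two-arm trial with constant reference hazard and a proportional contrast.
sim_ph_trial <- function(seed, n = 1000, rate = 0.1, log_hr = 0,
                         cutoff = 36, accrual = 0, dropout = 0) {
  sp <- trial_spec("t1", n_per_arm = n,
                   reference_hazard = list(breaks = 0, rates = rate),
                   contrast_truth = c(d0 = log_hr, d1 = 0, p = 0),
                   accrual_months = accrual, cutoff_months = cutoff,
                   dropout_rate = dropout, seed = seed)
  simulate_trial(sp)
}

# Star network of n_trials two-arm trials sharing one treatment, with an
# FP-family baseline on a monthly grid and the FP term evaluated on that
# grid (the discrete-time interval-hazard convention); administrative
# censoring at the 30-month cutoff.
sim_fp_network_counts <- function(seed, n = 2000, n_trials = 6,
                                  d0 = -0.6, d1 = 0.8, p = -2) {
  breaks <- c(0:24, 30)
  ref <- fp_reference_hazard(log(0.10), 0.3, p, breaks)
  ipd <- do.call(rbind, lapply(seq_len(n_trials), function(j) {
    sp <- trial_spec(paste0("trial", j), n_per_arm = n,
                     reference_hazard = ref,
                     contrast_truth = c(d0 = d0, d1 = d1, p = p),
                     accrual_months = 0, cutoff_months = 30,
                     dropout_rate = 0, seed = seed * 100 + j,
                     fp_time_grid = breaks)
    x <- simulate_trial(sp)
    x$arm <- ifelse(x$arm == "reference", "chemotherapy", "pd1")
    x
  }))
  interval_counts_from_ipd(ipd, breaks)
}

# Expected interval counts lying exactly on the FP model surface (the
# self-consistency oracle for contrast round trips). A two-month opening
# interval keeps steep negative-power contrasts finite.
fp_surface_counts <- function(d0, d1, p, beta0 = log(0.15), beta1 = 0.2,
                              breaks = c(0, 2:24), n0 = 600,
                              arm = "treatment") {
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  dl <- diff(breaks)
  xb <- if (p == 0) log(mids) else mids^p
  h_ref <- exp(beta0 + beta1 * xb)
  s_ref <- c(1, exp(-cumsum(h_ref * dl)))
  hr <- exp(d0 + d1 * xb)
  s_trt <- c(1, exp(-cumsum(h_ref * hr * dl)))
  rbind(
    interval_counts_from_survival(stats::approxfun(breaks, s_ref), n0,
                                  breaks, trial = "t1",
                                  arm = "chemotherapy"),
    interval_counts_from_survival(stats::approxfun(breaks, s_trt), n0,
                                  breaks, trial = "t1", arm = arm))
}

# Sup-norm distance between the KM estimates of two IPD tables.
km_sup_dist <- function(ipd_a, ipd_b, t_max = NULL) {
  t_max <- t_max %||% min(max(ipd_a$time), max(ipd_b$time))
  g <- seq(0, t_max, length.out = 1000)
  max(abs(km_survival_at(km_estimate(ipd_a), g) -
            km_survival_at(km_estimate(ipd_b), g)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
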