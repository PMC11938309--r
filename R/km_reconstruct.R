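## Reconstruction of individual patient data from digitised Kaplan-Meier
## coordinates and numbers-at-risk tables (the Guyot algorithm), KM
## re-estimation for fidelity checks, Cox HR validation against reported
## intervals, and proportional-hazards diagnostics.

validate_curve <- function(curve, jitter_tol = 0.005) {
  stopifnot(is.data.frame(curve), all(c("time", "survival") %in% names(curve)))
  curve <- curve[order(curve$time), c("time", "survival")]
  if (anyDuplicated(curve$time))
    stop("curve times must be strictly increasing", call. = FALSE)
  if (curve$time[1] > 0)
    curve <- rbind(data.frame(time = 0, survival = 1), curve)
  if (abs(curve$survival[1] - 1) > jitter_tol)
    stop("curve must start at survival 1", call. = FALSE)
  curve$survival[1] <- 1
  if (any(curve$survival < -jitter_tol | curve$survival > 1 + jitter_tol))
    stop("survival values outside [0, 1]", call. = FALSE)
  curve$survival <- pmin(pmax(curve$survival, 0), 1)
  ## isotonic repair of digitisation jitter; larger rises are input errors
  for (k in seq_len(nrow(curve))[-1]) {
    rise <- curve$survival[k] - curve$survival[k - 1]
    if (rise > jitter_tol)
      stop(sprintf("survival rises by %.4f at time %.4g: not a digitisation artifact",
                   rise, curve$time[k]), call. = FALSE)
    if (rise > 0) curve$survival[k] <- curve$survival[k - 1]
  }
  curve
}

validate_risk <- function(risk) {
  stopifnot(is.data.frame(risk), all(c("time", "n_at_risk") %in% names(risk)))
  risk <- risk[order(risk$time), c("time", "n_at_risk")]
  if (any(diff(risk$n_at_risk) > 0))
    stop("numbers at risk must be non-increasing", call. = FALSE)
  if (risk$n_at_risk[1] < 1) stop("initial number at risk must be >= 1", call. = FALSE)
  risk
}

#' Reconstruct individual patient data from a digitised KM curve
#'
#' Implements the Guyot iterative algorithm: within each interval between
#' consecutive numbers-at-risk times, the numbers of events and censorings
#' are solved so that the KM estimate of the output matches the digitised
#' survival steps and the at-risk counts match the risk table; censoring
#' times are spread uniformly within intervals. If the total number of
#' events is supplied, censoring in the final interval (the only one not
#' pinned by the risk table) is adjusted towards the reported count; with
#' a dense risk table the match is best-effort.
#'
#' @param curve data.frame with \code{time}, \code{survival} (the digitised
#'   step locations; a (0, 1) first point is inserted if absent). Rises up
#'   to 0.005 are clipped as digitisation jitter; larger rises are errors.
#' @param risk data.frame with \code{time}, \code{n_at_risk}.
#' @param total_events optional reported total number of events.
#' @param trial,arm labels stamped on the output records.
#' @return data.frame of IPD records: \code{trial}, \code{arm},
#'   \code{time}, \code{event}.
#' @references Guyot et al. (2012) BMC Medical Research Methodology 12:9.
#' @export
reconstruct_ipd <- function(curve, risk, total_events = NULL,
                            trial = "trial", arm = "arm") {
  curve <- validate_curve(curve)
  risk <- validate_risk(risk)
  t_s <- curve$time; S <- curve$survival
  n_t <- length(t_s)
  t_risk <- risk$time; n_risk <- risk$n_at_risk
  n_int <- length(t_risk)
  if (t_risk[1] > t_s[1] + 1e-9 || t_risk[1] > 0) {
    ## risk table must anchor the initial cohort at time 0
    t_risk <- c(0, t_risk); n_risk <- c(n_risk[1], n_risk); n_int <- n_int + 1
  }
  ## click-index bounds of each risk interval
  lower <- vapply(seq_len(n_int), function(i)
    which(t_s >= t_risk[i] - 1e-9)[1], integer(1))
  upper <- c(lower[-1] - 1L, n_t)
  if (anyNA(lower)) stop("risk table extends beyond the curve", call. = FALSE)
  ## drop risk rows with no curve support (empty intervals merged forward)
  keep <- !duplicated(lower)
  lower <- lower[keep]; upper <- c(lower[-1] - 1L, n_t)
  t_risk <- t_risk[keep]; n_risk <- n_risk[keep]; n_int <- length(lower)

  d <- integer(n_t)          # events at each click
  cen <- integer(n_t)        # censorings between click k and k+1
  km_hat <- rep(1, n_t)
  n_hat <- rep(n_risk[1], n_t + 1)
  n_censor <- integer(n_int)
  last_i <- rep(1L, n_int + 1)

  ## spread m censor times uniformly on (a, b) and bin them at the clicks
  bin_censor <- function(m, a, b, kfrom, kto) {
    counts <- integer(kto - kfrom + 1)
    if (m > 0 && b > a) {
      ct <- a + seq_len(m) * (b - a) / (m + 1)
      edges <- c(t_s[kfrom:kto], if (kto < n_t) t_s[kto + 1] else b + 1e-9)
      counts <- vapply(seq_len(kto - kfrom + 1), function(j)
        sum(ct >= edges[j] - 1e-12 & ct < edges[j + 1] - 1e-12), integer(1))
    }
    counts
  }

  process_interval <- function(i, ncen, d, cen, n_hat, km_hat, last) {
    kfrom <- lower[i]; kto <- upper[i]
    cen[kfrom:kto] <- bin_censor(ncen, t_s[kfrom],
                                 if (i < n_int) t_s[lower[i + 1]] else t_s[kto],
                                 kfrom, kto)
    n_hat[kfrom] <- n_risk[i]
    for (k in kfrom:kto) {
      if (i == 1 && k == 1) {
        d[k] <- 0L; km_hat[k] <- 1
      } else if (km_hat[last] > 0 && n_hat[k] > 0) {
        d[k] <- max(0L, as.integer(round(n_hat[k] * (1 - S[k] / km_hat[last]))))
        d[k] <- min(d[k], n_hat[k])
        km_hat[k] <- km_hat[last] * (1 - d[k] / n_hat[k])
      } else {
        d[k] <- 0L; km_hat[k] <- km_hat[last]
      }
      n_hat[k + 1] <- n_hat[k] - d[k] - cen[k]
      if (n_hat[k + 1] < 0) {
        n_hat[k + 1] <- 0
        cen[k] <- n_hat[k] - d[k]
      }
      if (d[k] != 0) last <- k
    }
    list(d = d, cen = cen, n_hat = n_hat, km_hat = km_hat, last = last)
  }

  if (n_int > 1) {
    for (i in seq_len(n_int - 1)) {
      s_lo <- S[lower[i]]; s_hi <- S[lower[i + 1]]
      n_censor[i] <- if (s_lo > 0)
        round(n_risk[i] * s_hi / s_lo) - n_risk[i + 1] else 0L
      iter <- 0L
      repeat {
        iter <- iter + 1L
        if (n_censor[i] < 0) n_censor[i] <- 0L
        st <- process_interval(i, n_censor[i], d, cen, n_hat, km_hat, last_i[i])
        gap <- st$n_hat[lower[i + 1]] - n_risk[i + 1]
        if (gap == 0 || (gap < 0 && n_censor[i] == 0) || iter > 100) break
        n_censor[i] <- n_censor[i] + gap
      }
      d <- st$d; cen <- st$cen; n_hat <- st$n_hat; km_hat <- st$km_hat
      if (n_hat[lower[i + 1]] < n_risk[i + 1]) n_risk[i + 1] <- n_hat[lower[i + 1]]
      last_i[i + 1] <- st$last
    }
  }
  ## final interval: carry forward the average censoring rate
  if (n_int > 1) {
    span_prev <- t_s[upper[n_int - 1]] - t_s[lower[1]]
    span_last <- t_s[upper[n_int]] - t_s[lower[n_int]]
    n_censor[n_int] <- if (span_prev > 0)
      min(round(sum(n_censor[-n_int]) * span_last / span_prev), n_risk[n_int])
    else 0L
  }
  n_censor[n_int] <- max(0L, n_censor[n_int])
  st <- process_interval(n_int, n_censor[n_int], d, cen, n_hat, km_hat,
                         last_i[n_int])
  d <- st$d; cen <- st$cen; n_hat <- st$n_hat; km_hat <- st$km_hat

  ## optional rescale of the final interval so total events match the report
  if (!is.null(total_events)) {
    sum_d <- sum(d)
    iter <- 0L
    while (sum_d != total_events && iter < 100) {
      iter <- iter + 1L
      n_censor[n_int] <- n_censor[n_int] + (sum_d - total_events)
      if (n_censor[n_int] < 0) n_censor[n_int] <- 0L
      st <- process_interval(n_int, n_censor[n_int], d, cen, n_hat, km_hat,
                             last_i[n_int])
      d <- st$d; cen <- st$cen; n_hat <- st$n_hat; km_hat <- st$km_hat
      new_sum <- sum(d)
      if (new_sum == sum_d && new_sum != total_events) break
      sum_d <- new_sum
    }
  }

  ## assemble the cohort: events at click times, censorings at interval
  ## midpoints, everyone remaining censored at the last click
  n0 <- n_risk[1]
  times <- rep(t_s[n_t], n0)
  events <- integer(n0)
  k <- 1L
  for (j in seq_len(n_t)) if (d[j] > 0) {
    idx <- k:(k + d[j] - 1L)
    times[idx] <- t_s[j]; events[idx] <- 1L; k <- k + d[j]
  }
  for (j in seq_len(n_t)) if (cen[j] > 0 && k <= n0) {
    upto <- min(n0, k + cen[j] - 1L)
    mid <- if (j < n_t) (t_s[j] + t_s[j + 1]) / 2 else t_s[n_t]
    times[k:upto] <- mid; events[k:upto] <- 0L; k <- upto + 1L
  }
  data.frame(trial = trial, arm = arm, time = pmax(times, 1e-9),
             event = events, stringsAsFactors = FALSE)
}

#' Kaplan-Meier product-limit estimate
#'
#' @param ipd data.frame with \code{time} and \code{event}.
#' @return object of class \code{km_curve}: step times, survival, numbers
#'   at risk and events (from \code{survival::survfit}).
#' @export
km_estimate <- function(ipd) {
  if (nrow(ipd) == 0) stop("empty IPD", call. = FALSE)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = ipd,
                          conf.type = "none")
  structure(list(time = sf$time, survival = sf$surv,
                 n_risk = sf$n.risk, n_event = sf$n.event,
                 n = sum(sf$n)),
            class = "km_curve")
}

#' Evaluate a KM step function at arbitrary times
#'
#' @param km a \code{km_curve}.
#' @param times evaluation times.
#' @return survival probabilities (1 before the first step).
#' @export
km_survival_at <- function(km, times) {
  idx <- findInterval(times, km$time)
  ifelse(idx == 0, 1, km$survival[pmax(idx, 1)])
}

#' Cox proportional-hazards HR with validation against a reported interval
#'
#' Partial-likelihood point estimate and Wald 95\% CI (Efron ties) for a
#' two-arm IPD table, optionally flagged for overlap with a reported HR
#' confidence interval (the reconstruction-quality check).
#'
#' @param ipd two-arm IPD data.frame (\code{arm}, \code{time}, \code{event}).
#' @param reference arm label used as baseline; defaults to the first arm
#'   in sort order.
#' @param reported optional numeric length-2 reported HR interval.
#' @return list of class \code{hr_validation}: \code{hr_point},
#'   \code{ci_low}, \code{ci_high}, \code{overlaps_reported}.
#' @export
cox_hr <- function(ipd, reference = NULL, reported = NULL) {
  arms <- sort(unique(ipd$arm))
  if (length(arms) != 2) stop("cox_hr needs exactly two arms", call. = FALSE)
  ev <- tapply(ipd$event, ipd$arm, sum)
  if (any(ev < 1)) stop("no events in arm ", names(ev)[ev < 1][1], call. = FALSE)
  reference <- reference %||% arms[1]
  ipd$arm <- factor(ipd$arm, levels = c(reference, setdiff(arms, reference)))
  fit <- survival::coxph(survival::Surv(time, event) ~ arm, data = ipd,
                         ties = "efron")
  b <- unname(stats::coef(fit)[1])
  se <- sqrt(stats::vcov(fit)[1, 1])
  ci <- exp(b + c(-1, 1) * stats::qnorm(0.975) * se)
  out <- list(hr_point = exp(b), ci_low = ci[1], ci_high = ci[2],
              comparison = paste(levels(ipd$arm)[2], "vs", reference),
              overlaps_reported = if (!is.null(reported))
                ci[1] <= max(reported) && ci[2] >= min(reported) else NA)
  class(out) <- "hr_validation"
  out
}

#' @export
print.hr_validation <- function(x, ...) {
  cat(sprintf("HR (%s) = %.3f [%.3f, %.3f]", x$comparison,
              x$hr_point, x$ci_low, x$ci_high))
  if (!is.na(x$overlaps_reported))
    cat("; overlaps reported interval:", x$overlaps_reported)
  cat("\n")
  invisible(x)
}

## Epanechnikov-kernel smoother of the Nelson-Aalen increments.
kernel_hazard <- function(km, grid, bandwidth) {
  inc <- km$n_event / km$n_risk      # dA(t_j)
  sel <- km$n_event > 0
  tj <- km$time[sel]; dj <- inc[sel]
  vapply(grid, function(g) {
    u <- (g - tj) / bandwidth
    sum(0.75 * pmax(0, 1 - u^2) * dj) / bandwidth
  }, numeric(1))
}

#' Proportional-hazards diagnostics for a two-arm trial
#'
#' Computes per-arm log-cumulative-hazard curves (log(-log S) from the KM
#' estimate) on a shared grid, kernel-smoothed hazard curves, and a
#' crossing flag: the between-arm log-cumulative-hazard difference changes
#' sign (beyond a tolerance band) after the first decile of event times.
#'
#' @param ipd two-arm IPD data.frame.
#' @param grid evaluation grid; defaults to 100 points over the event-time
#'   range.
#' @param bandwidth Epanechnikov bandwidth (months); defaults to one eighth
#'   of the event-time range.
#' @param band tolerance on the log-cumulative-hazard difference before a
#'   sign change counts as a crossing.
#' @return list of class \code{ph_diagnostics} with \code{log_cumhaz},
#'   \code{smoothed_hazard} (data.frames), and \code{crossing}.
#' @export
ph_diagnostics <- function(ipd, grid = NULL, bandwidth = NULL, band = 0.05) {
  arms <- sort(unique(ipd$arm))
  if (length(arms) != 2) stop("ph_diagnostics needs exactly two arms", call. = FALSE)
  ev_times <- ipd$time[ipd$event == 1]
  per_arm_events <- tapply(ipd$event, ipd$arm, sum)
  if (any(per_arm_events < 5))
    stop("need >= 5 events per arm", call. = FALSE)
  rng <- range(ev_times)
  grid <- grid %||% seq(rng[1], rng[2], length.out = 100)
  bandwidth <- bandwidth %||% (diff(rng) / 8)
  kms <- lapply(arms, function(a) km_estimate(ipd[ipd$arm == a, ]))
  names(kms) <- arms
  s1 <- km_survival_at(kms[[1]], grid); s2 <- km_survival_at(kms[[2]], grid)
  clh <- data.frame(time = grid,
                    arm1 = log(-log(pmin(pmax(s1, 1e-12), 1 - 1e-12))),
                    arm2 = log(-log(pmin(pmax(s2, 1e-12), 1 - 1e-12))))
  names(clh)[2:3] <- arms
  haz <- data.frame(time = grid,
                    arm1 = kernel_hazard(kms[[1]], grid, bandwidth),
                    arm2 = kernel_hazard(kms[[2]], grid, bandwidth))
  names(haz)[2:3] <- arms
  t_min <- stats::quantile(ev_times, 0.1)
  sel <- grid >= t_min & is.finite(clh[[2]]) & is.finite(clh[[3]])
  dd <- (clh[[3]] - clh[[2]])[sel]
  crossing <- any(dd > band) && any(dd < -band)
  structure(list(log_cumhaz = clh, smoothed_hazard = haz,
                 crossing = crossing, band = band, bandwidth = bandwidth),
            class = "ph_diagnostics")
}

#' @export
print.ph_diagnostics <- function(x, ...) {
  cat("PH diagnostics: crossing of log-cumulative-hazard curves =",
      x$crossing, "(band", x$band, ")\n")
  invisible(x)
}
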