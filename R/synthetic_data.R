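## Synthetic two-arm oncology trials with a known time-varying hazard-ratio
## truth. The reference arm has a piecewise-constant hazard; the treatment
## arm multiplies it by exp(d0 + d1 * t^p), the first-order fractional-
## polynomial contrast. Event times are drawn by inverting the cumulative
## hazard; accrual is uniform and follow-up is administratively censored at
## the data cutoff.

#' Specify a synthetic two-arm trial
#'
#' @param trial_id label for the trial.
#' @param n_per_arm patients per arm (>= 2).
#' @param reference_hazard piecewise-constant reference hazard: a list with
#'   \code{breaks} (increasing, starting at 0) and \code{rates}
#'   (events/month, one per interval; the last extends to infinity).
#' @param contrast_truth named vector \code{c(d0=, d1=, p=)}: the true
#'   log-hazard-ratio is \code{d0 + d1 * t^p} (with \code{log t} at p = 0).
#' @param accrual_months uniform accrual window (months).
#' @param cutoff_months administrative data cutoff, measured from the start
#'   of accrual (> 0).
#' @param dropout_rate exponential dropout (censoring) rate per month (>= 0).
#' @param seed integer seed making the simulated trial reproducible.
#' @param eps floor time for evaluating \code{t^p} (months); for negative
#'   powers with \code{d1 > 0} the FP hazard ratio diverges at the origin,
#'   so the transform is frozen below \code{eps}.
#' @param fp_time_grid optional increasing interval boundaries (months):
#'   when supplied, the FP term is evaluated at the midpoint of the
#'   containing interval (the discrete-time convention of interval-hazard
#'   network meta-analysis), which keeps steep negative-power contrasts
#'   integrable and matches the interval likelihood exactly. \code{NULL}
#'   evaluates the FP term in continuous time.
#' @return an object of class \code{trial_spec}.
#' @export
trial_spec <- function(trial_id = "trial1",
                       n_per_arm = 200,
                       reference_hazard = list(breaks = 0, rates = 0.1),
                       contrast_truth = c(d0 = 0, d1 = 0, p = 0),
                       accrual_months = 6,
                       cutoff_months = 24,
                       dropout_rate = 0,
                       seed = 1L,
                       eps = 0.01,
                       fp_time_grid = NULL) {
  stopifnot(is.numeric(n_per_arm), n_per_arm >= 2)
  if (cutoff_months <= 0) stop("cutoff_months must be > 0", call. = FALSE)
  if (dropout_rate < 0) stop("dropout_rate must be >= 0", call. = FALSE)
  br <- reference_hazard$breaks
  ra <- reference_hazard$rates
  if (length(br) != length(ra) || br[1] != 0 || is.unsorted(br, strictly = TRUE))
    stop("reference_hazard needs breaks (starting at 0, increasing) and one rate per interval",
         call. = FALSE)
  if (any(ra <= 0)) stop("all hazard rates must be > 0", call. = FALSE)
  ct <- contrast_truth
  if (!all(c("d0", "d1", "p") %in% names(ct)))
    stop("contrast_truth must have named elements d0, d1, p", call. = FALSE)
  if (!is.null(fp_time_grid))
    stopifnot(fp_time_grid[1] == 0, !is.unsorted(fp_time_grid, strictly = TRUE))
  ## the hazard-ratio multiplier must not overflow anywhere it is
  ## evaluated (underflow toward HR = 0 is harmless); t^p is monotone so
  ## the extremes sit at the endpoints of the evaluation range
  t_eval <- if (is.null(fp_time_grid)) eps else
    min(fp_time_grid[-1] / 2 + fp_time_grid[-length(fp_time_grid)] / 2)
  fp_ends <- fp_power(c(t_eval, cutoff_months), ct[["p"]], eps)
  lhr_up <- max(ct[["d0"]] + ct[["d1"]] * fp_ends)
  if (!is.finite(lhr_up) || lhr_up > 700)
    stop("log hazard ratio overflows near t = 0; supply a coarser ",
         "fp_time_grid or a larger eps", call. = FALSE)
  structure(list(trial_id = trial_id, n_per_arm = as.integer(n_per_arm),
                 reference_hazard = list(breaks = br, rates = ra),
                 contrast_truth = ct[c("d0", "d1", "p")],
                 accrual_months = accrual_months,
                 cutoff_months = cutoff_months,
                 dropout_rate = dropout_rate,
                 seed = as.integer(seed),
                 eps = eps,
                 fp_time_grid = fp_time_grid),
            class = "trial_spec")
}

#' @export
print.trial_spec <- function(x, ...) {
  cat("Synthetic trial spec '", x$trial_id, "': ", x$n_per_arm, "/arm, ",
      "cutoff ", x$cutoff_months, " mo, truth d0=", x$contrast_truth["d0"],
      " d1=", x$contrast_truth["d1"], " p=", x$contrast_truth["p"], "\n",
      sep = "")
  invisible(x)
}

## Exact cumulative hazard of the piecewise-constant reference at times t.
piecewise_cumhaz <- function(t, breaks, rates) {
  edges <- c(breaks, Inf)
  out <- numeric(length(t))
  for (j in seq_along(rates)) {
    lo <- edges[j]; hi <- edges[j + 1]
    out <- out + rates[j] * pmax(0, pmin(t, hi) - lo)
  }
  out
}

## Reference hazard evaluated pointwise.
piecewise_hazard <- function(t, breaks, rates) {
  idx <- findInterval(t, breaks)
  idx[idx < 1] <- 1
  rates[pmin(idx, length(rates))]
}

## FP time evaluation under the spec's rule: continuous (floored at eps) or
## at the midpoint of the containing fp_time_grid interval.
fp_eval_time <- function(u, spec) {
  g <- spec$fp_time_grid
  if (is.null(g)) return(pmax(u, spec$eps))
  mids <- (g[-1] + g[-length(g)]) / 2
  idx <- pmin(pmax(findInterval(u, g), 1), length(mids))
  out <- mids[idx]
  ## beyond the last boundary the final interval's midpoint carries on
  out
}

## Treatment-arm cumulative hazard on a time grid (numerical; reference arm
## piecewise part is exact, the FP multiplier is integrated by quadrature).
arm_cumhaz_grid <- function(spec, grid, arm = c("reference", "treatment"),
                            n_nodes = 15) {
  arm <- match.arg(arm)
  br <- spec$reference_hazard$breaks
  ra <- spec$reference_hazard$rates
  if (arm == "reference") return(piecewise_cumhaz(grid, br, ra))
  d0 <- spec$contrast_truth["d0"]; d1 <- spec$contrast_truth["d1"]
  p <- spec$contrast_truth["p"]
  f <- function(u)
    piecewise_hazard(u, br, ra) *
      exp(d0 + d1 * fp_power(fp_eval_time(u, spec), p, spec$eps))
  ## refine the grid with every hazard / FP-evaluation breakpoint (and the
  ## eps-floor kink) so each quadrature panel is smooth, then read back the
  ## requested points
  cuts <- c(br, spec$fp_time_grid, spec$eps)
  refined <- sort(unique(c(grid, cuts[cuts > min(grid) & cuts < max(grid)])))
  ch <- cum_quadrature(f, refined, n_nodes)
  if (!all(is.finite(ch))) stop("non-finite cumulative hazard; check contrast_truth",
                                call. = FALSE)
  stats::approx(refined, ch, xout = grid)$y
}

#' Simulate a two-arm trial with a time-varying hazard ratio
#'
#' Event times are drawn by inverting the arm-specific cumulative hazard
#' (exact piecewise inversion for the reference arm, inversion of a
#' quadrature-tabulated cumulative hazard for the treatment arm). Observed
#' time is the minimum of the event time, exponential dropout and
#' administrative censoring at \code{cutoff_months} minus the uniform
#' accrual offset.
#'
#' @param spec a \code{\link{trial_spec}}.
#' @return a data.frame with columns \code{trial}, \code{arm}
#'   (\code{"reference"}/\code{"treatment"}), \code{time} (months) and
#'   \code{event} (1 = event, 0 = censored).
#' Piecewise-constant reference hazard following a fractional polynomial
#'
#' Convenience constructor: rates \code{exp(beta0 + beta1 * m_j^p)} at the
#' midpoints \code{m_j} of the supplied breaks, so a simulated trial's
#' baseline lies exactly in the first-order FP family evaluated on that
#' grid.
#'
#' @param beta0,beta1 log-hazard intercept and FP slope of the baseline.
#' @param p fractional-polynomial power.
#' @param breaks increasing interval boundaries starting at 0 (months).
#' @return list with \code{breaks} and \code{rates} for
#'   \code{\link{trial_spec}}.
#' @export
fp_reference_hazard <- function(beta0, beta1, p, breaks) {
  stopifnot(breaks[1] == 0, !is.unsorted(breaks, strictly = TRUE))
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  list(breaks = breaks[-length(breaks)],
       rates = exp(beta0 + beta1 * fp_power(mids, p)))
}

## Exact inversion of a piecewise-constant cumulative hazard: the last
## segment extends to infinity, so every exponential draw is solvable.
invert_piecewise <- function(e, breaks, rates) {
  nb <- length(breaks)
  cb <- c(0, cumsum(rates[-nb] * diff(breaks)))
  idx <- findInterval(e, cb)
  breaks[idx] + (e - cb[idx]) / rates[idx]
}

## Piecewise-constant hazard of the treatment arm when the FP term is
## evaluated on fp_time_grid (union of reference breaks and grid cells).
treatment_piecewise <- function(spec) {
  br <- spec$reference_hazard$breaks
  ra <- spec$reference_hazard$rates
  ct <- spec$contrast_truth
  ubr <- sort(unique(c(br, spec$fp_time_grid)))
  mult <- exp(ct[["d0"]] + ct[["d1"]] *
                fp_power(fp_eval_time(ubr, spec), ct[["p"]], spec$eps))
  list(breaks = ubr, rates = piecewise_hazard(ubr, br, ra) * mult)
}

#' @export
simulate_trial <- function(spec) {
  stopifnot(inherits(spec, "trial_spec"))
  with_seed(spec$seed, {
    n <- spec$n_per_arm
    tmax <- spec$cutoff_months
    br <- spec$reference_hazard$breaks
    ra <- spec$reference_hazard$rates
    sim_arm <- function(arm) {
      e <- stats::rexp(n)
      d1 <- spec$contrast_truth[["d1"]]
      if (arm == "reference") {
        ev_time <- invert_piecewise(e, br, ra)
      } else if (d1 == 0) {
        ## proportional contrast: still piecewise-constant, invert exactly
        ev_time <- invert_piecewise(e, br,
                                    ra * exp(spec$contrast_truth[["d0"]]))
      } else if (!is.null(spec$fp_time_grid)) {
        ## hazard is exactly piecewise-constant: invert in closed form
        pw <- treatment_piecewise(spec)
        ev_time <- invert_piecewise(e, pw$breaks, pw$rates)
      } else {
        ## continuous FP multiplier: invert a finely tabulated cumhaz
        grid <- seq(0, tmax,
                    length.out = min(200000L,
                                     max(5000L, 200L * ceiling(tmax))))
        ch <- arm_cumhaz_grid(spec, grid, arm)
        ev_time <- ifelse(e >= ch[length(ch)], Inf,
                          stats::approx(ch, grid, xout = e,
                                        ties = "ordered")$y)
      }
      entry <- stats::runif(n, 0, min(spec$accrual_months, tmax))
      admin <- tmax - entry
      drop <- if (spec$dropout_rate > 0) stats::rexp(n, spec$dropout_rate) else Inf
      obs <- pmin(ev_time, drop, admin)
      data.frame(trial = spec$trial_id, arm = arm,
                 time = pmax(obs, 1e-9),
                 event = as.integer(ev_time <= pmin(drop, admin)),
                 stringsAsFactors = FALSE)
    }
    rbind(sim_arm("reference"), sim_arm("treatment"))
  })
}

#' True survival and hazard-ratio curves for a synthetic trial
#'
#' @param spec a \code{\link{trial_spec}}.
#' @param grid increasing time grid starting at 0 (months).
#' @return a list of class \code{truth_bundle}: the spec, per-arm true
#'   survival on the grid, and the true hazard ratio at each grid point.
#' @export
truth_bundle <- function(spec, grid) {
  stopifnot(inherits(spec, "trial_spec"), grid[1] >= 0, !is.unsorted(grid))
  ct <- spec$contrast_truth
  s_ref <- exp(-arm_cumhaz_grid(spec, grid, "reference"))
  s_trt <- exp(-arm_cumhaz_grid(spec, grid, "treatment"))
  hr <- exp(ct["d0"] + ct["d1"] * fp_power(fp_eval_time(grid, spec), ct["p"],
                                           spec$eps))
  structure(list(spec = spec,
                 grid = grid,
                 survival = data.frame(time = grid, reference = s_ref,
                                       treatment = s_trt),
                 hr = unname(hr)),
            class = "truth_bundle")
}

#' Digitisation-style Kaplan-Meier artifacts from individual patient data
#'
#' Produces what a curve digitiser would yield from a published KM plot:
#' the KM estimate read off at a grid of times (optionally rounded to three
#' decimals) plus a numbers-at-risk table at those times.
#'
#' @param ipd single-arm IPD data.frame with \code{time} and \code{event}.
#' @param grid increasing times starting at 0 (months) at which the curve
#'   is read; defaults to every KM step location (a digitiser reads every
#'   visible step).
#' @param risk_grid times of the numbers-at-risk table; defaults to
#'   \code{grid} thinned to about 12 rows (published risk tables are
#'   sparse).
#' @param coarsen round survival to 3 decimals to mimic digitisation.
#' @return list with \code{curve} (data.frame time, survival) and
#'   \code{risk} (data.frame time, n_at_risk).
#' @export
make_km_artifacts <- function(ipd, grid = NULL, risk_grid = NULL,
                              coarsen = TRUE) {
  if (nrow(ipd) == 0) stop("empty IPD", call. = FALSE)
  if (length(unique(ipd$arm %||% "a")) > 1)
    stop("make_km_artifacts takes a single arm; split the IPD first", call. = FALSE)
  if (is.null(grid))
    grid <- c(0, sort(unique(ipd$time[ipd$event == 1])))
  stopifnot(grid[1] >= 0, !is.unsorted(grid, strictly = TRUE))
  if (is.null(risk_grid))
    risk_grid <- seq(0, max(grid), length.out = 12)
  km <- km_estimate(ipd)
  s <- km_survival_at(km, grid)
  if (coarsen) s <- round(s, 3)
  nar <- vapply(risk_grid, function(g) sum(ipd$time >= g), integer(1))
  list(curve = data.frame(time = grid, survival = s),
       risk = data.frame(time = risk_grid, n_at_risk = nar))
}

#' Write simulated IPD, curves and risk tables as CSV
#'
#' @param ipd IPD data.frame.
#' @param artifacts output of \code{\link{make_km_artifacts}} (optional).
#' @param dir output directory (created if absent).
#' @param prefix file-name prefix.
#' @return invisibly, the paths written.
#' @export
write_trial_csv <- function(ipd, artifacts = NULL, dir = ".", prefix = "trial") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, "_ipd.csv"))
  utils::write.csv(ipd[, c("trial", "arm", "time", "event")],
                   paths, row.names = FALSE)
  if (!is.null(artifacts)) {
    p2 <- file.path(dir, paste0(prefix, "_curve.csv"))
    p3 <- file.path(dir, paste0(prefix, "_risk.csv"))
    utils::write.csv(artifacts$curve, p2, row.names = FALSE)
    utils::write.csv(artifacts$risk, p3, row.names = FALSE)
    paths <- c(paths, p2, p3)
  }
  invisible(paths)
}
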