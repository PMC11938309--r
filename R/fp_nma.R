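## First-order fractional-polynomial network meta-analysis of time-varying
## log hazards over a star network with a common chemotherapy reference.
## Each trial contributes interval event counts; the interval hazard is
## modelled through a binomial likelihood with cloglog link and a
## log-interval-length offset, with trial-specific reference-arm curves
## (beta0, beta1) and fixed treatment contrasts (d0, d1) shared across
## trials. Comparator survival is projected by applying the time-varying
## hazard ratio exp(d0 + d1 t^p) to the extrapolated reference hazard.

#' Interval event counts from individual patient data
#'
#' @param ipd data.frame with \code{trial}, \code{arm}, \code{time},
#'   \code{event}.
#' @param breaks increasing interval boundaries starting at 0 (months);
#'   consecutive pairs define the intervals.
#' @return data.frame of interval counts: \code{trial}, \code{arm},
#'   \code{a}, \code{b}, \code{n_at_risk} (entering), \code{events},
#'   \code{censored}.
#' @export
interval_counts_from_ipd <- function(ipd, breaks) {
  stopifnot(breaks[1] == 0, !is.unsorted(breaks, strictly = TRUE),
            length(breaks) >= 2)
  groups <- unique(ipd[, c("trial", "arm")])
  out <- lapply(seq_len(nrow(groups)), function(g) {
    sub <- ipd[ipd$trial == groups$trial[g] & ipd$arm == groups$arm[g], ]
    a <- breaks[-length(breaks)]; b <- breaks[-1]
    data.frame(trial = groups$trial[g], arm = groups$arm[g], a = a, b = b,
               n_at_risk = vapply(a, function(x) sum(sub$time >= x), numeric(1)),
               events = vapply(seq_along(a), function(j)
                 sum(sub$time >= a[j] & sub$time < b[j] & sub$event == 1),
                 numeric(1)),
               censored = vapply(seq_along(a), function(j)
                 sum(sub$time >= a[j] & sub$time < b[j] & sub$event == 0),
                 numeric(1)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Expected interval counts from a survival curve
#'
#' Converts a (possibly extrapolated) survival function into the expected
#' at-risk, event and censoring counts a trial of size \code{n0} would
#' produce, with administrative censoring from uniform accrual to a data
#' cutoff. Counts are left fractional; rounding is the caller's choice.
#'
#' @param surv a \code{surv_fit}, or a function of time returning survival.
#' @param n0 initial cohort size.
#' @param breaks increasing interval boundaries starting at 0.
#' @param cutoff administrative censoring time (months); \code{Inf} for none.
#' @param accrual uniform accrual window (months; 0 = simultaneous entry).
#' @param trial,arm labels stamped on the rows.
#' @return data.frame with the same columns as
#'   \code{\link{interval_counts_from_ipd}}.
#' @export
interval_counts_from_survival <- function(surv, n0, breaks, cutoff = Inf,
                                          accrual = 0, trial = "trial",
                                          arm = "arm") {
  stopifnot(n0 >= 1, breaks[1] == 0, !is.unsorted(breaks, strictly = TRUE))
  sfun <- if (inherits(surv, "surv_fit"))
    function(t) predict(surv, t)$survival else surv
  s <- sfun(breaks)
  if (abs(s[1] - 1) > 1e-8) stop("S(0) must be 1", call. = FALSE)
  if (any(diff(s) > 1e-9)) stop("survival must be non-increasing", call. = FALSE)
  cens_surv <- function(t) {
    if (!is.finite(cutoff)) return(rep(1, length(t)))
    if (accrual <= 0) return(as.numeric(t < cutoff))
    pmin(1, pmax(0, (cutoff - t) / accrual))
  }
  cs <- cens_surv(breaks)
  a <- breaks[-length(breaks)]; b <- breaks[-1]
  sa <- s[-length(s)]; sb <- s[-1]
  na <- n0 * sa * cs[-length(cs)]
  nb <- n0 * sb * cs[-1]
  r <- ifelse(sa > 0, na * (sa - sb) / sa, 0)
  cen <- pmax(0, na - r - nb)
  data.frame(trial = trial, arm = arm, a = a, b = b,
             n_at_risk = na, events = r, censored = cen,
             stringsAsFactors = FALSE)
}

## FP design columns for interval midpoints.
fp_columns <- function(t_mid, p, order, eps = 0.01) {
  x1 <- fp_power(t_mid, p, eps)
  if (order == 1) return(cbind(x1 = x1))
  ## repeated-power second-order convention: (t^p, t^p log t)
  x2 <- if (p == 0) x1^2 else x1 * log(pmax(t_mid, eps))
  cbind(x1 = x1, x2 = x2)
}

#' Fit a fractional-polynomial network meta-analysis model
#'
#' Fixed-effect FP model of order 1 (or 2 by the repeated-power
#' convention): within each interval the number of events is binomial in
#' the number at risk with cloglog link and log interval-length offset;
#' the linear predictor combines trial-specific reference-arm coefficients
#' with treatment contrasts shared across trials. \code{p = 0} uses the
#' \code{log(t)} convention. Intervals with zero at-risk are dropped.
#'
#' @param data interval counts across trials (see
#'   \code{\link{interval_counts_from_ipd}}); fractional expected counts
#'   are accepted.
#' @param p fractional-polynomial power.
#' @param endpoint label (\code{"PFS"} or \code{"OS"}) carried in the output.
#' @param reference arm label of the common reference treatment.
#' @param order 1 or 2.
#' @param fix_d1 constrain the time-varying contrast coefficients to zero,
#'   reducing the model to proportional hazards (constant log HR
#'   \code{d0}); the trial baselines keep their FP shape.
#' @return list of class \code{fp_model_fit}: \code{contrasts} (data.frame
#'   of d0/d1 with 95\% Wald CIs per treatment), per-trial reference
#'   coefficients, \code{loglik}, \code{aic}, \code{bic},
#'   \code{i_squared}, and the interval data used.
#' @export
fit_fp1 <- function(data, p, endpoint = "PFS", reference = "chemotherapy",
                    order = 1, fix_d1 = FALSE) {
  stopifnot(order %in% c(1, 2))
  data <- data[data$n_at_risk > 0, , drop = FALSE]
  if (!reference %in% data$arm)
    stop("reference arm '", reference, "' not present", call. = FALSE)
  for (tr in unique(data$trial)) {
    arms <- unique(data$arm[data$trial == tr])
    if (!reference %in% arms)
      stop("trial '", tr, "' lacks the reference arm (star network required)",
           call. = FALSE)
  }
  treats <- setdiff(sort(unique(data$arm)), reference)
  for (k in c(reference, treats)) {
    if (sum(data$events[data$arm == k]) <= 0)
      stop("arm '", k, "' has no events in any interval", call. = FALSE)
  }
  ## actuarial at-risk adjustment: subjects censored inside an interval
  ## contribute half an interval of risk (life-table convention)
  cen <- if ("censored" %in% names(data)) data$censored else 0
  n_eff <- pmax(data$n_at_risk - cen / 2, data$events)
  t_mid <- (data$a + data$b) / 2
  X_fp <- fp_columns(t_mid, p, order)
  trials <- sort(unique(data$trial))
  Xt <- sapply(trials, function(tr) as.numeric(data$trial == tr))
  cols <- list()
  for (j in seq_along(trials)) cols[[paste0("b0[", trials[j], "]")]] <- Xt[, j]
  for (m in seq_len(ncol(X_fp)))
    for (j in seq_along(trials))
      cols[[paste0("b", m, "[", trials[j], "]")]] <- Xt[, j] * X_fp[, m]
  Zk <- sapply(treats, function(k) as.numeric(data$arm == k))
  Zk <- matrix(Zk, nrow = nrow(data))
  for (j in seq_along(treats)) cols[[paste0("d0[", treats[j], "]")]] <- Zk[, j]
  if (!fix_d1)
    for (m in seq_len(ncol(X_fp)))
      for (j in seq_along(treats))
        cols[[paste0("d", m, "[", treats[j], "]")]] <- Zk[, j] * X_fp[, m]
  X <- do.call(cbind, cols)
  y <- data$events / n_eff
  y <- pmin(pmax(y, 0), 1)
  w <- n_eff
  off <- log(data$b - data$a)
  ## warm start from the Poisson log-hazard approximation (same design;
  ## cloglog ~ log for small interval probabilities), then the exact
  ## binomial cloglog fit
  h0 <- sum(data$events) / sum(w * (data$b - data$a))
  start0 <- c(rep(log(h0), length(trials)), rep(0, ncol(X) - length(trials)))
  pois <- suppressWarnings(stats::glm.fit(
    x = X, y = data$events, offset = off + log(w),
    family = stats::poisson(), start = start0,
    control = list(maxit = 100, epsilon = 1e-9)))
  start <- if (pois$converged && !anyNA(pois$coefficients))
    pois$coefficients else start0
  fit <- suppressWarnings(stats::glm.fit(
    x = X, y = y, weights = w, offset = off,
    family = stats::binomial(link = "cloglog"), start = start,
    control = list(maxit = 200, epsilon = 1e-10)))
  if (!fit$converged)
    warning("FP model IRLS did not fully converge (p = ", p, ")")
  beta <- fit$coefficients
  if (anyNA(beta))
    stop("FP design is rank deficient (degenerate intervals?)", call. = FALSE)
  ## observed-information covariance at dispersion 1 (fixed-effect model)
  Winfo <- fit$weights          # IRLS weights = working weights
  XtWX <- crossprod(X * sqrt(Winfo))
  V <- tryCatch(solve(XtWX), error = function(e)
    stop("singular information matrix", call. = FALSE))
  se <- sqrt(pmax(diag(V), 0))
  mu <- fit$fitted.values
  mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  loglik <- sum(w * (y * log(mu) + (1 - y) * log(1 - mu)))
  npar <- length(beta)
  nobs <- nrow(data)
  pearson_q <- sum(w * (y - mu)^2 / (mu * (1 - mu)))
  df_resid <- nobs - npar
  i2 <- if (df_resid > 0 && pearson_q > df_resid)
    100 * (pearson_q - df_resid) / pearson_q else 0
  z <- stats::qnorm(0.975)
  contrast_rows <- lapply(treats, function(k) {
    i0 <- paste0("d0[", k, "]")
    out <- data.frame(treatment = k, endpoint = endpoint, p = p,
                      d0 = beta[[i0]],
                      d0_low = beta[[i0]] - z * se[which(names(beta) == i0)],
                      d0_high = beta[[i0]] + z * se[which(names(beta) == i0)],
                      stringsAsFactors = FALSE)
    for (m in seq_len(ncol(X_fp))) {
      im <- paste0("d", m, "[", k, "]")
      if (fix_d1) {
        out[[paste0("d", m)]] <- 0
        out[[paste0("d", m, "_low")]] <- NA_real_
        out[[paste0("d", m, "_high")]] <- NA_real_
      } else {
        out[[paste0("d", m)]] <- beta[[im]]
        out[[paste0("d", m, "_low")]] <- beta[[im]] - z * se[which(names(beta) == im)]
        out[[paste0("d", m, "_high")]] <- beta[[im]] + z * se[which(names(beta) == im)]
      }
    }
    out
  })
  contrasts <- if (length(contrast_rows)) do.call(rbind, contrast_rows)
               else data.frame()
  rownames(contrasts) <- NULL
  structure(list(endpoint = endpoint, p = p, order = order,
                 reference = reference,
                 coefficients = beta, vcov = V,
                 contrasts = contrasts,
                 loglik = loglik,
                 aic = 2 * npar - 2 * loglik,
                 bic = npar * log(nobs) - 2 * loglik,
                 n_params = npar, n_intervals = nobs,
                 pearson_q = pearson_q, df_resid = df_resid,
                 i_squared = i2,
                 converged = fit$converged,
                 data = data),
            class = "fp_model_fit")
}

#' @export
print.fp_model_fit <- function(x, ...) {
  cat(sprintf("FP order-%d NMA (%s, p = %g): loglik %.2f, AIC %.2f, I^2 %.1f%%\n",
              x$order, x$endpoint, x$p, x$loglik, x$aic, x$i_squared))
  print(x$contrasts, row.names = FALSE)
  invisible(x)
}

#' Scan fractional-polynomial powers and orders
#'
#' Fits one FP model per grid cell and ranks the converged cells by AIC.
#' Individual non-convergent cells are recorded, not fatal. The top-ranked
#' model is returned as the selection; callers may override it (e.g. when
#' low-AIC cells show implausible long-term tails).
#'
#' @param data interval counts across trials.
#' @param endpoint label carried through.
#' @param p_grid powers to scan.
#' @param orders FP orders to scan (1 and/or 2).
#' @param reference reference arm label.
#' @return list with \code{ranking} (data.frame p, order, loglik, aic,
#'   bic, converged), \code{selected} (an \code{fp_model_fit}) and
#'   \code{fits}.
#' @export
scan_powers <- function(data, endpoint = "PFS",
                        p_grid = c(-2, -1, -0.5, 0, 0.5, 1, 2, 3),
                        orders = c(1, 2), reference = "chemotherapy") {
  stopifnot(length(p_grid) >= 1)
  cells <- expand.grid(p = p_grid, order = orders)
  fits <- vector("list", nrow(cells))
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    f <- tryCatch(fit_fp1(data, p = cells$p[i], endpoint = endpoint,
                          reference = reference, order = cells$order[i]),
                  error = function(e) e)
    if (inherits(f, "error"))
      return(data.frame(p = cells$p[i], order = cells$order[i],
                        loglik = NA, aic = NA, bic = NA, converged = FALSE,
                        note = conditionMessage(f)))
    fits[[i]] <<- f
    data.frame(p = cells$p[i], order = cells$order[i], loglik = f$loglik,
               aic = f$aic, bic = f$bic, converged = f$converged, note = "")
  })
  ranking <- do.call(rbind, rows)
  ok <- which(!is.na(ranking$aic) & ranking$converged)
  if (length(ok) == 0) stop("no FP grid cell converged", call. = FALSE)
  ord <- ok[order(ranking$aic[ok])]
  ranking <- ranking[c(ord, setdiff(seq_len(nrow(ranking)), ord)), ]
  list(ranking = ranking, selected = fits[[ord[1]]],
       fits = fits[!vapply(fits, is.null, logical(1))])
}

#' Time-varying hazard ratio of a fractional-polynomial contrast
#'
#' @param contrast one row of an \code{fp_model_fit} contrast table, or any
#'   list with \code{d0}, \code{d1}, \code{p}.
#' @param times strictly positive times (months).
#' @return \code{exp(d0 + d1 t^p)} (with \code{log t} at \code{p = 0}).
#' @export
hr_curve <- function(contrast, times) {
  if (any(times <= 0)) stop("times must be > 0", call. = FALSE)
  p <- contrast$p %||% contrast[["p"]]
  x <- if (p == 0) log(times) else times^p
  exp(contrast$d0 + contrast$d1 * x)
}

#' Project comparator survival from a reference fit and an FP contrast
#'
#' Computes \eqn{S_k(t) = \exp(-\int_0^t h_{ref}(u) e^{d_0 + d_1 u^p} du)}
#' by composite Gauss-Legendre quadrature on the grid. Because the FP
#' contrast is estimated from interval data, the hazard ratio is frozen at
#' its value at \code{t_floor} for earlier times (negative powers diverge
#' at the origin).
#'
#' @param reference_fit a \code{surv_fit} for the reference arm.
#' @param contrast list/row with \code{d0}, \code{d1}, \code{p}.
#' @param grid increasing time grid starting at 0 (months).
#' @param t_floor time below which the hazard ratio is held constant
#'   (months).
#' @return data.frame with \code{time} and \code{survival}.
#' @export
apply_contrast <- function(reference_fit, contrast, grid, t_floor = 1) {
  stopifnot(grid[1] == 0, !is.unsorted(grid, strictly = TRUE))
  p <- contrast$p
  d0 <- contrast$d0; d1 <- contrast$d1
  lp_max <- max(abs(d0) + abs(d1) * abs(fp_power(c(t_floor, max(grid)), p,
                                                 t_floor)))
  if (lp_max > 500)
    stop("divergent hazard-ratio integrand (|d0 + d1 t^p| too large)",
         call. = FALSE)
  integrand <- function(u) {
    h <- predict(reference_fit, u)$hazard
    h * exp(d0 + d1 * fp_power(u, p, eps = t_floor))
  }
  ch <- cum_quadrature(integrand, grid)
  if (!all(is.finite(ch)))
    stop("divergent cumulative hazard in apply_contrast", call. = FALSE)
  data.frame(time = grid, survival = exp(-ch))
}

#' Between-study heterogeneity of an FP model
#'
#' Cochran-Q-based I-squared computed on the interval-level Pearson
#' statistic versus its residual degrees of freedom (the GLM
#' overdispersion form).
#'
#' @param fit an \code{fp_model_fit}.
#' @return I-squared as a percentage in [0, 100].
#' @export
heterogeneity <- function(fit) {
  stopifnot(inherits(fit, "fp_model_fit"))
  if (fit$df_resid <= 0) stop("no residual degrees of freedom", call. = FALSE)
  fit$i_squared
}

#' Read/write FP contrast tables as CSV
#'
#' Column layout: treatment, endpoint, p, d0, d0_low, d0_high, d1, d1_low,
#' d1_high.
#'
#' @param contrasts contrast data.frame.
#' @param path CSV path.
#' @return the table (invisibly on write).
#' @export
write_contrasts_csv <- function(contrasts, path) {
  utils::write.csv(contrasts, path, row.names = FALSE)
  invisible(contrasts)
}

#' @rdname write_contrasts_csv
#' @export
read_contrasts_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
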