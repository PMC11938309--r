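## Reference-arm survival modelling: the seven standard parametric families
## recommended for technology appraisal, Royston-Parmar restricted-cubic-
## spline models on the log-cumulative-hazard, log-cumulative-odds and
## probit scales, and a restricted-cubic-spline log-hazard model, with
## AIC/BIC selection and survival/hazard prediction out to the model
## horizon.

.parametric_dists <- c(exponential = "exp", gamma = "gamma",
                       gompertz = "gompertz", weibull = "weibull",
                       loglogistic = "llogis", lognormal = "lnorm",
                       generalized_gamma = "gengamma")

new_surv_fit <- function(model_kind, detail, coefficients, knot_locations,
                         loglik, n_params, n, n_events, predictor) {
  structure(list(model_kind = model_kind, detail = detail,
                 coefficients = coefficients,
                 knot_locations = knot_locations,
                 loglik = loglik,
                 aic = 2 * n_params - 2 * loglik,
                 bic = n_params * log(n) - 2 * loglik,
                 n_params = n_params, n = n, n_events = n_events,
                 predictor = predictor),
            class = "surv_fit")
}

#' @export
print.surv_fit <- function(x, ...) {
  cat(sprintf("Survival fit [%s%s]: loglik %.3f, AIC %.2f, BIC %.2f (%d params, n = %d)\n",
              x$model_kind,
              if (nzchar(x$detail)) paste0(": ", x$detail) else "",
              x$loglik, x$aic, x$bic, x$n_params, x$n))
  invisible(x)
}

check_fit_inputs <- function(ipd, min_events = 3) {
  stopifnot(all(c("time", "event") %in% names(ipd)))
  if (sum(ipd$event) < min_events)
    stop("need at least ", min_events, " events", call. = FALSE)
  invisible(ipd)
}

#' Fit a standard parametric survival model
#'
#' Maximum-likelihood fit of one of the seven families recommended for
#' survival extrapolation in technology appraisal: exponential, gamma,
#' Gompertz, Weibull, log-logistic, log-normal and generalized gamma
#' (stable (mu, sigma, Q) parameterisation).
#'
#' @param ipd data.frame with \code{time} and \code{event}.
#' @param family one of \code{"exponential"}, \code{"gamma"},
#'   \code{"gompertz"}, \code{"weibull"}, \code{"loglogistic"},
#'   \code{"lognormal"}, \code{"generalized_gamma"}.
#' @return a \code{surv_fit} object with coefficients, log-likelihood,
#'   AIC/BIC (BIC on the number of subjects) and a survival/hazard
#'   predictor; query it with \code{\link{predict.surv_fit}}.
#' @export
fit_parametric <- function(ipd, family = names(.parametric_dists)) {
  family <- match.arg(family)
  check_fit_inputs(ipd)
  dist <- .parametric_dists[[family]]
  fit <- flexsurv::flexsurvreg(survival::Surv(time, event) ~ 1, data = ipd,
                               dist = dist)
  coefs <- stats::setNames(fit$res[, "est"], rownames(fit$res))
  predictor <- local({
    fns <- fit$dfns
    pars <- as.list(coefs)
    list(survival = function(t) do.call(fns$p, c(list(q = t), pars,
                                                 lower.tail = FALSE)),
         hazard = function(t) do.call(fns$h, c(list(x = t), pars)))
  })
  new_surv_fit(model_kind = "parametric", detail = family,
               coefficients = coefs,
               knot_locations = numeric(0),
               loglik = fit$loglik, n_params = fit$npars,
               n = nrow(ipd), n_events = sum(ipd$event),
               predictor = predictor)
}

#' Fit a Royston-Parmar flexible parametric survival model
#'
#' A restricted cubic spline in log time is placed on a transformed
#' survival scale: log cumulative hazard (\code{scale = "hazard"}), log
#' cumulative odds (\code{"odds"}) or \code{-qnorm(S)} (\code{"normal"}).
#' Boundary knots sit at the extreme uncensored log event times and
#' internal knots at equally spaced centiles of uncensored log event times.
#'
#' @param ipd data.frame with \code{time} and \code{event}.
#' @param scale transformation scale.
#' @param internal_knots number of internal knots (1, 2 or 3).
#' @return a \code{surv_fit}.
#' @export
fit_royston_parmar <- function(ipd, scale = c("hazard", "odds", "normal"),
                               internal_knots = 1) {
  scale <- match.arg(scale)
  stopifnot(internal_knots %in% 1:3)
  check_fit_inputs(ipd, min_events = internal_knots + 2)
  if (length(unique(ipd$time[ipd$event == 1])) < internal_knots + 2)
    stop("need at least ", internal_knots + 2, " distinct event times",
         call. = FALSE)
  fit <- flexsurv::flexsurvspline(survival::Surv(time, event) ~ 1, data = ipd,
                                  k = internal_knots, scale = scale)
  predictor <- local({
    gamma <- unname(fit$res[, "est"])
    knots <- fit$knots
    sc <- scale
    list(survival = function(t)
           flexsurv::psurvspline(t, gamma = gamma, knots = knots,
                                 scale = sc, lower.tail = FALSE),
         hazard = function(t)
           flexsurv::hsurvspline(t, gamma = gamma, knots = knots,
                                 scale = sc))
  })
  new_surv_fit(model_kind = "rp_spline",
               detail = sprintf("%s scale, %d internal knots", scale,
                                internal_knots),
               coefficients = fit$res[, "est"],
               knot_locations = fit$knots,
               loglik = fit$loglik, n_params = fit$npars,
               n = nrow(ipd), n_events = sum(ipd$event),
               predictor = predictor)
}

## g transforms between survival and the Royston-Parmar linear predictor.
g_from_survival <- function(s, scale) {
  switch(scale,
         hazard = log(-log(s)),
         odds = log((1 - s) / s),
         normal = -stats::qnorm(s))
}

survival_from_g <- function(g, scale) {
  switch(scale,
         hazard = exp(-exp(g)),
         odds = 1 / (1 + exp(g)),
         normal = stats::pnorm(-g))
}

#' Fit a restricted-cubic-spline log-hazard model
#'
#' The log hazard is a restricted cubic spline in time with knots at
#' centiles of the uncensored event times (boundary knots included in the
#' count). The cumulative hazard is computed by Gauss-Legendre quadrature;
#' parameters are estimated by maximum likelihood (BFGS with random
#' restarts).
#'
#' @param ipd data.frame with \code{time} and \code{event}.
#' @param knots total number of knots (3, 4 or 5).
#' @param n_restarts random restarts beyond the null start.
#' @param restart_seed seed controlling the restart draws.
#' @return a \code{surv_fit}.
#' @export
fit_rcs_hazard <- function(ipd, knots = 3, n_restarts = 5, restart_seed = 101) {
  stopifnot(knots %in% 3:5)
  check_fit_inputs(ipd, min_events = knots)
  ev <- sort(ipd$time[ipd$event == 1])
  kq <- stats::quantile(ev, probs = seq(0, 1, length.out = knots),
                        names = FALSE, type = 7)
  kq <- unique(kq)
  if (length(kq) < 3) stop("degenerate knot locations", call. = FALSE)
  nb <- length(kq) - 1   # basis columns (plus intercept)
  times <- ipd$time; events <- ipd$event
  basis_ev <- cbind(1, rcs_basis(times, kq))
  loghaz_fun <- function(beta) function(t) {
    exp(pmin(cbind(1, rcs_basis(t, kq)) %*% beta, 50))
  }
  negll <- function(beta) {
    h <- loghaz_fun(beta)
    ## cumulative hazard at each subject time via shared quadrature grid
    tg <- sort(unique(c(0, times)))
    ch <- cum_quadrature(function(u) as.vector(h(u)), tg)
    chi <- ch[match(times, tg)]
    ll <- sum(events * (basis_ev %*% beta)) - sum(chi)
    if (!is.finite(ll)) 1e10 else -ll
  }
  start0 <- c(log(sum(events) / sum(times)), rep(0, nb))
  starts <- list(start0)
  with_seed(restart_seed, {
    for (r in seq_len(n_restarts))
      starts[[r + 1]] <- start0 + stats::rnorm(nb + 1, 0, 0.3)
  })
  best <- NULL
  for (s in starts) {
    opt <- try(stats::optim(s, negll, method = "BFGS",
                            control = list(maxit = 500, reltol = 1e-10)),
               silent = TRUE)
    if (inherits(opt, "try-error")) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("RCS hazard fit failed to converge", call. = FALSE)
  beta <- best$par
  names(beta) <- c("(Intercept)", colnames(rcs_basis(times, kq)))
  predictor <- local({
    h <- loghaz_fun(beta)
    surv <- function(t) {
      tg <- sort(unique(c(0, t)))
      ch <- cum_quadrature(function(u) as.vector(h(u)), tg)
      exp(-ch[match(t, tg)])
    }
    list(survival = surv, hazard = function(t) as.vector(h(t)))
  })
  new_surv_fit(model_kind = "rcs_hazard",
               detail = sprintf("%d knots", length(kq)),
               coefficients = beta, knot_locations = kq,
               loglik = -best$value, n_params = nb + 1,
               n = nrow(ipd), n_events = sum(ipd$event),
               predictor = predictor)
}

#' Select a survival model by information criteria
#'
#' Minimum AIC wins; ties are broken by minimum BIC, then by fewest
#' parameters. The full ranking is returned alongside the winner.
#'
#' @param fits non-empty list of \code{surv_fit} objects.
#' @return list with \code{selected} (a \code{surv_fit}) and \code{ranking}
#'   (data.frame: model, detail, n_params, loglik, aic, bic).
#' @export
select_model <- function(fits) {
  stopifnot(length(fits) >= 1)
  tab <- do.call(rbind, lapply(fits, function(f)
    data.frame(model = f$model_kind, detail = f$detail,
               n_params = f$n_params, loglik = f$loglik,
               aic = f$aic, bic = f$bic, stringsAsFactors = FALSE)))
  ord <- order(tab$aic, tab$bic, tab$n_params)
  list(selected = fits[[ord[1]]], ranking = tab[ord, , drop = FALSE])
}

#' Predict survival and hazard from a fitted model
#'
#' @param object a \code{surv_fit}.
#' @param times non-negative times (months).
#' @param ... unused.
#' @return data.frame with \code{time}, \code{survival}, \code{hazard};
#'   survival is 1 at time 0 and clamped monotone non-increasing.
#' @export
predict.surv_fit <- function(object, times, ...) {
  stopifnot(all(times >= 0))
  s <- object$predictor$survival(times)
  h <- object$predictor$hazard(times)
  s[times == 0] <- 1
  s <- pmin(pmax(s, 0), 1)
  ## numerical guard: enforce monotonicity on the returned grid
  if (!is.unsorted(times)) s <- cummin(s)
  data.frame(time = times, survival = s, hazard = pmax(h, 0))
}

#' Serialise a fit as JSON
#'
#' @param fit a \code{surv_fit}.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_fit_json <- function(fit, path) {
  x <- fit[c("model_kind", "detail", "coefficients", "knot_locations",
             "loglik", "aic", "bic", "n_params", "n", "n_events")]
  x$coefficients <- as.list(x$coefficients)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
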