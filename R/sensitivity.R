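## Deterministic (one-way, tornado) and probabilistic sensitivity analysis
## for the partitioned-survival cost-effectiveness model: gamma for costs
## and body weight, beta on the appropriate support for utilities, body
## surface area and the discount rate, normal for the FP contrast
## coefficients, and Dirichlet for the post-progression treatment mix.

#' One-way (deterministic) sensitivity specification
#'
#' Builds the parameter list for the tornado analysis. Defaults follow the
#' base-case conventions: every selected parameter varied +/-20\% around
#' baseline, except drug prices whose upper limit is the baseline itself
#' (prices can only be negotiated down) with the lower limit at 80\% of
#' baseline.
#'
#' @param params an \code{econ_params}.
#' @param paths parameter paths to vary; defaults to utilities, per-cycle
#'   costs, AE costs, drug prices, weight, BSA.
#' @return data.frame of class \code{dsa_spec}: \code{path}, \code{low},
#'   \code{high}.
#' @export
dsa_spec <- function(params, paths = NULL) {
  if (is.null(paths)) {
    paths <- c("utilities.pfs", "utilities.pd",
               paste0("per_cycle_costs.", names(params$per_cycle_costs)),
               paste0("ae_costs.", names(params$ae_costs)),
               paste0("unit_costs.", names(params$unit_costs), ".price"),
               "body_weight", "bsa")
  }
  rows <- lapply(paths, function(pp) {
    base <- param_get(params, pp)
    is_price <- grepl("^unit_costs\\.", pp)
    lo <- if (is_price) 0.8 * base else base * 0.8
    hi <- if (is_price) base else base * 1.2
    data.frame(path = pp, baseline = base, low = min(lo, hi),
               high = max(lo, hi), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  stopifnot(all(out$low <= out$high))
  class(out) <- c("dsa_spec", "data.frame")
  out
}

model_icer <- function(model_fn, params, strategy, reference, contrasts = NULL) {
  totals <- if (is.null(contrasts)) model_fn(params)
            else model_fn(params, contrasts)
  tab <- icer_table(totals, reference, params)
  row <- tab[tab$strategy == strategy, ]
  list(icer = row$icer, dominated = isTRUE(row$dominated_or_equal))
}

#' One-way sensitivity analysis (tornado table)
#'
#' Perturbs each parameter alone to its low and high value, re-runs the
#' model and records the ICER of \code{strategy} versus \code{reference}.
#' A perturbation that makes the incremental QALY non-positive is recorded
#' as dominated, not an error.
#'
#' @param model_fn function of \code{params} returning per-strategy totals
#'   (see \code{\link{ce_model}}).
#' @param params baseline \code{econ_params}.
#' @param spec a \code{\link{dsa_spec}}.
#' @param strategy focal strategy.
#' @param reference comparator strategy.
#' @return data.frame sorted by descending span: \code{path},
#'   \code{icer_low}, \code{icer_high}, \code{span},
#'   \code{dominated_low/high}, plus the baseline ICER as an attribute.
#' @export
one_way <- function(model_fn, params, spec, strategy, reference) {
  base <- model_icer(model_fn, params, strategy, reference)
  rows <- lapply(seq_len(nrow(spec)), function(i) {
    lo <- model_icer(model_fn, param_set(params, spec$path[i], spec$low[i]),
                     strategy, reference)
    hi <- model_icer(model_fn, param_set(params, spec$path[i], spec$high[i]),
                     strategy, reference)
    span <- if (lo$dominated || hi$dominated) Inf else abs(hi$icer - lo$icer)
    data.frame(path = spec$path[i],
               icer_low = if (lo$dominated) NA_real_ else lo$icer,
               icer_high = if (hi$dominated) NA_real_ else hi$icer,
               span = span,
               dominated_low = lo$dominated, dominated_high = hi$dominated,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$span), ]
  rownames(out) <- NULL
  attr(out, "baseline_icer") <- base$icer
  out
}

## Moment-matched samplers -------------------------------------------------

sample_gamma <- function(n, mean, se) {
  if (se <= 0) stop("SE must be > 0", call. = FALSE)
  if (se / abs(mean) < 1e-7) return(rep(mean, n))
  stats::rgamma(n, shape = (mean / se)^2, scale = se^2 / mean)
}

sample_beta_scaled <- function(n, mean, se, lo = 0, hi = 1) {
  if (se <= 0) stop("SE must be > 0", call. = FALSE)
  if (se / max(abs(mean), 1e-12) < 1e-7) return(rep(mean, n))
  m <- (mean - lo) / (hi - lo)
  s <- se / (hi - lo)
  nu <- m * (1 - m) / s^2 - 1
  if (nu <= 0) stop("beta moment matching infeasible (SE too large)",
                    call. = FALSE)
  lo + (hi - lo) * stats::rbeta(n, m * nu, (1 - m) * nu)
}

sample_dirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  g / rowSums(g)
}

#' Probabilistic sensitivity specification
#'
#' Assigns each uncertain model input its sampling distribution: gamma
#' (moment-matched to mean and SE) for all costs and body weight, beta on
#' the appropriate support for the two state utilities (0-1), the AE
#' disutility magnitudes (0-1, negated on sampling), body surface area
#' (+/-20\% support) and the discount rate (0-0.08), independent normals
#' for each FP contrast coefficient with SE recovered from its reported
#' 95\% CI, and a Dirichlet over the post-progression treatment mix. SEs
#' without a published value default to 20\% of baseline divided by 1.96
#' (matching the deterministic ranges).
#'
#' @param params an \code{econ_params}.
#' @param contrasts optional contrast data.frame with CI columns
#'   (\code{d0_low}, \code{d0_high}, ...).
#' @param n_draws number of Monte Carlo draws.
#' @param seed RNG seed.
#' @param mix_count effective Dirichlet count for the PD treatment mix.
#' @return list of class \code{psa_spec}.
#' @export
psa_spec <- function(params, contrasts = NULL, n_draws = 1000, seed = 1,
                     mix_count = 100) {
  stopifnot(n_draws >= 1)
  se20 <- function(x) 0.2 * abs(x) / 1.96
  entries <- list()
  add <- function(path, dist, mean, se, lo = NA, hi = NA) {
    entries[[length(entries) + 1]] <<- list(path = path, dist = dist,
                                            mean = mean, se = se,
                                            lo = lo, hi = hi)
  }
  for (nm in names(params$unit_costs)) {
    v <- params$unit_costs[[nm]]$price
    add(paste0("unit_costs.", nm, ".price"), "gamma", v, se20(v))
  }
  for (nm in names(params$per_cycle_costs)) {
    v <- params$per_cycle_costs[[nm]]
    add(paste0("per_cycle_costs.", nm), "gamma", v, se20(v))
  }
  for (nm in names(params$ae_costs)) {
    v <- params$ae_costs[[nm]]
    add(paste0("ae_costs.", nm), "gamma", v, se20(v))
  }
  add("body_weight", "gamma", params$body_weight, se20(params$body_weight))
  add("utilities.pfs", "beta", params$utilities$pfs,
      se20(params$utilities$pfs), 0, 1)
  add("utilities.pd", "beta", params$utilities$pd,
      se20(params$utilities$pd), 0, 1)
  for (nm in names(params$ae_disutilities)) {
    v <- params$ae_disutilities[[nm]]
    add(paste0("ae_disutilities.", nm), "beta_negated", abs(v), se20(v), 0, 1)
  }
  add("bsa", "beta", params$bsa, se20(params$bsa),
      0.8 * params$bsa, 1.2 * params$bsa)
  if (params$annual_discount > 0)
    add("annual_discount", "beta", params$annual_discount,
        se20(params$annual_discount), 0, 0.08)
  if (!is.null(contrasts)) {
    for (i in seq_len(nrow(contrasts))) {
      row <- contrasts[i, ]
      pre <- paste0("contrast.", toupper(row$endpoint), ".", row$treatment)
      if (!is.null(row$d0_low) && is.finite(row$d0_low))
        add(paste0(pre, ".d0"), "normal", row$d0,
            (row$d0_high - row$d0_low) / (2 * 1.96))
      if (!is.null(row$d1_low) && is.finite(row$d1_low))
        add(paste0(pre, ".d1"), "normal", row$d1,
            (row$d1_high - row$d1_low) / (2 * 1.96))
    }
  }
  structure(list(entries = entries,
                 mix = unlist(params$pd_treatment_mix),
                 mix_count = mix_count,
                 n_draws = as.integer(n_draws), seed = seed),
            class = "psa_spec")
}

#' Draw parameter sets for probabilistic sensitivity analysis
#'
#' @param spec a \code{\link{psa_spec}}.
#' @return data.frame with \code{n_draws} rows; one column per parameter
#'   path (FP contrast columns are prefixed \code{contrast.}, the
#'   Dirichlet mix columns \code{pd_treatment_mix.}). Reproducible from
#'   \code{spec$seed}.
#' @export
sample_params <- function(spec) {
  stopifnot(inherits(spec, "psa_spec"))
  with_seed(spec$seed, {
    n <- spec$n_draws
    cols <- list()
    for (e in spec$entries) {
      cols[[e$path]] <- switch(e$dist,
        gamma = sample_gamma(n, e$mean, e$se),
        beta = sample_beta_scaled(n, e$mean, e$se, e$lo, e$hi),
        beta_negated = -sample_beta_scaled(n, e$mean, e$se, e$lo, e$hi),
        normal = if (e$se <= 0) stop("SE must be > 0", call. = FALSE)
                 else stats::rnorm(n, e$mean, e$se),
        stop("unknown distribution ", e$dist, call. = FALSE))
    }
    mix_draws <- sample_dirichlet(n, spec$mix * spec$mix_count)
    colnames(mix_draws) <- paste0("pd_treatment_mix.", names(spec$mix))
    out <- cbind(as.data.frame(cols, check.names = FALSE),
                 as.data.frame(mix_draws, check.names = FALSE))
    out
  })
}

apply_draw <- function(params, contrasts, draw) {
  for (nm in names(draw)) {
    v <- draw[[nm]]
    if (startsWith(nm, "contrast.")) {
      if (is.null(contrasts)) next
      parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
      sel <- toupper(contrasts$endpoint) == parts[2] &
        contrasts$treatment == parts[3]
      contrasts[sel, parts[4]] <- v
    } else {
      params <- param_set(params, nm, v)
    }
  }
  list(params = params, contrasts = contrasts)
}

#' Run the probabilistic sensitivity analysis
#'
#' Re-evaluates the whole pipeline (contrast application, partitioned
#' survival model, incremental analysis) for every sampled parameter set.
#' A strategy counts as cost-effective in a draw when its incremental net
#' monetary benefit versus the reference is strictly positive:
#' \code{wtp * dQALY - dCost > 0} (pairwise-versus-reference convention).
#' Draws on which the model fails are recorded and excluded; more than 5\%
#' failures aborts.
#'
#' @param model_fn function \code{(params, contrasts)} (or \code{(params)})
#'   returning per-strategy totals.
#' @param draws data.frame from \code{\link{sample_params}}.
#' @param params baseline \code{econ_params}.
#' @param reference comparator strategy.
#' @param wtp willingness-to-pay per QALY.
#' @param contrasts baseline contrast table (required when draws carry
#'   \code{contrast.} columns).
#' @return list of class \code{psa_result}: \code{scatter} (draw,
#'   strategy, inc_cost, inc_qaly), \code{prob_ce} (named vector),
#'   \code{n_failed}, \code{wtp}.
#' @export
run_psa <- function(model_fn, draws, params, reference,
                    wtp = params$wtp_per_qaly, contrasts = NULL) {
  stopifnot(nrow(draws) >= 1)
  takes_contrasts <- length(formals(model_fn)) >= 2
  scatter <- vector("list", nrow(draws))
  failed <- 0L
  for (i in seq_len(nrow(draws))) {
    res <- tryCatch({
      ap <- apply_draw(params, contrasts, draws[i, , drop = FALSE])
      totals <- if (takes_contrasts) model_fn(ap$params, ap$contrasts)
                else model_fn(ap$params)
      ref <- totals[totals$strategy == reference, ]
      data.frame(draw = i,
                 strategy = totals$strategy,
                 inc_cost = totals$cost - ref$cost,
                 inc_qaly = totals$qaly - ref$qaly,
                 stringsAsFactors = FALSE)
    }, error = function(e) NULL)
    if (is.null(res)) failed <- failed + 1L else scatter[[i]] <- res
  }
  if (failed > 0.05 * nrow(draws))
    stop(failed, " of ", nrow(draws), " PSA draws failed (> 5%)",
         call. = FALSE)
  scatter <- do.call(rbind, scatter)
  nmb <- wtp * scatter$inc_qaly - scatter$inc_cost
  prob <- tapply(nmb > 0, scatter$strategy, mean)
  prob <- prob[setdiff(names(prob), reference)]
  structure(list(scatter = scatter, prob_ce = prob, n_failed = failed,
                 wtp = wtp, reference = reference),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  n_draws <- length(unique(x$scatter$draw))
  cat(sprintf("PSA: %d draws (%d failed), WTP %.2f, reference '%s'\n",
              n_draws, x$n_failed, x$wtp, x$reference))
  print(round(100 * x$prob_ce, 1))
  invisible(x)
}

#' Cost-effectiveness acceptability curves
#'
#' Probability of cost-effectiveness per strategy across a grid of
#' willingness-to-pay values, under the same strict pairwise net-monetary-
#' benefit rule as \code{\link{run_psa}} (a draw whose ICER equals the WTP
#' exactly counts as not cost-effective).
#'
#' @param psa a \code{psa_result} (its scatter table is reused).
#' @param wtp_grid non-empty vector of WTP values.
#' @return data.frame: \code{wtp}, one probability column per strategy.
#' @export
ceac <- function(psa, wtp_grid) {
  stopifnot(length(wtp_grid) >= 1)
  scatter <- psa$scatter
  strategies <- setdiff(unique(scatter$strategy), psa$reference)
  rows <- lapply(wtp_grid, function(w) {
    nmb <- w * scatter$inc_qaly - scatter$inc_cost
    p <- tapply(nmb > 0, scatter$strategy, mean)[strategies]
    as.data.frame(c(list(wtp = w), as.list(p)), check.names = FALSE)
  })
  do.call(rbind, rows)
}
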