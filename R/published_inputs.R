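## Published network-meta-analysis and base-case inputs for the six
## first-line PD-1 inhibitor + chemotherapy regimens in advanced ESCC.
## These are the reported frequentist fractional-polynomial contrast
## estimates (first order; p = -2 for PFS, p = -1 for OS) and the reported
## base-case totals, shipped so the downstream economic machinery can be
## exercised and cross-checked without refitting the trial network.

#' Reported fractional-polynomial contrasts for the ESCC network
#'
#' First-order FP contrasts (log hazard ratio \code{d0 + d1 t^p} versus
#' chemotherapy) for the six PD-1 inhibitor combinations, as estimated
#' from the published six-trial first-line ESCC network: \code{p = -2}
#' for progression-free survival and \code{p = -1} for overall survival,
#' with 95\% confidence intervals.
#'
#' @return data.frame: treatment, endpoint, p, d0, d0_low, d0_high, d1,
#'   d1_low, d1_high.
#' @export
escc_fp_contrasts <- function() {
  pfs <- data.frame(
    treatment = c("toripalimab", "camrelizumab", "pembrolizumab",
                  "serplulimab", "sintilimab", "tislelizumab"),
    endpoint = "PFS", p = -2,
    d0 = c(-0.91, -0.69, -0.26, -0.62, -0.62, -0.38),
    d0_low = c(-1.30, -0.95, -0.47, -0.95, -0.88, -0.63),
    d0_high = c(-0.52, -0.43, -0.05, -0.30, -0.36, -0.14),
    d1 = c(2.76, 1.19, 1.14, 0.85, -0.10, -1.34),
    d1_low = c(-0.08, -1.08, -0.62, -1.50, -2.34, -3.36),
    d1_high = c(5.60, 3.46, 2.90, 3.19, 2.16, 0.69),
    stringsAsFactors = FALSE)
  os <- data.frame(
    treatment = pfs$treatment,
    endpoint = "OS", p = -1,
    d0 = c(-1.00, -0.41, -0.34, -0.73, -0.45, -0.52),
    d0_low = c(-1.59, -0.82, -0.60, -1.13, -0.82, -0.82),
    d0_high = c(-0.41, 0.01, -0.08, -0.33, -0.08, -0.23),
    d1 = c(1.71, -0.01, 0.30, 0.67, -0.56, -0.14),
    d1_low = c(-0.86, -2.18, -1.54, -1.28, -2.40, -1.63),
    d1_high = c(4.28, 2.17, 0.94, 2.62, 1.29, 1.36),
    stringsAsFactors = FALSE)
  rbind(pfs, os)
}

#' Reported base-case totals for the ESCC strategy comparison
#'
#' Per-strategy discounted total cost (USD), QALYs and life years as
#' reported for the published base case; useful for exercising
#' \code{\link{icer_table}} on known totals.
#'
#' @return data.frame: strategy, cost, qaly, ly.
#' @export
escc_base_case_totals <- function() {
  data.frame(
    strategy = c("chemotherapy", "toripalimab", "camrelizumab",
                 "pembrolizumab", "serplulimab", "sintilimab",
                 "tislelizumab"),
    cost = c(14025.37, 33743.55, 30594.67, 96591.87, 71012.44, 26033.52,
             28047.10),
    qaly = c(0.66, 1.27, 1.00, 0.92, 1.13, 1.06, 1.06),
    ly = c(0.96, 1.84, 1.41, 1.37, 1.62, 1.52, 1.56),
    stringsAsFactors = FALSE)
}
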