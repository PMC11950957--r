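## Radiobiological dose-response: EQD2 conversion, the Lyman-Kutcher-Burman
## (LKB) model and the relative-seriality (RS) model, with the published
## rectal endpoint parameter registry.
##
## All public outputs are probabilities in percent; internal math uses
## fractions. NTCP values are computed from the DVH of the craniocaudally
## cropped rectum (the contoured structure), with the linear-quadratic
## EQD2 conversion applied per dose bin at the plan's fraction count.

#' LKB model parameters
#'
#' @param n Volume-effect exponent (toward 0 = more serial organ).
#' @param m Slope of the dose-response curve.
#' @param td50 Tolerance dose of 50% complication probability, Gy.
#' @param alpha_beta Fractionation sensitivity alpha/beta, Gy.
#' @return Object of class `lkb_params`.
#' @export
lkb_params <- function(n, m, td50, alpha_beta = 3.0) {
  stopifnot(n > 0, m > 0, td50 > 0, alpha_beta > 0)
  structure(list(n = n, m = m, td50 = td50, alpha_beta = alpha_beta),
            class = "lkb_params")
}

#' Relative-seriality model parameters
#'
#' @param d50 Tolerance dose of 50% complication probability, Gy.
#' @param gamma Normalized slope of the response curve at D50.
#' @param s Seriality parameter (1 = fully serial, -> 0 parallel).
#' @param alpha_beta Fractionation sensitivity alpha/beta, Gy.
#' @return Object of class `rs_params`.
#' @export
rs_params <- function(d50, gamma, s, alpha_beta = 3.0) {
  stopifnot(d50 > 0, gamma > 0, s > 0, alpha_beta > 0)
  structure(list(d50 = d50, gamma = gamma, s = s,
                 alpha_beta = alpha_beta),
            class = "rs_params")
}

#' Rectal NTCP endpoint registry
#'
#' Loads the versioned endpoint parameter registry shipped with the
#' package: seven LKB endpoints (grade >= 1 and >= 2 late rectal bleeding,
#' stool frequency, bowel pain, sphincter control, stricture/ulcer) and
#' the relative-seriality grade >= 2 late-rectal-bleeding endpoint, all
#' with alpha/beta = 3 Gy.
#'
#' @return A list with elements `lkb` (named list of [lkb_params()]), `rs`
#'   (named list of [rs_params()]), `alpha_beta` and `version`.
#' @export
ntcp_registry <- function() {
  path <- system.file("extdata", "ntcp_endpoints.yaml",
                      package = "rtdosepred", mustWork = TRUE)
  reg <- yaml::read_yaml(path)
  ab <- reg$alpha_beta
  lkb <- lapply(reg$lkb, function(p)
    lkb_params(p$n, p$m, p$td50, alpha_beta = ab))
  rs <- lapply(reg$rs, function(p)
    rs_params(p$d50, p$gamma, p$s, alpha_beta = ab))
  list(lkb = lkb, rs = rs, alpha_beta = ab, version = reg$version)
}

#' Equivalent dose in 2-Gy fractions
#'
#' Linear-quadratic conversion `EQD2 = D * (d + a/b) / (2 + a/b)` with the
#' per-fraction dose `d = D / n_fractions`.
#'
#' @param total_dose Total physical dose D in Gy (vectorized, >= 0).
#' @param n_fractions Fraction count N (>= 1).
#' @param alpha_beta Alpha/beta ratio in Gy (default 3).
#' @return EQD2 in Gy.
#' @export
eqd2 <- function(total_dose, n_fractions, alpha_beta = 3.0) {
  stopifnot(all(total_dose >= 0), n_fractions >= 1, alpha_beta > 0)
  d <- total_dose / n_fractions
  total_dose * (d + alpha_beta) / (2 + alpha_beta)
}

## Differential relative volumes v_i and bin-centre doses from a
## cumulative curve; uses the actual edge midpoints so curves with
## non-uniform edges (e.g. after EQD2 conversion) are handled too.
## v_i sum to 1 over the structure.
dvh_differential <- function(curve) {
  cv <- curve$cum_volume / 100
  v <- cv[-length(cv)] - cv[-1]
  centers <- (curve$edges[-length(curve$edges)] + curve$edges[-1]) / 2
  keep <- v > 0
  list(v = v[keep], dose = centers[keep])
}

#' Effective dose of the LKB model
#'
#' Generalized (power) mean of the EQD2-converted DVH:
#' `Deff = (sum_i v_i * EQD2_i^(1/n))^n`. Equal to the mean dose at
#' `n = 1` and approaching the maximum dose as `n -> 0`. Evaluated in log
#' space for numerical stability at small `n`.
#'
#' @param curve A `dvh_curve` whose dose axis is already in EQD2 Gy.
#' @param params An [lkb_params()].
#' @return Effective dose in Gy.
#' @export
effective_dose <- function(curve, params) {
  dd <- dvh_differential(curve)
  if (!length(dd$v)) stop("empty DVH curve", call. = FALSE)
  lx <- log(pmax(dd$dose, 1e-12)) / params$n
  lmax <- max(lx)
  exp(params$n * (lmax + log(sum(dd$v * exp(lx - lmax)))))
}

#' LKB NTCP
#'
#' `NTCP = Phi((Deff - TD50) / (m * TD50))` with `Phi` the standard-normal
#' CDF and `Deff` from [effective_dose()].
#'
#' @inheritParams effective_dose
#' @param params An [lkb_params()].
#' @return Probability in \[0, 1\].
#' @export
lkb_ntcp <- function(curve, params) {
  deff <- effective_dose(curve, params)
  t <- (deff - params$td50) / (params$m * params$td50)
  stats::pnorm(t)
}

#' Poisson dose-response of the relative-seriality model
#'
#' `P(D) = 2^(-exp(e^gamma * (1 - D / D50)))`, the single-target Poisson
#' response: 0.5 at `D = D50`, approaching 0 at zero dose and 1 at high
#' dose.
#'
#' @param total_dose EQD2 dose in Gy (vectorized, >= 0).
#' @param params An [rs_params()].
#' @return Probability in (0, 1).
#' @export
rs_response <- function(total_dose, params) {
  stopifnot(all(total_dose >= 0))
  2^(-exp(exp(params$gamma) * (1 - total_dose / params$d50)))
}

#' Relative-seriality NTCP
#'
#' `NTCP = (1 - prod_i (1 - P(D_i)^s)^v_i)^(1/s)` over the differential
#' DVH bins, computed in log space.
#'
#' @param curve A `dvh_curve` whose dose axis is already in EQD2 Gy.
#' @param params An [rs_params()].
#' @return Probability in \[0, 1\].
#' @export
rs_ntcp <- function(curve, params) {
  dd <- dvh_differential(curve)
  if (!length(dd$v)) stop("empty DVH curve", call. = FALSE)
  p <- rs_response(dd$dose, params)
  log_prod <- sum(dd$v * log1p(-pmin(p^params$s, 1 - 1e-15)))
  (1 - exp(log_prod))^(1 / params$s)
}

## Convert a physical-dose DVH curve to an EQD2-axis curve by transforming
## its bin edges with the LQ formula (monotone, so cumulative volumes are
## unchanged); the resulting curve has non-uniform "bins" whose centres we
## evaluate directly.
eqd2_curve <- function(curve, n_fractions, alpha_beta) {
  out <- curve
  out$edges <- eqd2(curve$edges, n_fractions, alpha_beta)
  out
}

#' NTCP endpoint panel for a rectum dose
#'
#' Computes every registry endpoint (seven LKB plus relative-seriality
#' grade >= 2 late rectal bleeding) for one dose distribution: the rectum
#' DVH is built at `bin_width` Gy, each bin centre is converted to EQD2 at
#' the plan's fraction count, and both models are evaluated on the
#' converted curve. Results are percentages.
#'
#' @param dose A [dose_grid()] (carries prescription and fraction count).
#' @param rectum_mask Rectum [structure_mask()] (the craniocaudally
#'   cropped structure).
#' @param registry Result of [ntcp_registry()].
#' @param bin_width DVH bin width in Gy.
#' @return data.frame with columns `endpoint`, `model`, `ntcp_pct`.
#' @export
ntcp_suite <- function(dose, rectum_mask, registry = ntcp_registry(),
                       bin_width = 0.1) {
  curve <- compute_dvh(dose, rectum_mask, bin_width)
  ecurve <- eqd2_curve(curve, dose$n_fractions, registry$alpha_beta)
  rows <- list()
  for (nm in names(registry$lkb))
    rows[[length(rows) + 1L]] <-
      data.frame(endpoint = nm, model = "LKB",
                 ntcp_pct = 100 * lkb_ntcp(ecurve, registry$lkb[[nm]]))
  for (nm in names(registry$rs))
    rows[[length(rows) + 1L]] <-
      data.frame(endpoint = nm, model = "RS",
                 ntcp_pct = 100 * rs_ntcp(ecurve, registry$rs[[nm]]))
  do.call(rbind, rows)
}
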