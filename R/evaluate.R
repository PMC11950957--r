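## Plan-similarity and statistical evaluation: isodose Dice similarity,
## percent mean absolute errors, regression goodness-of-fit with Wald
## tests, power analysis, and the cohort-level report.

#' Isodose-volume Dice similarity coefficient
#'
#' Dice overlap `2|A ∩ B| / (|A| + |B|)` between the planned and predicted
#' boolean isodose volumes at level `d` Gy. When both volumes are empty
#' (levels above both maxima) the coefficient is defined as 1 (perfect
#' agreement on absence). Evaluated within the body mask when given.
#'
#' @param planned,predicted [dose_grid()]s on one grid.
#' @param d Isodose level in Gy.
#' @param body Optional body [structure_mask()] restricting the volumes.
#' @return Dice coefficient in \[0, 1\].
#' @export
idsc <- function(planned, predicted, d, body = NULL) {
  if (!identical(dim(planned$values), dim(predicted$values)))
    stop("misaligned dose grids", call. = FALSE)
  a <- planned$values >= d
  b <- predicted$values >= d
  if (!is.null(body)) {
    a <- a & body$values > 0
    b <- b & body$values > 0
  }
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0L) return(1)
  2 * sum(a & b) / (na + nb)
}

#' Mean iDSC over a range of dose levels
#'
#' Arithmetic mean of [idsc()] over the levels `d_min, d_min + step, ...`
#' up to the prescription. The two standard variants are `d_min = 0`
#' (overall agreement) and `d_min = 50` Gy (high-dose region).
#'
#' @inheritParams idsc
#' @param d_min Lowest level in Gy.
#' @param step Level spacing in Gy (default 1).
#' @return Mean Dice coefficient in \[0, 1\].
#' @export
mean_idsc <- function(planned, predicted, d_min = 0, step = 1,
                      body = NULL) {
  if (d_min > planned$prescription)
    stop("d_min exceeds the prescription", call. = FALSE)
  stopifnot(step > 0)
  levels <- seq(d_min, planned$prescription, by = step)
  mean(vapply(levels, function(d) idsc(planned, predicted, d, body),
              numeric(1)))
}

#' Percent mean absolute error of paired plan metrics
#'
#' For Gy-valued metrics: the mean of
#' `100 * |predicted - planned| / prescription`. For %-valued metrics
#' (V_xGy, NTCP): the mean absolute difference in percentage points.
#'
#' @param planned,predicted Paired numeric vectors of metric values.
#' @param kind `"gy"` or `"percent"`.
#' @param prescription Prescription dose in Gy (required for `kind =
#'   "gy"`).
#' @return %MAE (scalar).
#' @export
pmae <- function(planned, predicted, kind = c("gy", "percent"),
                 prescription = NULL) {
  kind <- match.arg(kind)
  if (length(planned) != length(predicted))
    stop("length mismatch between planned and predicted values",
         call. = FALSE)
  stopifnot(all(is.finite(planned)), all(is.finite(predicted)))
  if (kind == "gy") {
    stopifnot(!is.null(prescription), prescription > 0)
    mean(100 * abs(predicted - planned) / prescription)
  } else {
    mean(abs(predicted - planned))
  }
}

#' Linear regression of predicted on planned values
#'
#' Ordinary least squares with the coefficient of determination and the
#' two-sided Wald-test p-value (t-distributed statistic) for the null
#' hypothesis that the slope is zero.
#'
#' @param planned,predicted Paired numeric vectors (n >= 3).
#' @return An object of class `regression_result`: list with `slope`,
#'   `intercept`, `r2`, `p`, `n`.
#' @export
regress <- function(planned, predicted) {
  n <- length(planned)
  if (n < 3 || length(predicted) != n)
    stop("need at least 3 paired values", call. = FALSE)
  if (stats::var(planned) == 0)
    stop("zero variance in planned values", call. = FALSE)
  if (stats::var(predicted) == 0)
    ## constant prediction: no association by definition
    return(structure(list(slope = 0, intercept = predicted[1], r2 = 0,
                          p = 1, n = n),
                     class = "regression_result"))
  fit <- stats::lm(predicted ~ planned)
  sm <- suppressWarnings(summary(fit)) # silence perfect-fit notes
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r2 = sm$r.squared,
                 p = unname(sm$coefficients[2, 4]),
                 n = n),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf(
    "<regression> slope %.3f, intercept %.3f, R^2 %.3f, p %.3g, n %d\n",
    x$slope, x$intercept, x$r2, x$p, x$n))
  invisible(x)
}

#' Power of the slope test at a target R-squared
#'
#' Power to detect a true coefficient of determination `r2` with a
#' two-sided slope test at level `alpha` and sample size `n`, under the
#' effect size `f2 = r2 / (1 - r2)`. The primary convention is the
#' large-sample normal approximation
#' `Phi(sqrt(n * f2) - z_{1-alpha/2})`; `method = "ncf"` uses the exact
#' noncentral-F distribution (noncentrality `n * f2`, df 1 and `n - 2`).
#'
#' @param n Sample size (>= 4).
#' @param r2 Target coefficient of determination in (0, 1).
#' @param alpha Significance level in (0, 1).
#' @param method `"normal"` (default) or `"ncf"`.
#' @return Power in (0, 1).
#' @export
power_r2 <- function(n, r2, alpha = 0.05,
                     method = c("normal", "ncf")) {
  method <- match.arg(method)
  stopifnot(n >= 4, r2 > 0, r2 < 1, alpha > 0, alpha < 1)
  f2 <- r2 / (1 - r2)
  if (method == "normal") {
    stats::pnorm(sqrt(n * f2) - stats::qnorm(1 - alpha / 2))
  } else {
    crit <- stats::qf(1 - alpha, 1, n - 2)
    1 - stats::pf(crit, 1, n - 2, ncp = n * f2)
  }
}

#' Cohort evaluation report
#'
#' Reproduces the full plan-comparison layout for a test cohort: for every
#' DVH metric (23 rows) and NTCP endpoint (8 rows), the planned and
#' predicted mean +/- SD, the %MAE mean +/- SD, and the regression R² and
#' p-value; plus per-sample mean iDSC at the two standard level ranges
#' (>= 0 Gy and >= 50 Gy).
#'
#' @param samples List of preprocessed [plan_sample()]s (planned doses).
#' @param predicted List of predicted [dose_grid()]s, same order.
#' @param registry NTCP parameter registry ([ntcp_registry()]).
#' @param bin_width DVH bin width in Gy.
#' @param idsc_step Dose-level step for mean iDSC in Gy.
#' @param out_dir Optional directory; when given, writes `report.csv`,
#'   `idsc.csv` and `report.json`.
#' @return An object of class `eval_report`: list with `metrics`
#'   (data.frame), `idsc` (per-sample data.frame), `idsc_mean0`,
#'   `idsc_mean50`, and `idsc_step_sensitivity` (mean iDSC at half the
#'   level step).
#' @export
cohort_report <- function(samples, predicted,
                          registry = ntcp_registry(), bin_width = 0.1,
                          idsc_step = 1, out_dir = NULL) {
  n <- length(samples)
  if (n < 3 || length(predicted) != n)
    stop("need at least 3 paired samples", call. = FALSE)
  rx <- samples[[1]]$dose$prescription

  metric_tab <- function(dose, masks) {
    dvh <- metric_suite(dose, masks, bin_width)
    nt <- ntcp_suite(dose, masks$rectum, registry, bin_width)
    rbind(dvh,
          data.frame(structure = "rectum",
                     metric = paste0(nt$endpoint, "-", nt$model,
                                     "-NTCP"),
                     unit = "%", value = nt$ntcp_pct))
  }
  plan_vals <- lapply(seq_len(n), function(i)
    metric_tab(samples[[i]]$dose, samples[[i]]$masks))
  pred_vals <- lapply(seq_len(n), function(i)
    metric_tab(predicted[[i]], samples[[i]]$masks))

  spec <- plan_vals[[1]][, c("structure", "metric", "unit")]
  pl <- sapply(plan_vals, `[[`, "value")
  pr <- sapply(pred_vals, `[[`, "value")
  rows <- lapply(seq_len(nrow(spec)), function(i) {
    kind <- if (spec$unit[i] == "Gy") "gy" else "percent"
    errs <- if (kind == "gy") 100 * abs(pr[i, ] - pl[i, ]) / rx
            else abs(pr[i, ] - pl[i, ])
    reg <- tryCatch(regress(pl[i, ], pr[i, ]),
                    error = function(e) list(r2 = NA_real_, p = NA_real_))
    data.frame(structure = spec$structure[i], metric = spec$metric[i],
               unit = spec$unit[i],
               planned_mean = mean(pl[i, ]), planned_sd = sd(pl[i, ]),
               predicted_mean = mean(pr[i, ]), predicted_sd = sd(pr[i, ]),
               pmae_mean = mean(errs), pmae_sd = sd(errs),
               r2 = reg$r2, p = reg$p)
  })
  metrics <- do.call(rbind, rows)

  idsc_tab <- do.call(rbind, lapply(seq_len(n), function(i) {
    body <- samples[[i]]$masks$body
    data.frame(
      id = samples[[i]]$id,
      mean_idsc_0 = mean_idsc(samples[[i]]$dose, predicted[[i]], 0,
                              idsc_step, body),
      mean_idsc_50 = mean_idsc(samples[[i]]$dose, predicted[[i]], 50,
                               idsc_step, body))
  }))
  half_step <- mean(vapply(seq_len(n), function(i)
    mean_idsc(samples[[i]]$dose, predicted[[i]], 0, idsc_step / 2,
              samples[[i]]$masks$body), numeric(1)))

  report <- structure(
    list(metrics = metrics, idsc = idsc_tab,
         idsc_mean0 = mean(idsc_tab$mean_idsc_0),
         idsc_mean50 = mean(idsc_tab$mean_idsc_50),
         idsc_step_sensitivity = half_step,
         n = n, prescription = rx, bin_width = bin_width,
         idsc_step = idsc_step),
    class = "eval_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(metrics, file.path(out_dir, "report.csv"),
              row.names = FALSE)
    write.csv(idsc_tab, file.path(out_dir, "idsc.csv"),
              row.names = FALSE)
    jsonlite::write_json(report[setdiff(names(report), "metrics")],
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  report
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d samples, mean iDSC>=0Gy %.3f, >=50Gy %.3f\n",
              x$n, x$idsc_mean0, x$idsc_mean50))
  g2 <- x$metrics[x$metrics$metric == "G2-LRB-LKB-NTCP", ]
  if (nrow(g2))
    cat(sprintf("  G2-LRB-LKB-NTCP: planned %.2f +/- %.2f%%, %%MAE %.2f, R2 %.2f\n",
                g2$planned_mean, g2$planned_sd, g2$pmae_mean, g2$r2))
  invisible(x)
}
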