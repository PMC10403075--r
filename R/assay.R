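## Assay post-processing: turbidity AUC, saturation dose-response fits,
## percent-of-baseline lipid timecourses.

#' Area under a timeseries curve
#'
#' Trapezoidal area over the observed interval, e.g. of a DMPC vesicle
#' turbidity trace (absorbance at 660 nm vs minutes).
#'
#' @param t time points, strictly increasing.
#' @param y signal values, same length as `t`.
#' @return area in signal x time units.
#' @export
auc <- function(t, y) {
  if (is.data.frame(t)) { y <- t$y; t <- t$t }
  stopifnot(length(t) == length(y))
  if (length(t) < 2) stop("need at least two points", call. = FALSE)
  if (any(diff(t) <= 0))
    stop("time must be strictly increasing", call. = FALSE)
  pracma::trapz(t, y)
}

#' Fit a saturation dose-response curve
#'
#' Least-squares fit of the rectangular hyperbola
#' `response = baseline + Vmax * d / (EC50 + d)` (optionally a
#' four-parameter logistic with Hill coefficient when `logistic = TRUE`)
#' to a lipolysis-rate dose-response. The `converged` flag is honest: it
#' is `FALSE` whenever the optimizer fails, the response carries no dose
#' dependence, or the fitted parameters are not a positive saturating
#' curve, in which case the fit is flagged `degenerate`.
#'
#' @param dose doses (same units as the reported EC50, e.g. uM); at least
#'   three distinct values including 0.
#' @param response measured responses.
#' @param logistic add a Hill exponent (4-parameter logistic).
#' @return a `DoseResponseFit`: `EC50`, `Vmax`, `baseline`, `hill`,
#'   `residual_norm`, `converged`, `degenerate`.
#' @examples
#' d <- c(0, 0.02, 0.05, 0.1, 0.25, 1)
#' fit_saturation(d, 2 * d / (0.107 + d))
#' @export
fit_saturation <- function(dose, response, logistic = FALSE) {
  stopifnot(length(dose) == length(response))
  if (length(unique(dose)) < 3 || !any(dose == 0))
    stop("need at least three distinct doses including 0", call. = FALSE)

  out <- list(EC50 = NA_real_, Vmax = NA_real_, baseline = NA_real_,
              hill = if (logistic) NA_real_ else 1,
              residual_norm = NA_real_,
              converged = FALSE, degenerate = FALSE)
  class(out) <- "DoseResponseFit"

  b0 <- mean(response[dose == 0])
  span <- max(response) - b0
  if (!is.finite(span) || span <= 0 || stats::sd(response) < 1e-12 ||
      suppressWarnings(stats::cor(dose, response)) <= 0) {
    out$degenerate <- TRUE
    return(out)
  }
  half <- b0 + span / 2
  pos <- dose[dose > 0]
  ec0 <- pos[which.min(abs(response[dose > 0] - half))]
  df <- data.frame(d = dose, y = response)
  fit <- tryCatch({
    if (logistic)
      minpack.lm::nlsLM(
        y ~ b + Vmax * d^h / (EC50^h + d^h), data = df,
        start = list(b = b0, Vmax = span, EC50 = ec0, h = 1),
        lower = c(-Inf, 0, 1e-12, 0.1),
        control = minpack.lm::nls.lm.control(maxiter = 200))
    else
      minpack.lm::nlsLM(
        y ~ b + Vmax * d / (EC50 + d), data = df,
        start = list(b = b0, Vmax = span, EC50 = ec0),
        lower = c(-Inf, 0, 1e-12),
        control = minpack.lm::nls.lm.control(maxiter = 200))
  }, error = function(e) NULL)
  if (is.null(fit)) {
    out$degenerate <- TRUE
    return(out)
  }
  cf <- stats::coef(fit)
  out$EC50 <- unname(cf["EC50"])
  out$Vmax <- unname(cf["Vmax"])
  out$baseline <- unname(cf["b"])
  if (logistic) out$hill <- unname(cf["h"])
  out$residual_norm <- sqrt(sum(stats::resid(fit)^2))
  out$converged <- out$EC50 > 0 && out$Vmax > 0
  out$degenerate <- !out$converged
  out
}

#' @export
print.DoseResponseFit <- function(x, ...) {
  if (x$converged)
    cat(sprintf("DoseResponseFit: EC50 %.4g, Vmax %.4g, baseline %.4g (residual norm %.3g)\n",
                x$EC50, x$Vmax, x$baseline, x$residual_norm))
  else
    cat("DoseResponseFit: not converged",
        if (x$degenerate) "(degenerate response)", "\n")
  invisible(x)
}

#' Percent-of-baseline normalization
#'
#' Normalizes per-subject timecourses (e.g. plasma triglycerides after
#' peptide injection) to their `t = 0` baseline: `y(t) / y(0) * 100`, and
#' summarizes the group mean and SD at each time point.
#'
#' @param data data.frame with columns `subject`, `t`, `y`; every subject
#'   must have a positive `t = 0` value.
#' @return list with `per_subject` (input plus `percent`) and `summary`
#'   (`t`, `mean`, `sd`, `n`).
#' @export
percent_baseline <- function(data) {
  stopifnot(all(c("subject", "t", "y") %in% names(data)))
  out <- do.call(rbind, lapply(split(data, data$subject), function(d) {
    base <- d$y[d$t == 0]
    if (length(base) != 1)
      stop("subject ", d$subject[1], " needs exactly one t = 0 baseline",
           call. = FALSE)
    if (!is.finite(base) || base <= 0)
      stop("subject ", d$subject[1], " has a non-positive baseline",
           call. = FALSE)
    d$percent <- d$y / base * 100
    d
  }))
  rownames(out) <- NULL
  agg <- do.call(rbind, lapply(split(out, out$t), function(d)
    data.frame(t = d$t[1], mean = mean(d$percent),
               sd = stats::sd(d$percent), n = nrow(d))))
  rownames(agg) <- NULL
  list(per_subject = out, summary = agg[order(agg$t), ])
}
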