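# Enzyme-kinetics model fitting: four-parameter logistic dose-response
# (IC50) and uncompetitive / mixed inhibition models.
#
# All fits are unweighted nonlinear least squares via Levenberg-Marquardt
# (minpack.lm); strictly positive parameters (IC50, Km, alpha-Ki, Vmax) are
# log-parameterized so positivity holds by construction, with standard
# errors for the back-transformed parameters obtained by the delta method.

.dr_model <- function(conc, top, bottom, log10_ic50, hill) {
  bottom + (top - bottom) / (1 + 10^((log10_ic50 - log10(conc)) * hill))
}

.uncomp_model <- function(S, I, vmax, km, alpha_ki) {
  vmax * S / (km + S * (1 + I / alpha_ki))
}

.mixed_model <- function(S, I, vmax, km, ki, alpha_ki) {
  vmax * S / (km * (1 + I / ki) + S * (1 + I / alpha_ki))
}

#' Simulate a dose-response experiment
#'
#' Generates responses from the four-parameter logistic
#' `bottom + (top - bottom) / (1 + 10^((log10(ic50) - log10(conc)) * hill))`
#' plus Gaussian noise.
#'
#' @param conc Concentrations in uM (> 0).
#' @param top,bottom Plateaus in response units (RFU/min).
#' @param ic50 Half-maximal concentration in uM (> 0).
#' @param hill Hill slope (default 1).
#' @param noise_sd Gaussian noise SD (>= 0).
#' @param seed Optional seed for reproducible noise.
#' @return Data frame (`conc_uM`, `response`).
#' @export
simulate_dose_response <- function(conc, top, bottom, ic50, hill = 1,
                                   noise_sd = 0, seed = NULL) {
  if (any(conc <= 0)) stop("concentrations must be > 0")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  stopifnot_scalar_number(ic50, "ic50", positive = TRUE)
  mu <- .dr_model(conc, top, bottom, log10(ic50), hill)
  noise <- if (noise_sd > 0) {
    if (!is.null(seed)) with_seed(seed, stats::rnorm(length(conc), 0, noise_sd))
    else stats::rnorm(length(conc), 0, noise_sd)
  } else 0
  data.frame(conc_uM = conc, response = mu + noise)
}

#' Simulate an enzyme-inhibition kinetics experiment
#'
#' Generates initial rates from the uncompetitive model
#' `v = Vmax S / (Km + S (1 + I/alphaKi))` (or the mixed-model variant when
#' `ki` is supplied) over a design of (substrate, inhibitor) pairs, plus
#' Gaussian noise. Deterministic for a given seed.
#'
#' @param vmax Maximum velocity without inhibitor (RFU/min, > 0).
#' @param km Michaelis constant (uM, > 0).
#' @param alpha_ki Uncompetitive inhibition constant (uM, > 0).
#' @param design Data frame with columns `substrate_uM` and `inhibitor_uM`.
#' @param noise_sd Gaussian noise SD in RFU/min (>= 0).
#' @param seed Optional seed.
#' @param ki Optional competitive inhibition constant (uM); when given the
#'   mixed model is simulated.
#' @return Data frame (`substrate_uM`, `inhibitor_uM`, `rate_rfu_min`).
#' @export
simulate_kinetics <- function(vmax, km, alpha_ki, design, noise_sd = 0,
                              seed = NULL, ki = NULL) {
  stopifnot(is.data.frame(design),
            all(c("substrate_uM", "inhibitor_uM") %in% names(design)))
  stopifnot_scalar_number(vmax, "vmax", positive = TRUE)
  stopifnot_scalar_number(km, "km", positive = TRUE)
  stopifnot_scalar_number(alpha_ki, "alpha_ki", positive = TRUE)
  if (any(design$substrate_uM < 0) || any(design$inhibitor_uM < 0))
    stop("concentrations must be >= 0")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  mu <- if (is.null(ki))
    .uncomp_model(design$substrate_uM, design$inhibitor_uM, vmax, km, alpha_ki)
  else
    .mixed_model(design$substrate_uM, design$inhibitor_uM, vmax, km, ki, alpha_ki)
  noise <- if (noise_sd > 0) {
    if (!is.null(seed)) with_seed(seed, stats::rnorm(nrow(design), 0, noise_sd))
    else stats::rnorm(nrow(design), 0, noise_sd)
  } else 0
  data.frame(substrate_uM = design$substrate_uM,
             inhibitor_uM = design$inhibitor_uM,
             rate_rfu_min = mu + noise)
}

.delta_se <- function(se_log, est) est * se_log  # se of exp(theta) at theta-hat

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of
#' `response = bottom + (top - bottom) / (1 + 10^((log10(IC50) - log10(conc)) * hill))`
#' with IC50 log-parameterized. Initial values come from the data: plateaus
#' from the response extremes, IC50 from the concentration whose response is
#' nearest the half-range, hill from 1. After fitting, the curve is
#' normalized so `top >= bottom` (an exact reparameterization: swapping the
#' plateaus and negating the hill slope leaves the curve unchanged).
#'
#' @param data Data frame with columns `conc_uM` (> 0) and `response`; at
#'   least 5 distinct concentrations spanning >= 2 log units.
#' @param hill_mode `"variable"` (default) or `"fixed_1"` (hill fixed at 1).
#' @return Object of class `dose_response_fit`: `estimates` (top, bottom,
#'   log10_ic50, ic50, hill), `se`, `rss`, `converged`, `cov` (free-parameter
#'   covariance), `hill_mode`, and the underlying `nls` fit.
#' @examples
#' d <- simulate_dose_response(10^seq(-2, 2.7, length.out = 8),
#'                             top = 100, bottom = 0, ic50 = 1.1)
#' fit_dose_response(d)$estimates[["ic50"]]
#' @export
fit_dose_response <- function(data, hill_mode = c("variable", "fixed_1")) {
  hill_mode <- match.arg(hill_mode)
  stopifnot(is.data.frame(data),
            all(c("conc_uM", "response") %in% names(data)))
  data <- data[is.finite(data$conc_uM) & is.finite(data$response), , drop = FALSE]
  if (any(data$conc_uM <= 0)) {
    warning("dropping rows with non-positive concentration")
    data <- data[data$conc_uM > 0, , drop = FALSE]
  }
  concs <- sort(unique(data$conc_uM))
  if (length(concs) < 5L)
    stop("need at least 5 distinct concentrations")
  if (log10(max(concs) / min(concs)) < 2)
    stop("concentrations must span at least 2 log units")
  if (stats::sd(data$response) == 0) stop("all responses are equal")
  lo <- min(data$response); hi <- max(data$response)
  half <- (lo + hi) / 2
  start <- list(bottom = lo, top = hi,
                l10 = log10(data$conc_uM[which.min(abs(data$response - half))]))
  ctl <- minpack.lm::nls.lm.control(maxiter = 200)
  fit <- if (hill_mode == "variable") {
    minpack.lm::nlsLM(
      response ~ bottom + (top - bottom) / (1 + 10^((l10 - log10(conc_uM)) * hill)),
      data = data, start = c(start, hill = 1), control = ctl)
  } else {
    minpack.lm::nlsLM(
      response ~ bottom + (top - bottom) / (1 + 10^(l10 - log10(conc_uM))),
      data = data, start = start, control = ctl)
  }
  sm <- summary(fit)
  cf <- stats::coef(fit)
  se <- sm$coefficients[, "Std. Error"]
  top <- cf[["top"]]; bottom <- cf[["bottom"]]
  hill <- if (hill_mode == "variable") cf[["hill"]] else 1
  se_hill <- if (hill_mode == "variable") se[["hill"]] else NA_real_
  se_top <- se[["top"]]; se_bottom <- se[["bottom"]]
  if (top < bottom) {  # same curve with plateaus swapped and slope negated
    tmp <- top; top <- bottom; bottom <- tmp
    tmp <- se_top; se_top <- se_bottom; se_bottom <- tmp
    hill <- -hill
  }
  l10 <- cf[["l10"]]
  est <- c(top = top, bottom = bottom, log10_ic50 = l10,
           ic50 = 10^l10, hill = hill)
  ses <- c(top = se_top, bottom = se_bottom, log10_ic50 = se[["l10"]],
           ic50 = 10^l10 * log(10) * se[["l10"]], hill = se_hill)
  structure(list(estimates = est, se = ses,
                 rss = sum(stats::resid(fit)^2),
                 converged = fit$convInfo$isConv %||% TRUE,
                 cov = stats::vcov(fit), hill_mode = hill_mode, fit = fit),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  e <- x$estimates
  cat(sprintf("Dose-response fit (hill %s)\n",
              if (x$hill_mode == "fixed_1") "fixed at 1" else "variable"))
  cat(sprintf("  IC50   %.4g uM (log10 %.4g +/- %.2g)\n",
              e[["ic50"]], e[["log10_ic50"]], x$se[["log10_ic50"]]))
  cat(sprintf("  top    %.4g   bottom %.4g   hill %.3g\n",
              e[["top"]], e[["bottom"]], e[["hill"]]))
  cat(sprintf("  RSS %.4g, converged: %s\n", x$rss, x$converged))
  invisible(x)
}

.check_kinetic_data <- function(data) {
  stopifnot(is.data.frame(data),
            all(c("substrate_uM", "inhibitor_uM", "rate_rfu_min") %in% names(data)))
  if (!all(is.finite(data$rate_rfu_min))) stop("rates must be finite")
  if (any(data$substrate_uM < 0) || any(data$inhibitor_uM < 0))
    stop("concentrations must be >= 0")
  data <- data[data$substrate_uM > 0, , drop = FALSE]  # v = 0 rows carry no information
  if (length(unique(data$substrate_uM)) < 4L)
    stop("need at least 4 distinct substrate concentrations")
  if (length(unique(data$inhibitor_uM)) < 2L)
    stop("need at least 2 inhibitor levels")
  if (!any(data$inhibitor_uM == 0))
    warning("no inhibitor-free rows: Km and Vmax are weakly identified")
  data
}

.km_start <- function(data) {
  i0 <- data[data$inhibitor_uM == min(data$inhibitor_uM), , drop = FALSE]
  vhat <- max(i0$rate_rfu_min)
  km0 <- i0$substrate_uM[which.min(abs(i0$rate_rfu_min - vhat / 2))]
  list(vmax = vhat * 1.2, km = max(km0, 1e-3))
}

#' Fit the uncompetitive-inhibition model
#'
#' Joint least-squares fit of `v = Vmax S / (Km + S (1 + I/alphaKi))` over
#' all (substrate, inhibitor) rows; at `I = 0` the model reduces to
#' Michaelis-Menten, which is why inhibitor-free rows anchor Km and Vmax.
#' Vmax, Km and alpha-Ki are log-parameterized (positive by construction).
#'
#' @param data Data frame with columns `substrate_uM`, `inhibitor_uM`,
#'   `rate_rfu_min`; >= 4 substrate levels and >= 2 inhibitor levels, ideally
#'   including `I = 0`.
#' @return Object of class `inhibition_fit` with `estimates` (vmax, km,
#'   alpha_ki), delta-method `se`, `rss`, `converged`, `cov` (log-scale),
#'   `model`, and the underlying `nls` fit.
#' @export
fit_uncompetitive <- function(data) {
  data <- .check_kinetic_data(data)
  s0 <- .km_start(data)
  ipos <- data$inhibitor_uM[data$inhibitor_uM > 0]
  start <- list(lv = log(s0$vmax), lk = log(s0$km),
                la = log(if (length(ipos)) stats::median(ipos) else 1))
  fit <- minpack.lm::nlsLM(
    rate_rfu_min ~ exp(lv) * substrate_uM /
      (exp(lk) + substrate_uM * (1 + inhibitor_uM / exp(la))),
    data = data, start = start,
    control = minpack.lm::nls.lm.control(maxiter = 500))
  cf <- stats::coef(fit)
  se_log <- summary(fit)$coefficients[, "Std. Error"]
  est <- c(vmax = exp(cf[["lv"]]), km = exp(cf[["lk"]]),
           alpha_ki = exp(cf[["la"]]))
  ses <- c(vmax = .delta_se(se_log[["lv"]], est[["vmax"]]),
           km = .delta_se(se_log[["lk"]], est[["km"]]),
           alpha_ki = .delta_se(se_log[["la"]], est[["alpha_ki"]]))
  structure(list(estimates = est, se = ses,
                 rss = sum(stats::resid(fit)^2),
                 converged = fit$convInfo$isConv %||% TRUE,
                 cov = stats::vcov(fit), model = "uncompetitive", fit = fit),
            class = "inhibition_fit")
}

#' Fit the mixed-inhibition model
#'
#' `v = Vmax S / (Km (1 + I/Ki) + S (1 + I/alphaKi))`: the general linear
#' mixed mechanism, containing competitive (alphaKi -> Inf), uncompetitive
#' (Ki -> Inf) and non-competitive (Ki = alphaKi) inhibition as special
#' cases. Provided alongside [fit_uncompetitive()] because an allosteric
#' inhibitor may be better described by either; compare RSS.
#'
#' @inheritParams fit_uncompetitive
#' @return Object of class `inhibition_fit` with `estimates` (vmax, km, ki,
#'   alpha_ki).
#' @export
fit_mixed_inhibition <- function(data) {
  data <- .check_kinetic_data(data)
  s0 <- .km_start(data)
  ipos <- data$inhibitor_uM[data$inhibitor_uM > 0]
  i0 <- if (length(ipos)) stats::median(ipos) else 1
  start <- list(lv = log(s0$vmax), lk = log(s0$km), lki = log(i0), la = log(i0))
  fit <- minpack.lm::nlsLM(
    rate_rfu_min ~ exp(lv) * substrate_uM /
      (exp(lk) * (1 + inhibitor_uM / exp(lki)) +
         substrate_uM * (1 + inhibitor_uM / exp(la))),
    data = data, start = start,
    control = minpack.lm::nls.lm.control(maxiter = 500))
  cf <- stats::coef(fit)
  se_log <- summary(fit)$coefficients[, "Std. Error"]
  est <- c(vmax = exp(cf[["lv"]]), km = exp(cf[["lk"]]),
           ki = exp(cf[["lki"]]), alpha_ki = exp(cf[["la"]]))
  ses <- c(vmax = .delta_se(se_log[["lv"]], est[["vmax"]]),
           km = .delta_se(se_log[["lk"]], est[["km"]]),
           ki = .delta_se(se_log[["lki"]], est[["ki"]]),
           alpha_ki = .delta_se(se_log[["la"]], est[["alpha_ki"]]))
  structure(list(estimates = est, se = ses,
                 rss = sum(stats::resid(fit)^2),
                 converged = fit$convInfo$isConv %||% TRUE,
                 cov = stats::vcov(fit), model = "mixed", fit = fit),
            class = "inhibition_fit")
}

#' @export
print.inhibition_fit <- function(x, ...) {
  cat(sprintf("%s-inhibition fit\n", x$model))
  for (p in names(x$estimates))
    cat(sprintf("  %-9s %.4g +/- %.2g\n", p, x$estimates[[p]], x$se[[p]]))
  cat(sprintf("  RSS %.4g, converged: %s\n", x$rss, x$converged))
  invisible(x)
}

#' Predicted rates from an inhibition fit
#' @param object An `inhibition_fit`.
#' @param newdata Data frame with `substrate_uM`, `inhibitor_uM`.
#' @param ... Unused.
#' @return Numeric vector of predicted rates.
#' @export
predict.inhibition_fit <- function(object, newdata, ...) {
  e <- object$estimates
  if (object$model == "uncompetitive")
    .uncomp_model(newdata$substrate_uM, newdata$inhibitor_uM,
                  e[["vmax"]], e[["km"]], e[["alpha_ki"]])
  else
    .mixed_model(newdata$substrate_uM, newdata$inhibitor_uM,
                 e[["vmax"]], e[["km"]], e[["ki"]], e[["alpha_ki"]])
}

#' Predicted responses from a dose-response fit
#' @param object A `dose_response_fit`.
#' @param newdata Data frame with `conc_uM`.
#' @param ... Unused.
#' @return Numeric vector of predicted responses.
#' @export
predict.dose_response_fit <- function(object, newdata, ...) {
  e <- object$estimates
  .dr_model(newdata$conc_uM, e[["top"]], e[["bottom"]],
            e[["log10_ic50"]], e[["hill"]])
}
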