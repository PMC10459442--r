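#' Steady-state exposure metrics
#'
#' Simulates repeated dosing interval by interval until the AUC over
#' consecutive intervals changes by less than `tol` (relative), then
#' reports the final-interval AUC (AUC_tau,ss) and Cmax (Cmax,ss).
#' For a single-dose regimen the metrics are computed over
#' `[0, single_dose_horizon]` instead.
#'
#' @param x a `population_scenario` or a [one_compartment_model()].
#' @param regimen a [dosing_regimen()]; `interval` is the steady-state
#'   dosing interval tau.
#' @param body_weight kg (mab scenarios; defaults to the physiology's).
#' @param n_intervals fixed number of intervals to simulate instead of
#'   convergence detection (used to make sensitivity pairs comparable).
#' @param tol relative AUC_tau convergence tolerance.
#' @param max_doses convergence cap; exceeding it is an error carrying
#'   the AUC trend.
#' @param grid_per_interval output points per interval for the
#'   trapezoidal AUC.
#' @param single_dose_horizon days, for single-dose regimens.
#' @param ... passed to [scenario_model()].
#' @return list with `auc_tau_ss` (ug*day/mL), `cmax_ss` (ug/mL),
#'   `n_intervals`, `converged`.
#' @export
steady_state_metrics <- function(x, regimen, ...) {
  UseMethod("steady_state_metrics")
}

#' @rdname steady_state_metrics
#' @export
steady_state_metrics.population_scenario <- function(
    x, regimen, body_weight = NULL, n_intervals = NULL, tol = 1e-3,
    max_doses = 50L, grid_per_interval = 101L,
    single_dose_horizon = 150, ...) {
  model <- scenario_model(x, ...)
  if (regimen$n_doses == 1L || !is.finite(regimen$interval)) {
    tt <- seq(0, single_dose_horizon, length.out = 4L * grid_per_interval)
    sim <- simulate_regimen(model, regimen, body_weight,
                            output_times = tt)
    return(list(auc_tau_ss = auc_trapezoid(tt, sim$plasma_conc),
                cmax_ss = max(sim$plasma_conc),
                n_intervals = 1L, converged = TRUE))
  }
  tau <- regimen$interval
  one <- dosing_regimen(regimen$dose_per_kg, n_doses = 1L,
                        infusion_duration = regimen$infusion_duration)
  tt <- seq(0, tau, length.out = grid_per_interval)
  y <- NULL; dosed <- 0
  auc_trend <- numeric(0)
  cmax_k <- NA_real_
  k_stop <- if (is.null(n_intervals)) max_doses else n_intervals
  for (k in seq_len(k_stop)) {
    sim <- simulate_regimen(model, one, body_weight, output_times = tt,
                            y0 = y, dosed0 = dosed)
    auc_k <- auc_trapezoid(tt, sim$plasma_conc)
    cmax_k <- max(sim$plasma_conc)
    auc_trend <- c(auc_trend, auc_k)
    y <- sim$final_state
    dosed <- max(sim$ledger$dosed)
    if (is.null(n_intervals) && k > 1L) {
      if (abs(auc_k - auc_trend[k - 1L]) < tol * auc_k)
        return(list(auc_tau_ss = auc_k, cmax_ss = cmax_k,
                    n_intervals = k, converged = TRUE))
    }
  }
  if (is.null(n_intervals)) {
    stop("AUC_tau did not converge within ", max_doses,
         " doses; last relative changes: ",
         paste(signif(utils::tail(abs(diff(auc_trend)) /
                                    utils::tail(auc_trend, -1), 3), 3),
               collapse = ", "))
  }
  list(auc_tau_ss = auc_trend[length(auc_trend)], cmax_ss = cmax_k,
       n_intervals = k_stop, converged = TRUE)
}

# Parameters the sensitivity module can perturb on a mab scenario.
sensitivity_parameters <- c("kd_fcrn", "kd_target", "r0_reference",
                            "kdeg", "kint", "koff")

perturb_parameter <- function(x, parameter, factor) {
  UseMethod("perturb_parameter")
}

#' @export
perturb_parameter.population_scenario <- function(x, parameter, factor) {
  cur <- switch(parameter,
                kd_fcrn = x$drug$kd_fcrn,
                kd_target = x$target$kd_target,
                r0_reference = x$target$r0_reference,
                kdeg = x$target$kdeg,
                kint = x$target$kint,
                koff = x$target$koff,
                stop("unknown parameter '", parameter, "'"))
  if (is.null(cur)) return(NULL)
  set_scenario_params(x, setNames(list(cur * factor), parameter),
                      provenance = "scaled")
}

#' Local sensitivity of an exposure metric
#'
#' Normalized one-sided sensitivity coefficient
#' \deqn{S = \frac{(P(p(1+\delta)) - P(p))/P(p)}{\delta}}
#' with perturbation \eqn{\delta} (default 10 percent).  A central
#' difference is available via `method = "central"`.  The perturbed run
#' reuses the number of dosing intervals selected by the baseline
#' convergence so the pair is comparable.  Parameters that are absent
#' from the active pathways (e.g. target parameters with no target, or
#' a zero-valued parameter) give S = 0.
#'
#' @param x a `population_scenario` or [one_compartment_model()].
#' @param regimen a [dosing_regimen()].
#' @param parameter parameter name; for mab scenarios one of
#'   `r paste(sensitivity_parameters, collapse = ", ")`.
#' @param perturbation relative perturbation delta (> 0).
#' @param method `"forward"` or `"central"`.
#' @param baseline optional precomputed [steady_state_metrics()] result
#'   for `x` under `regimen` (avoids recomputing the reference run when
#'   scanning several parameters).
#' @param ... passed to [steady_state_metrics()].
#' @return a `sensitivity_result` data frame with one row per metric:
#'   `parameter`, `metric`, `s_value`, `perturbation`, `dose_per_kg`.
#' @export
local_sensitivity <- function(x, regimen, parameter,
                              perturbation = 0.10,
                              method = c("forward", "central"),
                              baseline = NULL, ...) {
  method <- match.arg(method)
  if (perturbation <= 0) stop("perturbation must be positive")
  base <- if (is.null(baseline)) steady_state_metrics(x, regimen, ...)
          else baseline
  metrics <- c("auc_tau_ss", "cmax_ss")
  p0 <- unlist(base[metrics])
  if (any(p0 == 0)) stop("baseline metric is zero; S undefined")
  up <- perturb_parameter(x, parameter, 1 + perturbation)
  zero_s <- is.null(up) ||
    identical(perturb_signature(up), perturb_signature(x))
  if (zero_s) {
    s <- setNames(numeric(length(metrics)), metrics)
  } else {
    m_up <- steady_state_metrics(up, regimen,
                                 n_intervals = base$n_intervals, ...)
    if (method == "forward") {
      s <- (unlist(m_up[metrics]) - p0) / p0 / perturbation
    } else {
      dn <- perturb_parameter(x, parameter, 1 - perturbation)
      m_dn <- steady_state_metrics(dn, regimen,
                                   n_intervals = base$n_intervals, ...)
      s <- (unlist(m_up[metrics]) - unlist(m_dn[metrics])) / p0 /
        (2 * perturbation)
    }
  }
  structure(
    data.frame(parameter = parameter, metric = metrics,
               s_value = as.numeric(s), perturbation = perturbation,
               dose_per_kg = regimen$dose_per_kg,
               n_intervals = base$n_intervals, row.names = NULL),
    class = c("sensitivity_result", "data.frame"))
}

# Signature used to detect no-op perturbations (zero-valued or absent
# parameters), which must yield S = 0 without a second simulation.
perturb_signature <- function(x) UseMethod("perturb_signature")

#' @export
perturb_signature.population_scenario <- function(x) {
  c(x$drug$kd_fcrn, x$drug$koff_fcrn,
    unlist(x$target[c("kd_target", "kon", "koff", "kdeg", "kint",
                      "r0_reference")]))
}

#' Sensitivity panel over doses and parameters
#'
#' Full grid of normalized sensitivity coefficients per dose x
#' parameter x metric for one scenario.  Duplicate parameters are
#' deduplicated.
#'
#' @param scenario a `population_scenario`.
#' @param doses mg/kg values.
#' @param parameters parameter names (default: the panel of interest
#'   for an FcRn/TMDD antibody model).
#' @param n_doses,interval,infusion_duration regimen template applied
#'   to every dose (default: repeated dosing every 14 days).
#' @param perturbation relative perturbation.
#' @param ... passed to [local_sensitivity()].
#' @return a `sensitivity_result` data frame.
#' @export
sensitivity_panel <- function(scenario, doses,
                              parameters = sensitivity_parameters,
                              n_doses = 50L, interval = 14,
                              infusion_duration = 0.0625,
                              perturbation = 0.10, ...) {
  parameters <- unique(parameters)
  out <- list()
  for (d in doses) {
    reg <- dosing_regimen(d, n_doses = n_doses, interval = interval,
                          infusion_duration = infusion_duration)
    base <- steady_state_metrics(scenario, reg, ...)
    for (p in parameters) {
      out[[length(out) + 1L]] <-
        local_sensitivity(scenario, reg, p,
                          perturbation = perturbation,
                          baseline = base, ...)
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("sensitivity_result", "data.frame")
  res
}

#' Linear one-compartment analogue (sensitivity oracle)
#'
#' A closed-form linear model with clearance `cl` and volume `v`, used
#' as an independent oracle for the sensitivity machinery:
#' AUC_tau,ss = dose/CL and Cmax,ss = (dose/V)/(1 - exp(-CL/V tau)).
#'
#' @param cl clearance (volume/day).
#' @param v volume.
#' @return a `one_compartment_model`.
#' @export
one_compartment_model <- function(cl, v) {
  stopifnot(cl > 0, v > 0)
  structure(list(cl = cl, v = v), class = "one_compartment_model")
}

#' @rdname steady_state_metrics
#' @export
steady_state_metrics.one_compartment_model <- function(x, regimen, ...) {
  dose <- regimen$dose_per_kg  # interpreted as absolute dose
  k <- x$cl / x$v
  if (regimen$n_doses == 1L || !is.finite(regimen$interval)) {
    list(auc_tau_ss = dose / x$cl, cmax_ss = dose / x$v,
         n_intervals = 1L, converged = TRUE)
  } else {
    tau <- regimen$interval
    list(auc_tau_ss = dose / x$cl,
         cmax_ss = (dose / x$v) / (1 - exp(-k * tau)),
         n_intervals = 1L, converged = TRUE)
  }
}

#' @export
perturb_parameter.one_compartment_model <- function(x, parameter,
                                                    factor) {
  if (!parameter %in% c("cl", "v"))
    stop("unknown parameter '", parameter, "'")
  x[[parameter]] <- x[[parameter]] * factor
  x
}

#' @export
perturb_signature.one_compartment_model <- function(x) c(x$cl, x$v)
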