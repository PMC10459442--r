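#' Assemble a whole-body model
#'
#' Builds the state layout and the parameter set for the compiled ODE
#' system from a physiology, a drug and (optionally) a target.  Each
#' organ contributes five drug-related states (vascular plasma,
#' interstitial, endosomal free drug, free FcRn, drug-FcRn complex);
#' a central plasma pool closes the circulation.  When a target is
#' present, receptor and complex states (R, DR) are instantiated in the
#' central plasma and in the interstitial space of every organ with
#' positive expression weight.  Two cumulative elimination ledgers
#' (endosomal degradation, complex internalization) complete the state
#' vector.
#'
#' @param physiology a [load_physiology()] spec.
#' @param drug a [drug_properties()] object.
#' @param target a [target_properties()] object, or `NULL` for the
#'   linear (target-free) model.
#' @param flux_mode transcapillary exchange mode, `"single_sigma"`
#'   (default) or `"two_pore"`; see [two_pore_flux()].
#' @param sigma_lymph lymph reflection coefficient (default 0.2).
#' @param fcrn_dynamic if `TRUE`, free FcRn is a conserved dynamic
#'   state; if `FALSE` (default) it is clamped at its total
#'   concentration, which makes the target-free system exactly linear
#'   in dose (see [fcrn_endosome_rhs()]).
#' @param solver list with `rtol`, `atol` (nmol) and `h_init`.
#' @return A `mab_model` with elements `physiology`, `drug`, `target`,
#'   `state_names`, `params` (the compiled-model parameter list) and
#'   `solver`.
#' @export
build_model <- function(physiology, drug, target = NULL,
                        flux_mode = c("single_sigma", "two_pore"),
                        sigma_lymph = 0.2, fcrn_dynamic = FALSE,
                        solver = list(rtol = 1e-8, atol = 1e-10,
                                      h_init = 1e-4)) {
  flux_mode <- match.arg(flux_mode)
  validate_physiology(physiology)
  stopifnot(inherits(drug, "drug_properties"))
  org <- physiology$organs
  n <- nrow(org)

  cls <- lapply(seq_len(n), function(i)
    exchange_classes(org[i, ], drug, flux_mode))
  K <- nrow(cls[[1]])
  SIG <- t(vapply(cls, function(x) x$sigma, numeric(K)))
  PS <- t(vapply(cls, function(x) x$PS, numeric(K)))
  JF <- t(vapply(cls, function(x) ifelse(x$J > 0, x$J / sum(x$J), 0),
                 numeric(K)))
  dim(SIG) <- dim(PS) <- dim(JF) <- c(n, K)

  endo <- endosomal_defaults()
  has_target <- !is.null(target)
  v_c <- central_plasma_volume(physiology)

  params <- list(
    n_org = n,
    v_central = v_c,
    v_plasma = org$plasma_volume,
    v_interstitial = org$interstitial_volume,
    v_endosomal = org$endosomal_volume,
    q_plasma = org$blood_flow,
    q_lymph = org$lymph_flow,
    sigma = SIG, ps = PS, j_frac = JF,
    sigma_lymph = sigma_lymph,
    cl_up = physiology$uptake_clearance_per_L * org$endosomal_volume,
    k_deg_endo = endo$k_deg_endo,
    k_rec = endo$k_rec,
    f_recycle_plasma = endo$f_recycle_plasma,
    kon_fcrn = drug$kon_fcrn,
    koff_fcrn = drug$koff_fcrn,
    fcrn_conc = org$fcrn_concentration,
    fcrn_dynamic = fcrn_dynamic,
    has_target = has_target)

  state_names <- c("central.plasma",
                   as.vector(t(outer(org$name,
                                     c("plasma", "interstitial",
                                       "endosomal", "fcrn", "fcrn_complex"),
                                     paste, sep = "."))))
  expr_names <- character(0)
  if (has_target) {
    stopifnot(inherits(target, "target_properties"))
    r0 <- distribute_target(target$r0_reference,
                            setNames(org$expression_weight, org$name))
    expr_names <- names(r0$interstitial)
    expr_idx <- match(expr_names, org$name) - 1L
    params <- c(params, list(
      kon_target = target$kon,
      koff_target = target$koff,
      kdeg_target = target$kdeg,
      kint_target = target$kint,
      r0_central = r0$plasma * v_c,
      expr_idx = expr_idx,
      r0_interstitial = r0$interstitial *
        org$interstitial_volume[expr_idx + 1L]))
    state_names <- c(state_names, "central.R", "central.DR",
                     as.vector(t(outer(expr_names, c("R", "DR"),
                                       paste, sep = "."))))
  }
  state_names <- c(state_names, "eliminated.endosomal",
                   "eliminated.internalized")

  stopifnot(.cpp_state_dim(params) == length(state_names))
  structure(
    list(physiology = physiology, drug = drug, target = target,
         flux_mode = flux_mode, fcrn_dynamic = fcrn_dynamic,
         state_names = state_names, params = params,
         expressing_organs = expr_names, solver = solver),
    class = "mab_model")
}

#' @export
print.mab_model <- function(x, ...) {
  cat(sprintf("<mab_model> %s in %s (%d organs, %d states, %s)\n",
              x$drug$name, x$physiology$species,
              x$params$n_org, length(x$state_names),
              if (x$params$has_target) "TMDD" else "linear"))
  invisible(x)
}

# Indices of states that carry drug mass (for the ledger).
drug_state_idx <- function(model) {
  nm <- model$state_names
  which(!startsWith(nm, "eliminated.") &
          (nm == "central.plasma" |
             grepl("\\.(plasma|interstitial|endosomal|fcrn_complex|DR)$",
                   nm)))
}

# Initial condition: drug-free steady state.
initial_state <- function(model) {
  p <- model$params
  y <- numeric(length(model$state_names))
  names(y) <- model$state_names
  y[grepl("\\.fcrn$", model$state_names)] <-
    p$fcrn_conc * p$v_endosomal
  if (p$has_target) {
    y["central.R"] <- p$r0_central
    y[paste0(model$expressing_organs, ".R")] <- p$r0_interstitial
  }
  y
}

#' Simulate a dosing regimen
#'
#' Integrates the stiff whole-body system with dose events (constant
#' rate infusion into the central plasma pool, or bolus).  The dose in
#' nmol is `dose_per_kg * body_weight * 1e6 / molecular_weight`.
#'
#' @param model a [build_model()] object.
#' @param regimen a [dosing_regimen()].
#' @param body_weight kg; defaults to the physiology's body weight.
#' @param output_times sorted non-negative times (days) at which states
#'   are reported.
#' @param y0 optional initial state (advanced use: continuing a
#'   simulation); defaults to the drug-free steady state.
#' @param dosed0 drug amount (nmol) already administered before time 0
#'   when continuing from `y0`.
#' @return A `mab_sim` with `times`, `states` (matrix, nmol),
#'   `plasma_conc` (ug/mL), `profile` (a [concentration_profile()]),
#'   and `ledger` (data frame: time, dosed, in_system, eliminated,
#'   balance_error).
#' @export
simulate_regimen <- function(model, regimen, body_weight = NULL,
                             output_times, y0 = NULL, dosed0 = 0) {
  stopifnot(inherits(model, "mab_model"),
            inherits(regimen, "dosing_regimen"))
  if (is.unsorted(output_times, strictly = FALSE) ||
      any(output_times < 0))
    stop("output_times must be sorted and non-negative")
  if (is.null(body_weight)) body_weight <- model$physiology$body_weight
  stopifnot(body_weight > 0)

  dose_nmol <- mg_to_nmol(regimen$dose_per_kg * body_weight,
                          model$drug$molecular_weight)
  dur <- regimen$infusion_duration
  starts <- if (regimen$n_doses > 1L)
    (seq_len(regimen$n_doses) - 1L) * regimen$interval else 0
  t_end <- max(output_times)

  # piecewise-constant infusion schedule
  bounds <- sort(unique(c(0, starts, if (dur > 0) starts + dur, t_end)))
  bounds <- bounds[bounds <= t_end + 1e-12]
  if (max(bounds) < t_end) bounds <- c(bounds, t_end)
  rate_in <- function(t) {
    if (dur <= 0) return(0)
    if (any(t >= starts - 1e-12 & t < starts + dur - 1e-12))
      dose_nmol / dur else 0
  }

  y <- if (is.null(y0)) initial_state(model) else y0
  if (dur <= 0 && any(starts <= 1e-12)) y[1] <- y[1] + dose_nmol
  n_out <- length(output_times)
  states <- matrix(0, n_out, length(y),
                   dimnames = list(NULL, model$state_names))
  taken <- output_times <= 1e-12
  if (any(taken)) states[taken, ] <- matrix(rep(y, sum(taken)),
                                            ncol = length(y), byrow = TRUE)
  sv <- model$solver
  for (k in seq_len(length(bounds) - 1L)) {
    t0 <- bounds[k]; t1 <- bounds[k + 1L]
    if (t1 - t0 < 1e-12) next
    # bolus events at interior piece starts
    if (dur <= 0 && any(abs(starts - t0) < 1e-12) && t0 > 1e-12)
      y[1] <- y[1] + dose_nmol
    sel <- output_times > t0 + 1e-12 & output_times <= t1 + 1e-12
    res <- tryCatch(
      .cpp_integrate_piece(y, t0, t1, output_times[sel],
                           rate_in((t0 + min(t1, t0 + 1e-9)) / 2),
                           model$params, sv$rtol, sv$atol, sv$h_init),
      error = function(e)
        stop("ODE solver failed on [", signif(t0, 6), ", ", signif(t1, 6),
             "] days: ", conditionMessage(e), call. = FALSE))
    if (any(sel)) states[sel, ] <- res$states
    y <- as.numeric(res$y_end)
    names(y) <- model$state_names
  }

  dosed <- dosed0 + vapply(output_times, function(t) {
    if (dur <= 0)
      dose_nmol * sum(starts <= t + 1e-12)
    else
      dose_nmol / dur * sum(pmin(pmax(t - starts, 0), dur))
  }, numeric(1))
  in_sys <- rowSums(states[, drug_state_idx(model), drop = FALSE])
  elim <- states[, "eliminated.endosomal"] +
    states[, "eliminated.internalized"]
  balance <- (dosed - in_sys - elim) / pmax(dosed, 1e-300)
  balance[dosed == 0] <- 0

  v_c <- model$params$v_central
  conc <- nmolL_to_ugml(states[, "central.plasma"] / v_c,
                        model$drug$molecular_weight)
  profile <- concentration_profile(
    study_id = paste0("sim_", model$physiology$species),
    population = model$physiology$species,
    dose_per_kg = regimen$dose_per_kg,
    times = output_times, concentrations = conc,
    n_doses = regimen$n_doses, interval = regimen$interval,
    drug = model$drug$name, validate_positive = FALSE)

  structure(
    list(times = output_times, states = states, plasma_conc = conc,
         profile = profile,
         ledger = data.frame(time = output_times, dosed = dosed,
                             in_system = in_sys, eliminated = elim,
                             balance_error = balance),
         final_state = y, dosed_total = max(dosed)),
    class = "mab_sim")
}

#' @export
print.mab_sim <- function(x, ...) {
  cat(sprintf(
    "<mab_sim> %d times over %.3g days, Cmax %.3g ug/mL, |balance| <= %.2g\n",
    length(x$times), max(x$times), max(x$plasma_conc),
    max(abs(x$ledger$balance_error))))
  invisible(x)
}

#' Terminal half-life from the log-linear terminal phase
#'
#' Least-squares slope of log concentration over the terminal window
#' (by default the last 40 percent of the time span); half-life is
#' ln(2) divided by the negative slope.
#'
#' @param profile a [concentration_profile()].
#' @param window_fraction fraction of the time span (from the end) used
#'   as the terminal window.
#' @return half-life in days.
#' @export
terminal_half_life <- function(profile, window_fraction = 0.4) {
  tt <- profile$times
  cc <- profile$concentrations
  t_cut <- max(tt) - window_fraction * (max(tt) - min(tt))
  sel <- tt >= t_cut & cc > 0
  if (sum(sel) < 3)
    stop("need at least 3 positive points in the terminal window")
  lc <- log(cc[sel])
  if (any(diff(lc) > 1e-9))
    stop("terminal phase is not monotonically decreasing")
  slope <- coef(lm(lc ~ tt[sel]))[[2]]
  if (slope >= 0) stop("terminal phase is not decreasing")
  log(2) / (-slope)
}
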