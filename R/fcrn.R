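#' Endosomal FcRn salvage kinetics (single organ)
#'
#' Right-hand side of the non-equilibrium endosomal submodel for one
#' organ, in amounts (nmol) and nmol/day.  Free drug in the endosome is
#' fed by first-order uptake from organ plasma and interstitium, binds
#' FcRn at `kon_fcrn`, and is degraded at `k_deg_endo` if unbound.  The
#' drug-FcRn complex dissociates at `koff_fcrn` or exits by recycling at
#' `k_rec`, returning the drug to plasma (fraction `f_recycle_plasma`)
#' or interstitium and the receptor to the endosome, so that total FcRn
#' (free + bound) is conserved.
#'
#' The compiled whole-body model uses these same equations.  By default
#' it runs them in a linearized form in which free FcRn is clamped at
#' its total concentration: therapeutic antibody occupies a negligible
#' share of FcRn (which in vivo is heavily buffered by endogenous IgG),
#' and clamping makes the target-free model exactly linear in dose.
#' Set `fcrn_dynamic = TRUE` in [build_model()] for the conserved
#' dynamic form below.
#'
#' @param state named numeric: `free` (endosomal free drug, nmol),
#'   `fcrn` (free receptor, nmol), `complex` (nmol); all >= 0.
#' @param organ one row of a physiology organ table (for
#'   `endosomal_volume`).
#' @param drug a [drug_properties()] object (`kon_fcrn`, `koff_fcrn`).
#' @param rates list with `cl_up` (L/day), `k_deg_endo`, `k_rec`
#'   (1/day), `f_recycle_plasma`, and the feeding concentrations
#'   `c_plasma`, `c_interstitial` (nmol/L, default 0).
#' @return named list of derivatives (nmol/day): `free`, `fcrn`,
#'   `complex`, plus the side fluxes `to_plasma`, `to_interstitial`,
#'   `degraded`.
#' @export
fcrn_endosome_rhs <- function(state, organ, drug, rates) {
  if (any(state < 0)) stop("endosomal state must be non-negative")
  need <- c("free", "fcrn", "complex")
  if (!all(need %in% names(state)))
    stop("state must have elements: ", paste(need, collapse = ", "))
  r <- modifyList(list(c_plasma = 0, c_interstitial = 0), rates)
  v_e <- organ$endosomal_volume
  fc_conc <- state[["fcrn"]] / v_e
  bind <- drug$kon_fcrn * state[["free"]] * fc_conc
  diss <- drug$koff_fcrn * state[["complex"]]
  rec <- r$k_rec * state[["complex"]]
  deg <- r$k_deg_endo * state[["free"]]
  uptake <- r$cl_up * (r$c_plasma + r$c_interstitial)
  list(free = uptake - bind + diss - deg,
       fcrn = -bind + diss + rec,
       complex = bind - diss - rec,
       to_plasma = r$f_recycle_plasma * rec,
       to_interstitial = (1 - r$f_recycle_plasma) * rec,
       degraded = deg)
}
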