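#' Target-mediated drug disposition kinetics (one compartment)
#'
#' The three-equation TMDD block for a turning-over soluble target:
#' \deqn{dR/dt = k_{syn} - k_{deg} R - k_{on} D R + k_{off} DR}
#' \deqn{dD/dt \mathrel{+}= -k_{on} D R + k_{off} DR}
#' \deqn{dDR/dt = k_{on} D R - k_{off} DR - k_{int} DR}
#' with \eqn{k_{syn} = k_{deg} R_0} locally, so that the drug-free
#' steady state is \eqn{R = R_0}.  All quantities are concentrations
#' (nmol/L) and rates 1/day.
#'
#' @param d free drug concentration.
#' @param r free target concentration.
#' @param dr complex concentration.
#' @param target a [target_properties()] object.
#' @param r0_local local steady-state target concentration, nmol/L.
#' @return list with `dR`, `dD` (the drug's binding contribution) and
#'   `dDR`, each in nmol/L/day.
#' @export
#' @examples
#' tp <- target_properties(kd_target = 0.25, koff = 0.5, kdeg = 0.1,
#'                         kint = 0.3, r0_reference = 1)
#' tmdd_rhs(1, 1, 0, tp, 1)
tmdd_rhs <- function(d, r, dr, target, r0_local) {
  if (any(c(d, r, dr, r0_local) < 0))
    stop("TMDD states and r0_local must be non-negative")
  bind <- target$kon * d * r
  diss <- target$koff * dr
  ksyn <- target$kdeg * r0_local
  list(dR = ksyn - target$kdeg * r - bind + diss,
       dD = -bind + diss,
       dDR = bind - diss - target$kint * dr)
}

#' Distribute the reference target concentration across compartments
#'
#' The plasma compartment receives the reference concentration; each
#' expressing organ's interstitial space receives the reference scaled
#' by its expression weight, normalized so that the maximum weight maps
#' to 1 (the most strongly expressing tissue matches the reference).
#'
#' @param r0_reference plasma steady-state target concentration, nmol/L.
#' @param expression_weights named non-negative weights per organ.
#' @return list with `plasma` (nmol/L) and `interstitial`, a named
#'   vector over the expressing organs (weight > 0) only.
#' @export
distribute_target <- function(r0_reference, expression_weights) {
  if (r0_reference < 0) stop("r0_reference must be non-negative")
  w <- expression_weights
  if (length(w) == 0 || all(w == 0))
    stop("target present but all expression weights are zero")
  if (any(w < 0)) stop("expression weights must be non-negative")
  expr <- w[w > 0]
  list(plasma = r0_reference,
       interstitial = r0_reference * expr / max(expr))
}
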