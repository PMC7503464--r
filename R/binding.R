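## Two-state binding equilibrium: E + L <-> EL, Kd = [E][L]/[EL].
## Concentrations are in uM throughout; enthalpies in kcal/mol.

#' Gas constant in kcal mol-1 K-1
#' @noRd
.R_KCAL <- 1.98720425e-3

#' Equilibrium binding parameters for one enzyme-ligand pair
#'
#' Bundles the dissociation constant measured at a reference temperature
#' (typically by isothermal titration calorimetry, ITC) with the binding
#' enthalpy, so that `Kd` can be projected to the post-jump temperature by
#' the van 't Hoff relation.
#'
#' @param kd_ref Dissociation constant at `T_ref` (uM). Must be positive.
#' @param delta_H Association enthalpy (kcal mol-1); negative values mean
#'   exothermic binding, the usual ITC sign convention.
#' @param T_ref Reference temperature in Kelvin (default 298.15 K = 25 C).
#' @param delta_Cp Optional heat-capacity change (kcal mol-1 K-1). Default 0
#'   (constant-enthalpy van 't Hoff).
#' @return An object of class `"binding_parameters"`.
#' @examples
#' bp <- binding_parameters(kd_ref = 4.7, delta_H = -10)
#' adjust_kd(bp, 309.15)
#' @export
binding_parameters <- function(kd_ref, delta_H, T_ref = 298.15, delta_Cp = 0) {
  stopifnot(is.numeric(kd_ref), length(kd_ref) == 1L, is.finite(kd_ref),
            is.numeric(delta_H), length(delta_H) == 1L, is.finite(delta_H),
            is.numeric(T_ref), length(T_ref) == 1L, is.finite(T_ref))
  if (kd_ref <= 0) stop("'kd_ref' must be positive (uM)")
  if (T_ref <= 0) stop("'T_ref' must be a positive absolute temperature (K)")
  structure(list(kd_ref = kd_ref, delta_H = delta_H, T_ref = T_ref,
                 delta_Cp = delta_Cp),
            class = "binding_parameters")
}

#' @export
print.binding_parameters <- function(x, ...) {
  cat("Binding parameters:\n")
  cat(sprintf("  Kd = %.3g uM at %.2f K (%.1f C)\n",
              x$kd_ref, x$T_ref, x$T_ref - 273.15))
  cat(sprintf("  delta H (association) = %.3g kcal/mol\n", x$delta_H))
  if (x$delta_Cp != 0)
    cat(sprintf("  delta Cp = %.3g kcal/mol/K\n", x$delta_Cp))
  invisible(x)
}

#' Project a dissociation constant to another temperature
#'
#' Integrated van 't Hoff relation applied to the association constant
#' `Ka = 1/Kd`: with constant enthalpy,
#' `ln Ka(T2) - ln Ka(T1) = -(dH/R) (1/T2 - 1/T1)`, so an exothermic
#' complex (`delta_H < 0`) binds more weakly when heated. If a non-zero
#' `delta_Cp` is supplied the standard temperature-dependent-enthalpy
#' extension is used.
#'
#' @param params A [binding_parameters()] object.
#' @param T_target Target absolute temperature (K).
#' @return Kd at `T_target`, in uM.
#' @examples
#' adjust_kd(binding_parameters(4.7, -10, T_ref = 302.15), 309.15)  # ~6.85 uM
#' @export
adjust_kd <- function(params, T_target) {
  stopifnot(inherits(params, "binding_parameters"),
            is.numeric(T_target), length(T_target) == 1L)
  if (!is.finite(T_target) || T_target <= 0)
    stop("'T_target' must be a positive absolute temperature (K)")
  T1 <- params$T_ref
  T2 <- T_target
  ## ln Kd(T2) - ln Kd(T1) = (dH/R)(1/T2 - 1/T1)  [sign flipped from Ka]
  lnkd <- log(params$kd_ref) + params$delta_H / .R_KCAL * (1 / T2 - 1 / T1)
  if (params$delta_Cp != 0) {
    ## dH(T) = dH(T1) + dCp (T - T1); integrate d lnKa/dT = dH/(R T^2)
    dCp <- params$delta_Cp
    lnkd <- log(params$kd_ref) +
      (params$delta_H - dCp * T1) / .R_KCAL * (1 / T2 - 1 / T1) -
      dCp / .R_KCAL * log(T2 / T1)
  }
  exp(lnkd)
}

#' Free and bound concentrations for two-state binding
#'
#' Solves the mass-action equilibrium for a single-site complex. The bound
#' concentration is the physical root of
#' `EL^2 - (E_total + L_total + Kd) EL + E_total L_total = 0`, computed in
#' the numerically stable product form so that the case `Kd << totals`
#' does not suffer cancellation.
#'
#' @param E_total Total enzyme concentration (uM).
#' @param L_total Total ligand concentration (uM).
#' @param Kd Dissociation constant (uM), positive.
#' @param temperature Optional absolute temperature (K) recorded in the
#'   result, for bookkeeping only.
#' @return An object of class `"equilibrium_state"`: a list with `E_free`,
#'   `L_free`, `EL`, `sum_free` (= `E_free + L_free`, the concentration
#'   axis of relaxation-rate plots) and `temperature`, all in uM.
#' @examples
#' free_concentrations(100, 50, 10)
#' @export
free_concentrations <- function(E_total, L_total, Kd, temperature = NA_real_) {
  stopifnot(is.numeric(E_total), is.numeric(L_total), is.numeric(Kd),
            length(E_total) == 1L, length(L_total) == 1L, length(Kd) == 1L)
  if (E_total < 0 || L_total < 0) stop("total concentrations must be >= 0")
  if (!is.finite(Kd) || Kd <= 0) stop("'Kd' must be positive")
  b <- E_total + L_total + Kd
  disc <- b * b - 4 * E_total * L_total
  ## disc >= Kd^2 > 0 algebraically; guard rounding
  root <- sqrt(max(disc, 0))
  ## smaller root via product form: EL = 2 E L / (b + sqrt(disc))
  EL <- 2 * E_total * L_total / (b + root)
  EL <- min(EL, E_total, L_total)     # clamp rounding overshoot
  E_free <- E_total - EL
  L_free <- L_total - EL
  structure(list(E_free = E_free, L_free = L_free, EL = EL,
                 sum_free = E_free + L_free, temperature = temperature),
            class = "equilibrium_state")
}

#' @export
print.equilibrium_state <- function(x, ...) {
  cat(sprintf("Equilibrium state: E_free %.4g, L_free %.4g, EL %.4g uM (sum free %.4g)\n",
              x$E_free, x$L_free, x$EL, x$sum_free))
  invisible(x)
}

#' Sum of free concentrations at the post-jump temperature
#'
#' Convenience wrapper used by the kinetics pipeline: adjusts Kd to
#' `T_target` and returns `E_free + L_free` there.
#'
#' @inheritParams free_concentrations
#' @param params A [binding_parameters()] object.
#' @param T_target Absolute temperature (K) after the jump.
#' @return Sum of free enzyme and ligand concentrations (uM).
#' @export
sum_free_at <- function(params, E_total, L_total, T_target) {
  kd <- adjust_kd(params, T_target)
  free_concentrations(E_total, L_total, kd, temperature = T_target)$sum_free
}
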