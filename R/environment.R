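# Thermodynamic environment and molecular parameters of the two-state
# (protein-relaxation) charge-recombination model.

#' Boltzmann constant in meV/K
#'
#' All free-energy gaps in this package are expressed in meV, lifetimes in ns
#' (ps for the femtosecond module), and temperatures in K.
#' @export
KB_MEV_K <- 0.08617

#' Thermodynamic environment
#'
#' @param temperature_K Absolute temperature in K. Must be positive; values
#'   outside 70--320 K trigger a warning because the kinetic model has only
#'   been exercised in that range.
#' @return An object of class `rc_environment` with fields `T` (K) and
#'   `kB` (meV/K).
#' @examples
#' env <- rc_environment(298)
#' kT(env) # thermal energy in meV
#' @export
rc_environment <- function(temperature_K) {
  if (!is.numeric(temperature_K) || length(temperature_K) != 1L ||
      !is.finite(temperature_K) || temperature_K <= 0) {
    stop("invalid-parameter: temperature must be a single positive number",
         call. = FALSE)
  }
  if (temperature_K < 70 || temperature_K > 320) {
    warning("temperature ", temperature_K,
            " K is outside the supported 70-320 K range", call. = FALSE)
  }
  structure(list(T = temperature_K, kB = KB_MEV_K), class = "rc_environment")
}

#' Thermal energy kT in meV
#' @param env An [rc_environment()].
#' @return kT in meV.
#' @export
kT <- function(env) {
  stopifnot(inherits(env, "rc_environment"))
  env$kB * env$T
}

#' Molecular parameters of the relaxation scheme
#'
#' Parameters of the one-step protein-relaxation model of P+HA- charge
#' recombination: the radical pair is formed in an unrelaxed conformation
#' (state 1) separated from P+BA- by a gap `dG1`, and relaxes with lifetime
#' `tau12` to a conformation (state 2) with a larger gap `dG2`. Each state
#' recombines thermally through P+BA- (intrinsic lifetime `tauPB`), directly
#' by superexchange (`tauDir1`, `tauDir2`) or to the donor triplet
#' (`tauTrip1`, `tauTrip2`). An infinite lifetime disables a channel.
#'
#' @param dG1,dG2 Free-energy gaps (meV) between P+BA- and the unrelaxed /
#'   relaxed P+HA- state. `dG2 >= dG1` (the gap grows upon relaxation).
#' @param tauPB Intrinsic P+BA- -> ground recombination lifetime (ns).
#' @param tau12 Protein relaxation lifetime (ns); `Inf` disables relaxation.
#' @param tauDir1,tauDir2 Direct (temperature-independent) recombination
#'   lifetimes (ns); default disabled.
#' @param tauTrip1,tauTrip2 Triplet-formation lifetimes (ns); default disabled.
#' @return An object of class `molecular_params`.
#' @export
molecular_params <- function(dG1, dG2, tauPB, tau12,
                             tauDir1 = Inf, tauDir2 = Inf,
                             tauTrip1 = Inf, tauTrip2 = Inf) {
  taus <- c(tauPB = tauPB, tau12 = tau12, tauDir1 = tauDir1,
            tauDir2 = tauDir2, tauTrip1 = tauTrip1, tauTrip2 = tauTrip2)
  if (any(!is.numeric(taus)) || any(is.na(taus)) || any(taus <= 0)) {
    stop("invalid-parameter: all lifetimes must be positive (Inf allowed)",
         call. = FALSE)
  }
  if (!is.finite(tauPB)) {
    stop("invalid-parameter: tauPB must be finite", call. = FALSE)
  }
  if (!is.finite(dG1) || !is.finite(dG2)) {
    stop("invalid-parameter: free-energy gaps must be finite", call. = FALSE)
  }
  if (dG2 < dG1) {
    stop("invalid-parameter: dG2 must be >= dG1 (the gap increases upon relaxation)",
         call. = FALSE)
  }
  structure(list(dG1 = dG1, dG2 = dG2, tauPB = tauPB, tau12 = tau12,
                 tauDir1 = tauDir1, tauDir2 = tauDir2,
                 tauTrip1 = tauTrip1, tauTrip2 = tauTrip2),
            class = "molecular_params")
}

#' Thermally activated recombination lifetime
#'
#' Lifetime of charge recombination proceeding through thermal population of
#' P+BA-: `tau_T = tauPB * (1 + exp(dG / kT))`. Strictly increasing in `dG`
#' and, for positive `dG`, in 1/T.
#'
#' @param tauPB Intrinsic P+BA- recombination lifetime (ns), positive.
#' @param dG Free-energy gap (meV) between P+BA- and P+HA-.
#' @param env An [rc_environment()].
#' @return Lifetime in ns.
#' @examples
#' thermal_lifetime(0.2, 250, rc_environment(298)) # > 1000 ns
#' thermal_lifetime(0.2, 0, rc_environment(298))   # exactly 2 * tauPB
#' @export
thermal_lifetime <- function(tauPB, dG, env) {
  stopifnot(inherits(env, "rc_environment"))
  if (!is.numeric(tauPB) || any(tauPB <= 0)) {
    stop("invalid-parameter: tauPB must be positive", call. = FALSE)
  }
  tauPB * (1 + exp(dG / kT(env)))
}

#' Boltzmann occupancy of the P+HA- side of the equilibrium
#'
#' Probability `P1 = exp(dG/kT) / (1 + exp(dG/kT))` that the equilibrated
#' P+BA-/P+HA- pool occupies the lower-lying P+HA- state. Tends to 1 for a
#' large gap and to 1/2 for an isoenergetic pair.
#'
#' @inheritParams thermal_lifetime
#' @return A fraction in (0, 1).
#' @export
equilibrium_population <- function(dG, env) {
  stopifnot(inherits(env, "rc_environment"))
  # logistic form is overflow-safe for large |dG|
  stats::plogis(dG / kT(env))
}
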