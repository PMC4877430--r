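# First-order compartmental kinetic networks: construction, rate matrices,
# analytic (eigen) solution and exact multi-exponential representation.

#' First-order kinetic scheme
#'
#' A directed network of compartments with first-order rate constants.
#' Sinks are absorbing states (no outgoing rates allowed).
#'
#' @param compartments Character vector of state labels (ordered).
#' @param rates Data frame with columns `from`, `to`, `rate` (ns^-1, >= 0).
#'   Rates equal to zero are dropped.
#' @param initial Named numeric vector of initial populations; missing
#'   compartments default to 0. Must sum to 1.
#' @param sinks Character vector of absorbing state labels (subset of
#'   `compartments`).
#' @return An object of class `kinetic_scheme`.
#' @export
kinetic_scheme <- function(compartments, rates, initial, sinks = character(0)) {
  stopifnot(is.character(compartments), anyDuplicated(compartments) == 0)
  rates <- as.data.frame(rates)
  stopifnot(all(c("from", "to", "rate") %in% names(rates)))
  if (any(!rates$from %in% compartments) || any(!rates$to %in% compartments)) {
    stop("rate edge references unknown compartment", call. = FALSE)
  }
  if (any(!is.finite(rates$rate)) || any(rates$rate < 0)) {
    stop("invalid-parameter: rate constants must be finite and >= 0",
         call. = FALSE)
  }
  rates <- rates[rates$rate > 0, , drop = FALSE]
  if (!all(sinks %in% compartments)) {
    stop("sink label not among compartments", call. = FALSE)
  }
  if (any(rates$from %in% sinks)) {
    stop("sinks are absorbing: no rate may leave a sink", call. = FALSE)
  }
  init <- stats::setNames(numeric(length(compartments)), compartments)
  init[names(initial)] <- initial
  if (abs(sum(init) - 1) > 1e-10) {
    stop("initial populations must sum to 1", call. = FALSE)
  }
  structure(list(compartments = compartments, rates = rates,
                 initial = init, sinks = sinks),
            class = "kinetic_scheme")
}

#' Rate matrix of a kinetic scheme
#'
#' Builds the generator K of `dP/dt = K P`. Off-diagonal `K[i, j]` is the
#' rate from compartment j to compartment i; diagonal entries are minus the
#' total outflow. With sinks included every column sums to zero (population
#' conservation); with sinks excluded columns sum to <= 0.
#'
#' @param scheme A [kinetic_scheme()].
#' @param include_sinks Keep absorbing states in the matrix?
#' @return Square numeric matrix (ns^-1) with dimnames.
#' @export
rate_matrix <- function(scheme, include_sinks = TRUE) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  comps <- scheme$compartments
  n <- length(comps)
  K <- matrix(0, n, n, dimnames = list(comps, comps))
  for (i in seq_len(nrow(scheme$rates))) {
    r <- scheme$rates[i, ]
    K[r$to, r$from] <- K[r$to, r$from] + r$rate
  }
  diag(K) <- diag(K) - colSums(K)
  if (!include_sinks && length(scheme$sinks)) {
    keep <- setdiff(comps, scheme$sinks)
    K <- K[keep, keep, drop = FALSE]
  }
  K
}

#' Build the two-state relaxation scheme for P+HA- recombination
#'
#' Constructs the charge-recombination network in which the radical pair
#' relaxes from an unrelaxed to a relaxed conformation while recombining
#' thermally (through P+BA-), directly, or to the donor triplet.
#'
#' In `"rapid-equilibrium"` mode each P+HA- form and its P+BA- partner are
#' collapsed into one pool state. Pool rates carry the Boltzmann occupancies:
#' the thermal channel proceeds at `(1 - P_i)/tauPB` (equivalently
#' `1/thermal_lifetime(tauPB, dG_i, env)`), while relaxation, direct
#' recombination and triplet formation act on the P+HA- configuration and
#' proceed at `P_i/tau12`, `P_i/tauDir_i` and `P_i/tauTrip_i`. This matches
#' the target-analysis identities `tau12 = P1 * tau_c` and
#' `tauPB = (1 - P1) * tau_e`.
#'
#' In `"explicit"` mode each pool is expanded into a discrete P+BA- state
#' exchanging with its P+HA- partner with detailed balance
#' (forward/backward ratio `exp(dG_i/kT)`) at a user-chosen equilibration
#' rate `k_eq`; P+BA- decays to ground at `1/tauPB` and the intrinsic
#' channel lifetimes act unweighted on the explicit states. For `k_eq` much
#' faster than every decay the slow eigenvalues converge to the
#' rapid-equilibrium ones.
#'
#' Relaxation is one-way (no back-transfer from the relaxed state).
#'
#' @param mp A [molecular_params()].
#' @param env An [rc_environment()].
#' @param mode `"rapid-equilibrium"` (default) or `"explicit"`.
#' @param k_eq Equilibration rate (ns^-1) for explicit mode; defaults to
#'   100 times the fastest decay rate in the scheme.
#' @return A [kinetic_scheme()]. Compartments are `PHA1`, `PHA2` (plus
#'   `PBA1`, `PBA2` in explicit mode) with sinks `ground` and `triplet`.
#' @export
build_recombination_scheme <- function(mp, env,
                                       mode = c("rapid-equilibrium", "explicit"),
                                       k_eq = NULL) {
  stopifnot(inherits(mp, "molecular_params"), inherits(env, "rc_environment"))
  mode <- match.arg(mode)
  P1 <- equilibrium_population(mp$dG1, env)
  P2 <- equilibrium_population(mp$dG2, env)

  if (mode == "rapid-equilibrium") {
    rates <- data.frame(
      from = c("PHA1", "PHA1", "PHA1", "PHA2", "PHA2"),
      to   = c("ground", "triplet", "PHA2", "ground", "triplet"),
      rate = c((1 - P1) / mp$tauPB + P1 / mp$tauDir1,
               P1 / mp$tauTrip1,
               P1 / mp$tau12,
               (1 - P2) / mp$tauPB + P2 / mp$tauDir2,
               P2 / mp$tauTrip2),
      stringsAsFactors = FALSE
    )
    return(kinetic_scheme(
      compartments = c("PHA1", "PHA2", "ground", "triplet"),
      rates = rates,
      initial = c(PHA1 = 1),
      sinks = c("ground", "triplet")
    ))
  }

  # explicit mode: discrete P+BA- conformers in detailed balance with each form
  kTv <- kT(env)
  if (is.null(k_eq)) {
    decay <- c(1 / mp$tauPB, 1 / mp$tau12, 1 / mp$tauDir1, 1 / mp$tauDir2,
               1 / mp$tauTrip1, 1 / mp$tauTrip2)
    k_eq <- 100 * max(decay[is.finite(decay)])
  }
  if (!is.numeric(k_eq) || k_eq <= 0) {
    stop("configuration error: explicit mode requires a positive k_eq",
         call. = FALSE)
  }
  rates <- data.frame(
    from = c("PBA1", "PHA1", "PBA1",
             "PBA2", "PHA2", "PBA2",
             "PHA1", "PHA1", "PHA1",
             "PHA2", "PHA2"),
    to   = c("PHA1", "PBA1", "ground",
             "PHA2", "PBA2", "ground",
             "PHA2", "ground", "triplet",
             "ground", "triplet"),
    rate = c(k_eq, k_eq * exp(-mp$dG1 / kTv), 1 / mp$tauPB,
             k_eq, k_eq * exp(-mp$dG2 / kTv), 1 / mp$tauPB,
             1 / mp$tau12, 1 / mp$tauDir1, 1 / mp$tauTrip1,
             1 / mp$tauDir2, 1 / mp$tauTrip2),
    stringsAsFactors = FALSE
  )
  kinetic_scheme(
    compartments = c("PBA1", "PHA1", "PBA2", "PHA2", "ground", "triplet"),
    rates = rates,
    initial = c(PBA1 = 1 - P1, PHA1 = P1),  # pool starts equilibrated
    sinks = c("ground", "triplet")
  )
}

# Eigen-decomposition of the kinetic (non-sink) block with a usability check.
# Returns NULL when the block is near-defective or has oscillatory modes, in
# which case callers fall back to numerical integration.
.kinetic_eigen <- function(scheme) {
  A <- rate_matrix(scheme, include_sinks = FALSE)
  eg <- eigen(A)
  V <- eg$vectors
  lam <- eg$values
  if (is.complex(lam)) {
    if (max(abs(Im(lam))) > 1e-8 * max(abs(Re(lam)), 1e-12)) return(NULL)
    lam <- Re(lam); V <- Re(V)
  }
  rc <- tryCatch(rcond(V), error = function(e) 0)
  if (!is.finite(rc) || rc < 1e-10) return(NULL)
  beta <- solve(V, scheme$initial[rownames(A)])
  list(A = A, V = V, lambda = lam, beta = beta, kinetic = rownames(A))
}

#' Solve compartment populations over time
#'
#' Integrates `dP/dt = K P` for a kinetic scheme. When the kinetic block is
#' diagonalizable the analytic eigen-solution is used (sink populations from
#' the integrated inflow); otherwise the solver falls back to stiff numerical
#' integration with [deSolve::lsoda()].
#'
#' @param scheme A [kinetic_scheme()].
#' @param times Sorted non-negative time grid (ns).
#' @return Object of class `population_trajectory`: list with `times` and a
#'   `populations` matrix (time x compartment, sinks included).
#' @export
solve_populations <- function(scheme, times) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  if (is.unsorted(times) || any(times < 0)) {
    stop("times must be sorted and non-negative", call. = FALSE)
  }
  comps <- scheme$compartments
  sinks <- scheme$sinks
  dec <- .kinetic_eigen(scheme)

  if (is.null(dec)) {
    K <- rate_matrix(scheme, include_sinks = TRUE)
    p0 <- scheme$initial
    # lsoda needs t = 0 present for the initial state
    tt <- times
    add0 <- tt[1] > 0
    if (add0) tt <- c(0, tt)
    sol <- deSolve::lsoda(
      y = p0, times = tt,
      func = function(t, y, parms) list(parms %*% y), parms = K,
      rtol = 1e-10, atol = 1e-12
    )
    if (attr(sol, "istate")[1] < 0) {
      stop("numerical error: stiff integration of the rate matrix failed",
           call. = FALSE)
    }
    P <- sol[, comps, drop = FALSE]
    if (add0) P <- P[-1, , drop = FALSE]
    rownames(P) <- NULL
    return(structure(list(times = times, populations = P,
                          method = "numeric"),
                     class = "population_trajectory"))
  }

  lam <- dec$lambda
  if (any(abs(lam) < 1e-14)) {
    stop("numerical error: non-decaying kinetic compartment; declare it a sink",
         call. = FALSE)
  }
  E <- exp(outer(times, lam))                       # nt x k
  Pk <- E %*% t(dec$V %*% diag(dec$beta, length(lam)))  # kinetic populations
  colnames(Pk) <- dec$kinetic

  P <- matrix(0, length(times), length(comps), dimnames = list(NULL, comps))
  P[, dec$kinetic] <- Pk
  if (length(sinks)) {
    K <- rate_matrix(scheme, include_sinks = TRUE)
    R <- K[sinks, dec$kinetic, drop = FALSE]        # inflow rates into sinks
    # s(t) = s0 + R V diag(beta) (exp(lambda t) - 1) / lambda
    W <- R %*% dec$V %*% diag(dec$beta / lam, length(lam))  # nsink x k
    S <- sweep(E, 2, 1) %*% t(W)                    # nt x nsink
    P[, sinks] <- sweep(S, 2, scheme$initial[sinks], `+`)
  }
  structure(list(times = times, populations = P, method = "eigen"),
            class = "population_trajectory")
}

#' Exact multi-exponential representation of a weighted population signal
#'
#' Expresses `signal(t) = sum_c w_c P_c(t)` exactly as
#' `sum_j A_j exp(-t/tau_j) + A0`, with lifetimes equal to minus the inverse
#' eigenvalues of the kinetic block, amplitudes from the eigenvectors and
#' weights, and the offset equal to the asymptotic signal of the populated
#' sinks.
#'
#' @param scheme A [kinetic_scheme()].
#' @param weights Named numeric vector of signal coefficients, one per
#'   compartment (sinks included; missing names default to 0).
#' @return List with `lifetimes` (ns, ascending), `amplitudes` (same order)
#'   and `offset`. Class `apparent_decay`.
#' @export
apparent_decay <- function(scheme, weights) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  comps <- scheme$compartments
  w <- stats::setNames(numeric(length(comps)), comps)
  w[names(weights)] <- weights
  dec <- .kinetic_eigen(scheme)
  if (is.null(dec)) {
    stop("numerical error: kinetic block is defective; no exact exponential form",
         call. = FALSE)
  }
  lam <- dec$lambda
  if (any(lam >= -1e-14)) {
    stop("numerical error: non-decaying kinetic compartment; declare it a sink",
         call. = FALSE)
  }
  wk <- w[dec$kinetic]
  amp <- as.numeric((wk %*% dec$V) * dec$beta)      # kinetic contribution
  offset <- 0
  sinks <- scheme$sinks
  if (length(sinks)) {
    K <- rate_matrix(scheme, include_sinks = TRUE)
    R <- K[sinks, dec$kinetic, drop = FALSE]
    ws <- w[sinks]
    # sink contribution per eigenmode and asymptotic offset
    amp <- amp + as.numeric((ws %*% R %*% dec$V) * dec$beta / lam)
    s_inf <- scheme$initial[sinks] -
      as.numeric(R %*% dec$V %*% (dec$beta / lam))
    offset <- sum(ws * s_inf)
  }
  ord <- order(-1 / lam)
  structure(list(lifetimes = (-1 / lam)[ord], amplitudes = amp[ord],
                 offset = offset),
            class = "apparent_decay")
}

#' Evaluate an apparent-decay signal on a time grid
#' @param ad An [apparent_decay()] result.
#' @param times Time grid (ns).
#' @return Numeric signal values.
#' @export
eval_apparent_decay <- function(ad, times) {
  stopifnot(inherits(ad, "apparent_decay"))
  E <- exp(outer(times, -1 / ad$lifetimes))
  as.numeric(E %*% ad$amplitudes) + ad$offset
}
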