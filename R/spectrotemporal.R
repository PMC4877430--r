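# Global lifetime analysis (DADS) and compartmental target analysis (SADS)
# of femtosecond wavelength x time absorption-difference matrices.

#' Spectro-temporal absorption-difference matrix
#'
#' @param wavelengths Wavelength grid (nm), ascending.
#' @param times Delay grid (ps); may be irregular.
#' @param deltaA Matrix of absorbance changes, wavelength x time.
#' @param irf List with `t0` (ps) and `fwhm` (ps) of the Gaussian IRF.
#' @return Object of class `ta_matrix`.
#' @export
ta_matrix <- function(wavelengths, times, deltaA,
                      irf = list(t0 = 0, fwhm = 0.4)) {
  deltaA <- as.matrix(deltaA)
  if (nrow(deltaA) != length(wavelengths) || ncol(deltaA) != length(times)) {
    stop("deltaA must be wavelength x time and match the grids", call. = FALSE)
  }
  if (any(diff(wavelengths) <= 0)) {
    stop("wavelengths must be ascending", call. = FALSE)
  }
  if (is.null(irf$t0) || is.null(irf$fwhm) || irf$fwhm <= 0) {
    stop("irf must provide t0 and a positive fwhm", call. = FALSE)
  }
  structure(list(wavelengths = as.numeric(wavelengths),
                 times = as.numeric(times), deltaA = deltaA,
                 irf = irf),
            class = "ta_matrix")
}

#' Component spectra (DADS or SADS)
#'
#' @param kind `"DADS"` or `"SADS"`.
#' @param lifetimes Numeric vector of component lifetimes (ps).
#' @param fixed Logical vector: was each lifetime held fixed?
#' @param spectra Matrix wavelength x component of spectral amplitudes.
#' @param wavelengths Wavelength grid (nm).
#' @param ... Extra fields (residual matrix, rss, branching, ...).
#' @return Object of class `component_spectra`.
#' @export
component_spectra <- function(kind, lifetimes, fixed, spectra, wavelengths,
                              ...) {
  stopifnot(kind %in% c("DADS", "SADS"),
            ncol(spectra) == length(lifetimes),
            length(fixed) == length(lifetimes))
  structure(c(list(kind = kind, lifetimes = lifetimes, fixed = fixed,
                   spectra = spectra, wavelengths = wavelengths),
              list(...)),
            class = "component_spectra")
}

# time profiles (IRF-convolved exponentials) for a set of lifetimes
.profiles <- function(lifetimes, times, irf) {
  vapply(lifetimes, irf_convolved_exponential, numeric(length(times)),
         t0 = irf$t0, fwhm = irf$fwhm, times = times)
}

# variable projection: spectra solved linearly given time profiles C (nt x k)
.varpro_spectra <- function(deltaA, C) {
  G <- crossprod(C)
  S <- t(solve(G, t(deltaA %*% C)))   # nl x k
  S
}

.varpro_rss <- function(deltaA, C) {
  S <- .varpro_spectra(deltaA, C)
  sum((deltaA - S %*% t(C))^2)
}

#' Global lifetime analysis (decay-associated difference spectra)
#'
#' Fits `deltaA(lambda, t) = sum_k DADS_k(lambda) c_k(t)` where each
#' `c_k` is an exponential decay convolved with the Gaussian IRF. Lifetimes
#' are optimized by variable projection (nonlinear in the lifetimes, linear
#' per-wavelength in the spectra). Free-lifetime starting values are
#' log-spaced between twice the median time step and half the time window,
#' with a fixed three-point multi-start.
#'
#' @param data A [ta_matrix()].
#' @param n_components Total number of kinetic components (>= 1).
#' @param fixed_lifetimes Lifetimes (ps) held fixed during the fit (e.g. a
#'   slow phase the time window cannot determine). Must be fewer than
#'   `n_components`... equal is allowed (fully fixed fit).
#' @param init Optional starting values for the free lifetimes.
#' @return A [component_spectra()] of kind `"DADS"` with fields `residuals`
#'   and `rss`. If two fitted lifetimes collapse (ratio < 1%), they are
#'   merged with a warning.
#' @export
global_fit <- function(data, n_components, fixed_lifetimes = numeric(0),
                       init = NULL) {
  stopifnot(inherits(data, "ta_matrix"), n_components >= 1)
  if (!all(is.finite(data$deltaA))) {
    stop("data must be finite", call. = FALSE)
  }
  n_free <- n_components - length(fixed_lifetimes)
  if (n_free < 0) stop("more fixed lifetimes than components", call. = FALSE)
  tt <- data$times
  if (is.null(init) && n_free > 0) {
    lo <- 2 * stats::median(diff(sort(tt)))
    hi <- (max(tt) - data$irf$t0) / 2
    init <- exp(seq(log(lo), log(hi), length.out = n_free))
  }

  obj <- function(lpar) {
    taus <- c(exp(lpar), fixed_lifetimes)
    .varpro_rss(data$deltaA, .profiles(taus, tt, data$irf))
  }

  if (n_free > 0) {
    best <- NULL
    for (s in c(1, 0.5, 2)) {
      start <- log(init * s)
      opt <- if (n_free == 1) {
        # Nelder-Mead is unreliable in one dimension; bracket in log space
        stats::optim(start, obj, method = "Brent",
                     lower = start - log(100), upper = start + log(100),
                     control = list(reltol = 1e-14))
      } else {
        stats::optim(start, obj, method = "Nelder-Mead",
                     control = list(maxit = 5000, reltol = 1e-14))
      }
      if (is.null(best) || opt$value < best$value) best <- opt
    }
    free_taus <- exp(best$par)
  } else {
    free_taus <- numeric(0)
  }
  taus <- c(free_taus, fixed_lifetimes)
  fixed <- c(rep(FALSE, n_free), rep(TRUE, length(fixed_lifetimes)))
  ord <- order(taus)
  taus <- taus[ord]; fixed <- fixed[ord]

  # collapse near-degenerate lifetimes (rank deficiency tie-break)
  if (length(taus) > 1) {
    while (any(ratio <- taus[-1] / taus[-length(taus)] < 1.01)) {
      i <- which(ratio)[1]
      warning("lifetimes ", signif(taus[i], 4), " and ", signif(taus[i + 1], 4),
              " ps collapsed; merging components", call. = FALSE)
      merged <- sqrt(taus[i] * taus[i + 1])
      keep_fixed <- fixed[i] || fixed[i + 1]
      taus <- c(taus[seq_len(i - 1)], merged, taus[-seq_len(i + 1)])
      fixed <- c(fixed[seq_len(i - 1)], keep_fixed, fixed[-seq_len(i + 1)])
      if (length(taus) == 1) break
    }
  }

  C <- .profiles(taus, tt, data$irf)
  S <- .varpro_spectra(data$deltaA, C)
  resid <- data$deltaA - S %*% t(C)
  component_spectra("DADS", lifetimes = taus, fixed = fixed, spectra = S,
                    wavelengths = data$wavelengths,
                    residuals = resid, rss = sum(resid^2))
}

#' Target (compartmental) scheme of the closed reaction center
#'
#' Sequential scheme `B* -> P* -> EQ -> RLX` with branching at EQ: the
#' equilibrated P+BA-/(P+HA-)1 pool either recombines to the ground state
#' (lifetime `tauE`) or relaxes to (P+HA-)2 (`tauC`); the relaxed state
#' recombines with `tauD`. `tauA` (excitation energy transfer B* -> P*) and
#' `tauD` are fixed by convention: 0.4 ps because it is at the resolution
#' limit, and 20 ns because a 2 ns time window cannot determine the slow
#' recombination lifetime.
#'
#' @param tauB P* -> EQ charge-separation lifetime (ps).
#' @param tauC EQ -> RLX relaxation lifetime (ps).
#' @param tauE EQ -> ground recombination lifetime (ps).
#' @param tauA B* -> P* lifetime (ps), fixed.
#' @param tauD RLX -> ground lifetime (ps), fixed.
#' @return Object of class `target_scheme`.
#' @export
target_scheme <- function(tauB, tauC, tauE, tauA = 0.4, tauD = 20000) {
  taus <- c(tauA = tauA, tauB = tauB, tauC = tauC, tauD = tauD, tauE = tauE)
  if (any(!is.finite(taus)) || any(taus <= 0)) {
    stop("invalid-parameter: all target lifetimes must be positive and finite",
         call. = FALSE)
  }
  structure(as.list(taus), class = "target_scheme")
}

#' Branching fractions of the equilibrated state
#'
#' Fraction of the equilibrated P+BA-/(P+HA-)1 pool that recombines to the
#' ground state, `tauE^-1 / (tauC^-1 + tauE^-1)`, and its complement (the
#' fraction that relaxes).
#'
#' @param ts A [target_scheme()].
#' @return Named vector `c(recombine = ..., relax = ...)`.
#' @export
branching_fractions <- function(ts) {
  stopifnot(inherits(ts, "target_scheme"))
  kC <- 1 / ts$tauC; kE <- 1 / ts$tauE
  c(recombine = kE / (kC + kE), relax = kC / (kC + kE))
}

#' Apparent lifetimes of a target scheme
#' @param ts A [target_scheme()].
#' @return The four apparent (eigen) lifetimes in ps, ascending: `tauA`,
#'   `tauB`, the EQ lifetime `1/(1/tauC + 1/tauE)` and `tauD`.
#' @export
apparent_lifetimes <- function(ts) {
  stopifnot(inherits(ts, "target_scheme"))
  sort(c(ts$tauA, ts$tauB, 1 / (1 / ts$tauC + 1 / ts$tauE), ts$tauD))
}

# exponential-mixture coefficients of the four compartment populations:
# P_k(t) = sum_j cmat[k, j] exp(-t / tau_app[j]); initial population in B*.
.target_coefficients <- function(ts) {
  kA <- 1 / ts$tauA; kB <- 1 / ts$tauB
  kEQ <- 1 / ts$tauC + 1 / ts$tauE; kD <- 1 / ts$tauD
  k <- c(kA, kB, kEQ, kD)
  if (min(dist(k)) < 1e-12 * max(k)) {
    stop("numerical error: degenerate apparent rates in target scheme",
         call. = FALSE)
  }
  K <- matrix(0, 4, 4,
              dimnames = list(c("Bstar", "Pstar", "EQ", "RLX"), NULL))
  K[1, 1] <- -kA
  K[2, 1] <- kA;        K[2, 2] <- -kB
  K[3, 2] <- kB;        K[3, 3] <- -kEQ
  K[4, 3] <- 1 / ts$tauC; K[4, 4] <- -kD
  eg <- eigen(K)
  V <- Re(eg$vectors)
  beta <- solve(V, c(1, 0, 0, 0))
  cmat <- V %*% diag(beta)
  list(cmat = cmat, rates = -Re(eg$values),
       compartments = c("Bstar", "Pstar", "EQ", "RLX"))
}

# IRF-convolved compartment populations, nt x 4
.target_profiles <- function(ts, times, irf) {
  tc <- .target_coefficients(ts)
  E <- vapply(1 / tc$rates, irf_convolved_exponential,
              numeric(length(times)), t0 = irf$t0, fwhm = irf$fwhm,
              times = times)
  P <- E %*% t(tc$cmat)
  colnames(P) <- tc$compartments
  P
}

# nearest wavelength index
.wl_index <- function(wavelengths, nm) which.min(abs(wavelengths - nm))

# linear band-sum constraint solve:
# min ||deltaA - S C'||_F  s.t.  g' vec_by_row(S) = 0, where the constraint
# couples the EQ and RLX columns at the 545/600/565 nm grid points.
.constrained_spectra <- function(deltaA, C, wavelengths,
                                 comps = c("EQ", "RLX"),
                                 nm = c(545, 600, 565)) {
  if (min(wavelengths) > 540 || max(wavelengths) < 605) {
    stop("constraint error: data do not cover the 545/600 nm bands",
         call. = FALSE)
  }
  S0 <- .varpro_spectra(deltaA, C)
  colnames(S0) <- colnames(C)
  i545 <- .wl_index(wavelengths, nm[1])
  i600 <- .wl_index(wavelengths, nm[2])
  i565 <- .wl_index(wavelengths, nm[3])
  kEQ <- match(comps[1], colnames(C))
  kRL <- match(comps[2], colnames(C))
  # g as a sparse set of (row, col, value): band depths relative to 565 nm
  g <- list(rows = c(i545, i600, i565, i545, i600, i565),
            cols = c(kEQ, kEQ, kEQ, kRL, kRL, kRL),
            vals = c(1, 1, -2, -1, -1, 2))
  Ginv <- solve(crossprod(C))
  viol <- sum(g$vals * S0[cbind(g$rows, g$cols)])
  # accumulate g_row' Ginv g_row over the wavelength rows touched by g
  denom <- 0
  adj <- matrix(0, nrow(S0), ncol(S0))
  for (r in unique(g$rows)) {
    gr <- numeric(ncol(S0))
    sel <- g$rows == r
    gr[g$cols[sel]] <- g$vals[sel]
    h <- Ginv %*% gr
    denom <- denom + sum(gr * h)
    adj[r, ] <- h
  }
  if (!is.finite(denom) || denom <= 0) {
    stop("constraint error: band-sum constraint is degenerate", call. = FALSE)
  }
  S <- S0 - (viol / denom) * adj
  colnames(S) <- colnames(C)
  S
}

#' Target (compartmental) analysis with the band-sum constraint
#'
#' Fits the compartment populations of a [target_scheme()] (convolved with
#' the Gaussian IRF) to a spectro-temporal matrix. `tauA` and `tauD` are held
#' fixed; `tauB`, `tauC` and `tauE` are optimized. The species spectra (SADS)
#' are solved linearly at each step, subject (by default) to the equality
#' constraint that the summed depths of the ~545 and ~600 nm photobleaching
#' bands, measured relative to the ~565 nm local maximum, are the same in the
#' fast (EQ) and slow (RLX) recombination spectra. This constraint reflects
#' the assumption of equal differential extinction coefficients for the
#' bleaching signals and is what makes the branching between recombination
#' and relaxation identifiable. It is imposed exactly, as a linear equality
#' in the spectral least-squares step, using the grid points nearest the
#' nominal 545/600/565 nm wavelengths.
#'
#' @param data A [ta_matrix()] covering the 520--630 nm region.
#' @param scheme A [target_scheme()] with starting values for the free
#'   lifetimes.
#' @param constraint `"band-sum"` (default) or `"none"`.
#' @return A [component_spectra()] of kind `"SADS"` with the fitted scheme
#'   (`scheme`), branching fractions (`branching`), residuals and rss.
#'   Spectra columns are `Bstar`, `Pstar`, `EQ`, `RLX`; `lifetimes` are the
#'   apparent lifetimes of the fitted scheme.
#' @export
target_fit <- function(data, scheme, constraint = c("band-sum", "none")) {
  stopifnot(inherits(data, "ta_matrix"), inherits(scheme, "target_scheme"))
  constraint <- match.arg(constraint)
  tt <- data$times

  solve_spectra <- function(C) {
    if (constraint == "band-sum") {
      .constrained_spectra(data$deltaA, C, data$wavelengths)
    } else {
      S <- .varpro_spectra(data$deltaA, C)
      colnames(S) <- colnames(C)
      S
    }
  }
  obj <- function(lpar) {
    ts <- target_scheme(tauB = exp(lpar[1]), tauC = exp(lpar[2]),
                        tauE = exp(lpar[3]), tauA = scheme$tauA,
                        tauD = scheme$tauD)
    C <- .target_profiles(ts, tt, data$irf)
    S <- solve_spectra(C)
    sum((data$deltaA - S %*% t(C))^2)
  }

  start0 <- log(c(scheme$tauB, scheme$tauC, scheme$tauE))
  best <- NULL
  for (s in c(1, 0.5, 2)) {
    opt <- stats::optim(start0 + log(s), obj, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-14))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  fitted <- target_scheme(tauB = exp(best$par[1]), tauC = exp(best$par[2]),
                          tauE = exp(best$par[3]), tauA = scheme$tauA,
                          tauD = scheme$tauD)
  C <- .target_profiles(fitted, tt, data$irf)
  S <- solve_spectra(C)
  resid <- data$deltaA - S %*% t(C)
  component_spectra("SADS",
                    lifetimes = apparent_lifetimes(fitted),
                    fixed = c(TRUE, FALSE, FALSE, TRUE),
                    spectra = S, wavelengths = data$wavelengths,
                    scheme = fitted, branching = branching_fractions(fitted),
                    residuals = resid, rss = sum(resid^2))
}

#' Reconstruct DADS from SADS and the scheme's eigen-structure
#'
#' For a compartmental scheme the decay-associated spectra are exact linear
#' combinations of the species spectra:
#' `DADS_j = sum_k c_kj SADS_k` where `P_k(t) = sum_j c_kj exp(-t/tau_j)`.
#'
#' @param sads A `component_spectra` of kind `"SADS"` carrying a fitted
#'   `scheme` (as returned by [target_fit()]).
#' @return A [component_spectra()] of kind `"DADS"` on the apparent
#'   lifetimes of the scheme.
#' @export
sads_to_dads <- function(sads) {
  stopifnot(inherits(sads, "component_spectra"), sads$kind == "SADS",
            inherits(sads$scheme, "target_scheme"))
  tc <- .target_coefficients(sads$scheme)
  D <- sads$spectra[, tc$compartments, drop = FALSE] %*% tc$cmat
  taus <- 1 / tc$rates
  ord <- order(taus)
  component_spectra("DADS", lifetimes = taus[ord],
                    fixed = rep(FALSE, length(taus)),
                    spectra = D[, ord, drop = FALSE],
                    wavelengths = sads$wavelengths)
}

#' Quantify the ~545 and ~600 nm photobleaching bands of a spectrum
#'
#' Measures the two negative Qx photobleaching bands relative to the local
#' maximum near 565 nm, either as depths at the band minima
#' (`"amplitude"`) or as areas over the band minimum +/- `half_width` nm
#' (`"area"`).
#'
#' @param spectrum Numeric spectral amplitudes (photobleaching negative).
#' @param wavelengths Wavelength grid (nm); must cover 520--630 nm.
#' @param convention `"area"` or `"amplitude"`.
#' @param half_width Integration half width in nm for the area convention.
#' @return Object of class `band_quantification`: list with `band545`,
#'   `band600` (positive bleach measures), `reference` (value and nm of the
#'   565 nm local maximum) and the convention used.
#' @export
quantify_bands <- function(spectrum, wavelengths,
                           convention = c("area", "amplitude"),
                           half_width = 20) {
  convention <- match.arg(convention)
  stopifnot(length(spectrum) == length(wavelengths))
  if (min(wavelengths) > 520 || max(wavelengths) < 630) {
    stop("spectrum must cover 520-630 nm", call. = FALSE)
  }
  win <- which(wavelengths >= 555 & wavelengths <= 575)
  if (!length(win)) stop("no grid points in 555-575 nm", call. = FALSE)
  iref <- win[which.max(spectrum[win])]
  # a monotone ramp through the window that keeps rising outside has no
  # local maximum; noise-level plateaus (non-monotone) are accepted
  d <- diff(spectrum[win])
  ramp_up <- all(d >= 0) && any(d > 0) && iref == max(win) &&
    iref < length(spectrum) && spectrum[iref + 1] > spectrum[iref]
  ramp_dn <- all(d <= 0) && any(d < 0) && iref == min(win) &&
    iref > 1 && spectrum[iref - 1] > spectrum[iref]
  if (ramp_up || ramp_dn) {
    stop("quantification error: no local maximum found in 555-575 nm",
         call. = FALSE)
  }
  ref <- spectrum[iref]

  one_band <- function(lo, hi) {
    reg <- which(wavelengths >= lo & wavelengths <= hi)
    imin <- reg[which.min(spectrum[reg])]
    if (convention == "amplitude") {
      ref - spectrum[imin]
    } else {
      c0 <- wavelengths[imin]
      sel <- which(wavelengths >= c0 - half_width & wavelengths <= c0 + half_width)
      pracma::trapz(wavelengths[sel], ref - spectrum[sel])
    }
  }
  structure(list(band545 = one_band(525, 560), band600 = one_band(580, 625),
                 reference = c(value = ref, nm = wavelengths[iref]),
                 convention = convention, half_width = half_width),
            class = "band_quantification")
}
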