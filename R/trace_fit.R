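# Fitting of nanosecond single-wavelength recombination traces with sums of
# exponentials plus a constant, and the derived summary statistics.

#' Nanosecond kinetic trace
#'
#' @param times Time points (ns), strictly increasing.
#' @param deltaA Absorbance change at each time point.
#' @param wavelength_nm Probe wavelength (metadata).
#' @param temperature_K Sample temperature (metadata).
#' @return Object of class `kinetic_trace`.
#' @export
kinetic_trace <- function(times, deltaA, wavelength_nm = NA_real_,
                          temperature_K = NA_real_) {
  stopifnot(length(times) == length(deltaA))
  if (any(diff(times) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  structure(list(times = as.numeric(times), deltaA = as.numeric(deltaA),
                 wavelength_nm = wavelength_nm,
                 temperature_K = temperature_K),
            class = "kinetic_trace")
}

#' Exponential fit parameters
#'
#' Container mirroring the published fit convention
#' `deltaA = sum_i A_i exp(-t/tau_i) + A0` with lifetimes sorted ascending
#' for two-exponential fits.
#'
#' @param tau1,A1 Lifetime (ns) and amplitude of the fast component.
#' @param tau2,A2 Lifetime and amplitude of the slow component (`NA` for
#'   one-exponential fits).
#' @param A0 Constant offset.
#' @param n Number of exponentials (1 or 2).
#' @param covariance Optional covariance matrix of the estimates.
#' @param window_ns Fit window (metadata).
#' @return Object of class `fit_params`.
#' @export
fit_params <- function(tau1, A1, tau2 = NA_real_, A2 = NA_real_, A0 = 0,
                       n = if (is.na(tau2)) 1L else 2L,
                       covariance = NULL, window_ns = NA_real_) {
  if (n == 2L) {
    stopifnot(is.finite(tau2), tau2 > 0)
    if (tau1 > tau2) {  # ascending-lifetime convention
      tmp <- tau1; tau1 <- tau2; tau2 <- tmp
      tmp <- A1; A1 <- A2; A2 <- tmp
    }
  }
  stopifnot(is.finite(tau1), tau1 > 0)
  structure(list(n = as.integer(n), tau1 = tau1, A1 = A1, tau2 = tau2,
                 A2 = A2, A0 = A0, covariance = covariance,
                 window_ns = window_ns),
            class = "fit_params")
}

#' @export
print.fit_params <- function(x, ...) {
  cat(sprintf("%d-exponential fit: ", x$n))
  if (x$n == 2L) {
    cat(sprintf("tau1 = %.4g ns (A1 = %.4g), tau2 = %.4g ns (A2 = %.4g), A0 = %.4g\n",
                x$tau1, x$A1, x$tau2, x$A2, x$A0))
  } else {
    cat(sprintf("tau1 = %.4g ns (A1 = %.4g), A0 = %.4g\n", x$tau1, x$A1, x$A0))
  }
  invisible(x)
}

# model evaluation for a parameter vector c(A..., A0, tau...)
.multiexp_model <- function(t, A, tau, A0) {
  as.numeric(exp(outer(t, -1 / tau)) %*% A) + A0
}

#' Fit a trace with one or two exponentials plus a constant
#'
#' Nonlinear least squares of `deltaA = sum A_i exp(-t/tau_i) + A0` over a
#' window starting at the maximum of the trace (earliest maximum on ties).
#' Times are re-referenced to the window start so that amplitudes refer to
#' the signal at the maximum. Initial guesses are deterministic
#' (`tau1 = window/50`, `tau2 = window/5`, amplitudes from the signal
#' extremes) and a fixed five-point multi-start on the lifetime scale guards
#' against local minima.
#'
#' @param trace A [kinetic_trace()].
#' @param n Number of exponentials, 1 or 2.
#' @param window_ns Fit window length in ns (typically 100 or 200).
#' @param multi_start Use the fixed multi-start (default TRUE).
#' @return A [fit_params()] with covariance.
#' @export
fit_multiexp <- function(trace, n = 2, window_ns = 200, multi_start = TRUE) {
  stopifnot(inherits(trace, "kinetic_trace"), n %in% c(1, 2))
  i0 <- which.max(trace$deltaA)[1]           # earliest maximum
  t0 <- trace$times[i0]
  sel <- trace$times >= t0 & trace$times <= t0 + window_ns
  t <- trace$times[sel] - t0
  y <- trace$deltaA[sel]
  if (length(t) < 20) {
    stop("trace must contain at least 20 samples within the fit window",
         call. = FALSE)
  }
  if (max(t) < 0.5 * window_ns) {
    stop("trace does not cover the fit window", call. = FALSE)
  }

  yr <- diff(range(y))
  if (yr <= 1e-12 * max(abs(y), 1e-300)) {   # constant trace: degenerate fit
    return(fit_params(tau1 = window_ns / 50, A1 = 0,
                      tau2 = if (n == 2) window_ns / 5 else NA_real_,
                      A2 = if (n == 2) 0 else NA_real_,
                      A0 = mean(y), n = n, window_ns = window_ns))
  }

  A0_init <- mean(utils::tail(y, max(3L, length(y) %/% 20L)))
  Atot <- y[1] - A0_init
  tau_base <- if (n == 2) c(window_ns / 50, window_ns / 5) else window_ns / 10
  scales <- if (multi_start) c(1, 0.3, 3, 0.1, 10) else 1

  residual_fun <- if (n == 2) {
    function(p) y - (p[1] * exp(-t / exp(p[4])) + p[2] * exp(-t / exp(p[5])) +
                       p[3])
  } else {
    function(p) y - (p[1] * exp(-t / exp(p[3])) + p[2])
  }

  best <- NULL
  last <- NULL
  for (s in scales) {
    tau_init <- tau_base * s
    start <- if (n == 2) {
      c(A1 = Atot / 2, A2 = Atot / 2, A0 = A0_init,
        ltau1 = log(tau_init[1]), ltau2 = log(tau_init[2]))
    } else {
      c(A1 = Atot, A0 = A0_init, ltau1 = log(tau_init[1]))
    }
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start, fn = residual_fun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) e
    )
    if (inherits(fit, "error")) next
    last <- fit
    if (fit$info %in% c(0, 5)) next        # did not converge
    if (is.null(best) || fit$deviance < best$deviance * (1 - 1e-12)) {
      best <- fit
    }
  }
  if (is.null(best)) {
    msg <- "fit error: nonlinear least squares did not converge for any start"
    if (!is.null(last)) {
      msg <- paste0(msg, "; last iterate residual norm ",
                    signif(sqrt(last$deviance), 6))
    }
    stop(msg, call. = FALSE)
  }

  cf <- unlist(best$par)
  dof <- length(y) - length(cf)
  vc <- tryCatch({
    v <- solve(best$hessian) * best$deviance / dof
    dimnames(v) <- list(names(cf), names(cf))
    v
  }, error = function(e) NULL)
  # delta method: ltau -> tau
  if (!is.null(vc)) {
    J <- diag(length(cf))
    dimnames(J) <- list(names(cf), names(cf))
    for (nm in grep("^ltau", names(cf), value = TRUE)) {
      J[nm, nm] <- exp(cf[nm])
    }
    vc <- J %*% vc %*% t(J)
    nn <- sub("^ltau", "tau", names(cf))
    dimnames(vc) <- list(nn, nn)
  }
  if (n == 2) {
    fit_params(tau1 = exp(cf[["ltau1"]]), A1 = cf[["A1"]],
               tau2 = exp(cf[["ltau2"]]), A2 = cf[["A2"]],
               A0 = cf[["A0"]], n = 2L, covariance = vc,
               window_ns = window_ns)
  } else {
    fit_params(tau1 = exp(cf[["ltau1"]]), A1 = cf[["A1"]], A0 = cf[["A0"]],
               n = 1L, covariance = vc, window_ns = window_ns)
  }
}

#' Amplitude-weighted average lifetime
#'
#' `tau_av = (tau1 A1 + tau2 A2) / (A1 + A2)`; the constant offset is
#' excluded. For a one-exponential fit the single lifetime is returned.
#'
#' @param fp A [fit_params()].
#' @return Average lifetime in ns.
#' @export
average_lifetime <- function(fp) {
  stopifnot(inherits(fp, "fit_params"))
  if (fp$n == 1L) return(fp$tau1)
  denom <- fp$A1 + fp$A2
  if (denom == 0) {
    stop("undefined: amplitudes sum to zero", call. = FALSE)
  }
  (fp$tau1 * fp$A1 + fp$tau2 * fp$A2) / denom
}

#' Non-decaying fraction of the fitted signal
#'
#' `A0 / (A1 + A2 + A0)`, an extinction-uncorrected proxy for the yield of
#' long-lived (triplet) states: the true yield equals this fraction only if
#' the triplet and radical-pair differential extinction coefficients are
#' equal at the probe wavelength.
#'
#' @param fp A [fit_params()] with non-negative amplitudes and offset.
#' @return Fraction in [0, 1].
#' @export
triplet_offset_fraction <- function(fp) {
  stopifnot(inherits(fp, "fit_params"))
  a <- c(fp$A1, if (fp$n == 2L) fp$A2, fp$A0)
  if (any(a < 0)) {
    stop("amplitudes and offset must be non-negative", call. = FALSE)
  }
  s <- sum(a)
  if (s == 0) stop("undefined: all amplitudes are zero", call. = FALSE)
  fp$A0 / s
}
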