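# Observable -> molecular inversion, target-lifetime identities, band-area
# gap estimation and uncertainty propagation.

# forward model: molecular parameters -> exact biexponential fit parameters
.forward_fp <- function(mp, env) {
  ad <- apparent_decay(build_recombination_scheme(mp, env),
                       c(PHA1 = 1, PHA2 = 1))
  ord <- order(ad$lifetimes)
  fit_params(tau1 = ad$lifetimes[ord[1]], A1 = ad$amplitudes[ord[1]],
             tau2 = ad$lifetimes[ord[2]], A2 = ad$amplitudes[ord[2]],
             A0 = ad$offset)
}

test_that("extraction_options validates its assumption sets", {
  expect_error(extraction_options("a", 298), "dg1 and dg2")
  expect_error(extraction_options("b", 298), "taupb")
  expect_s3_class(extraction_options("a", 298, dg1 = 60, dg2 = 120),
                  "extraction_options")
})

test_that("A2 = 0 gives an infinite relaxation lifetime", {
  fp <- fit_params(2.4, 0.34, 13, 0)
  er <- extract_from_ns_fit(fp, extraction_options("a", 298, dg1 = 90,
                                                   dg2 = 128, taupb = 0.2))
  expect_true(is.infinite(er$tau12))
})

test_that("infeasible combinations raise named errors", {
  fp <- fit_params(2.4, 0.34, 13, 0.61, A0 = 0.048)
  # option a: thermal channel alone exceeds the fast decay rate
  expect_error(extract_from_ns_fit(fp, extraction_options(
    "a", 298, dg1 = 0, dg2 = 128, taupb = 0.5)), "infeasible")
  # option b: taupb slower than the observed slow phase
  expect_error(extract_from_ns_fit(fp, extraction_options(
    "b", 298, taupb = 15)), "infeasible")
  # degenerate lifetimes
  expect_error(extract_from_ns_fit(fit_params(5, 0.5, 5, 0.5),
                                   extraction_options("a", 298, dg1 = 60,
                                                      dg2 = 120)),
               "infeasible")
})

test_that("option a (shared direct lifetime) inverts the forward model", {
  env <- rc_environment(298)
  mp <- molecular_params(dG1 = 77, dG2 = 119, tauPB = 0.26, tau12 = 4.2,
                         tauDir1 = 25, tauDir2 = 25)
  fp <- .forward_fp(mp, env)
  er <- extract_from_ns_fit(fp, extraction_options("a", 298, dg1 = 77,
                                                   dg2 = 119))
  expect_equal(er$tau12, 4.2, tolerance = 1e-8)
  expect_equal(er$tauPB, 0.26, tolerance = 1e-8)
  expect_equal(er$tauDir1, 25, tolerance = 1e-8)
  expect_equal(er$tauDir2, 25, tolerance = 1e-8)
  expect_true(all(is.finite(er$uncertainty)))
})

test_that("option a with given taupb recovers per-state direct lifetimes", {
  env <- rc_environment(298)
  mp <- molecular_params(dG1 = 60, dG2 = 150, tauPB = 0.3, tau12 = 5,
                         tauDir1 = 40, tauDir2 = 22)
  fp <- .forward_fp(mp, env)
  er <- extract_from_ns_fit(fp, extraction_options("a", 298, dg1 = 60,
                                                   dg2 = 150, taupb = 0.3))
  expect_equal(er$tau12, 5, tolerance = 1e-8)
  expect_equal(er$tauDir1, 40, tolerance = 1e-8)
  expect_equal(er$tauDir2, 22, tolerance = 1e-8)
})

test_that("option b inverts the forward model when its assumptions hold", {
  env <- rc_environment(298)
  mp <- molecular_params(dG1 = 70, dG2 = 120, tauPB = 0.3, tau12 = 4,
                         tauDir1 = Inf, tauDir2 = 30)
  fp <- .forward_fp(mp, env)
  er <- extract_from_ns_fit(fp, extraction_options("b", 298, taupb = 0.3,
                                                   tau_dir2 = 30))
  expect_equal(er$dG1, 70, tolerance = 1e-7)
  expect_equal(er$dG2, 120, tolerance = 1e-7)
  expect_equal(er$tau12, 4, tolerance = 1e-7)
  # scanned-bracket variant: reported interval brackets the true gap
  er2 <- extract_from_ns_fit(fp, extraction_options("b", 298, taupb = 0.3,
                                                    dir2_bracket = c(20, 50)))
  expect_lt(er2$dG2 - er2$uncertainty[["dG2"]], 120)
  expect_gt(er2$dG2 + er2$uncertainty[["dG2"]], 120)
})

test_that("target-lifetime identities match their closed forms", {
  env <- rc_environment(296)
  expect_equal(tau12_from_target(0, 8, env), 4)     # P1 = 1/2
  expect_equal(taupb_from_target(0, 8, env), 4)
  expect_equal(tau12_from_target(60, 3.40, env), 3.1, tolerance = 0.01)
  expect_equal(taupb_from_target(60, 3.0, env), 0.26, tolerance = 0.01)
  # large-gap limits
  expect_equal(tau12_from_target(1e5, 7, env), 7)
  expect_equal(taupb_from_target(1e5, 7, env), 0)
  # monotone in the gap, linear in the lifetime
  gaps <- seq(0, 200, 20)
  v <- vapply(gaps, tau12_from_target, numeric(1), tauC = 5, env = env)
  expect_true(all(diff(v) > 0))
  expect_equal(tau12_from_target(60, 10, env), 2 * tau12_from_target(60, 5, env))
  expect_error(tau12_from_target(60, -1, env))
})

test_that("dg_from_band_areas inverts the synthetic EQ/RLX construction", {
  env <- rc_environment(296)
  wl <- seq(500, 650, 0.25)
  for (dg in c(15, 49, 60, 90)) {
    sp <- closed_rc_spectra("WT", dG1 = dg, env = env)
    bf <- quantify_bands(eval_spectrum(sp$EQ, wl), wl)
    bs <- quantify_bands(eval_spectrum(sp$RLX, wl), wl)
    est <- dg_from_band_areas(bf, bs, env, eps_ratio = 1)
    expect_equal(est$dG, dg, tolerance = 0.02)
    expect_lt(abs(est$dG - dg), 1)
  }
})

test_that("dg_from_band_areas is invariant to a common spectral scaling", {
  env <- rc_environment(296)
  wl <- seq(500, 650, 0.25)
  sp <- closed_rc_spectra("WT", dG1 = 60, env = env)
  yf <- eval_spectrum(sp$EQ, wl)
  ys <- eval_spectrum(sp$RLX, wl)
  base <- dg_from_band_areas(quantify_bands(yf, wl), quantify_bands(ys, wl),
                             env, eps_ratio = 1)
  scl <- dg_from_band_areas(quantify_bands(3 * yf, wl),
                            quantify_bands(ys, wl), env, eps_ratio = 1)
  expect_equal(scl$dG, base$dG, tolerance = 1e-10)
  expect_equal(scl$scale, base$scale / 3, tolerance = 1e-10)
})

test_that("no 600 nm excess means the gap is undefined", {
  env <- rc_environment(296)
  wl <- seq(500, 650, 0.25)
  sp <- closed_rc_spectra("WT", dG1 = 60, env = env)
  bs <- quantify_bands(eval_spectrum(sp$RLX, wl), wl)
  expect_error(dg_from_band_areas(bs, bs, env, eps_ratio = 1),
               "gap-undefined")
})

test_that("scanning the extinction ratio brackets the known-ratio value", {
  env <- rc_environment(296)
  wl <- seq(500, 650, 0.25)
  sp <- closed_rc_spectra("WT", dG1 = 60, env = env)
  bf <- quantify_bands(eval_spectrum(sp$EQ, wl), wl)
  bs <- quantify_bands(eval_spectrum(sp$RLX, wl), wl)
  scan <- dg_from_band_areas(bf, bs, env)
  known <- dg_from_band_areas(bf, bs, env, eps_ratio = 1)
  expect_lt(scan$dG_min, known$dG)
  expect_gt(scan$dG_max, known$dG)
  expect_equal(scan$dG, (scan$dG_min + scan$dG_max) / 2)
})

test_that("correct_open_rc enforces the reference band ratio", {
  env <- rc_environment(296)
  wl <- seq(500, 650, 0.25)
  sp <- closed_rc_spectra("WT", dG1 = 60, env = env)
  bs <- quantify_bands(eval_spectrum(sp$RLX, wl), wl)
  # contaminate the slow spectrum's 600 nm band, then correct against itself
  dirty <- bs
  dirty$band600 <- bs$band600 * 1.4
  fixed <- correct_open_rc(dirty, bs)
  expect_equal(fixed$band600 / fixed$band545, bs$band600 / bs$band545)
  expect_equal(fixed$band545, dirty$band545)
})

test_that("propagate_uncertainty reproduces analytic cases", {
  fp <- fit_params(2.4, 0.34, 13, 0.61, A0 = 0.048)
  expect_equal(propagate_uncertainty(function(f) f$tau1, fp), 0.2 * 2.4,
               tolerance = 1e-6)
  expect_equal(propagate_uncertainty(function(f) f$tau1 + f$tau2, fp),
               0.2 * sqrt(2.4^2 + 13^2), tolerance = 1e-6)
  expect_equal(propagate_uncertainty(function(f) 5, fp), 0)
})

test_that("linearized uncertainty matches Monte Carlo for tau_av", {
  fp <- fit_params(2.4, 0.34, 13, 0.61, A0 = 0.048)
  u_lin <- propagate_uncertainty(average_lifetime, fp)
  set.seed(42)
  n <- 2e4
  draws <- vapply(seq_len(n), function(i) {
    average_lifetime(fit_params(
      tau1 = rnorm(1, 2.4, 0.2 * 2.4), A1 = rnorm(1, 0.34, 0.2 * 0.34),
      tau2 = rnorm(1, 13, 0.2 * 13), A2 = rnorm(1, 0.61, 0.2 * 0.61),
      A0 = rnorm(1, 0.048, 0.2 * 0.048)))
  }, numeric(1))
  expect_equal(u_lin, stats::sd(draws), tolerance = 0.1)
})

test_that("slow thermal lifetime is nearly temperature-independent at dG1=0 (property)", {
  # with a barrierless unrelaxed state and a large relaxed gap the slow
  # phase is carried by the direct channel, so cooling changes it little
  for (taupb in c(0.2, 0.7, 1.3)) {
    mp <- molecular_params(dG1 = 0, dG2 = 250, tauPB = taupb, tau12 = 3,
                           tauDir2 = 20)
    slow_at <- function(T) {
      ad <- apparent_decay(build_recombination_scheme(mp, rc_environment(T)),
                           c(PHA1 = 1, PHA2 = 1))
      max(ad$lifetimes)
    }
    expect_lt(abs(slow_at(298) / slow_at(77) - 1), 0.05)
  }
})
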