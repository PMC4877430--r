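# Kinetic core: environment, thermal lifetimes, scheme construction and the
# analytic population solver.

test_that("rc_environment validates and warns outside the supported range", {
  env <- rc_environment(298)
  expect_s3_class(env, "rc_environment")
  expect_equal(kT(env), 0.08617 * 298)
  expect_error(rc_environment(0), "invalid-parameter")
  expect_error(rc_environment(-5), "invalid-parameter")
  expect_warning(rc_environment(50), "supported")
  expect_warning(rc_environment(400), "supported")
})

test_that("thermal_lifetime matches the closed form and its examples", {
  env298 <- rc_environment(298)
  # tauPB (1 + exp(dG/kT)) at 0.26 ns, 77 meV, 298 K
  expect_equal(thermal_lifetime(0.26, 77, env298),
               0.26 * (1 + exp(77 / (0.08617 * 298))))
  expect_equal(thermal_lifetime(0.26, 77, env298), 5.46, tolerance = 0.01)
  # dG = 0 gives exactly 2 tauPB at any temperature
  expect_equal(thermal_lifetime(0.2, 0, env298), 0.4)
  expect_equal(thermal_lifetime(0.2, 0, rc_environment(77)), 0.4)
  expect_error(thermal_lifetime(-1, 50, env298), "invalid-parameter")
})

test_that("thermal_lifetime is monotone in dG and in 1/T for positive gaps", {
  env <- rc_environment(298)
  gaps <- seq(0, 300, by = 10)
  vals <- vapply(gaps, thermal_lifetime, numeric(1), tauPB = 0.2, env = env)
  expect_true(all(diff(vals) > 0))
  temps <- seq(320, 80, by = -20)
  vals_t <- vapply(temps, function(T) thermal_lifetime(0.2, 100,
                                                       rc_environment(T)),
                   numeric(1))
  expect_true(all(diff(vals_t) > 0))   # decreasing T increases the lifetime
})

test_that("equilibrium_population matches the Boltzmann form", {
  expect_equal(equilibrium_population(0, rc_environment(298)), 0.5)
  expect_equal(equilibrium_population(1e6, rc_environment(298)), 1.0)
  expect_equal(equilibrium_population(60, rc_environment(296)), 0.913,
               tolerance = 1e-3)
})

test_that("molecular_params enforces its invariants", {
  expect_error(molecular_params(dG1 = 100, dG2 = 50, tauPB = 0.2, tau12 = 4),
               "dG2")
  expect_error(molecular_params(dG1 = 0, dG2 = 50, tauPB = -1, tau12 = 4))
  mp <- molecular_params(dG1 = 0, dG2 = 50, tauPB = 0.2, tau12 = 4)
  expect_true(is.infinite(mp$tauDir1))
})

test_that("rapid-equilibrium scheme has the documented structure", {
  env <- rc_environment(298)
  mp <- molecular_params(dG1 = 77, dG2 = 119, tauPB = 0.26, tau12 = 4.2)
  sc <- build_recombination_scheme(mp, env)
  expect_setequal(sc$compartments, c("PHA1", "PHA2", "ground", "triplet"))
  K <- rate_matrix(sc, include_sinks = FALSE)
  ev <- eigen(K, only.values = TRUE)$values
  expect_length(ev, 2)
  expect_true(all(Re(ev) < 0) && all(abs(Im(ev)) < 1e-12))
  # degenerate scheme: all optional channels off, tau12 infinite
  mp1 <- molecular_params(dG1 = 50, dG2 = 60, tauPB = 0.5, tau12 = Inf)
  ad <- apparent_decay(build_recombination_scheme(mp1, env), c(PHA1 = 1))
  live <- abs(ad$amplitudes) > 1e-12
  expect_equal(sum(live), 1)           # single-exponential decay of PHA1
})

test_that("explicit mode obeys detailed balance and converges to rapid eq", {
  env <- rc_environment(298)
  mp <- molecular_params(dG1 = 40, dG2 = 120, tauPB = 0.3, tau12 = 3,
                         tauDir2 = 25)
  ex <- build_recombination_scheme(mp, env, mode = "explicit")
  K <- rate_matrix(ex)
  expect_equal(K["PHA1", "PBA1"] / K["PBA1", "PHA1"], exp(mp$dG1 / kT(env)))
  expect_equal(K["PHA2", "PBA2"] / K["PBA2", "PHA2"], exp(mp$dG2 / kT(env)))
  # k_eq >> decay rates: slow eigenvalues approach the rapid-eq ones
  req <- build_recombination_scheme(mp, env)
  lam_req <- sort(eigen(rate_matrix(req, FALSE), only.values = TRUE)$values)
  ex_fast <- build_recombination_scheme(mp, env, mode = "explicit",
                                        k_eq = 1e5)
  lam_ex <- sort(eigen(rate_matrix(ex_fast, FALSE), only.values = TRUE)$values)
  slow <- utils::tail(Re(lam_ex), 2)   # two slowest modes
  expect_equal(slow, Re(lam_req), tolerance = 0.01)
  expect_error(build_recombination_scheme(mp, env, mode = "explicit",
                                          k_eq = -1),
               "configuration error")
})

test_that("kinetic_scheme validators reject malformed networks", {
  expect_error(kinetic_scheme("A", data.frame(from = "A", to = "B", rate = 1),
                              c(A = 1)),
               "unknown compartment")
  expect_error(kinetic_scheme(c("A", "B"),
                              data.frame(from = "B", to = "A", rate = 1),
                              c(A = 1), sinks = "B"),
               "absorbing")
  expect_error(kinetic_scheme(c("A", "B"),
                              data.frame(from = "A", to = "B", rate = 1),
                              c(A = 0.5)),
               "sum to 1")
  expect_error(kinetic_scheme(c("A", "B"),
                              data.frame(from = "A", to = "B", rate = -1),
                              c(A = 1)),
               "invalid-parameter")
})

test_that("rate_matrix columns conserve population", {
  env <- rc_environment(298)
  mp <- molecular_params(dG1 = 40, dG2 = 120, tauPB = 0.3, tau12 = 3,
                         tauDir1 = 30, tauDir2 = 25, tauTrip2 = 50)
  sc <- build_recombination_scheme(mp, env)
  expect_equal(colSums(rate_matrix(sc, include_sinks = TRUE)),
               c(PHA1 = 0, PHA2 = 0, ground = 0, triplet = 0))
  expect_true(all(colSums(rate_matrix(sc, include_sinks = FALSE)) <= 0))
})

test_that("solve_populations reproduces closed forms", {
  one <- kinetic_scheme(c("A", "g"),
                        data.frame(from = "A", to = "g", rate = 1),
                        c(A = 1), sinks = "g")
  tt <- seq(0, 5, 0.1)
  tr <- solve_populations(one, tt)
  expect_equal(tr$populations[, "A"], exp(-tt), tolerance = 1e-10)
  # irreversible chain A (1 ns) -> B (5 ns) -> g
  chain <- kinetic_scheme(c("A", "B", "g"),
                          data.frame(from = c("A", "B"), to = c("B", "g"),
                                     rate = c(1, 1 / 5)),
                          c(A = 1), sinks = "g")
  tr2 <- solve_populations(chain, tt)
  expect_equal(tr2$populations[, "A"], exp(-tt), tolerance = 1e-10)
  expect_equal(tr2$populations[, "B"], (5 / 4) * (exp(-tt / 5) - exp(-tt)),
               tolerance = 1e-10)
})

test_that("populations are conserved and bounded at every time", {
  env <- rc_environment(298)
  mp <- molecular_params(dG1 = 30, dG2 = 150, tauPB = 0.4, tau12 = 5,
                         tauDir2 = 20, tauTrip1 = 80, tauTrip2 = 60)
  sc <- build_recombination_scheme(mp, env)
  tr <- solve_populations(sc, seq(0, 300, length.out = 500))
  totals <- rowSums(tr$populations)
  expect_true(all(abs(totals - 1) < 1e-9))
  expect_true(all(tr$populations > -1e-12 & tr$populations < 1 + 1e-12))
})

test_that("eigen solution agrees with stiff ODE integration (property)", {
  set.seed(101)
  tt <- seq(0, 100, length.out = 1000)
  worst <- 0
  for (i in 1:100) {
    dg1 <- runif(1, 0, 150)
    mp <- molecular_params(
      dG1 = dg1, dG2 = dg1 + runif(1, 0, 150),
      tauPB = runif(1, 0.1, 2), tau12 = runif(1, 0.5, 20),
      tauDir1 = if (runif(1) < 0.5) Inf else runif(1, 5, 100),
      tauDir2 = runif(1, 5, 100),   # keeps PHA2 decaying at any temperature
      tauTrip1 = if (runif(1) < 0.5) Inf else runif(1, 20, 500),
      tauTrip2 = if (runif(1) < 0.5) Inf else runif(1, 20, 500)
    )
    sc <- build_recombination_scheme(mp, rc_environment(runif(1, 77, 300)))
    eig <- solve_populations(sc, tt)$populations
    K <- rate_matrix(sc)
    ode <- deSolve::lsoda(sc$initial, tt,
                          function(t, y, p) list(p %*% y), K,
                          rtol = 1e-10, atol = 1e-12)
    worst <- max(worst, max(abs(eig - ode[, sc$compartments])))
  }
  expect_lt(worst, 1e-7)
})

test_that("apparent_decay is exact, linear in weights and offset-correct", {
  one <- kinetic_scheme(c("A", "g"),
                        data.frame(from = "A", to = "g", rate = 0.5),
                        c(A = 1), sinks = "g")
  ad <- apparent_decay(one, c(A = 1))
  expect_equal(ad$lifetimes, 2)
  expect_equal(ad$amplitudes, 1)
  expect_equal(ad$offset, 0)
  # linearity: doubling weights doubles amplitudes and offset
  env <- rc_environment(298)
  mp <- molecular_params(dG1 = 30, dG2 = 140, tauPB = 0.4, tau12 = 5,
                         tauDir2 = 20, tauTrip1 = 60, tauTrip2 = 40)
  sc <- build_recombination_scheme(mp, env)
  w <- c(PHA1 = 1, PHA2 = 1, triplet = 0.3)
  a1 <- apparent_decay(sc, w)
  a2 <- apparent_decay(sc, 2 * w)
  expect_equal(a2$amplitudes, 2 * a1$amplitudes)
  expect_equal(a2$offset, 2 * a1$offset)
  expect_equal(a2$lifetimes, a1$lifetimes)
  # offset equals final triplet population times the triplet weight
  tr <- solve_populations(sc, c(0, 1e5))
  trip_inf <- tr$populations[2, "triplet"]
  expect_equal(a1$offset, unname(0.3 * trip_inf), tolerance = 1e-8)
  # the exponential representation reproduces the weighted populations
  tt <- seq(0, 200, 1)
  sig <- eval_apparent_decay(a1, tt)
  P <- solve_populations(sc, tt)$populations
  expect_equal(sig, as.numeric(P[, c("PHA1", "PHA2", "triplet")] %*%
                                 c(1, 1, 0.3)),
               tolerance = 1e-10)
})

test_that("apparent lifetimes equal the eigen-lifetimes of the scheme", {
  env <- rc_environment(298)
  mp <- molecular_params(dG1 = 50, dG2 = 160, tauPB = 0.3, tau12 = 4,
                         tauDir2 = 25)
  sc <- build_recombination_scheme(mp, env)
  ad <- apparent_decay(sc, c(PHA1 = 1, PHA2 = 1))
  lam <- sort(-1 / Re(eigen(rate_matrix(sc, FALSE), only.values = TRUE)$values))
  expect_equal(sort(ad$lifetimes), lam, tolerance = 1e-12)
})
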