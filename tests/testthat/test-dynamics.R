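# Extraction factors, single-pass efficiency, the closed-form recirculating
# time course and its mass-balance metrics.

test_that("extraction factors are the partition-weighted ratios", {
  expect_equal(extraction_factor_E(1, 2, 2), 1)
  expect_equal(extraction_factor_E(600, 40, 3), 8000)
  expect_equal(extraction_factor_E(600, 4, 3) / extraction_factor_E(300, 4, 3), 2)
  expect_equal(reservoir_factor_R(2, 1, 2), 1)
  expect_equal(reservoir_factor_R(600, 50, 100), 300)
  expect_equal(reservoir_factor_R(600, 5, 10), 300)  # scale-invariant
  expect_error(extraction_factor_E(1, 1, 0), "Q_w")
  expect_error(reservoir_factor_R(1, 1, 0), "V_w")
})

test_that("module efficiency has the right limits", {
  A <- 5.65e-3; Q <- ml_min_to_m3_s(3)
  expect_equal(module_efficiency_phi(0, A, Q, 100), 0)
  # E -> Inf reduces to the plug-extraction form 1 - exp(-x)
  x <- 2.2e-6 * A / Q
  expect_equal(module_efficiency_phi(2.2e-6, A, Q, Inf), 1 - exp(-x),
               tolerance = 1e-12)
  # x -> Inf drives phi -> 1
  expect_equal(module_efficiency_phi(1, A, Q, Inf), 1, tolerance = 1e-12)
  # E = 1 analytic limit x/(1+x), approached continuously from E != 1
  expect_equal(module_efficiency_phi(2.2e-6, A, Q, 1), x / (1 + x),
               tolerance = 1e-12)
  expect_equal(module_efficiency_phi(2.2e-6, A, Q, 1 + 1e-9),
               module_efficiency_phi(2.2e-6, A, Q, 1), tolerance = 1e-7)
})

test_that("module efficiency reproduces the reported in-out value", {
  phi <- module_efficiency_phi(2.2e-6, A = 5.65e-3, Q_w = ml_min_to_m3_s(3),
                               E = 1000)
  expect_equal(phi, 0.22, tolerance = 0.01)
})

test_that("efficiency is strictly increasing in K_w A / Q_w and in E, bounded in (0,1)", {
  A <- 5.65e-3; Q <- ml_min_to_m3_s(3)
  kws <- 10^seq(-8, -4, length.out = 25)
  for (E in c(1.5, 10, 1000)) {
    phis <- vapply(kws, module_efficiency_phi, numeric(1), A = A, Q_w = Q, E = E)
    expect_true(all(diff(phis) > 0))
    expect_true(all(phis > 0 & phis < 1))
  }
  phisE <- vapply(c(1.01, 2, 5, 50, 5000), function(E) {
    module_efficiency_phi(2.2e-6, A, Q, E)
  }, numeric(1))
  expect_true(all(diff(phisE) > 0))
})

test_that("kw_from_phi inverts module_efficiency_phi exactly", {
  A <- 5.65e-3; Q <- ml_min_to_m3_s(3)
  for (K in 10^seq(-7.5, -5, length.out = 7)) {
    for (E in c(1, 1.5, 10, 45, 8000)) {
      phi <- module_efficiency_phi(K, A, Q, E)
      expect_equal(kw_from_phi(phi, A, Q, E), K, tolerance = 1e-9)
    }
  }
})

test_that("kw_from_phi matches the closed form at E -> Inf and a numeric oracle", {
  A <- 5.65e-3; Q <- ml_min_to_m3_s(40)
  phi <- 0.05
  expect_equal(kw_from_phi(phi, A, Q, Inf), -Q * log(1 - phi) / A,
               tolerance = 1e-12)
  # independent numeric inversion by bisection on the forward formula
  E <- 45
  f <- function(K) module_efficiency_phi(K, A, Q, E) - phi
  K_oracle <- uniroot(f, c(1e-12, 1e-2), tol = 1e-18)$root
  expect_equal(kw_from_phi(phi, A, Q, E), K_oracle, tolerance = 1e-8)
})

test_that("unattainable efficiencies are rejected with the feasible range", {
  expect_error(kw_from_phi(0.6, 1e-3, 1e-6, E = 0.5), "attainable")
  expect_error(kw_from_phi(1, 1e-3, 1e-6, E = 10), "attainable")
})

test_that("the closed-form time course matches numerical ODE integration", {
  # oracle: dc_w/dt = -(Q_w phi / V_w) (c_w (1 + 1/R) - c_w0 / R)
  grid <- expand.grid(phi = c(0.05, 0.222, 0.8), R = c(2, 50, 300),
                      Q_ml_min = c(3, 40))
  times <- min_to_s(seq(0, 480, by = 30))
  for (i in seq_len(nrow(grid))) {
    phi <- grid$phi[i]; R <- grid$R[i]
    Q <- ml_min_to_m3_s(grid$Q_ml_min[i])
    V_w <- ml_to_m3(100); V_s <- ml_to_m3(50); c_w0 <- 0.15
    course <- simulate_timecourse(phi, R, Q, V_w, c_w0, V_s, times)
    ode <- deSolve::ode(
      y = c(cw = c_w0), times = times,
      func = function(t, y, p) {
        list(-(Q * phi / V_w) * (y[1] * (1 + 1 / R) - c_w0 / R))
      }, parms = NULL, rtol = 1e-11, atol = 1e-14)
    expect_equal(course$c_w, unname(ode[, "cw"]), tolerance = 1e-8)
  }
})

test_that("time course starts at the initial condition and ends at equilibrium", {
  op <- study_operating()
  P <- 600
  R <- reservoir_factor_R(P, op$V_s, op$V_w)
  times <- c(0, min_to_s(c(60, 1e5)))
  course <- simulate_timecourse(0.2, R, op$Q_w, op$V_w, op$c_w0, op$V_s, times)
  expect_equal(course$c_w[1], op$c_w0)
  expect_equal(course$c_s[1], 0)
  expect_equal(course$c_w[3], op$c_w0 / (1 + R), tolerance = 1e-9)
  expect_equal(course$c_s[3] / course$c_w[3], P, tolerance = 1e-9)
})

test_that("simulated courses conserve mass and are monotone", {
  set.seed(9)
  times <- min_to_s(seq(0, 480, by = 15))
  for (i in 1:10) {
    phi <- runif(1, 0.01, 0.9); R <- 10^runif(1, 0, 3)
    V_w <- ml_to_m3(100); V_s <- ml_to_m3(runif(1, 20, 200))
    course <- simulate_timecourse(phi, R, ml_min_to_m3_s(3), V_w, 0.15, V_s, times)
    total <- V_w * course$c_w + V_s * course$c_s
    expect_equal(total, rep(V_w * 0.15, length(times)), tolerance = 1e-12)
    expect_true(all(diff(course$c_w) < 0))
    expect_true(all(diff(course$c_s) > 0))
  }
  # both reservoirs move faster at higher efficiency
  lo <- simulate_timecourse(0.1, 300, ml_min_to_m3_s(3), ml_to_m3(100), 0.15,
                            ml_to_m3(50), times)
  hi <- simulate_timecourse(0.4, 300, ml_min_to_m3_s(3), ml_to_m3(100), 0.15,
                            ml_to_m3(50), times)
  expect_true(all(hi$c_w[-1] < lo$c_w[-1]))
  expect_true(all(hi$c_s[-1] > lo$c_s[-1]))
})

test_that("the linearisation of a noiseless course is exactly linear", {
  op <- study_operating()
  R <- 300
  phi <- 0.222
  times <- min_to_s(c(0, 15, 30, 60, 120, 240, 360, 480))
  course <- simulate_timecourse(phi, R, op$Q_w, op$V_w, op$c_w0, op$V_s, times)
  y <- log((1 + 1 / R) * course$c_w / op$c_w0 - 1 / R)
  slope_true <- -(op$Q_w * phi / op$V_w) * (1 + 1 / R)
  expect_equal(y[1], 0)
  fit <- lm(y ~ times)
  expect_equal(unname(coef(fit)[["times"]]), slope_true, tolerance = 1e-10)
  expect_lt(max(abs(residuals(fit))), 1e-12)
})

test_that("mass-balance metrics report recovery, concentration factor, enrichment", {
  op <- study_operating()
  R <- 300
  times <- min_to_s(c(0, 60, 480, 1e5))
  course <- simulate_timecourse(0.222, R, op$Q_w, op$V_w, op$c_w0, op$V_s, times)
  mets <- mass_balance_metrics(course)
  expect_equal(mets$recovery, rep(1, 4), tolerance = 1e-12)  # lossless model
  expect_equal(mets$concentration_factor[1], 0)
  expect_equal(mets$enrichment[1], 0)
  # equilibrium with R >> 1 and V_w/V_s = 2: factor -> (V_w/V_s) R/(R+1) ~ 2
  expect_equal(mets$concentration_factor[4], 2 * R / (R + 1), tolerance = 1e-9)
  expect_equal(mets$concentration_factor[4], 2, tolerance = 0.01)
  expect_error(mass_balance_metrics(course, c_w0 = 0), "c_w0")
})
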