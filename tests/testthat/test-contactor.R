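# Module geometry and individual/overall mass-transfer coefficients.

test_that("log-mean diameter behaves like a log mean", {
  expect_equal(log_mean_diameter(3e-3, 3e-3), 3e-3)
  expect_equal(log_mean_diameter(3e-3, 4e-3), 1e-3 / log(4 / 3), tolerance = 1e-12)
  set.seed(3)
  for (i in 1:25) {
    d_i <- runif(1, 1e-4, 5e-3)
    d_o <- d_i * runif(1, 1.001, 3)
    dlm <- log_mean_diameter(d_i, d_o)
    expect_gt(dlm, d_i)
    expect_lt(dlm, d_o)
  }
  expect_error(log_mean_diameter(0, 1e-3), "positive")
})

test_that("module geometry reproduces the stated 56 cm2 inner area", {
  m <- study_module()
  expect_equal(m$inner_area, 3 * pi * 3e-3 * 0.2, tolerance = 1e-12)
  expect_equal(m$inner_area * 1e4, 56, tolerance = 0.015)  # within 1.5%
  expect_gt(m$d_lm, m$d_i); expect_lt(m$d_lm, m$d_o)
  expect_true(m$packing_fraction > 0 && m$packing_fraction < 1)
  expect_error(membrane_module(3, 3e-3, 3e-3, 0.2, porosity = 0.5,
                               tortuosity = 2, shell_inner_diameter = 1e-2),
               "d_o")
  expect_error(membrane_module(50, 3e-3, 3.3e-3, 0.2, porosity = 0.5,
                               tortuosity = 2, shell_inner_diameter = 1e-2),
               "packing")
})

test_that("Leveque lumen coefficient matches the frozen hand evaluation", {
  D <- wilke_chang_diffusivity(carvone(), water_phase(), 298.15)
  k <- k_fibre_leveque(D, d_i = 3e-3, flow_per_fibre = ml_min_to_m3_s(1),
                       length = 0.2)
  expect_equal(k$k, 1.999130813e-06, tolerance = 1e-8)
  expect_gt(k$graetz, 4)  # no accuracy warning in the study regime
})

test_that("Leveque coefficient scales with the cube root of flow", {
  D <- 6.9e-10
  k1 <- k_fibre_leveque(D, 3e-3, ml_min_to_m3_s(1), 0.2)$k
  k8 <- k_fibre_leveque(D, 3e-3, ml_min_to_m3_s(8), 0.2)$k
  expect_equal(k8 / k1, 2, tolerance = 1e-12)
})

test_that("Leveque agrees with its Sherwood-number restatement", {
  D <- 6.9e-10
  k <- k_fibre_leveque(D, 3e-3, ml_min_to_m3_s(1), 0.2)
  Sh <- k$k * 3e-3 / D
  expect_equal(Sh, 1.62 * k$graetz^(1 / 3), tolerance = 1e-12)
})

test_that("low Graetz number warns but does not error", {
  expect_warning(k <- k_fibre_leveque(1e-8, 3e-3, 1e-10, 0.2), "Graetz")
  expect_gt(k$k, 0)
})

test_that("shell coefficient matches an independent spreadsheet evaluation", {
  # oracle: explicit re-evaluation of the parallel-flow correlation on the
  # study geometry with water at 40 ml/min (frozen to 6 significant digits)
  D <- wilke_chang_diffusivity(carvone(), water_phase(), 298.15)
  k <- k_shell_parallel_flow(D, study_module(), ml_min_to_m3_s(40), water_phase())
  expect_equal(k$k, 2.22135144e-06, tolerance = 1e-7)
  expect_equal(k$reynolds, 96.1444, tolerance = 1e-5)
})

test_that("shell coefficient scales as Re^0.6 and vanishes with full packing", {
  m <- study_module()
  w <- water_phase()
  k1 <- k_shell_parallel_flow(6.9e-10, m, ml_min_to_m3_s(40), w)$k
  k2 <- k_shell_parallel_flow(6.9e-10, m, ml_min_to_m3_s(80), w)$k
  expect_equal(k2 / k1, 2^0.6, tolerance = 1e-12)
  # k is proportional to (1 - theta) at fixed Re
  m_tight <- membrane_module(3, 3e-3, 3.3e-3, 0.2, porosity = 0.5,
                             tortuosity = 2, shell_inner_diameter = 5.8e-3)
  k_tight <- k_shell_parallel_flow(6.9e-10, m_tight, ml_min_to_m3_s(40), w)$k
  # packing 0.905 vs 0.327: same beta*D/L * Re^0.6 Sc^0.33 factor (Re is
  # independent of the shell bore), so the ratio is the (1-theta) ratio
  expect_equal(k_tight / k1,
               (1 - m_tight$packing_fraction) / (1 - m$packing_fraction),
               tolerance = 1e-12)
})

test_that("membrane coefficient follows the porous-wall formula", {
  m <- membrane_module(3, 3e-3, 3.4e-3, 0.2, porosity = 0.5, tortuosity = 2,
                       shell_inner_diameter = 1e-2)
  expect_equal(k_membrane(2.3e-9, m), 2 * 0.5 * 2.3e-9 / (2 * 4e-4),
               tolerance = 1e-12)
  # k proportional to porosity/tortuosity
  m2 <- membrane_module(3, 3e-3, 3.4e-3, 0.2, porosity = 0.25, tortuosity = 4,
                        shell_inner_diameter = 1e-2)
  expect_equal(k_membrane(2.3e-9, m2), k_membrane(2.3e-9, m) / 4)
})

test_that("overall coefficient equals a brute-force resistance sum", {
  m <- study_module()
  set.seed(5)
  for (i in 1:30) {
    P <- 10^runif(1, -1, 3)
    kw <- 10^runif(1, -7, -4); ko <- 10^runif(1, -7, -4); km <- 10^runif(1, -7, -4)
    mode <- sample(c("in-out", "out-in"), 1)
    bk <- overall_kw(P, kw, ko, km, m, mode)
    d_b <- if (mode == "in-out") m$d_i else m$d_o
    d_x <- if (mode == "in-out") m$d_o else m$d_i
    K_oracle <- 1 / (d_b * (1 / (P * ko * d_x) + 1 / (P * km * m$d_lm) +
                              1 / (kw * d_b)))
    expect_equal(bk$K_w, K_oracle, tolerance = 1e-12)
    expect_equal(sum(bk$resistance_fractions), 1, tolerance = 1e-12)
    expect_true(all(bk$resistance_fractions >= 0))
    # aqueous film is an upper bound (diameter-basis corrected)
    expect_lte(bk$K_w, kw * (1 + 1e-12))
  }
})

test_that("aqueous film controls as the partition coefficient grows", {
  # d_i = d_o limit approximated by a very thin wall
  m <- membrane_module(3, 3e-3, 3.0000001e-3, 0.2, porosity = 0.5,
                       tortuosity = 2, shell_inner_diameter = 1e-2)
  bk <- overall_kw(1e12, 2e-6, 5e-6, 4e-6, m, "in-out")
  expect_equal(bk$K_w, 2e-6, tolerance = 1e-6)
  expect_equal(unname(bk$resistance_fractions["aqueous"]), 1, tolerance = 1e-5)
})

test_that("overall coefficient is monotone in each input coefficient", {
  m <- study_module()
  base <- list(P = 50, kw = 2e-6, ko = 5e-6, km = 4e-6)
  K0 <- overall_kw(base$P, base$kw, base$ko, base$km, m, "in-out")$K_w
  expect_gt(overall_kw(base$P * 2, base$kw, base$ko, base$km, m, "in-out")$K_w, K0)
  expect_gt(overall_kw(base$P, base$kw * 2, base$ko, base$km, m, "in-out")$K_w, K0)
  expect_gt(overall_kw(base$P, base$kw, base$ko * 2, base$km, m, "in-out")$K_w, K0)
  expect_gt(overall_kw(base$P, base$kw, base$ko, base$km * 2, m, "in-out")$K_w, K0)
})

test_that("predict_kw assigns film roles by operation mode", {
  fx <- synth_paper_fixture()
  bk_io <- predict_kw(fx$module, fx$operating$in_out, fx$solute, fx$water,
                      fx$heptane, fx$P)
  bk_oi <- predict_kw(fx$module, fx$operating$out_in, fx$solute, fx$water,
                      fx$heptane, fx$P)
  # in-out: aqueous film is the lumen (Leveque) coefficient in water
  D_w <- wilke_chang_diffusivity(fx$solute, fx$water, 298.15)
  k_lumen_w <- k_fibre_leveque(D_w, fx$module$d_i, ml_min_to_m3_s(1), 0.2)$k
  expect_equal(bk_io$k_w, k_lumen_w, tolerance = 1e-12)
  # out-in: aqueous film is the shell coefficient in water
  k_shell_w <- k_shell_parallel_flow(D_w, fx$module, ml_min_to_m3_s(40),
                                     fx$water)$k
  expect_equal(bk_oi$k_w, k_shell_w, tolerance = 1e-12)
  expect_equal(bk_io$area_basis, "inner")
  expect_equal(bk_oi$area_basis, "outer")
})

test_that("unknown operation mode is rejected", {
  expect_error(overall_kw(10, 1e-6, 1e-6, 1e-6, study_module(), "sideways"),
               "unknown operation mode")
})
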