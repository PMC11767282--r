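test_that("radiative rate matches published values and the closed form", {
  expect_equal(radiative_rate(0, 500), 0)
  # published aqueous-solution rate, solvent factor 1.333
  expect_equal(radiative_rate(1.2263, 458.2, solvent_factor = 1.333),
               2.94e8, tolerance = 0.01)
  expect_equal(radiative_rate(1.1905, 512.9, solvent_factor = 1.333),
               2.28e8, tolerance = 0.01)
  # vacuum formula vs standard Einstein-A closed form across the UV-Vis-NIR
  for (lambda in seq(200, 1000, by = 50)) {
    f <- 0.8
    expect_equal(radiative_rate(f, lambda),
                 6.6703e15 * f / (lambda * 10)^2, tolerance = 1e-3)
  }
})

test_that("energy-gap internal conversion reproduces published rates", {
  expect_equal(internal_conversion_rate(500), 1e8)
  expect_equal(internal_conversion_rate(458.2), 4.31e7, tolerance = 0.01)
  expect_equal(internal_conversion_rate(512.9), 1.26e8, tolerance = 0.01)
})

test_that("quantum yield and intensity correction match worked examples", {
  expect_equal(quantum_yield(1e8, 1e8), 0.5)
  expect_equal(100 * quantum_yield(2.94e8, 4.31e7), 87.0, tolerance = 0.3 / 87)
  expect_equal(100 * quantum_yield(2.28e8, 1.26e8), 64.4, tolerance = 0.1 / 64.4)
  expect_equal(intensity_scale(1.0, 0.870, 0.644, 458.2, 512.9), 0.661,
               tolerance = 5e-3)
  # identity and homogeneity
  expect_equal(intensity_scale(2.5, 0.7, 0.7, 500, 500), 2.5)
  expect_equal(intensity_scale(2, 0.87, 0.64, 458, 513),
               2 * intensity_scale(1, 0.87, 0.64, 458, 513))
})

test_that("mean energy deviation reproduces both published statistics", {
  expect_equal(mean_energy_deviation(c(369.1, 372.3, 381.6),
                                     c(385.0, 396.0, 410.0)),
               6.04, tolerance = 1e-3)
  expect_equal(mean_energy_deviation(c(458.2, 512.9), c(454.0, 514.0)),
               0.566, tolerance = 1e-3)
  expect_equal(mean_energy_deviation(c(400, 500), c(400, 500)), 0)
  expect_error(mean_energy_deviation(numeric(), numeric()), "non-empty")
})

test_that("rate monotonicity properties hold", {
  lams <- seq(250, 900, by = 25)
  # k_ic strictly increasing in wavelength (energy-gap law direction)
  expect_true(all(diff(internal_conversion_rate(lams)) > 0))
  # k_r increasing in f, decreasing in wavelength
  expect_true(all(diff(radiative_rate(seq(0.1, 2, by = 0.1), 500)) > 0))
  expect_true(all(diff(radiative_rate(1.0, lams)) < 0))
  # phi in (0,1), increasing in k_r, decreasing in k_ic
  phis <- quantum_yield(seq(1e7, 1e9, length.out = 20), 1e8)
  expect_true(all(phis > 0 & phis < 1))
  expect_true(all(diff(phis) > 0))
  expect_true(all(diff(quantum_yield(1e8, seq(1e7, 1e9, length.out = 20))) < 0))
})

test_that("intensity correction round-trips A -> B -> A", {
  ia <- 1.7
  ib <- intensity_scale(ia, 0.87, 0.64, 458.2, 512.9)
  back <- intensity_scale(ib, 0.64, 0.87, 512.9, 458.2)
  expect_equal(back, ia, tolerance = 1e-12)
})

test_that("assemble_photophysics composes the three rate operations", {
  tab <- steom_table()
  res <- assemble_photophysics(tab[1, ], solvent_factor = 1.333)
  expect_s3_class(res, "rate_result")
  expect_equal(res$radiative_rate, radiative_rate(1.2263, 458.2, 1.333))
  expect_equal(res$internal_conversion_rate, internal_conversion_rate(458.2))
  expect_equal(res$quantum_yield, 0.871, tolerance = 1e-3)
  # the phi-from-rates invariant over random valid inputs
  set.seed(42)
  for (k in 1:25) {
    tr <- transition_table("X", "emission", 1, 0,
                           runif(1, 250, 900), runif(1, 0, 2.5), "m")
    r <- assemble_photophysics(tr, solvent_factor = runif(1, 1, 2))
    expect_equal(r$quantum_yield,
                 r$radiative_rate /
                   (r$radiative_rate + r$internal_conversion_rate),
                 tolerance = 1e-12)
  }
  # zero oscillator strength: dark state, phi = 0, k_ic unchanged
  dark <- assemble_photophysics(
    transition_table("X", "emission", 1, 0, 458.2, 0, "m"))
  expect_equal(dark$quantum_yield, 0)
  expect_equal(dark$internal_conversion_rate, internal_conversion_rate(458.2))
  # experimental rows are rejected
  expect_error(assemble_photophysics(tab[2, ]), "emission")
})

test_that("deviation_report pairs calculated and experimental rows", {
  rep <- deviation_report(steom_table())
  expect_equal(nrow(rep$pairs), 2)
  expect_equal(rep$mean_deviation_percent, 0.566, tolerance = 1e-3)
})
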