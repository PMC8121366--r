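test_that("Debye intensity has its closed forms for one and two centers", {
  one <- new_structure(atoms_tbl("A", 1, "ALA", "CA", "C", 0, 0, 0))
  q <- seq(0, 0.4, by = 0.05)
  c1 <- debye_intensity(one, q, granularity = "atom")
  expect_true(all(c1$intensity == 6^2))  # carbon: 6 electrons, flat curve
  two <- new_structure(atoms_tbl("A", 1:2, "ALA", "CA", "C",
                                 c(0, 10), c(0, 0), c(0, 0)))
  c2 <- debye_intensity(two, q, granularity = "atom")
  want <- ifelse(q == 0, (2 * 6)^2,
                 2 * 36 * (1 + sin(q * 10) / (q * 10)))
  expect_equal(c2$intensity, want, tolerance = 1e-12)
})

test_that("I(q) never exceeds I(0) on a compact convex body", {
  ball <- ball_structure(n = 200, R = 10, seed = 13)
  cur <- debye_intensity(ball, seq(0, 0.5, by = 0.01), granularity = "atom")
  expect_true(all(cur$intensity <= cur$intensity[1] + 1e-9))
})

test_that("residue-level Debye uses electron-count weights at C-alpha", {
  s <- make_ideal_helix(helix_spec(10, sequence = "GGGGGGGGGG"))
  cur <- debye_intensity(s, c(0), granularity = "residue")
  expect_equal(cur$intensity[1], (10 * 30)^2)  # Gly residue: 30 electrons
})

test_that("Guinier analysis is exact on an ideal Gaussian curve", {
  q <- seq(0.001, 0.2, by = 0.001)
  curve <- scattering_curve(q, 10 * exp(-q^2 * 20^2 / 3))
  g <- guinier_fit(curve)
  expect_equal(g$rg, 20, tolerance = 1e-6)
  expect_equal(g$i0, 10, tolerance = 1e-6)
  expect_true(all(curve$q[seq_len(g$n_points)] * 20 <= 1.3 + 1e-9))
})

test_that("Guinier Rg survives 1% noise within 2%", {
  q <- seq(0.001, 0.2, by = 0.001)
  ideal <- 10 * exp(-q^2 * 20^2 / 3)
  withr::local_seed(17)
  noisy <- scattering_curve(q, ideal * (1 + rnorm(length(q), 0, 0.01)),
                            sigma = 0.01 * ideal)
  g <- guinier_fit(noisy)
  expect_equal(g$rg, 20, tolerance = 0.02)
})

test_that("Guinier Rg of a hard-sphere cloud approaches sqrt(3/5) R", {
  ball <- ball_structure(n = 400, R = 15, seed = 2)
  cur <- debye_intensity(ball, seq(0.002, 0.2, by = 0.002), granularity = "atom")
  g <- guinier_fit(cur)
  expect_equal(g$rg, radius_of_gyration(ball), tolerance = 0.03)
  expect_equal(g$rg, sqrt(3 / 5) * 15, tolerance = 0.03)
})

test_that("rising low-q data is rejected", {
  q <- seq(0.001, 0.1, by = 0.001)
  expect_error(guinier_fit(scattering_curve(q, exp(q^2 * 100))), "not negative")
  expect_error(guinier_fit(scattering_curve(q[1:3], rep(1, 3))), "too few")
})

test_that("model-to-data scaling recovers a pure scale factor", {
  s <- make_ideal_helix(helix_spec(20))
  q <- seq(0.005, 0.4, by = 0.005)
  model <- debye_intensity(s, q, granularity = "residue")
  fake <- scattering_curve(q, 2.5 * model$intensity, sigma = rep(1, length(q)))
  fit <- fit_model_to_curve(model, fake)
  expect_equal(fit$scale, 2.5, tolerance = 1e-9)
  expect_equal(fit$constant, 0, tolerance = 1e-6)
  expect_lt(fit$chi_reduced, 1e-12)
})

test_that("chi-square is ~1 against own-noise data and larger for a wrong model", {
  s <- make_ideal_helix(helix_spec(20))
  q <- seq(0.005, 0.4, by = 0.005)
  model <- debye_intensity(s, q, granularity = "residue")
  withr::local_seed(19)
  noisy <- scattering_curve(q, model$intensity + rnorm(length(q)),
                            sigma = rep(1, length(q)))
  fit <- fit_model_to_curve(model, noisy)
  expect_equal(fit$chi_reduced, 1, tolerance = 0.3)
  wrong <- debye_intensity(make_ideal_helix(helix_spec(40)), q,
                           granularity = "residue")
  fit_wrong <- fit_model_to_curve(wrong, noisy)
  expect_gt(fit_wrong$chi_reduced, fit$chi_reduced)
})

test_that("missing uncertainties or disjoint q ranges are refused", {
  a <- scattering_curve(1:10 / 100, rep(1, 10))
  b <- scattering_curve(20:30 / 100, rep(1, 11), sigma = rep(1, 11))
  expect_error(fit_model_to_curve(a, a), "sigma")
  expect_error(fit_model_to_curve(a, b), "overlap")
})

test_that("scattering files round-trip, including inverse-nm input", {
  s <- make_ideal_helix(helix_spec(10))
  cur <- make_synthetic_curve(s, noise_frac = 0.02, seed = 23)
  tf <- withr::local_tempfile(fileext = ".dat")
  write_saxs_curve(cur, tf)
  rt <- read_saxs_curve(tf)
  expect_equal(rt$q, cur$q, tolerance = 1e-12)
  expect_equal(rt$intensity, cur$intensity, tolerance = 1e-9)
  expect_equal(rt$sigma, cur$sigma, tolerance = 1e-9)
  # a curve tabulated in inverse nm reads back onto the angstrom grid
  tf2 <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("# q[1/nm] I sigma",
               paste(cur$q * 10, cur$intensity, cur$sigma)), tf2)
  rt2 <- read_saxs_curve(tf2, q_unit = "nm")
  expect_equal(rt2$q, cur$q, tolerance = 1e-12)
  expect_error(scattering_curve(c(0.2, 0.1), c(1, 1)), "increasing")
})
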