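test_that("ideal helix geometry follows the closed forms", {
  h <- make_ideal_helix(helix_spec(20))
  ca <- coords_matrix(h)
  d <- sqrt(rowSums(diff(ca)^2))
  want <- sqrt(1.5^2 + (2 * 2.3 * sin(lobescope:::deg2rad(100) / 2))^2)
  expect_equal(unique(round(d, 9)), round(want, 9))
  expect_equal(want, 3.86, tolerance = 0.01)
  expect_error(helix_spec(4), "at least 5")
})

test_that("full-backbone helices carry N, CA, C, O with sane geometry", {
  h <- make_ideal_helix(helix_spec(10), full_backbone = TRUE)
  at <- tibble::as_tibble(h)
  expect_setequal(unique(at$elety), c("N", "CA", "C", "O"))
  expect_equal(nrow(at), 40)
  ca <- as.matrix(at[at$elety == "CA", c("x", "y", "z")])
  d <- sqrt(rowSums(diff(ca)^2))
  expect_true(all(abs(d - 3.8) < 0.15))  # canonical helical CA-CA spacing
  ax <- helix_axis(h)
  expect_gt(abs(ax$direction[3]), 0.999)
})

test_that("the dimer generator hits its ground-truth angle and separation", {
  for (ang in c(0, 60, 140.7)) {
    d <- make_helix_dimer(helix_spec(18), 9, ang)
    a1 <- helix_axis(d, "A"); a2 <- helix_axis(d, "B")
    expect_equal(cross_angle(a1, a2), ang, tolerance = 0.5)
    expect_equal(attr(d, "true_cross_angle"), ang)
  }
  far <- make_helix_dimer(helix_spec(15), 50, 140.7)
  expect_lt(buried_surface_area(far, "A", "B")$bsa_total, 1)
})

test_that("synthetic alignments hit target entropies in expectation", {
  # zero target: all rows identical
  m0 <- make_synthetic_msa(30, 20, 0, seed = 7)
  expect_equal(length(unique(m0$seq)), 1)
  # two-residue mixture target
  m1 <- make_synthetic_msa(500, 40, 0.2314, seed = 8)
  prof <- column_entropy(m1)
  expect_lt(max(abs(prof$entropy - 0.2314)), 0.05)
  expect_lt(abs(mean(prof$entropy) - 0.2314), 0.01)
  # high-entropy columns need more residue types but still land on target
  m2 <- make_synthetic_msa(800, 15, 0.8, seed = 9)
  expect_lt(abs(mean(column_entropy(m2)$entropy) - 0.8), 0.02)
  expect_error(make_synthetic_msa(10, 5, 1.2, seed = 1), "unreachable")
  expect_error(make_synthetic_msa(10, 5, 0.2), "seed")
})

test_that("gap profiles and redundancy clusters are realized", {
  m <- make_synthetic_msa(200, 30, 0.3, gap_profile = 0.2, seed = 10)
  gf <- column_entropy(m)$gap_fraction
  expect_lt(abs(mean(gf) - 0.2), 0.03)
  mr <- make_synthetic_msa(50, 40, 0.3,
                           redundancy = list(n_clusters = 5,
                                             mutations_per_copy = 2),
                           seed = 11)
  cl <- attr(mr, "clusters")
  expect_equal(sort(unique(cl)), 1:5)
  # near-copies within a cluster are close, across clusters far
  d <- distance_matrix(mr)
  same <- outer(cl, cl, "==") & upper.tri(d)
  diff_cl <- outer(cl, cl, "!=") & upper.tri(d)
  expect_lt(mean(d[same]), mean(d[diff_cl]))
  # pruning to the cluster count retains one member per cluster
  p <- prune_redundancy(mr, 5)
  expect_setequal(cl[match(p$id, mr$id)], 1:5)
})

test_that("generators are bit-reproducible under a fixed seed", {
  expect_identical(make_synthetic_msa(25, 30, 0.4, seed = 77)$seq,
                   make_synthetic_msa(25, 30, 0.4, seed = 77)$seq)
  s <- make_ideal_helix(helix_spec(12))
  c1 <- make_synthetic_curve(s, noise_frac = 0.05, seed = 13)
  c2 <- make_synthetic_curve(s, noise_frac = 0.05, seed = 13)
  expect_identical(c1$intensity, c2$intensity)
  c3 <- make_synthetic_curve(s, noise_frac = 0.05, seed = 14)
  expect_false(identical(c1$intensity, c3$intensity))
})

test_that("a noise-free synthetic curve equals the Debye curve exactly", {
  s <- make_ideal_helix(helix_spec(12))
  q <- seq(0.01, 0.3, by = 0.01)
  expect_identical(make_synthetic_curve(s, q, noise_frac = 0, seed = 1)$intensity,
                   debye_intensity(s, q)$intensity)
})

test_that("Guinier analysis recovers the generator Rg from a noisy compact body", {
  ball <- ball_structure(n = 400, R = 15, seed = 2)
  cur <- make_synthetic_curve(ball, q = seq(0.002, 0.3, by = 0.002),
                              noise_frac = 0.01, seed = 15)
  g <- guinier_fit(cur)
  expect_equal(g$rg, radius_of_gyration(ball), tolerance = 0.03)
})

test_that("a model refits its own noisy curve with chi-square near 1", {
  s <- make_ideal_helix(helix_spec(25))
  q <- seq(0.005, 0.4, by = 0.005)
  noisy <- make_synthetic_curve(s, q, noise_frac = 0.03, seed = 16)
  model <- debye_intensity(s, q)
  fit <- fit_model_to_curve(model, noisy)
  expect_equal(fit$chi_reduced, 1, tolerance = 0.3)
  expect_equal(fit$scale, 1, tolerance = 0.05)
})
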