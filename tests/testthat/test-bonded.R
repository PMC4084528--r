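# Amber-form bonded terms: analytic limits, gradient consistency,
# translation/rotation invariance, the FLOP cost model and topology I/O.

test_that("bond term reproduces the harmonic convention", {
  coords <- rbind(c(0, 0, 0), c(1.2, 0, 0))
  b_eq <- data.frame(i = 1, j = 2, k_b = 100, r0 = 1.2)
  res <- bond_force(coords, b_eq)
  expect_equal(res$energy, 0)
  expect_equal(max(abs(res$forces)), 0)
  # K (r - r0)^2 without a 1/2 factor: K = 100, stretch 1 -> energy 100
  b1 <- data.frame(i = 1, j = 2, k_b = 100, r0 = 0.2)
  expect_equal(bond_force(coords, b1)$energy, 100)
  expect_error(bond_force(rbind(c(0, 0, 0), c(0, 0, 0)), b_eq),
               "oincident")
})

test_that("angle and torsion terms vanish at their minima", {
  # theta = theta0: no angle force
  th0 <- 1.9
  coords <- rbind(c(cos(th0), sin(th0), 0), c(0, 0, 0), c(1, 0, 0))
  a <- data.frame(i = 1, j = 2, k = 3, k_theta = 40, theta0 = th0)
  res <- angle_force(coords, a)
  expect_equal(res$energy, 0, tolerance = 1e-12)
  expect_lt(max(abs(res$forces)), 1e-9)
  # V_n = 0: torsion identically zero
  coords4 <- matrix(rnorm(12), 4, 3)
  t0 <- data.frame(i = 1, j = 2, k = 3, l = 4, v_n = 0, n = 2,
                   gamma = 0.3)
  rt <- torsion_force(coords4, t0)
  expect_equal(rt$energy, 0)
  expect_equal(max(abs(rt$forces)), 0)
})

test_that("torsion energy hits zero where n phi - gamma = pi", {
  # planar cis geometry: phi = 0, so pick gamma = -pi (n = 1):
  # 1 + cos(0 + pi) = 0
  coords <- rbind(c(-1, 1, 0), c(-1, 0, 0), c(1, 0, 0), c(1, 1, 0))
  tr <- data.frame(i = 1, j = 2, k = 3, l = 4, v_n = 2.5, n = 1,
                   gamma = pi)
  res <- torsion_force(coords, tr)
  # phi = 0 for the cis arrangement: E = V (1 + cos(-pi)) = 0
  expect_equal(res$energy, 0, tolerance = 1e-12)
})

test_that("every bonded force is minus the energy gradient", {
  set.seed(41)
  for (rep in 1:5) {
    coords <- matrix(rnorm(12, sd = 1.5), 4, 3)
    b <- data.frame(i = 1, j = 2, k_b = 310, r0 = 1.5)
    a <- data.frame(i = 1, j = 2, k = 3, k_theta = 40, theta0 = 1.9)
    t <- data.frame(i = 1, j = 2, k = 3, l = 4, v_n = 1.4, n = 3,
                    gamma = 0.4)
    for (term in list(
      list(f = function(cc) bond_force(cc, b)),
      list(f = function(cc) angle_force(cc, a)),
      list(f = function(cc) torsion_force(cc, t))
    )) {
      res <- term$f(coords)
      g <- numerical_gradient(function(cc) term$f(cc)$energy, coords)
      scale <- max(max(abs(g)), 1)
      expect_lt(max(abs(res$forces + g)) / scale, 1e-6)
    }
  }
})

test_that("isolated bonded terms exert no net force or torque", {
  set.seed(42)
  coords <- matrix(rnorm(12, sd = 2), 4, 3)
  a <- data.frame(i = 1, j = 2, k = 3, k_theta = 40, theta0 = 1.7)
  t <- data.frame(i = 1, j = 2, k = 3, l = 4, v_n = 1.4, n = 2,
                  gamma = 0.8)
  for (res in list(angle_force(coords, a), torsion_force(coords, t))) {
    expect_lt(max(abs(colSums(res$forces))), 1e-10)
    torque <- colSums(cbind(
      coords[, 2] * res$forces[, 3] - coords[, 3] * res$forces[, 2],
      coords[, 3] * res$forces[, 1] - coords[, 1] * res$forces[, 3],
      coords[, 1] * res$forces[, 2] - coords[, 2] * res$forces[, 1]
    ))
    expect_lt(max(abs(torque)), 1e-10)
  }
})

test_that("the FLOP model reproduces the printed per-interaction totals", {
  expect_equal(flops_per_interaction(c(add = 12, mul = 9, rsqrt = 1)), 31)
  expect_equal(flops_per_interaction(c(add = 34, mul = 42, rsqrt = 4,
                                       cos = 1, acos = 1)), 136)
  expect_equal(flops_per_interaction(c(add = 0, mul = 0)), 0)
  expect_error(flops_per_interaction(c(add = -1)), "non-negative")
  expect_error(flop_weights(add = 0), "positive")
})

test_that("per-atom bonded load sums the rounded per-type contributions", {
  pa <- per_atom_flops()
  expect_equal(unname(pa$contributions),  c(31, 244.8, 717.0))
  expect_equal(pa$total, 992.8)
  # one-decimal rounding before summation is what makes 717.0 exact
  expect_equal(round(183.84 * 3.9, 1), 717.0)
  # zero multiplicity contributes nothing
  z <- per_atom_flops(data.frame(flop_total = 136, per_atom_mult = 0))
  expect_equal(z$total, 0)
})

test_that("topology text format round trips", {
  topo <- md_topology(
    6,
    bonds = data.frame(i = 1:5, j = 2:6, k_b = 310, r0 = 1.53),
    angles = data.frame(i = 1:4, j = 2:5, k = 3:6, k_theta = 40,
                        theta0 = 1.94),
    torsions = data.frame(i = 1:3, j = 2:4, k = 3:5, l = 4:6,
                          v_n = 1.4, n = 3, gamma = 0)
  )
  f <- tempfile(fileext = ".top")
  write_topology(topo, f)
  back <- read_topology(f)
  expect_equal(back$n_particles, 6L)
  expect_equal(back$bonds, topo$bonds)
  expect_equal(back$angles, topo$angles)
  expect_equal(back$torsions, topo$torsions)
  unlink(f)
})

test_that("topology validation rejects malformed terms", {
  expect_error(md_topology(3, bonds = data.frame(i = 1, j = 1, k_b = 1,
                                                 r0 = 1)), "distinct")
  expect_error(md_topology(3, bonds = data.frame(i = 1, j = 4, k_b = 1,
                                                 r0 = 1)), "range")
  expect_error(md_topology(3, bonds = data.frame(i = 1, j = 2, k_b = 1,
                                                 r0 = 0)), "r0")
  expect_error(md_topology(4, torsions = data.frame(i = 1, j = 2, k = 3,
                                                    l = 4, v_n = 1,
                                                    n = 0, gamma = 0)),
               "period")
})
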