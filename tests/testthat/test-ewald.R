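# Gaussian-split Ewald: charge spreading, FFT Poisson solve, back
# interpolation, real-space correction and total energies against a
# direct Ewald summation oracle.

test_that("charge spreading conserves charge and symmetry", {
  box <- c(10, 10, 10)
  ep <- ewald_params(1.0, box)
  # single unit charge: mesh total = 1
  m1 <- spread_charges(matrix(c(3.31, 4.72, 5.15), 1, 3), 1, ep)
  expect_equal(sum(m1$values), 1, tolerance = 1e-12)
  # two opposite charges at the same point: zero mesh
  m0 <- spread_charges(rbind(c(2.5, 2.5, 2.5), c(2.5, 2.5, 2.5)),
                       c(1, -1), ep)
  expect_equal(max(abs(m0$values)), 0)
  # charge on a mesh node: octahedral symmetry of the stencil
  h <- ep$spacing
  node <- h * c(8, 8, 8)
  ms <- spread_charges(matrix(node, 1, 3), 1, ep)
  v <- ms$values
  expect_equal(v[9 + 1, 9, 9], v[9 - 1, 9, 9])
  expect_equal(v[9 + 1, 9, 9], v[9, 9 + 1, 9])
  expect_equal(v[9 + 2, 9, 9], v[9, 9, 9 + 2])
  # unwrapped particles are rejected
  expect_error(spread_charges(matrix(c(-1, 5, 5), 1, 3), 1, ep), "wrap")
  # oversized support is rejected
  expect_error(ewald_params(1.0, box, r_spread_cut = 6), "half the box")
})

test_that("Poisson solve is linear with the expected eigenmodes", {
  box <- c(10, 10, 10)
  ep <- ewald_params(0.7, box, mesh_dims = c(16, 16, 16),
                     sigma_spread = 0.505, r_spread_cut = 3.5)
  zero <- structure(list(values = array(0, c(16, 16, 16)), params = ep),
                    class = "charge_mesh")
  expect_equal(max(abs(solve_poisson(zero, ep)$values)), 0)
  # a single Fourier mode is an eigenfunction of the solve
  g <- expand.grid(x = 0:15, y = 0:15, z = 0:15)
  mode <- array(cos(2 * pi * g$x / 16), c(16, 16, 16))
  mesh <- structure(list(values = mode, params = ep),
                    class = "charge_mesh")
  phi <- solve_poisson(mesh, ep)
  scale <- sum(phi$values * mode) / sum(mode^2)
  expect_lt(max(abs(phi$values - scale * mode)), 1e-10 * abs(scale))
})

test_that("back interpolation gives zero force in a uniform potential", {
  set.seed(31)
  box <- c(10, 10, 10)
  ep <- ewald_params(1.0, box)
  pos <- random_positions(6, box)
  q <- c(1, 1, 1, -1, -1, -1)
  flat <- structure(list(values = array(2.5, ep$mesh_dims), params = ep),
                    class = "potential_mesh")
  bi <- back_interpolate(flat, pos, q, ep)
  expect_lt(max(abs(bi$forces)), 1e-12)
  # mismatched parameters are rejected
  ep2 <- ewald_params(1.0, box, sigma_spread = 0.42)
  expect_error(back_interpolate(flat, pos, q, ep2), "same parameters")
})

test_that("reciprocal-space forces conserve momentum", {
  set.seed(32)
  box <- c(10, 10, 10)
  ep <- ewald_params(0.975, box)
  pos <- random_positions(8, box)
  q <- c(rep(1, 4), rep(-1, 4))
  mesh <- spread_charges(pos, q, ep)
  phi <- solve_poisson(mesh, ep)
  bi <- back_interpolate(phi, pos, q, ep)
  net <- max(abs(colSums(bi$forces)))
  rms <- sqrt(mean(bi$forces^2))
  expect_lt(net / rms, 1e-8)
})

test_that("real-space correction enforces the erfc consistency bound", {
  box <- c(12, 12, 12)
  ep <- ewald_params(1.0, box, mesh_dims = c(48, 48, 48))
  # erfc(alpha r_c) must be < 1e-7: alpha * r_c = 4 is consistent
  pos <- rbind(c(2, 6, 6), c(5, 6, 6))
  rs <- real_space_correction(pos, c(1, -1), ep, cutoff = 4)
  expect_equal(rs$energy, -oracle_erfc(1 * 3) / 3, tolerance = 1e-12)
  expect_error(real_space_correction(pos, c(1, -1), ep, cutoff = 2.5),
               "inconsistent")
})

test_that("total Coulomb energy matches direct Ewald summation", {
  set.seed(33)
  box <- c(10, 10, 10)
  alpha <- 0.975
  pos <- random_positions(8, box)
  q <- c(rep(1, 4), rep(-1, 4))
  ep <- ewald_params(alpha, box)
  res <- total_coulomb_energy(pos, q, ep)
  oracle <- direct_ewald_energy(pos, q, box, alpha)
  expect_equal(res$energy, oracle, tolerance = 1e-4)
  # alpha-invariance across a factor-2 range (finer mesh at larger alpha)
  res2 <- total_coulomb_energy(pos, q, ewald_params(2 * alpha, box,
                                                    mesh_dims = rep(64, 3)))
  expect_equal(res2$energy, res$energy, tolerance = 1e-4)
  # empty / uncharged systems
  expect_equal(total_coulomb_energy(pos, rep(0, 8), ep)$energy, 0)
  # non-neutral systems are rejected
  expect_error(total_coulomb_energy(pos, rep(1, 8), ep), "neutral")
})

test_that("forces match the gradient of the direct Ewald oracle", {
  box <- c(10, 10, 10)
  alpha <- 0.975
  pos <- rbind(c(2, 5, 5), c(6.5, 5, 5))
  q <- c(1, -1)
  ep <- ewald_params(alpha, box)
  res <- total_coulomb_energy(pos, q, ep)
  h <- 1e-5
  fn <- numeric(3)
  for (k in 1:3) {
    pp <- pos; pm <- pos
    pp[1, k] <- pp[1, k] + h
    pm[1, k] <- pm[1, k] - h
    fn[k] <- -(direct_ewald_energy(pp, q, box, alpha) -
                 direct_ewald_energy(pm, q, box, alpha)) / (2 * h)
  }
  expect_lt(max(abs(res$forces[1, ] - fn)) / sqrt(sum(fn^2)), 1e-4)
})

test_that("rock-salt lattice recovers the Madelung energy", {
  s <- 4; a <- 2.82; L <- s * a
  g <- expand.grid(0:(s - 1), 0:(s - 1), 0:(s - 1))
  pos <- as.matrix(g) * a + a / 2
  q <- ifelse(rowSums(g) %% 2 == 0, 1, -1)
  cutoff <- L / 2 * 0.999
  ep <- ewald_params(3.9 / cutoff, rep(L, 3))
  res <- total_coulomb_energy(pos, q, ep, cutoff = cutoff)
  per_pair <- res$energy / (length(q) / 2)
  expect_equal(per_pair * a, -1.747565, tolerance = 1e-3)
})

test_that("isolated pair in a large box approaches bare Coulomb", {
  L <- 40
  pos <- rbind(c(19, 20, 20), c(21, 20, 20))
  q <- c(1, -1)
  ep <- ewald_params(0.5, rep(L, 3), mesh_dims = rep(64, 3))
  res <- total_coulomb_energy(pos, q, ep, cutoff = 10)
  expect_equal(res$energy, -1 / 2, tolerance = 1e-3)
})
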