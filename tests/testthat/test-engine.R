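# MD engine: synthetic generators, domain decomposition, leap-frog
# integration, the full fixed-point step, and trajectory output.

test_that("synthetic generators are reproducible and well-formed", {
  s1 <- generate_system("lj_fluid", 32, 0.012, seed = 9)
  s2 <- generate_system("lj_fluid", 32, 0.012, seed = 9)
  expect_identical(s1$positions, s2$positions)
  expect_identical(s1$velocities, s2$velocities)
  s3 <- generate_system("lj_fluid", 32, 0.012, seed = 10)
  expect_false(identical(s1$positions, s3$positions))
  # rock salt: exact neutrality and alternating charges
  salt <- generate_system("salt_lattice", 8, 0.045, seed = 1)
  expect_equal(sum(salt$charges), 0)
  expect_setequal(unique(salt$charges), c(-1, 1))
  expect_error(generate_system("salt_lattice", 27, 0.045), "even")
  # chain combinatorics of the polymer
  poly <- generate_system("toy_polymer", 10, 0.002, seed = 2)
  expect_equal(nrow(poly$topology$bonds), 9)
  expect_equal(nrow(poly$topology$angles), 8)
  expect_equal(nrow(poly$topology$torsions), 7)
  # 1-2 and 1-3 exclusions
  expect_equal(nrow(poly$exclusions), 9 + 8)
  # overlapping density is rejected
  expect_error(generate_system("lj_fluid", 64, 0.2, seed = 1), "overlap")
})

test_that("decomposition finds exactly the brute-force pair set", {
  set.seed(61)
  sys <- generate_system("lj_fluid", 48, 0.011, seed = 61)
  cutoff <- 5.5
  dec <- decompose(sys, cell_size = cutoff, cutoff = cutoff)
  ref <- brute_force_pairs(sys$positions, sys$box, cutoff)
  key <- function(m) sort(paste(m[, 1], m[, 2]))
  expect_identical(key(dec$pairs), key(ref))
  # no pair may appear twice
  expect_equal(anyDuplicated(paste(dec$pairs[, 1], dec$pairs[, 2])), 0)
  # every particle sits in exactly one cell
  expect_equal(length(dec$cell_of), sys$n)
  expect_true(all(dec$cell_of >= 0 & dec$cell_of < prod(dec$grid)))
  expect_error(decompose(sys, cell_size = 4, cutoff = 5), "at least")
})

test_that("single-cell decomposition degenerates to all pairs", {
  sys <- generate_system("lj_fluid", 16, 0.012, seed = 3)
  cutoff <- min(sys$box) * 0.45
  dec <- decompose(sys, cell_size = min(sys$box), cutoff = cutoff)
  ref <- brute_force_pairs(sys$positions, sys$box, cutoff)
  expect_equal(nrow(dec$pairs), nrow(ref))
})

test_that("leap-frog reproduces closed-form motion", {
  types <- atom_type_table(0.1, 3)
  mk <- function(v) md_system(matrix(c(5, 5, 5), 1, 3), matrix(v, 1, 3),
                              1, 0, 1L, types, c(100, 100, 100))
  # zero force: uniform linear motion
  sys <- mk(c(0.01, 0, 0))
  for (i in 1:10) sys <- leapfrog_step(sys, matrix(0, 1, 3), 1,
                                       accel_unit = 1)
  expect_equal(sys$positions[1, 1], 5 + 10 * 0.01, tolerance = 1e-12)
  # constant force from rest: r(t) = f/m t^2 / 2 at the half-step offset
  f <- matrix(c(2e-4, 0, 0), 1, 3)
  sys <- mk(c(0, 0, 0))
  dt <- 0.5; nstep <- 20
  for (i in seq_len(nstep)) sys <- leapfrog_step(sys, f, dt,
                                                 accel_unit = 1)
  t_tot <- nstep * dt
  # leap-frog from rest integrates to (t^2 + t dt)/2 exactly
  expect_equal(sys$positions[1, 1] - 5,
               2e-4 * (t_tot^2 + t_tot * dt) / 2, tolerance = 1e-10)
})

test_that("harmonic oscillator energy stays bounded over 1000 steps", {
  # 1D oscillator via a stiff bond; period T = 2 pi sqrt(m / (2 k))
  types <- atom_type_table(0, 1)
  k_b <- 10; m <- 1
  topo <- md_topology(2, bonds = data.frame(i = 1, j = 2, k_b = k_b,
                                            r0 = 2))
  pos <- rbind(c(48.7, 50, 50), c(51.3, 50, 50))  # stretched by 0.6
  sys <- md_system(pos, matrix(0, 2, 3), c(m, m), c(0, 0), c(1L, 1L),
                   types, c(100, 100, 100), topology = topo)
  omega <- sqrt(2 * 2 * k_b / m)  # reduced-mass oscillator, E = K x^2
  period <- 2 * pi / omega
  dt <- period / 100
  cfg <- pipeline_config(alpha = 0, cutoff_radius = 1e-3)
  fmt <- fixed_format(lsb = 1e-6)  # peak force ~12 stays within the word
  e0 <- k_b * 0.6^2
  energies <- numeric(1000)
  for (i in 1:1000) {
    ff <- compute_forces(sys, cfg, force_fmt = fmt)
    vhalf_old <- sys$velocities
    sys <- leapfrog_step(sys, ff$forces, dt, accel_unit = 1)
    vmid <- (vhalf_old + sys$velocities) / 2
    ke <- 0.5 * sum(sys$masses * rowSums(vmid^2))
    energies[i] <- ke + ff$e_bonded
  }
  # bounded oscillation with no systematic drift beyond O(dt^2)
  expect_lt(max(abs(energies - e0)) / e0, (2 * pi / 100)^2 * 2)
  late <- mean(energies[900:1000]); early <- mean(energies[1:100])
  expect_lt(abs(late - early) / e0, 1e-3)
})

test_that("each step conserves momentum exactly in fixed point", {
  sys <- generate_system("toy_polymer", 12, 0.002, seed = 8,
                         temperature = 200)
  cfg <- pipeline_config(alpha = 0, cutoff_radius = min(sys$box) * 0.4)
  out <- run_step(sys, cfg, dt = 0.5)
  expect_identical(out$net_force_words, c(0, 0, 0))
  res <- run_md(sys, cfg, n_steps = 20, dt = 0.5)
  expect_identical(res$max_net_force_words, 0)
})

test_that("decomposed and flat force paths agree bit-exactly", {
  sys <- generate_system("lj_fluid", 64, 0.012, seed = 5)
  cutoff <- min(sys$box) / 2 * 0.8
  cfg <- pipeline_config(alpha = 0, cutoff_radius = cutoff)
  flat <- compute_forces(sys, cfg)
  dec <- decompose(sys, cell_size = cutoff, cutoff = cutoff)
  # scramble the pair order: fixed-point accumulation is order-free
  perm <- sample(nrow(dec$pairs))
  via_dec <- compute_forces(sys, cfg, pairs = dec$pairs[perm, ])
  expect_identical(via_dec$words, flat$words)
})

test_that("short microcanonical LJ run conserves energy", {
  sys <- generate_system("lj_fluid", 216, 0.0125, seed = 13,
                         temperature = 110)
  cfg <- pipeline_config(alpha = 0, cutoff_radius = min(sys$box) / 2 * 0.9)
  res <- run_md(sys, cfg, n_steps = 100, dt = 1, record_every = 2)
  E <- res$energies$total
  expect_lt(max(abs(E - E[1])) / abs(E[1]), 1e-3)
  expect_identical(res$max_net_force_words, 0)
})

test_that("XYZ and PDB writers emit the standard layouts", {
  sys <- generate_system("lj_fluid", 2, 0.001, seed = 1)
  f <- tempfile(fileext = ".xyz")
  write_xyz(sys, f, step = 7)
  lines <- readLines(f)
  expect_length(lines, 4)  # count, comment, 2 atom rows
  expect_equal(as.integer(lines[1]), 2)
  back <- read_xyz(f)
  expect_equal(back$step, 7L)
  expect_equal(back$positions, unname(sys$positions), tolerance = 1e-7)
  expect_equal(back$box, sys$box, tolerance = 1e-5)
  unlink(f)
  fp <- tempfile(fileext = ".pdb")
  write_pdb(sys, fp)
  pl <- readLines(fp)
  expect_match(pl[1], "^CRYST1")
  atoms <- grep("^ATOM", pl, value = TRUE)
  expect_length(atoms, 2)
  # fixed-column layout: coordinates in columns 31-54
  x <- as.numeric(substr(atoms[1], 31, 38))
  expect_equal(x, sys$positions[1, 1], tolerance = 1e-3)
  unlink(fp)
})

test_that("energy logs are written as tab-separated columns", {
  sys <- generate_system("lj_fluid", 16, 0.012, seed = 2)
  cfg <- pipeline_config(alpha = 0, cutoff_radius = min(sys$box) * 0.4)
  res <- run_md(sys, cfg, n_steps = 5, dt = 1)
  f <- tempfile(fileext = ".tsv")
  write_energies(res$energies, f)
  tab <- utils::read.delim(f)
  expect_equal(nrow(tab), 5)
  expect_true(all(c("step", "kinetic", "potential", "total") %in%
                    names(tab)))
  unlink(f)
})
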