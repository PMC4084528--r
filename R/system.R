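# MD system container and synthetic system generators.  Internal units
# follow the Amber ecosystem: Angstrom, femtosecond, atomic mass unit,
# elementary charge, kcal/mol.  The acceleration conversion constant
# (kcal/mol/Angstrom per amu -> Angstrom/fs^2) is 4.184e-4.

#' Acceleration unit conversion constant
#'
#' Converts force/mass in (kcal/mol/Angstrom)/amu to acceleration in
#' Angstrom/fs^2.
#'
#' @return the constant 4.184e-4.
#' @export
md_accel_unit <- function() 4.184e-4

#' Boltzmann constant in internal units
#'
#' @return kcal/(mol K).
#' @export
md_boltzmann <- function() 0.0019872041

#' MD system container
#'
#' Particles (positions, velocities, masses, charges, type indices,
#' optional group labels), the bonded topology, the non-bonded exclusion
#' list, the Lennard-Jones type table and the periodic box.
#'
#' @param positions n x 3 matrix, wrapped into `[0, box)`.
#' @param velocities n x 3 matrix (Angstrom/fs).
#' @param masses length-n, positive (amu).
#' @param charges length-n (elementary charges).
#' @param type_idx length-n 1-based indices into `types`.
#' @param types an [atom_type_table()].
#' @param box length-3 box edges (Angstrom).
#' @param topology optional [md_topology()].
#' @param groups optional per-particle group labels.
#' @param exclusions optional 2-column matrix of non-bonded excluded
#'   pairs (stored symmetric, as unordered pairs).
#' @return an object of class `md_system`.
#' @export
md_system <- function(positions, velocities, masses, charges, type_idx,
                      types, box, topology = NULL, groups = NULL,
                      exclusions = NULL) {
  positions <- matrix(positions, ncol = 3)
  velocities <- matrix(velocities, ncol = 3)
  n <- nrow(positions)
  stopifnot(nrow(velocities) == n, length(masses) == n,
            length(charges) == n, length(type_idx) == n,
            inherits(types, "atom_type_table"), length(box) == 3L)
  if (any(masses <= 0)) stop("masses must be positive")
  bx <- matrix(box, n, 3, byrow = TRUE)
  if (any(positions < 0 | positions >= bx)) {
    stop("positions must be wrapped into [0, box)")
  }
  if (!is.null(topology)) stopifnot(inherits(topology, "md_topology"))
  if (!is.null(exclusions)) {
    exclusions <- matrix(exclusions, ncol = 2)
    exclusions <- unique(cbind(pmin(exclusions[, 1], exclusions[, 2]),
                               pmax(exclusions[, 1], exclusions[, 2])))
  }
  structure(
    list(positions = positions, velocities = velocities,
         masses = as.numeric(masses), charges = as.numeric(charges),
         type_idx = as.integer(type_idx), types = types,
         box = as.numeric(box), topology = topology,
         groups = groups, exclusions = exclusions, n = n),
    class = "md_system"
  )
}

#' @export
print.md_system <- function(x, ...) {
  cat(sprintf(
    "<md_system> %d particles, box %.2f x %.2f x %.2f, net charge %.3g\n",
    x$n, x$box[1], x$box[2], x$box[3], sum(x$charges)))
  if (!is.null(x$topology)) print(x$topology)
  invisible(x)
}

# wrap positions into [0, box)
wrap_positions <- function(pos, box) {
  bx <- matrix(box, nrow(pos), 3, byrow = TRUE)
  pos - bx * floor(pos / bx)
}

#' Generate a synthetic molecular system
#'
#' Reproducible (seeded) generators for the three study systems:
#' `lj_fluid` -- a neutral Lennard-Jones fluid (argon-like parameters) on
#' a jittered lattice with Maxwell-Boltzmann velocities; `salt_lattice` --
#' a rock-salt arrangement of alternating +1/-1 charges (the Madelung
#' benchmark); `toy_polymer` -- a single chain with bonds, angles,
#' torsions and matching 1-2/1-3 non-bonded exclusions.
#'
#' @param kind `"lj_fluid"`, `"salt_lattice"` or `"toy_polymer"`.
#' @param n_particles number of particles (`>= 2`); `salt_lattice`
#'   requires a cube of an even integer (8, 64, 216, ...).
#' @param density particles per cubic Angstrom; sets the box volume.
#' @param seed RNG seed; identical seeds give identical systems.
#' @param temperature initial kinetic temperature in K.
#' @param exclude14 for `toy_polymer`: also exclude 1-4 pairs from
#'   non-bonded interactions (default `FALSE`, i.e. full 1-4).
#' @return an [md_system()].
#' @export
generate_system <- function(kind = c("lj_fluid", "salt_lattice",
                                     "toy_polymer"),
                            n_particles, density, seed = 1L,
                            temperature = 120, exclude14 = FALSE) {
  kind <- match.arg(kind)
  stopifnot(n_particles >= 2, density > 0)
  set.seed(seed)
  L <- (n_particles / density)^(1 / 3)
  switch(kind,
    lj_fluid = generate_lj_fluid(n_particles, L, temperature),
    salt_lattice = generate_salt_lattice(n_particles, L, temperature),
    toy_polymer = generate_toy_polymer(n_particles, L, temperature,
                                       exclude14)
  )
}

mb_velocities <- function(n, masses, temperature) {
  sd <- sqrt(md_boltzmann() * temperature * md_accel_unit() / masses)
  v <- matrix(stats::rnorm(3 * n), n, 3) * sd
  # remove net momentum
  p <- colSums(v * masses) / sum(masses)
  sweep(v, 2, p, "-")
}

lattice_sites <- function(n, L) {
  s <- ceiling(n^(1 / 3))
  g <- expand.grid(x = 0:(s - 1), y = 0:(s - 1), z = 0:(s - 1))
  as.matrix(g[seq_len(n), ]) * (L / s) + L / (2 * s)
}

generate_lj_fluid <- function(n, L, temperature) {
  sigma <- 3.4; epsilon <- 0.238; mass <- 39.948  # argon-like
  s <- ceiling(n^(1 / 3))
  spacing <- L / s
  pos <- lattice_sites(n, L)
  pos <- pos + matrix(stats::runif(3 * n, -0.05, 0.05) * spacing, n, 3)
  pos <- wrap_positions(pos, rep(L, 3))
  if (min_pair_distance(pos, rep(L, 3)) < 0.85 * sigma) {
    stop("density too high: particles overlap beyond tolerance")
  }
  md_system(
    positions = pos,
    velocities = mb_velocities(n, rep(mass, n), temperature),
    masses = rep(mass, n), charges = rep(0, n),
    type_idx = rep(1L, n),
    types = atom_type_table(epsilon = epsilon, sigma = sigma),
    box = rep(L, 3)
  )
}

generate_salt_lattice <- function(n, L, temperature) {
  s <- round(n^(1 / 3))
  if (s^3 != n || s %% 2 != 0) {
    stop("salt_lattice requires n = s^3 with s even (8, 64, 216, ...)")
  }
  g <- expand.grid(x = 0:(s - 1), y = 0:(s - 1), z = 0:(s - 1))
  a <- L / s
  pos <- as.matrix(g) * a + a / 2
  q <- ifelse((g$x + g$y + g$z) %% 2 == 0, 1, -1)
  masses <- ifelse(q > 0, 22.99, 35.45)
  md_system(
    positions = pos,
    velocities = mb_velocities(n, masses, temperature),
    masses = masses, charges = q,
    type_idx = rep(1L, n),
    types = atom_type_table(epsilon = 0.1, sigma = 2.8),
    box = rep(L, 3)
  )
}

generate_toy_polymer <- function(n, L, temperature, exclude14 = FALSE) {
  r0 <- 1.53; theta0 <- 111 * pi / 180
  # zig-zag backbone with small random perturbations, centred in the box
  pos <- matrix(0, n, 3)
  dirs <- matrix(0, n - 1, 3)
  step_len <- r0
  for (i in seq_len(n - 1)) {
    ang <- (pi - theta0) / 2 * if (i %% 2 == 0) 1 else -1
    dirs[i, ] <- c(cos(ang), sin(ang), 0)
  }
  for (i in 2:n) pos[i, ] <- pos[i - 1, ] + step_len * dirs[i - 1, ]
  pos <- pos + matrix(stats::rnorm(3 * n, 0, 0.03), n, 3)
  pos <- sweep(pos, 2, colMeans(pos), "-")
  pos <- sweep(pos, 2, rep(L / 2, 3), "+")
  if (any(pos < 0 | pos >= L)) {
    stop("density too high: chain does not fit in the box")
  }
  bonds <- data.frame(i = 1:(n - 1), j = 2:n, k_b = 310, r0 = r0)
  angles <- if (n >= 3) {
    data.frame(i = 1:(n - 2), j = 2:(n - 1), k = 3:n,
               k_theta = 40, theta0 = theta0)
  } else NULL
  torsions <- if (n >= 4) {
    data.frame(i = 1:(n - 3), j = 2:(n - 2), k = 3:(n - 1), l = 4:n,
               v_n = 1.4, n = 3, gamma = 0)
  } else NULL
  topo <- md_topology(n, bonds, angles, torsions)
  ex12 <- cbind(bonds$i, bonds$j)
  ex13 <- if (n >= 3) cbind(1:(n - 2), 3:n) else NULL
  ex14 <- if (exclude14 && n >= 4) cbind(1:(n - 3), 4:n) else NULL
  mass <- 14.027  # CH2 bead
  md_system(
    positions = pos,
    velocities = mb_velocities(n, rep(mass, n), temperature),
    masses = rep(mass, n), charges = rep(0, n),
    type_idx = rep(1L, n),
    types = atom_type_table(epsilon = 0.1094, sigma = 3.39),
    box = rep(L, 3), topology = topo,
    exclusions = rbind(ex12, ex13, ex14)
  )
}

# smallest minimum-image pair distance (brute force; generator guard)
min_pair_distance <- function(pos, box) {
  n <- nrow(pos)
  if (n < 2) return(Inf)
  prs <- utils::combn(n, 2L)
  d <- min_image(pos[prs[1, ], , drop = FALSE] -
                   pos[prs[2, ], , drop = FALSE], box)
  sqrt(min(rowSums(d^2)))
}
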