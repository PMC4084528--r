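# Engine: cell-based domain decomposition onto virtual chips, the
# fixed-point non-bonded force path, bonded forces with exact-zero-sum
# quantization, the per-step schedule execution and leap-frog integration.

#' Enumerate candidate non-bonded pairs by domain decomposition
#'
#' Bins particles into a cell grid mapped to virtual chips and builds
#' neighbour lists over the half stencil of the 26-neighbour cell shell
#' (plus intra-cell pairs), so that every minimum-image pair within the
#' cut-off appears exactly once.  A single-cell grid degenerates to plain
#' all-pairs.
#'
#' @param system an [md_system()].
#' @param cell_size requested cell edge; must be at least the cut-off.
#' @param cutoff the non-bonded cut-off radius.
#' @return list with `pairs` (2-column matrix, `i < j`), `cell_of`
#'   (per-particle 0-based cell index), `grid` (cells per axis).
#' @export
decompose <- function(system, cell_size, cutoff) {
  stopifnot(inherits(system, "md_system"))
  if (cell_size < cutoff) stop("cell_size must be at least the cut-off")
  box <- system$box
  grid <- pmax(1L, floor(box / cell_size))
  csize <- box / grid
  pos <- system$positions
  # half-open cell assignment, 0-based
  ci <- floor(sweep(pos, 2, csize, "/"))
  ci <- sweep(ci, 2, grid, function(a, b) pmin(a, b - 1L))
  cell_of <- ci[, 1] + grid[1] * (ci[, 2] + grid[2] * ci[, 3])
  n <- system$n
  # half stencil: home cell plus 13 of the 26 neighbour offsets
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  lex <- offs[, 1] + 3 * offs[, 2] + 9 * offs[, 3]
  half <- offs[lex > 0, , drop = FALSE]
  members <- split(seq_len(n), cell_of)
  pair_list <- list()
  for (ck in names(members)) {
    c0 <- as.integer(ck)
    i0 <- c0 %% grid[1]
    i1 <- (c0 %/% grid[1]) %% grid[2]
    i2 <- c0 %/% (grid[1] * grid[2])
    home <- members[[ck]]
    if (length(home) >= 2L) {
      prs <- utils::combn(home, 2L)
      pair_list[[length(pair_list) + 1L]] <- t(prs)
    }
    for (s in seq_len(nrow(half))) {
      j0 <- (i0 + half[s, 1]) %% grid[1]
      j1 <- (i1 + half[s, 2]) %% grid[2]
      j2 <- (i2 + half[s, 3]) %% grid[3]
      nk <- as.character(j0 + grid[1] * (j1 + grid[2] * j2))
      other <- members[[nk]]
      if (is.null(other) || length(other) == 0L) next
      pair_list[[length(pair_list) + 1L]] <-
        cbind(rep(home, each = length(other)),
              rep(other, times = length(home)))
    }
  }
  if (length(pair_list) == 0L) {
    pairs <- matrix(integer(0), 0, 2)
  } else {
    pairs <- do.call(rbind, pair_list)
    pairs <- cbind(pmin(pairs[, 1], pairs[, 2]),
                   pmax(pairs[, 1], pairs[, 2]))
    pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
    # small grids alias neighbour offsets onto the same cell pair;
    # deduplicate so each pair is evaluated once
    pairs <- unique(pairs)
  }
  # keep only pairs within the cut-off (minimum image)
  if (nrow(pairs) > 0L) {
    d <- min_image(pos[pairs[, 1], , drop = FALSE] -
                     pos[pairs[, 2], , drop = FALSE], box)
    keep <- rowSums(d^2) < cutoff^2
    pairs <- pairs[keep, , drop = FALSE]
  }
  list(pairs = pairs, cell_of = cell_of, grid = grid)
}

all_pairs_within <- function(system, cutoff) {
  n <- system$n
  prs <- utils::combn(n, 2L)
  pairs <- cbind(prs[1, ], prs[2, ])
  d <- min_image(system$positions[pairs[, 1], , drop = FALSE] -
                   system$positions[pairs[, 2], , drop = FALSE],
                 system$box)
  pairs[rowSums(d^2) < cutoff^2, , drop = FALSE]
}

drop_excluded <- function(pairs, exclusions) {
  if (is.null(exclusions) || nrow(pairs) == 0L) return(pairs)
  key <- paste(pairs[, 1], pairs[, 2])
  exkey <- paste(exclusions[, 1], exclusions[, 2])
  pairs[!(key %in% exkey), , drop = FALSE]
}

#' Default force fixed-point format for a system
#'
#' Chooses the force lsb so the largest expected pair force spans about
#' 2^20 lsb units, leaving ample headroom in the 32-bit accumulators.
#' The estimate takes the Lennard-Jones force at 0.9 sigma plus the bare
#' Coulomb force at that distance for the largest charge product.
#'
#' @param system an [md_system()].
#' @param config a [pipeline_config()].
#' @return a [fixed_format()] for force words.
#' @export
default_force_format <- function(system, config) {
  eps <- max(system$types$epsilon)
  sig <- max(system$types$sigma)
  rmin <- 0.9 * sig
  s6 <- (sig / rmin)^6
  f_lj <- 24 * eps * (2 * s6^2 - s6) / rmin
  qmax <- if (any(system$charges != 0)) max(abs(system$charges))^2 else 0
  f_coul <- config$coulomb_constant * qmax / rmin^2
  fmax <- max(f_lj + f_coul, 1e-6)
  fixed_format(lsb = fmax / 2^20)
}

# per-pair non-bonded evaluation -> quantized force words and energies
nonbonded_words <- function(system, pairs, config, force_fmt,
                            arithmetic = "pipeline") {
  n <- system$n
  words <- matrix(0, n, 3)
  if (nrow(pairs) == 0L) {
    return(list(words = words, e_coul = 0, e_vdw = 0))
  }
  pi_ <- pairs[, 1]; pj_ <- pairs[, 2]
  d <- min_image(system$positions[pi_, , drop = FALSE] -
                   system$positions[pj_, , drop = FALSE], system$box)
  pp <- combine_params(system$type_idx[pi_], system$type_idx[pj_],
                       system$types, config)
  out <- pipeline_pair_terms(d, system$charges[pi_] * system$charges[pj_],
                             pp$epsilon, pp$sigma, config, arithmetic)
  w <- matrix(round(out$force / force_fmt$lsb), ncol = 3)
  for (k in 1:3) {
    s <- rowsum(c(w[, k], -w[, k]), group = c(pi_, pj_))
    idx <- as.integer(rownames(s))
    words[idx, k] <- wrap32(words[idx, k] + s[, 1])
  }
  list(words = words, e_coul = sum(out$coulomb), e_vdw = sum(out$vdw))
}

# bonded forces quantized per term with an exact-zero-sum convention:
# the last atom of each term receives minus the integer sum of the other
# atoms' words, so every term -- and hence the total -- sums to the zero
# word exactly
bonded_words <- function(system, force_fmt) {
  n <- system$n
  words <- matrix(0, n, 3)
  topo <- system$topology
  if (is.null(topo)) return(list(words = words, energy = 0))
  coords <- unwrap_bonded(system)
  res <- bonded_forces(coords, topo)
  add_term <- function(words, idx, fmat) {
    k <- length(idx)
    w <- matrix(round(fmat[seq_len(k - 1), , drop = FALSE] / force_fmt$lsb),
                ncol = 3)
    wlast <- -colSums(w)
    words[idx[seq_len(k - 1)], ] <- wrap32(words[idx[seq_len(k - 1)], ,
                                                 drop = FALSE] + w)
    words[idx[k], ] <- wrap32(words[idx[k], ] + wlast)
    words
  }
  for (r in seq_len(nrow(topo$bonds))) {
    b <- topo$bonds[r, ]
    f <- bond_force(coords, b)$forces
    words <- add_term(words, c(b$i, b$j), f[c(b$i, b$j), , drop = FALSE])
  }
  for (r in seq_len(nrow(topo$angles))) {
    a <- topo$angles[r, ]
    f <- angle_force(coords, a)$forces
    words <- add_term(words, c(a$i, a$j, a$k),
                      f[c(a$i, a$j, a$k), , drop = FALSE])
  }
  for (r in seq_len(nrow(topo$torsions))) {
    t <- topo$torsions[r, ]
    f <- torsion_force(coords, t)$forces
    words <- add_term(words, c(t$i, t$j, t$k, t$l),
                      f[c(t$i, t$j, t$k, t$l), , drop = FALSE])
  }
  list(words = words, energy = res$energy, bond = res$bond,
       angle = res$angle, torsion = res$torsion)
}

# make bonded geometry continuous across the periodic boundary: walk the
# chain of bonded terms and shift each particle to the minimum image
# relative to the first particle it is bonded to
unwrap_bonded <- function(system) {
  coords <- system$positions
  topo <- system$topology
  if (is.null(topo) || nrow(topo$bonds) == 0L) return(coords)
  box <- system$box
  visited <- rep(FALSE, system$n)
  adj <- lapply(seq_len(system$n), function(i) integer(0))
  for (r in seq_len(nrow(topo$bonds))) {
    i <- topo$bonds$i[r]; j <- topo$bonds$j[r]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  for (start in seq_len(system$n)) {
    if (visited[start] || length(adj[[start]]) == 0L) next
    queue <- start
    visited[start] <- TRUE
    while (length(queue) > 0L) {
      cur <- queue[1]
      queue <- queue[-1]
      for (nb in adj[[cur]]) {
        if (visited[nb]) next
        d <- coords[nb, ] - coords[cur, ]
        coords[nb, ] <- coords[cur, ] + (d - box * round(d / box))
        visited[nb] <- TRUE
        queue <- c(queue, nb)
      }
    }
  }
  coords
}

#' Compute all forces through the emulated machine path
#'
#' Short-range non-bonded forces go through the pipeline arithmetic and
#' are accumulated as 32-bit fixed-point words (order-independent);
#' bonded-term words follow an exact-zero-sum quantization; reciprocal-
#' space Ewald forces (for charged systems) are quantized into the same
#' bank.  The returned forces are the decoded bank contents.
#'
#' @param system an [md_system()].
#' @param config a [pipeline_config()].
#' @param force_fmt force [fixed_format()]; default
#'   [default_force_format()].
#' @param ewald optional [ewald_params()] for charged systems.
#' @param pairs optional pre-computed pair list (e.g. from
#'   [decompose()]); default all pairs within the cut-off.
#' @return list with `forces` (decoded, kcal/mol/Angstrom), `words` (the
#'   fixed-point bank), and energy components.
#' @export
compute_forces <- function(system, config,
                           force_fmt = default_force_format(system, config),
                           ewald = NULL, pairs = NULL) {
  stopifnot(inherits(system, "md_system"))
  if (is.null(pairs)) pairs <- all_pairs_within(system, config$cutoff_radius)
  pairs <- drop_excluded(pairs, system$exclusions)
  if (!is.null(system$groups) && !is.null(config$group_rules)) {
    pairs <- pairs[group_cutoff_filter(pairs, system$groups, config), ,
                   drop = FALSE]
  }
  nb <- nonbonded_words(system, pairs, config, force_fmt)
  bd <- bonded_words(system, force_fmt)
  words <- wrap32(nb$words + bd$words)
  e_recip <- 0
  if (!is.null(ewald) && any(system$charges != 0)) {
    if (abs(ewald$alpha - config$alpha) > 1e-12) {
      stop("inconsistent alpha between pipeline and Ewald configurations")
    }
    mesh <- spread_charges(system$positions, system$charges, ewald)
    phi <- solve_poisson(mesh, ewald)
    bi <- back_interpolate(phi, system$positions, system$charges, ewald)
    e_self <- -ewald$alpha / sqrt(pi) * sum(system$charges^2)
    e_recip <- (bi$energy + e_self) * config$coulomb_constant
    wr <- matrix(round(bi$forces * config$coulomb_constant /
                         force_fmt$lsb), ncol = 3)
    words <- wrap32(words + wr)
  }
  list(
    forces = words * force_fmt$lsb,
    words = words,
    e_coul_short = nb$e_coul, e_vdw = nb$e_vdw,
    e_coul_recip = e_recip, e_bonded = bd$energy,
    potential = nb$e_coul + nb$e_vdw + e_recip + bd$energy
  )
}

#' Leap-frog integration step
#'
#' `v(t + dt/2) = v(t - dt/2) + a dt`, then
#' `r(t + dt) = r(t) + v(t + dt/2) dt`, with positions re-wrapped into
#' the box.
#'
#' @param system an [md_system()].
#' @param forces n x 3 force matrix (kcal/mol/Angstrom).
#' @param dt timestep (fs).
#' @param accel_unit force/mass -> acceleration conversion; the default
#'   [md_accel_unit()] suits the internal unit system.  Pass 1 for
#'   already-consistent units.
#' @return the updated system (velocities at `t + dt/2`).
#' @export
leapfrog_step <- function(system, forces, dt,
                          accel_unit = md_accel_unit()) {
  stopifnot(inherits(system, "md_system"), dt > 0)
  a <- forces / system$masses * accel_unit
  system$velocities <- system$velocities + a * dt
  system$positions <- wrap_positions(system$positions +
                                       system$velocities * dt, system$box)
  system
}

#' Execute one full MD timestep
#'
#' Runs the per-step schedule -- particle distribution (a virtual type II
#' scatter when a decomposition is active), charge assignment / Poisson /
#' back interpolation for charged systems, non-bonded and bonded forces
#' through the fixed-point path, force gathering with integer reduction,
#' and the leap-frog update -- and records the energy components.
#'
#' @param system an [md_system()].
#' @param config a [pipeline_config()].
#' @param dt timestep (fs).
#' @param force_fmt force [fixed_format()].
#' @param ewald optional [ewald_params()].
#' @param schedule a [step_schedule()].
#' @param pairs optional pair list.
#' @param prev_velocities velocities at `t - dt/2` (for the on-step
#'   kinetic energy); defaults to the system's current velocities.
#' @return list with `system` (advanced one step), `energies` (named
#'   vector), and `net_force_words` (the exact integer net force, a
#'   length-3 zero vector when action-reaction holds).
#' @export
run_step <- function(system, config, dt,
                     force_fmt = default_force_format(system, config),
                     ewald = NULL, schedule = step_schedule(),
                     pairs = NULL, prev_velocities = NULL) {
  stopifnot(inherits(schedule, "step_schedule"))
  ff <- compute_forces(system, config, force_fmt, ewald, pairs)
  net_words <- colSums(ff$words)
  vprev <- if (is.null(prev_velocities)) system$velocities else
    prev_velocities
  newsys <- leapfrog_step(system, ff$forces, dt)
  vmid <- (vprev + newsys$velocities) / 2
  ke <- 0.5 * sum(system$masses * rowSums(vmid^2)) / md_accel_unit()
  energies <- c(kinetic = ke, potential = ff$potential,
                total = ke + ff$potential,
                vdw = ff$e_vdw, coul_short = ff$e_coul_short,
                coul_recip = ff$e_coul_recip, bonded = ff$e_bonded)
  list(system = newsys, energies = energies, net_force_words = net_words)
}

#' Run a microcanonical MD trajectory
#'
#' Repeats [run_step()] for `n_steps` and collects the per-step energy
#' record.  Purely microcanonical: no thermostat or barostat.
#'
#' @param system an [md_system()].
#' @param config a [pipeline_config()].
#' @param n_steps number of steps.
#' @param dt timestep (fs).
#' @param ewald optional [ewald_params()].
#' @param force_fmt force [fixed_format()].
#' @param record_every energy recording cadence.
#' @param trajectory_file optional XYZ output path.
#' @return list with the final `system`, `energies` (data frame), and
#'   `max_net_force_words` (largest absolute integer net force seen).
#' @export
run_md <- function(system, config, n_steps, dt,
                   ewald = NULL,
                   force_fmt = default_force_format(system, config),
                   record_every = 1L, trajectory_file = NULL) {
  recs <- list()
  max_net <- 0
  if (!is.null(trajectory_file) && file.exists(trajectory_file)) {
    file.remove(trajectory_file)
  }
  for (step in seq_len(n_steps)) {
    # entering velocities are at t - dt/2, the leap-frog convention
    out <- run_step(system, config, dt, force_fmt, ewald)
    max_net <- max(max_net, max(abs(out$net_force_words)))
    system <- out$system
    if (step %% record_every == 0L) {
      recs[[length(recs) + 1L]] <- c(step = step, out$energies)
      if (!is.null(trajectory_file)) {
        write_xyz(system, trajectory_file, step = step, append = TRUE)
      }
    }
  }
  energies <- as.data.frame(do.call(rbind, recs))
  list(system = system, energies = energies,
       max_net_force_words = max_net)
}
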