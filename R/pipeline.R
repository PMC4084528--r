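# Emulation of the non-bonded force pipeline: simultaneous Coulomb +
# van der Waals force/potential evaluation through ROM-table arithmetic,
# cut-off kernels, combination rules, action-reaction accumulation and
# 16-particle block semantics.

# complementary error function with full relative accuracy in the tail
erfc_ref <- function(t) 2 * stats::pnorm(t * sqrt(2), lower.tail = FALSE)

#' Atom-type parameter table
#'
#' Per-type Lennard-Jones parameters looked up by the pipeline.  The
#' modelled hardware stores at most 64 atom types.
#'
#' @param epsilon numeric vector of well depths (energy units), `>= 0`.
#' @param sigma numeric vector of radii (length units), `> 0`.
#' @return an object of class `atom_type_table`.
#' @export
atom_type_table <- function(epsilon, sigma) {
  stopifnot(length(epsilon) == length(sigma))
  if (length(epsilon) > 64L) stop("the maximum number of atom types is 64")
  if (length(epsilon) < 1L) stop("at least one atom type is required")
  if (any(epsilon < 0)) stop("epsilon must be non-negative")
  if (any(sigma <= 0)) stop("sigma must be positive")
  structure(
    list(epsilon = as.numeric(epsilon), sigma = as.numeric(sigma)),
    class = "atom_type_table"
  )
}

#' @export
print.atom_type_table <- function(x, ...) {
  cat(sprintf("<atom_type_table> %d type(s)\n", length(x$epsilon)))
  invisible(x)
}

#' Combine per-type Lennard-Jones parameters for a pair
#'
#' Builds `(epsilon_ij, sigma_ij)` from the per-atom values by the
#' configured rule per parameter (arithmetic or geometric mean).  The
#' default configuration is Lorentz-Berthelot: arithmetic `sigma`,
#' geometric `epsilon`.
#'
#' @param type_i,type_j 1-based type indices (vectorized).
#' @param types an [atom_type_table()].
#' @param config a [pipeline_config()].
#' @return list with numeric vectors `epsilon` and `sigma`.
#' @export
combine_params <- function(type_i, type_j, types, config) {
  stopifnot(inherits(types, "atom_type_table"))
  n <- length(types$epsilon)
  if (any(type_i < 1 | type_i > n | type_j < 1 | type_j > n)) {
    stop("unknown atom type index")
  }
  comb <- function(a, b, rule) {
    if (rule == "arithmetic") (a + b) / 2 else sqrt(a * b)
  }
  list(
    epsilon = comb(types$epsilon[type_i], types$epsilon[type_j],
                   config$combination_rule_epsilon),
    sigma = comb(types$sigma[type_i], types$sigma[type_j],
                 config$combination_rule_sigma)
  )
}

# analytic cut-off factors; the potential factor g_phi enters as
# phi_c = k q_i q_j g_phi(alpha r) / r and the force factor is
# g_c(t) = g_phi(t) - t g_phi'(t), which makes f = -grad phi exact
cutoff_phi_fun <- function(kernel, t_c) {
  if (kernel == "gaussian") {
    erfc_ref
  } else {
    function(t) {
      s <- pmin((t / t_c)^2, 1)
      1 - 10 * s^3 + 15 * s^4 - 6 * s^5
    }
  }
}

cutoff_force_fun <- function(kernel, t_c) {
  if (kernel == "gaussian") {
    function(t) erfc_ref(t) + 2 * t / sqrt(pi) * exp(-t^2)
  } else {
    function(t) {
      s <- pmin((t / t_c)^2, 1)
      g <- 1 - 10 * s^3 + 15 * s^4 - 6 * s^5
      dg_ds <- -30 * s^2 + 60 * s^3 - 30 * s^4
      # t g'(t) = 2 s dg/ds since s = (t/t_c)^2
      g - 2 * s * dg_ds
    }
  }
}

#' Pipeline configuration
#'
#' Collects the tunable parameters of the emulated non-bonded pipeline: the
#' Ewald splitting constant `alpha`, the Coulomb cut-off kernel, combination
#' rules, cut-off radius, optional soft-core van der Waals settings and
#' optional group-based cut-off rules.  ROM tables for the cut-off factors
#' and the reciprocal square root are built once at construction.
#'
#' @param alpha Ewald splitting constant (inverse length), `>= 0`.
#' @param cutoff_radius pair cut-off radius (length units), `> 0`.
#' @param kernel Coulomb cut-off kernel: `"gaussian"` (complementary error
#'   function, the Ewald real-space screen) or `"finite_support"` (a quintic
#'   taper in `r^2/r_c^2` that reaches zero with two vanishing derivatives
#'   at the cut-off).
#' @param combination_rule_sigma,combination_rule_epsilon `"arithmetic"` or
#'   `"geometric"`; defaults are Lorentz-Berthelot.
#' @param coulomb_constant prefactor of `q_i q_j / r` in energy units
#'   (1 for Gaussian units; 332.0637 for kcal/mol, e, Angstrom).
#' @param softcore optional `list(lambda =, alpha_sc =)` for soft-core van
#'   der Waals (see [softcore_vdw()]).
#' @param group_rules optional `list(exclude_same_group =, exclude_pairs =)`
#'   for [group_cutoff_filter()].
#' @param table_segments segments used for the ROM tables.
#' @param r2_min smallest squared distance covered by the reciprocal square
#'   root table.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(alpha, cutoff_radius,
                            kernel = c("gaussian", "finite_support"),
                            combination_rule_sigma = c("arithmetic", "geometric"),
                            combination_rule_epsilon = c("geometric", "arithmetic"),
                            coulomb_constant = 1,
                            softcore = NULL,
                            group_rules = NULL,
                            table_segments = 4096L,
                            r2_min = 1e-6) {
  kernel <- match.arg(kernel)
  combination_rule_sigma <- match.arg(combination_rule_sigma)
  combination_rule_epsilon <- match.arg(combination_rule_epsilon)
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha >= 0)
  stopifnot(is.numeric(cutoff_radius), cutoff_radius > 0)
  if (kernel == "finite_support" && alpha <= 0) {
    stop("the finite-support kernel requires alpha > 0")
  }
  if (!is.null(softcore)) {
    stopifnot(is.list(softcore))
    lam <- softcore$lambda
    if (is.null(lam) || lam < 0 || lam > 1) {
      stop("softcore$lambda must lie in [0, 1]")
    }
    if (is.null(softcore$alpha_sc)) softcore$alpha_sc <- 0.5
  }
  t_c <- alpha * cutoff_radius
  cfg <- structure(
    list(
      alpha = alpha, cutoff_radius = cutoff_radius, kernel = kernel,
      combination_rule_sigma = combination_rule_sigma,
      combination_rule_epsilon = combination_rule_epsilon,
      coulomb_constant = coulomb_constant,
      softcore = softcore, group_rules = group_rules,
      t_c = t_c
    ),
    class = "pipeline_config"
  )
  # ROM tables; alpha = 0 leaves the Coulomb factors constant at 1
  if (alpha > 0) {
    cfg$tab_phi <- build_function_table(cutoff_phi_fun(kernel, t_c),
                                        0, t_c, table_segments, "uniform")
    cfg$tab_force <- build_function_table(cutoff_force_fun(kernel, t_c),
                                          0, t_c, table_segments, "uniform")
  }
  r2_min <- min(r2_min, cutoff_radius^2 / 1e6)
  cfg$tab_rsqrt <- build_function_table(function(u) 1 / sqrt(u),
                                        r2_min, cutoff_radius^2,
                                        2L * table_segments, "log")
  cfg
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf(
    "<pipeline_config> kernel=%s alpha=%.4g cutoff=%.4g (sigma:%s, epsilon:%s)\n",
    x$kernel, x$alpha, x$cutoff_radius,
    x$combination_rule_sigma, x$combination_rule_epsilon
  ))
  invisible(x)
}

#' Coulomb cut-off factor
#'
#' The dimensionless factor applied to the bare Coulomb potential at
#' `t = alpha * r`.  The Gaussian kernel returns `erfc(t)` (the Ewald
#' real-space screen); the finite-support kernel returns a quintic taper in
#' `(t/t_c)^2` that is 1 at `t = 0` and reaches 0 with two vanishing
#' derivatives at the cut-off.
#'
#' @param t numeric vector, `>= 0`, in units of `alpha * r`.
#' @param config a [pipeline_config()], used for the kernel choice and (for
#'   the finite-support kernel) the cut-off argument `t_c`.
#' @return numeric vector of factors in `[0, 1]`.
#' @export
coulomb_cutoff_phi <- function(t, config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (any(t < 0)) stop("t must be non-negative")
  cutoff_phi_fun(config$kernel, config$t_c)(t)
}

# minimum-image displacement for an orthorhombic periodic box
min_image <- function(d, box) {
  if (is.null(box)) return(d)
  sweep_box <- matrix(box, nrow = nrow(d), ncol = 3, byrow = TRUE)
  d - sweep_box * round(d / sweep_box)
}

# Vectorized pair kernel.  `dx` is an n x 3 matrix of displacements
# r_i - r_j (already minimum-image); qq = q_i*q_j; eps/sig are combined
# pair parameters.  arithmetic = "pipeline" evaluates the reciprocal square
# root and the cut-off factors from the ROM tables (single-precision-grade);
# "reference" uses exact double-precision arithmetic.
pipeline_pair_terms <- function(dx, qq, eps, sig, config,
                                arithmetic = c("pipeline", "reference")) {
  arithmetic <- match.arg(arithmetic)
  n <- nrow(dx)
  r2 <- dx[, 1]^2 + dx[, 2]^2 + dx[, 3]^2
  if (any(r2 == 0)) stop("coincident particles in pair evaluation")
  force <- matrix(0, n, 3)
  e_coul <- numeric(n)
  e_vdw <- numeric(n)
  keep <- r2 < config$cutoff_radius^2
  if (!any(keep)) {
    return(list(force = force, coulomb = e_coul, vdw = e_vdw))
  }
  r2k <- r2[keep]
  if (arithmetic == "pipeline") {
    rinv <- eval_table(config$tab_rsqrt, r2k)
  } else {
    rinv <- 1 / sqrt(r2k)
  }
  rinv2 <- rinv * rinv
  qqk <- qq[keep]
  kC <- config$coulomb_constant
  if (config$alpha > 0) {
    t <- config$alpha * (r2k * rinv)
    if (arithmetic == "pipeline") {
      t <- pmin(t, config$t_c)  # guard the table edge against rounding
      gphi <- eval_table(config$tab_phi, t)
      gc_ <- eval_table(config$tab_force, t)
    } else {
      gphi <- cutoff_phi_fun(config$kernel, config$t_c)(t)
      gc_ <- cutoff_force_fun(config$kernel, config$t_c)(t)
    }
  } else {
    gphi <- 1
    gc_ <- 1
  }
  ec <- kC * qqk * gphi * rinv
  fc <- kC * qqk * gc_ * rinv2 * rinv      # |f| / r
  s2 <- (sig[keep]^2) * rinv2
  s6 <- s2 * s2 * s2
  s12 <- s6 * s6
  epsk <- eps[keep]
  ev <- 4 * epsk * (s12 - s6)
  fv <- 24 * epsk * (2 * s12 - s6) * rinv2  # |f| / r
  fscale <- fc + fv
  force[keep, ] <- dx[keep, , drop = FALSE] * fscale
  e_coul[keep] <- ec
  e_vdw[keep] <- ev
  list(force = force, coulomb = e_coul, vdw = e_vdw)
}

#' Evaluate one non-bonded pair through the emulated pipeline
#'
#' Computes the Coulomb and van der Waals force and potentials for one pair
#' in a single call, the way the hardware pipeline does.  The Coulomb
#' potential is `k q_i q_j g_phi(alpha r) / r` with the configured cut-off
#' kernel; the van der Waals term is 12-6 Lennard-Jones with combined pair
#' parameters.  Beyond the cut-off radius all outputs are exactly zero.
#' The force on `j` is exactly the negation of the force on `i`.
#'
#' @param r_i,r_j positions (length-3 numeric).
#' @param q_i,q_j charges.
#' @param type_i,type_j 1-based atom type indices.
#' @param types an [atom_type_table()].
#' @param config a [pipeline_config()].
#' @param box optional length-3 box for minimum-image displacement.
#' @param arithmetic `"pipeline"` (ROM tables, single-precision grade) or
#'   `"reference"` (exact double precision).
#' @return list with `force_on_i`, `force_on_j`, `coulomb_potential`,
#'   `vdw_potential` and the pair distance `r`.
#' @export
eval_pair <- function(r_i, r_j, q_i, q_j, type_i, type_j, types, config,
                      box = NULL, arithmetic = c("pipeline", "reference")) {
  arithmetic <- match.arg(arithmetic)
  d <- min_image(matrix(r_i - r_j, 1, 3), box)
  pp <- combine_params(type_i, type_j, types, config)
  out <- pipeline_pair_terms(d, q_i * q_j, pp$epsilon, pp$sigma, config,
                             arithmetic)
  f <- as.numeric(out$force[1, ])
  list(
    force_on_i = f, force_on_j = -f,
    coulomb_potential = out$coulomb[1], vdw_potential = out$vdw[1],
    r = sqrt(sum(d^2))
  )
}

#' Evaluate a block of pairs with fixed-point accumulation
#'
#' Emulates one pipeline-block dispatch: up to 16 `i` particles against up
#' to 16 broadcast `j` particles, every `(i, j)` pair evaluated once, `+f`
#' accumulated to `i` and `-f` to `j` (action-reaction), with per-particle
#' partial forces reduced inside the block before the single
#' accumulate-on-write to the force bank.  When `i_batch` and `j_batch` are
#' identical the block is a self-block and each unordered pair is evaluated
#' once with `i < j`; otherwise the batches must be disjoint.
#'
#' @param i_batch,j_batch integer particle indices (each of length <= 16).
#' @param positions n x 3 matrix of all particle positions.
#' @param charges,type_idx per-particle charges and type indices.
#' @param types an [atom_type_table()].
#' @param config a [pipeline_config()].
#' @param bank n x 3 matrix of 32-bit force words (the GM force array).
#' @param force_fmt `fixed_format` of the force words.
#' @param box optional periodic box (length 3).
#' @return the updated force bank.
#' @export
eval_block <- function(i_batch, j_batch, positions, charges, type_idx,
                       types, config, bank, force_fmt, box = NULL) {
  if (length(i_batch) > 16L || length(j_batch) > 16L) {
    stop("pipeline blocks hold at most 16 particles per side")
  }
  if (length(i_batch) == 0L || length(j_batch) == 0L) return(bank)
  if (identical(sort(i_batch), sort(j_batch))) {
    if (length(i_batch) < 2L) return(bank)
    prs <- utils::combn(sort(i_batch), 2L)
    pi_ <- prs[1, ]; pj_ <- prs[2, ]
  } else {
    if (length(intersect(i_batch, j_batch)) > 0L) {
      stop("i and j batches must be identical (self-block) or disjoint")
    }
    pi_ <- rep(i_batch, each = length(j_batch))
    pj_ <- rep(j_batch, times = length(i_batch))
  }
  d <- min_image(positions[pi_, , drop = FALSE] - positions[pj_, , drop = FALSE],
                 box)
  pp <- combine_params(type_idx[pi_], type_idx[pj_], types, config)
  out <- pipeline_pair_terms(d, charges[pi_] * charges[pj_],
                             pp$epsilon, pp$sigma, config)
  w <- matrix(round(out$force / force_fmt$lsb), ncol = 3)
  # within-block reduction, then one accumulate-on-write per particle
  for (k in 1:3) {
    red <- rowsum(c(w[, k], -w[, k]), group = c(pi_, pj_))
    idx <- as.integer(rownames(red))
    bank[idx, k] <- wrap32(bank[idx, k] + red[, 1])
  }
  bank
}

#' Soft-core van der Waals interaction
#'
#' Beutler-style soft core: the 12-6 Lennard-Jones interaction with the
#' effective sixth power `r^6 -> r^6 + alpha_sc (1 - lambda) sigma^6`,
#' scaled by `lambda`.  At `lambda = 1` it reduces exactly to plain
#' Lennard-Jones; for `lambda < 1` the potential stays finite at `r = 0`.
#'
#' @param r2 squared pair distance(s).
#' @param lambda coupling parameter in `[0, 1]`.
#' @param epsilon,sigma combined pair parameters.
#' @param config a [pipeline_config()] (supplies `alpha_sc`; default 0.5).
#' @return list with `force` (magnitude along the pair axis, positive =
#'   repulsive) and `potential`.
#' @export
softcore_vdw <- function(r2, lambda, epsilon, sigma, config = NULL) {
  if (any(lambda < 0 | lambda > 1)) stop("lambda must lie in [0, 1]")
  alpha_sc <- 0.5
  if (!is.null(config) && !is.null(config$softcore$alpha_sc)) {
    alpha_sc <- config$softcore$alpha_sc
  }
  r6 <- r2^3
  s6 <- sigma^6
  r6eff <- r6 + alpha_sc * (1 - lambda) * s6
  sr6 <- s6 / r6eff
  pot <- 4 * epsilon * lambda * (sr6^2 - sr6)
  r <- sqrt(r2)
  force <- 24 * epsilon * lambda * r2^2 * r * (2 * sr6^2 - sr6) / r6eff
  list(force = force, potential = pot)
}

#' Particle-group interaction filter
#'
#' Decides, per pair, whether the pipeline evaluates the interaction based
#' on the particles' group labels: pairs whose (unordered) group pair is
#' listed in `exclude_pairs`, or same-group pairs when
#' `exclude_same_group` is set, are skipped.
#'
#' @param pairs 2-column matrix of particle indices.
#' @param group_labels per-particle group labels (no missing values).
#' @param config a [pipeline_config()] whose `group_rules` holds
#'   `exclude_same_group` (logical) and/or `exclude_pairs` (2-column matrix
#'   of group labels).
#' @return logical vector: `TRUE` = keep, `FALSE` = skip.
#' @export
group_cutoff_filter <- function(pairs, group_labels, config) {
  pairs <- matrix(pairs, ncol = 2)
  gi <- group_labels[pairs[, 1]]
  gj <- group_labels[pairs[, 2]]
  if (any(is.na(gi) | is.na(gj))) stop("missing group label")
  keep <- rep(TRUE, nrow(pairs))
  rules <- config$group_rules
  if (is.null(rules)) return(keep)
  if (isTRUE(rules$exclude_same_group)) keep <- keep & (gi != gj)
  if (!is.null(rules$exclude_pairs)) {
    ex <- matrix(rules$exclude_pairs, ncol = 2)
    key <- paste(pmin(gi, gj), pmax(gi, gj))
    exkey <- paste(pmin(ex[, 1], ex[, 2]), pmax(ex[, 1], ex[, 2]))
    keep <- keep & !(key %in% exkey)
  }
  keep
}
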