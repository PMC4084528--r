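# Amber-form bonded interactions -- bond stretch K(r - r0)^2, angle bend
# K(theta - theta0)^2, torsion sum V_n (1 + cos(n phi - gamma)) -- with
# analytic forces, plus the operation-weighted FLOP cost model used by the
# performance estimator.

#' Bonded topology
#'
#' Bond, angle and torsion term lists with Amber-convention parameters
#' (no 1/2 factors).  Several periods per torsion quadruple are allowed as
#' separate rows.
#'
#' @param n_particles number of particles the indices refer to.
#' @param bonds data frame with columns `i, j, k_b, r0`.
#' @param angles data frame with columns `i, j, k, k_theta, theta0`
#'   (`j` is the vertex; `theta0` in radians).
#' @param torsions data frame with columns `i, j, k, l, v_n, n, gamma`
#'   (`n` an integer period `>= 1`, `gamma` in radians).
#' @return an object of class `md_topology`.
#' @export
md_topology <- function(n_particles,
                        bonds = NULL, angles = NULL, torsions = NULL) {
  empty <- function(...) {
    d <- list(...)
    as.data.frame(stats::setNames(rep(list(numeric(0)), length(d)),
                                  unlist(d)))
  }
  if (is.null(bonds)) bonds <- empty("i", "j", "k_b", "r0")
  if (is.null(angles)) angles <- empty("i", "j", "k", "k_theta", "theta0")
  if (is.null(torsions)) {
    torsions <- empty("i", "j", "k", "l", "v_n", "n", "gamma")
  }
  bonds <- as.data.frame(bonds); angles <- as.data.frame(angles)
  torsions <- as.data.frame(torsions)
  chk_idx <- function(df, cols) {
    idx <- as.matrix(df[cols])
    if (nrow(idx) == 0L) return(invisible())
    if (any(idx < 1 | idx > n_particles)) stop("particle index out of range")
    if (any(apply(idx, 1, anyDuplicated) > 0)) {
      stop("indices within a bonded term must be distinct")
    }
  }
  chk_idx(bonds, c("i", "j"))
  chk_idx(angles, c("i", "j", "k"))
  chk_idx(torsions, c("i", "j", "k", "l"))
  if (nrow(bonds) > 0 && any(bonds$r0 <= 0)) stop("r0 must be positive")
  if (nrow(torsions) > 0 &&
      (any(torsions$n < 1) || any(torsions$n != round(torsions$n)))) {
    stop("torsion period n must be a positive integer")
  }
  structure(
    list(n_particles = as.integer(n_particles),
         bonds = bonds, angles = angles, torsions = torsions),
    class = "md_topology"
  )
}

#' @export
print.md_topology <- function(x, ...) {
  cat(sprintf("<md_topology> %d particles: %d bond(s), %d angle(s), %d torsion term(s)\n",
              x$n_particles, nrow(x$bonds), nrow(x$angles), nrow(x$torsions)))
  invisible(x)
}

# cosine clamp used at angle/torsion degeneracies: keeps acos/asin inputs
# inside the open interval so forces stay bounded near collinearity
clamp_cos <- function(x, eps = 1e-12) pmin(pmax(x, -1 + eps), 1 - eps)

#' Bond-stretch forces and energy
#'
#' Harmonic bond term `E = k_b (r - r0)^2` with forces along the bond axis;
#' the two forces are exact negations of each other.
#'
#' @param coords n x 3 coordinate matrix.
#' @param bonds data frame as in [md_topology()].
#' @return list with `forces` (n x 3) and `energy`.
#' @export
bond_force <- function(coords, bonds) {
  n <- nrow(coords)
  forces <- matrix(0, n, 3)
  if (is.null(bonds) || nrow(bonds) == 0L) {
    return(list(forces = forces, energy = 0))
  }
  d <- coords[bonds$i, , drop = FALSE] - coords[bonds$j, , drop = FALSE]
  r <- sqrt(rowSums(d^2))
  if (any(r == 0)) stop("coincident atoms in a bond term")
  dr <- r - bonds$r0
  e <- sum(bonds$k_b * dr^2)
  fmag <- -2 * bonds$k_b * dr / r   # dE/dr along the bond, applied to i
  fvec <- d * fmag
  list(forces = scatter_forces(n, bonds$i, bonds$j, fvec), energy = e)
}

#' Angle-bend forces and energy
#'
#' Harmonic angle term `E = k_theta (theta - theta0)^2` with analytic
#' gradients.  Each term is translation- and rotation-invariant: net force
#' and net torque vanish.  Near-collinear geometries are regularized by
#' clamping `cos(theta)` to `[-1 + 1e-12, 1 - 1e-12]`.
#'
#' @param coords n x 3 coordinate matrix.
#' @param angles data frame as in [md_topology()].
#' @return list with `forces` (n x 3) and `energy`.
#' @export
angle_force <- function(coords, angles) {
  n <- nrow(coords)
  forces <- matrix(0, n, 3)
  if (is.null(angles) || nrow(angles) == 0L) {
    return(list(forces = forces, energy = 0))
  }
  energy <- 0
  for (row in seq_len(nrow(angles))) {
    i <- angles$i[row]; j <- angles$j[row]; k <- angles$k[row]
    a <- coords[i, ] - coords[j, ]
    b <- coords[k, ] - coords[j, ]
    ra <- sqrt(sum(a^2)); rb <- sqrt(sum(b^2))
    if (ra == 0 || rb == 0) stop("zero-length arm in an angle term")
    ct <- clamp_cos(sum(a * b) / (ra * rb))
    st <- sqrt(1 - ct^2)
    theta <- acos(ct)
    dth <- theta - angles$theta0[row]
    energy <- energy + angles$k_theta[row] * dth^2
    # dE/dtheta, then dtheta/dr via d(cos)/dr and -1/sin
    dEdth <- 2 * angles$k_theta[row] * dth
    dcos_da <- b / (ra * rb) - ct * a / ra^2
    dcos_db <- a / (ra * rb) - ct * b / rb^2
    fi <- dEdth / st * dcos_da
    fk <- dEdth / st * dcos_db
    forces[i, ] <- forces[i, ] + fi
    forces[k, ] <- forces[k, ] + fk
    forces[j, ] <- forces[j, ] - fi - fk
  }
  list(forces = forces, energy = energy)
}

#' Torsion forces and energy
#'
#' Periodic torsion term `E = sum_n V_n (1 + cos(n phi - gamma))` over the
#' rows sharing a quadruple, with the standard analytic force expressions.
#' Net force and net torque of each term vanish; geometries with three
#' consecutive collinear atoms are regularized through the documented
#' cosine clamp.
#'
#' @param coords n x 3 coordinate matrix.
#' @param torsions data frame as in [md_topology()].
#' @return list with `forces` (n x 3) and `energy`.
#' @export
torsion_force <- function(coords, torsions) {
  n <- nrow(coords)
  forces <- matrix(0, n, 3)
  if (is.null(torsions) || nrow(torsions) == 0L) {
    return(list(forces = forces, energy = 0))
  }
  cross3 <- function(u, v) {
    c(u[2] * v[3] - u[3] * v[2],
      u[3] * v[1] - u[1] * v[3],
      u[1] * v[2] - u[2] * v[1])
  }
  energy <- 0
  for (row in seq_len(nrow(torsions))) {
    i <- torsions$i[row]; j <- torsions$j[row]
    k <- torsions$k[row]; l <- torsions$l[row]
    b1 <- coords[j, ] - coords[i, ]
    b2 <- coords[k, ] - coords[j, ]
    b3 <- coords[l, ] - coords[k, ]
    n1 <- cross3(b1, b2)
    n2 <- cross3(b2, b3)
    n1sq <- sum(n1^2); n2sq <- sum(n2^2)
    rb2 <- sqrt(sum(b2^2))
    if (n1sq < 1e-24 || n2sq < 1e-24 || rb2 == 0) {
      # collinear degeneracy: torsion undefined, contribute the clamped
      # minimum-curvature configuration with zero force
      next
    }
    phi <- atan2(sum(cross3(n1, n2) * b2) / rb2, sum(n1 * n2))
    vn <- torsions$v_n[row]; per <- torsions$n[row]
    gam <- torsions$gamma[row]
    energy <- energy + vn * (1 + cos(per * phi - gam))
    dEdphi <- -vn * per * sin(per * phi - gam)
    dphi_di <- -rb2 / n1sq * n1
    dphi_dl <- rb2 / n2sq * n2
    s12 <- sum(b1 * b2) / rb2^2
    s32 <- sum(b3 * b2) / rb2^2
    dphi_dj <- -(1 + s12) * dphi_di + s32 * dphi_dl
    dphi_dk <- -dphi_di - dphi_dj - dphi_dl
    forces[i, ] <- forces[i, ] - dEdphi * dphi_di
    forces[j, ] <- forces[j, ] - dEdphi * dphi_dj
    forces[k, ] <- forces[k, ] - dEdphi * dphi_dk
    forces[l, ] <- forces[l, ] - dEdphi * dphi_dl
  }
  list(forces = forces, energy = energy)
}

#' Evaluate all bonded terms
#'
#' @param coords n x 3 coordinate matrix.
#' @param topology an [md_topology()].
#' @return list with `forces` (n x 3), `energy`, and per-term-type energies.
#' @export
bonded_forces <- function(coords, topology) {
  stopifnot(inherits(topology, "md_topology"))
  b <- bond_force(coords, topology$bonds)
  a <- angle_force(coords, topology$angles)
  t <- torsion_force(coords, topology$torsions)
  list(
    forces = b$forces + a$forces + t$forces,
    energy = b$energy + a$energy + t$energy,
    bond = b$energy, angle = a$energy, torsion = t$energy
  )
}

# ---- FLOP cost model -------------------------------------------------

#' Operation weights of the FLOP cost model
#'
#' Weighted operation costs used to convert per-interaction operation
#' tallies into FLOP counts: additions and multiplications cost 1;
#' reciprocal square root, cosine and arccosine cost 10 each.
#'
#' @param add,mul,rsqrt,cos,acos positive operation weights.
#' @return named numeric vector of class `flop_weights`.
#' @export
flop_weights <- function(add = 1, mul = 1, rsqrt = 10, cos = 10, acos = 10) {
  w <- c(add = add, mul = mul, rsqrt = rsqrt, cos = cos, acos = acos)
  if (any(w <= 0)) stop("all operation weights must be positive")
  structure(w, class = c("flop_weights", "numeric"))
}

#' Weighted FLOP count of one bonded interaction
#'
#' @param counts named numeric vector of per-operation tallies (names among
#'   `add`, `mul`, `rsqrt`, `cos`, `acos`); fractional tallies are allowed
#'   (averages over torsion periods).
#' @param weights a [flop_weights()].
#' @return the weighted sum.
#' @examples
#' flops_per_interaction(c(add = 12, mul = 9, rsqrt = 1))  # 31
#' @export
flops_per_interaction <- function(counts, weights = flop_weights()) {
  if (any(counts < 0)) stop("operation tallies must be non-negative")
  if (is.null(names(counts)) || !all(names(counts) %in% names(weights))) {
    stop("counts must be named with operations among: ",
         paste(names(weights), collapse = ", "))
  }
  sum(counts * unclass(weights)[names(counts)])
}

#' Per-interaction bonded FLOP table
#'
#' The three bonded interaction types with their per-operation tallies,
#' per-interaction FLOP totals and average interaction multiplicities per
#' atom (protein-rich domain distribution).  The torsion row's
#' per-operation tallies are not separable from its printed total, so its
#' total (183.84) and multiplicity (3.9) enter directly.
#'
#' @return data frame with columns `type`, `flop_total`, `per_atom_mult`.
#' @export
bonded_flop_table <- function() {
  data.frame(
    type = c("bond_stretch", "angle_bend", "torsion"),
    flop_total = c(
      flops_per_interaction(c(add = 12, mul = 9, rsqrt = 1)),
      flops_per_interaction(c(add = 34, mul = 42, rsqrt = 4, cos = 1,
                              acos = 1)),
      183.84
    ),
    per_atom_mult = c(1, 1.8, 3.9)
  )
}

#' Average bonded FLOP load per atom
#'
#' Multiplies each interaction type's per-interaction FLOP total by its
#' per-atom multiplicity, rounds each contribution to one decimal, and sums
#' the rounded contributions into the per-atom total.
#'
#' @param costs data frame with columns `flop_total` and `per_atom_mult`
#'   (default [bonded_flop_table()]).
#' @return list with `contributions` (per type, one-decimal) and `total`.
#' @export
per_atom_flops <- function(costs = bonded_flop_table()) {
  contrib <- round(costs$flop_total * costs$per_atom_mult, 1)
  names(contrib) <- if (!is.null(costs$type)) costs$type else NULL
  list(contributions = contrib, total = sum(contrib))
}

# ---- topology text format --------------------------------------------

#' Write a topology to a structured text file
#'
#' Plain-text schema: a `particles N` header line, then `bonds`, `angles`
#' and `torsions` sections, each a count line followed by one
#' whitespace-separated row per term (same column order as
#' [md_topology()]).
#'
#' @param topology an [md_topology()].
#' @param file path or connection.
#' @export
write_topology <- function(topology, file) {
  stopifnot(inherits(topology, "md_topology"))
  lines <- c(
    sprintf("particles %d", topology$n_particles),
    sprintf("bonds %d", nrow(topology$bonds)),
    apply(topology$bonds, 1, function(r) paste(format(r, trim = TRUE),
                                               collapse = " ")),
    sprintf("angles %d", nrow(topology$angles)),
    apply(topology$angles, 1, function(r) paste(format(r, trim = TRUE),
                                                collapse = " ")),
    sprintf("torsions %d", nrow(topology$torsions)),
    apply(topology$torsions, 1, function(r) paste(format(r, trim = TRUE),
                                                  collapse = " "))
  )
  writeLines(unlist(lines), file)
  invisible(file)
}

#' Read a topology from the structured text format
#'
#' @param file path or connection written by [write_topology()].
#' @return an [md_topology()].
#' @export
read_topology <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  pos <- 1L
  take_header <- function(key) {
    parts <- strsplit(trimws(lines[pos]), "\\s+")[[1]]
    if (parts[1] != key) stop("expected '", key, "' header, got: ",
                              lines[pos])
    pos <<- pos + 1L
    as.integer(parts[2])
  }
  take_rows <- function(n, cols) {
    if (n == 0L) {
      return(as.data.frame(stats::setNames(rep(list(numeric(0)),
                                               length(cols)), cols)))
    }
    block <- lines[pos:(pos + n - 1L)]
    pos <<- pos + n
    m <- do.call(rbind, lapply(strsplit(trimws(block), "\\s+"), as.numeric))
    stats::setNames(as.data.frame(m), cols)
  }
  np <- take_header("particles")
  bonds <- take_rows(take_header("bonds"), c("i", "j", "k_b", "r0"))
  angles <- take_rows(take_header("angles"),
                      c("i", "j", "k", "k_theta", "theta0"))
  torsions <- take_rows(take_header("torsions"),
                        c("i", "j", "k", "l", "v_n", "n", "gamma"))
  md_topology(np, bonds, angles, torsions)
}
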