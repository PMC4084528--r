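# Independent numerical oracles used across the suite.  These deliberately
# avoid the package's own code paths: pracma for special functions, plain
# double-precision loops for lattice sums, igraph for graph distances.

# high-accuracy complementary error function (independent of the package's
# pnorm-based evaluation)
oracle_erfc <- function(t) pracma::erfc(t)

# direct Ewald summation: explicit real-space image sum plus explicit
# k-space sum, Gaussian units
direct_ewald_energy <- function(pos, q, box, alpha, kmax = 10, nreal = 2) {
  n <- nrow(pos)
  V <- prod(box)
  e_real <- 0
  shifts <- as.matrix(expand.grid(-nreal:nreal, -nreal:nreal,
                                  -nreal:nreal))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    for (s in seq_len(nrow(shifts))) {
      sh <- shifts[s, ] * box
      if (i == j && all(sh == 0)) next
      r <- sqrt(sum((pos[i, ] - pos[j, ] + sh)^2))
      e_real <- e_real + 0.5 * q[i] * q[j] * oracle_erfc(alpha * r) / r
    }
  }
  e_rec <- 0
  for (mx in -kmax:kmax) for (my in -kmax:kmax) for (mz in -kmax:kmax) {
    if (mx == 0 && my == 0 && mz == 0) next
    k <- 2 * pi * c(mx, my, mz) / box
    k2 <- sum(k^2)
    S <- sum(q * exp(1i * (pos %*% k)))
    e_rec <- e_rec + 2 * pi / (V * k2) * exp(-k2 / (4 * alpha^2)) *
      Mod(S)^2
  }
  e_real + e_rec - alpha / sqrt(pi) * sum(q^2)
}

# central-difference gradient of a scalar function of an n x 3 matrix
numerical_gradient <- function(efun, coords, h = 1e-6) {
  g <- coords * 0
  for (i in seq_len(nrow(coords))) for (k in 1:3) {
    cp <- coords; cm <- coords
    cp[i, k] <- cp[i, k] + h
    cm[i, k] <- cm[i, k] - h
    g[i, k] <- (efun(cp) - efun(cm)) / (2 * h)
  }
  g
}

# brute-force within-cutoff pair enumeration with minimum image
brute_force_pairs <- function(pos, box, cutoff) {
  n <- nrow(pos)
  out <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- pos[i, ] - pos[j, ]
    d <- d - box * round(d / box)
    if (sum(d^2) < cutoff^2) out[[length(out) + 1L]] <- c(i, j)
  }
  if (length(out) == 0L) return(matrix(integer(0), 0, 2))
  do.call(rbind, out)
}

# torus graph BFS distances via igraph
torus_bfs_distance <- function(dims, src, dst) {
  idx_of <- function(p) 1L + p[1] + dims[1] * (p[2] + dims[2] * p[3])
  edges <- c()
  for (x in 0:(dims[1] - 1)) for (y in 0:(dims[2] - 1)) {
    for (z in 0:(dims[3] - 1)) {
      p <- c(x, y, z)
      for (ax in 1:3) {
        q <- p
        q[ax] <- (q[ax] + 1) %% dims[ax]
        edges <- c(edges, idx_of(p), idx_of(q))
      }
    }
  }
  g <- igraph::make_graph(edges, n = prod(dims), directed = FALSE)
  as.numeric(igraph::distances(g, v = idx_of(src), to = idx_of(dst)))
}

# random wrapped positions in a box
random_positions <- function(n, box) {
  matrix(runif(3 * n), n, 3) %*% diag(box)
}
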