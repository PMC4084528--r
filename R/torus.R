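# Model of the 3D torus interconnect: topology, dimension-ordered type I
# routing, the programmable three-stage type II scatter to the 26
# surrounding chips, hop-decrement type III gather with integer reduction,
# the SerDes link bandwidth model and the measured latency model.

DIR_NAMES <- c("+x", "-x", "+y", "-y", "+z", "-z")
DIR_VECS <- rbind(
  "+x" = c(1, 0, 0), "-x" = c(-1, 0, 0),
  "+y" = c(0, 1, 0), "-y" = c(0, -1, 0),
  "+z" = c(0, 0, 1), "-z" = c(0, 0, -1)
)

#' Torus network topology
#'
#' A periodic 3D grid of nodes, each with six directed outgoing links
#' (X, Y, Z) x (+, -).  Nodes are addressed by 0-based integer 3-vectors.
#'
#' @param dims length-3 integer vector of nodes per axis (default the
#'   modelled machine's 8 x 8 x 8).
#' @return an object of class `torus_topology`.
#' @export
torus_topology <- function(dims = c(8L, 8L, 8L)) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3L, all(dims >= 1L))
  structure(list(dims = dims, n_nodes = prod(dims)),
            class = "torus_topology")
}

#' @export
print.torus_topology <- function(x, ...) {
  cat(sprintf("<torus_topology> %d x %d x %d (%d nodes)\n",
              x$dims[1], x$dims[2], x$dims[3], x$n_nodes))
  invisible(x)
}

# signed shortest displacement along one axis of size n
axis_disp <- function(from, to, n) {
  d <- (to - from) %% n
  if (d > n / 2) d <- d - n
  # ties (d == n/2) resolve to the positive direction
  d
}

#' Torus distance between two nodes
#'
#' @param a,b 0-based integer 3-vectors.
#' @param topology a [torus_topology()].
#' @return the hop count (sum of per-axis wrap distances).
#' @export
torus_distance <- function(a, b, topology) {
  sum(abs(vapply(1:3, function(ax) {
    axis_disp(a[ax], b[ax], topology$dims[ax])
  }, numeric(1))))
}

#' Route a point-to-point (type I) packet
#'
#' Dimension-ordered (X then Y then Z) shortest-path routing with
#' wraparound.  The hop count equals the sum of per-axis torus distances.
#'
#' @param src,dst 0-based integer 3-vectors; must differ.
#' @param topology a [torus_topology()].
#' @return list with `path` (matrix of visited nodes, starting at `src`)
#'   and `n_hop`.
#' @export
route_type1 <- function(src, dst, topology) {
  stopifnot(inherits(topology, "torus_topology"))
  src <- as.integer(src); dst <- as.integer(dst)
  if (all(src == dst)) stop("src and dst must differ")
  path <- list(src)
  cur <- src
  for (ax in 1:3) {
    d <- axis_disp(src[ax], dst[ax], topology$dims[ax])
    step <- sign(d)
    for (s in seq_len(abs(d))) {
      cur[ax] <- (cur[ax] + step) %% topology$dims[ax]
      path[[length(path) + 1L]] <- cur
    }
  }
  path <- do.call(rbind, path)
  list(path = path, n_hop = nrow(path) - 1L)
}

#' Default forwarding configuration for type II packets
#'
#' Per-stage, per-inbound-direction outbound direction sets.  Stage 1
#' sends from the source on all six directions; stage 2 forwards each axis
#' to two orthogonal directions so the 12 edge neighbours are each reached
#' once; stage 3 completes the 8 vertex neighbours, with one extra rule
#' that re-covers two vertices -- reproducing the two redundant receptions
#' of the modelled machine's routing pattern.  The table is programmable:
#' supply your own list of the same shape to [scatter_type2()].
#'
#' @return nested list `stage2`, `stage3` keyed by inbound direction.
#' @export
default_forwarding <- function() {
  list(
    stage1 = DIR_NAMES,
    stage2 = list(
      "+x" = c("+y", "-y"), "-x" = c("+y", "-y"),
      "+y" = c("+z", "-z"), "-y" = c("+z", "-z"),
      "+z" = c("+x", "-x"), "-z" = c("+x", "-x")
    ),
    stage3 = list(
      "+y" = c("+z", "-z"), "-y" = c("+z", "-z"),
      "+z" = c("+x")
    )
  )
}

#' Simulate a type II multi-stage scatter
#'
#' Replays the three forwarding stages of a type II packet from `src` on
#' the torus and records every reception: the stage it happened in,
#' whether the receiver sees the payload for the first time, and the
#' duplicate count.  With the default forwarding table the packet reaches
#' the 6 face neighbours at stage 1, the 12 edge neighbours at stage 2 and
#' the 8 vertex neighbours at stage 3 (all 26 Chebyshev-distance-1
#' neighbours), with exactly 2 redundant receptions.
#'
#' @param src 0-based integer 3-vector.
#' @param topology a [torus_topology()]; all dims must be `>= 3` so the 26
#'   neighbours are distinct nodes.
#' @param config forwarding table (see [default_forwarding()]).
#' @return list with `receptions` (data frame: node key, stage, inbound
#'   direction, first_time), `unique_receivers`, `stage_first_counts`,
#'   `duplicates`.
#' @export
scatter_type2 <- function(src, topology = torus_topology(),
                          config = default_forwarding()) {
  stopifnot(inherits(topology, "torus_topology"))
  if (any(topology$dims < 3L)) {
    stop("type II scatter requires torus dims >= 3 (neighbour aliasing)")
  }
  src <- as.integer(src)
  dims <- topology$dims
  key <- function(p) paste(p, collapse = ",")
  step <- function(p, dir) (p + DIR_VECS[dir, ]) %% dims
  seen <- character(0)
  recs <- list()
  # stage 1: source transmits on the configured directions
  frontier <- lapply(config$stage1, function(d) {
    list(node = step(src, d), inbound = d)
  })
  for (stage in 1:3) {
    new_frontier <- list()
    for (pk in frontier) {
      k <- key(pk$node)
      first <- !(k %in% seen)
      if (first) seen <- c(seen, k)
      recs[[length(recs) + 1L]] <- data.frame(
        node = k, stage = stage, inbound = pk$inbound,
        first_time = first, stringsAsFactors = FALSE
      )
      if (stage < 3L) {
        tab <- config[[paste0("stage", stage + 1L)]]
        outs <- tab[[pk$inbound]]
        for (d in outs) {
          new_frontier[[length(new_frontier) + 1L]] <-
            list(node = step(pk$node, d), inbound = d)
        }
      }
    }
    frontier <- new_frontier
  }
  receptions <- do.call(rbind, recs)
  list(
    receptions = receptions,
    unique_receivers = length(seen),
    stage_first_counts = vapply(1:3, function(s) {
      sum(receptions$first_time[receptions$stage == s])
    }, numeric(1)),
    duplicates = sum(!receptions$first_time)
  )
}

#' Simulate a type III hop-decrement gather
#'
#' A packet travels along a line of nodes, each forwarding it in the same
#' direction with a decremented hop number; it terminates where the hop
#' number reaches zero.  With `reduce = TRUE` each node's contribution is
#' folded into the terminal node's memory through integer
#' accumulate-on-write, so the terminal value is the exact 32-bit modular
#' sum of all contributions regardless of arrival order.
#'
#' @param payloads numeric vector: the integer word contributed by each
#'   node along the line, ordered from the farthest node (largest hop
#'   count) to the terminal node (hop 0).
#' @param reduce logical; integer reduction at the terminal node.
#' @return list with `value` at the terminal node (a vector of all
#'   payloads when `reduce = FALSE`) and `hops` (the initial hop number).
#' @export
gather_type3 <- function(payloads, reduce = TRUE) {
  if (length(payloads) == 0L) stop("at least one node must contribute")
  if (reduce && any(payloads != round(payloads))) {
    stop("type III reduction payloads must be integer words")
  }
  hops <- length(payloads) - 1L
  if (reduce) {
    bank <- 0
    for (p in payloads) bank <- accumulate_write(bank, 1L, p, "sum")
    list(value = bank, hops = hops)
  } else {
    list(value = payloads, hops = hops)
  }
}

#' Link specification of the SerDes interconnect
#'
#' @param lanes number of serial lanes per inter-chip link (the modelled
#'   machine has three 4-lane SerDes blocks per direction: 12 lanes).
#' @param lane_rate_gbps raw line rate per lane in Gbit/s.
#' @param encoding_efficiency fraction of line bits carrying payload
#'   (0.8 for 8b/10b coding).
#' @return an object of class `link_spec`.
#' @export
link_spec <- function(lanes = 12L, lane_rate_gbps = 6,
                      encoding_efficiency = 0.8) {
  stopifnot(lanes > 0, lane_rate_gbps > 0,
            encoding_efficiency > 0, encoding_efficiency <= 1)
  structure(list(lanes = lanes, lane_rate_gbps = lane_rate_gbps,
                 encoding_efficiency = encoding_efficiency),
            class = "link_spec")
}

#' Payload bandwidth of one inter-chip link
#'
#' `lanes x lane_rate x encoding_efficiency / 8` bytes per second; the
#' default 12-lane, 6 Gbps, 8b/10b link yields 7.2 GB/s.
#'
#' @param spec a [link_spec()].
#' @return bandwidth in bytes per second.
#' @examples
#' link_bandwidth(link_spec()) / 1e9  # 7.2
#' @export
link_bandwidth <- function(spec = link_spec()) {
  stopifnot(inherits(spec, "link_spec"))
  spec$lanes * spec$lane_rate_gbps * 1e9 * spec$encoding_efficiency / 8
}

#' Measured latency model of the network
#'
#' Affine model `T(ns) = base + per_hop * N_hop + per_128words * D / 128`
#' fitted to packet-transfer measurements on the modelled machine
#' (`base = 600` ns, `per_hop = 450` ns, `per_128words = 200` ns).
#'
#' @param base,per_hop,per_128words model coefficients in nanoseconds.
#' @return an object of class `latency_model`.
#' @export
latency_model <- function(base = 600, per_hop = 450, per_128words = 200) {
  stopifnot(base >= 0, per_hop >= 0, per_128words >= 0)
  structure(list(base = base, per_hop = per_hop,
                 per_128words = per_128words),
            class = "latency_model")
}

#' Predicted transfer time of one packet
#'
#' @param n_hop number of hops (`>= 0`).
#' @param d_words payload size in 4-byte words (`>= 0`).
#' @param model a [latency_model()].
#' @return time in nanoseconds.
#' @examples
#' transfer_time(4, 64)  # 2500 ns
#' @export
transfer_time <- function(n_hop, d_words, model = latency_model()) {
  stopifnot(inherits(model, "latency_model"))
  if (any(n_hop < 0) || any(d_words < 0)) {
    stop("n_hop and d_words must be non-negative")
  }
  model$base + model$per_hop * n_hop + model$per_128words * d_words / 128
}

#' Write a per-packet event trace
#'
#' Tab-separated event log (one row per reception) for inspection of a
#' scatter simulation.
#'
#' @param scatter result of [scatter_type2()].
#' @param file path or connection.
#' @export
write_packet_trace <- function(scatter, file) {
  utils::write.table(scatter$receptions, file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file)
}
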