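# 3D torus network: routing, the three-stage scatter pattern, the
# hop-decrement gather, and the bandwidth and latency models.

test_that("type I routing takes dimension-ordered shortest paths", {
  topo <- torus_topology(c(8, 8, 8))
  expect_equal(route_type1(c(0, 0, 0), c(1, 0, 0), topo)$n_hop, 1)
  # wraparound: 0 -> 7 is one hop through the periodic link
  expect_equal(route_type1(c(0, 0, 0), c(7, 0, 0), topo)$n_hop, 1)
  expect_error(route_type1(c(1, 2, 3), c(1, 2, 3), topo), "differ")
})

test_that("hop counts equal BFS distances on a 4^3 torus", {
  dims <- c(4, 4, 4)
  topo <- torus_topology(dims)
  set.seed(51)
  nodes <- expand.grid(0:3, 0:3, 0:3)
  picks <- nodes[sample(nrow(nodes), 12), ]
  for (r in seq_len(nrow(picks) - 1)) {
    a <- as.integer(picks[r, ])
    b <- as.integer(picks[r + 1, ])
    if (all(a == b)) next
    expect_equal(route_type1(a, b, topo)$n_hop,
                 torus_bfs_distance(dims, a, b),
                 info = paste(a, collapse = ","))
  }
})

test_that("type II scatter reaches the 26 neighbours in 6/12/8 stages", {
  for (src in list(c(0, 0, 0), c(7, 3, 5))) {
    sc <- scatter_type2(src, torus_topology(c(8, 8, 8)))
    expect_equal(sc$unique_receivers, 26)
    expect_equal(sc$stage_first_counts, c(6, 12, 8))
    expect_equal(sc$duplicates, 2)
    # all receivers are Chebyshev-distance-1 neighbours of the source
    nodes <- do.call(rbind, lapply(strsplit(unique(sc$receptions$node),
                                            ","), as.integer))
    rel <- sweep(nodes, 2, src)
    rel <- ifelse(rel > 4, rel - 8, ifelse(rel < -4, rel + 8, rel))
    expect_true(all(apply(abs(rel), 1, max) == 1))
    expect_equal(nrow(unique(nodes)), 26)
  }
  # small tori alias the neighbour shell
  expect_error(scatter_type2(c(0, 0, 0), torus_topology(c(2, 4, 4))),
               "dims >= 3")
})

test_that("scatter works on non-cubic tori of width >= 3", {
  sc <- scatter_type2(c(1, 2, 0), torus_topology(c(3, 5, 4)))
  expect_equal(sc$unique_receivers, 26)
  expect_equal(sc$stage_first_counts, c(6, 12, 8))
})

test_that("type III gather reduces to the exact integer sum", {
  g <- gather_type3(c(1, 2, 3, 4))
  expect_equal(g$value, 10)
  expect_equal(g$hops, 3)
  expect_equal(gather_type3(7)$value, 7)
  expect_equal(gather_type3(7)$hops, 0)
  set.seed(52)
  payloads <- sample(-1e6:1e6, 8)
  base <- gather_type3(payloads)$value
  for (rep in 1:5) {
    expect_identical(gather_type3(sample(payloads))$value, base)
  }
  expect_equal(base, sum(payloads))
  expect_error(gather_type3(c(1.5, 2)), "integer")
})

test_that("link bandwidth follows lanes x rate x encoding", {
  expect_equal(link_bandwidth(link_spec()), 7.2e9)
  expect_equal(link_bandwidth(link_spec(lanes = 4)), 2.4e9)
  expect_equal(link_bandwidth(link_spec(lanes = 8, lane_rate_gbps = 1,
                                        encoding_efficiency = 1)), 1e9)
})

test_that("latency model matches the measured affine fit", {
  expect_equal(transfer_time(4, 64), 2500)
  expect_equal(transfer_time(0, 0), 600)
  expect_equal(transfer_time(3, 600), 2887.5)
  expect_error(transfer_time(-1, 0), "non-negative")
  # monotone in both arguments
  hops <- sample(0:20, 10, TRUE)
  words <- sample(0:2000, 10, TRUE)
  expect_true(all(transfer_time(hops + 1, words) > transfer_time(hops,
                                                                 words)))
  expect_true(all(transfer_time(hops, words + 128) >
                    transfer_time(hops, words)))
})

test_that("packet traces serialize as tab-separated events", {
  sc <- scatter_type2(c(0, 0, 0))
  f <- tempfile(fileext = ".tsv")
  write_packet_trace(sc, f)
  tr <- utils::read.delim(f)
  expect_equal(nrow(tr), 28)  # 26 first receptions + 2 duplicates
  expect_setequal(names(tr), c("node", "stage", "inbound", "first_time"))
  unlink(f)
})
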