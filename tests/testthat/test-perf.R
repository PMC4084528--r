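# Performance estimator: machine constants, stage times, the FFT cost
# convention and critical-path composition.

test_that("machine constants reproduce the published figures", {
  spec <- machine_spec()
  expect_equal(peak_interaction_rate(spec), 51.2e9)
  expect_equal(link_bandwidth(spec$link), 7.2e9)
  expect_equal(aggregate_gp_bandwidth(spec), 76.8e9)
  one_pipe <- machine_spec(pipelines_per_chip = 1,
                           pipeline_clock_ghz = 1e-9)
  expect_equal(peak_interaction_rate(one_pipe), 1)
})

test_that("pipeline stage time scales as count over effective rate", {
  expect_equal(pipeline_stage_time(0), 0)
  # 100 atoms x 1728 mesh points at 30% of 51.2 G/s
  expect_equal(pipeline_stage_time(172800), 172800 / (51.2e9 * 0.3) * 1e6)
  expect_equal(pipeline_stage_time(172800), 11.25)
  # the published non-bonded count evaluates to about 41 us
  expect_equal(pipeline_stage_time(100 * 100 * 63), 41.015625)
  # halving the interaction count halves the time
  expect_equal(pipeline_stage_time(315000), pipeline_stage_time(630000) / 2)
  expect_error(pipeline_stage_time(10, machine_spec(pipeline_efficiency = 0)))
})

test_that("bonded stage time follows the per-atom FLOP load", {
  # 992.8 FLOP at 0.6 GHz x 20% = 8.27 us per atom
  expect_equal(bonded_stage_time(1), 992.8 / 0.12e9 * 1e6)
  expect_equal(bonded_stage_time(1), 8.2733, tolerance = 1e-4)
  expect_equal(bonded_stage_time(0), 0)
  # doubling efficiency halves the time
  expect_equal(bonded_stage_time(1, spec = machine_spec(gp_efficiency = 0.4)),
               bonded_stage_time(1) / 2)
})

test_that("FFT cost model uses the real-transform convention", {
  expect_equal(fft_flops(32), 400)
  expect_equal(fft_flops(2), 5)
  expect_equal(fft_flops(64), 960)
  expect_error(fft_flops(24), "power of two")
  expect_error(fft_flops(1), "power of two")
})

test_that("Poisson estimate composes FFT rounds, transposes and moves", {
  pt <- poisson_time()
  expect_equal(pt$transpose_us, 2.5)
  expect_equal(pt$fft_round_us, 400 / 0.12e9 * 1e6)
  # the composed estimate lands in the published 25-45 us band
  expect_gt(pt$total_us, 25)
  expect_lt(pt$total_us, 45)
  expect_error(poisson_time(workload_spec(mesh_dims = c(0, 32, 32))))
})

test_that("critical path respects the schedule and its monotonicity", {
  tb <- step_time_estimate()
  # default 50 k-atom workload: at least 50 us per step
  expect_gte(tb$critical_path_us, 50)
  # charge assignment and back interpolation within 1.5x of 10 us
  expect_lt(tb$stages_us[["charge_assign"]], 15)
  expect_lt(tb$stages_us[["back_interp"]], 15)
  # the non-bonded discrepancy is reported, not silently resolved
  expect_match(tb$notes[["nonbonded"]], "30 us")
  expect_match(tb$notes[["nonbonded"]], "41")
  # zeroed communication leaves the compute-only path
  sched <- step_schedule()
  times <- tb$stages_us
  times[c("distribute", "gather")] <- 0
  cp0 <- mdsoc:::schedule_critical_path(sched, times)
  expect_equal(cp0,
               max(times[["charge_assign"]] + times[["poisson"]] +
                     times[["back_interp"]],
                   times[["nonbonded"]], times[["bonded"]]) +
                 times[["update"]])
  # doubling any single stage never shortens the critical path
  for (nm in names(times)) {
    t2 <- tb$stages_us
    t2[nm] <- 2 * t2[nm]
    expect_gte(mdsoc:::schedule_critical_path(sched, t2),
               tb$critical_path_us)
  }
})

test_that("schedules validate their dependency structure", {
  expect_error(step_schedule(list(a = "b", b = "a")), "cyclic")
  s <- step_schedule()
  expect_equal(s$order[1], "distribute")
  expect_equal(s$order[length(s$order)], "update")
  # every executed order is a topological order of the dependency graph
  for (task in names(s$deps)) {
    for (pre in s$deps[[task]]) {
      expect_lt(match(pre, s$order), match(task, s$order))
    }
  }
})

test_that("machine configuration files override the defaults", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c(
    "machine:",
    "  pipeline_efficiency: 0.5",
    "workload:",
    "  atoms_per_node: 50",
    "  total_atoms: 25600",
    "latency:",
    "  base: 1000"
  ), f)
  mw <- read_machine_config(f)
  expect_equal(mw$machine$pipeline_efficiency, 0.5)
  expect_equal(mw$workload$atoms_per_node, 50)
  expect_equal(transfer_time(0, 0, mw$machine$latency), 1000)
  unlink(f)
})
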