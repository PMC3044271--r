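# Edge-gate state machine, synchronous simulation, knockouts, intervals.

run_gate <- function(source_bits, theta, r, accumulate = TRUE) {
  s <- list(tau = 0, g = 0L, on_run = 0L)
  vapply(source_bits, function(b) {
    up <- edge_gate_update(s, b, theta, r, accumulate = accumulate)
    s <<- up$state
    up$g
  }, 0L)
}

test_that("edge gate implements delayed activation and sustained decay", {
  # theta = 2, r = 1: on once the source has been on 2 consecutive minutes
  src <- c(0, 1, 1, 1, 1, 1, 0)          # minutes 0..6, on at 1..5
  g <- run_gate(src, theta = 2, r = 1)
  expect_equal(which(g == 1L) - 1L, 2:5)

  # theta = 1, r = 4, bounded: three sustained minutes after the drop
  src <- c(0, rep(1, 45), rep(0, 10))    # on at 1..45
  g <- run_gate(src, theta = 1, r = 4, accumulate = FALSE)
  expect_equal(range(which(g == 1L) - 1L), c(1, 48))

  # unbounded accumulation: 45 on-minutes bank 135 minutes of sustain
  src_long <- c(0, rep(1, 45), rep(0, 150))
  g <- run_gate(src_long, theta = 1, r = 4, accumulate = TRUE)
  expect_equal(range(which(g == 1L) - 1L), c(1, 180))

  # delayed response resets when the input drops
  src <- c(0, 1, 1, 0, 1, 1, 0, 1, 1)
  g <- run_gate(src, theta = 1, r = -3)
  expect_equal(sum(g), 0L)
  # ...but fires after theta - 1 + |r| minutes of continuous input
  src <- c(0, rep(1, 10))
  g <- run_gate(src, theta = 1, r = -3)
  expect_equal(min(which(g == 1L)) - 1L, 3)

  # below-threshold run never activates
  g <- run_gate(c(0, 1, 1, 1, 1, 0), theta = 5, r = 7)
  expect_equal(sum(g), 0L)

  expect_error(edge_gate_update(list(tau = 0, g = 0, on_run = 0), 1, 1, 0),
               "nonzero")
})

test_that("activation intervals are maximal, sorted and disjoint", {
  m <- matrix(c(0, 1, 1, 0, 1), ncol = 1,
              dimnames = list(0:4, "X"))
  iv <- activation_intervals(m, "X")
  expect_equal(iv, data.frame(start = c(1L, 4L), end = c(2L, 4L)))
  expect_equal(nrow(activation_intervals(m * 0L, "X")), 0L)
  expect_error(activation_intervals(m, "nope"), "unknown node")
  # burn-in excludes the leading transient
  expect_equal(activation_intervals(m, "X", burn_in = 3)$start, 4L)
})

test_that("simulation is deterministic and respects the protocol", {
  net <- builtin_nfkb_network()
  p <- stimulus_protocol(stim_event("TNF", 0, 45), 300)
  t1 <- simulate_network(net, p)
  t2 <- simulate_network(net, p)
  expect_identical(t1$states, t2$states)
  # stimulus interval is half-open [0, 45)
  expect_equal(unname(t1$states["44", "TNF"]), 1L)
  expect_equal(unname(t1$states["0", "TNF"]), 1L)
  # events must target declared stimulus nodes
  expect_error(
    simulate_network(net, stimulus_protocol(stim_event("IKK", 0, 5), 50)),
    "stimulus node")
  expect_error(stimulus_protocol(stim_event("TNF", 10, 5), 50),
               "start < end")
})

test_that("the unstimulated bundled model settles into the resting state", {
  # IkBa is present at rest and NF-kB shows only the start-up blip from
  # the all-off initial condition
  tr <- simulate_network(builtin_nfkb_network(), horizon = 300)
  expect_equal(activation_intervals(tr, "IkBa"),
               data.frame(start = 1L, end = 300L))
  expect_equal(activation_intervals(tr, "NFkB"),
               data.frame(start = 1L, end = 1L))
  for (n in c("IKK", "NIK", "TNFR1", "A20", "IL1", "TNF", "IRAK1"))
    expect_equal(sum(tr$states[, n]), 0L)
  # starting from the resting state removes the blip entirely
  tr2 <- simulate_network(builtin_nfkb_network(), horizon = 300,
                          initial = c(IkBa = 1))
  expect_equal(sum(tr2$states[, "NFkB"]), 0L)
})

test_that("knockouts clamp a node and equal deleting its influence", {
  net <- builtin_nfkb_network()
  p <- stimulus_protocol(stim_event("TNF", 0, 45), 400)
  ko <- simulate_network(net, p, knockouts = "A20")
  expect_equal(sum(ko$states[, "A20"]), 0L)
  # pushing the A20 -> TNFR1 delay beyond the horizon silences the edge
  # the same way the clamp does
  silenced <- set_edge_params(net, data.frame(
    target = "TNFR1", source = "A20", theta = 10000L, r = 1L))
  tr2 <- simulate_network(silenced, p)
  others <- setdiff(net$nodes, "A20")
  expect_identical(ko$states[, others], tr2$states[, others])
  # a knocked-out stimulus node that the protocol drives is contradictory
  expect_error(simulate_network(net, p, knockouts = "TNF"),
               "knocked out and driven")
  expect_error(simulate_network(net, p, knockouts = "NOPE"),
               "unknown knockout")
})

test_that("compiled simulator matches the literal reference interpreter", {
  # random small networks, both accumulator policies
  for (seed in 1:15) {
    net <- random_network(sample(2:5, 1), max_theta = 3, max_r = 3,
                          seed = seed)
    p <- stimulus_protocol(stim_event(net$stimulus[1], 0,
                                      sample(5:20, 1)), 30)
    for (acc in c("accumulate", "bounded")) {
      a <- simulate_network(net, p, accumulator = acc)
      b <- simulate_reference(net, p, accumulator = acc)
      expect_identical(a$states, b$states)
    }
  }
  # and on the bundled model with a knockout
  net <- builtin_nfkb_network()
  p <- stimulus_protocol(stim_event("TNF", 0, 45), 200)
  a <- simulate_network(net, p, knockouts = "A20")
  b <- simulate_reference(net, p, knockouts = "A20")
  expect_identical(a$states, b$states)
})

test_that("trace CSV round trips and experiment YAML parses", {
  net <- builtin_nfkb_network()
  tr <- simulate_network(net, stimulus_protocol(stim_event("TNF", 0, 10), 30))
  f <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, f)
  back <- read_trace(f)
  expect_equal(unname(back$states), unname(tr$states))
  expect_equal(colnames(back$states), colnames(tr$states))

  y <- withr::local_tempfile(fileext = ".yaml")
  write_experiment_config(tr$protocol, knockouts = "A20", path = y)
  cfg <- read_experiment_config(y)
  expect_equal(cfg$protocol$horizon, 30L)
  expect_equal(cfg$knockouts, "A20")
  expect_equal(cfg$protocol$events$node, "TNF")
})
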