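# Structural analysis: chain reduction, kernel pathway, feedback loops.

test_that("linear pass-through nodes collapse with additive delays", {
  net <- boolean_delay_network(c(B = "A(t-2)", C = "4*B(t-3)"),
                               stimulus = "A", observable = "C")
  simp <- simplify_network(net)
  expect_setequal(simp$nodes, c("A", "C"))
  tm <- expr_terms(simp$rules[["C"]])[[1]]
  expect_equal(tm$source, "A")
  expect_equal(tm$theta, 5L)      # 2 + 3
  expect_equal(tm$r, 4L)          # the receiving edge's response
  expect_false(tm$negated)
})

test_that("signs compose through collapsed nodes", {
  # inhibitory inbound edge: the collapsed edge is inhibitory
  net <- boolean_delay_network(c(B = "NOT A(t-2)", C = "B(t-3)"),
                               stimulus = "A", observable = "C")
  tm <- expr_terms(simplify_network(net)$rules[["C"]])[[1]]
  expect_true(tm$negated)
  expect_equal(tm$theta, 5L)
  # two inhibitions cancel
  net <- boolean_delay_network(c(B = "NOT A(t-2)", C = "NOT B(t-3)"),
                               stimulus = "A", observable = "C")
  tm <- expr_terms(simplify_network(net)$rules[["C"]])[[1]]
  expect_false(tm$negated)
})

test_that("branching nodes are preserved and reduction is idempotent", {
  fan <- boolean_delay_network(c(B = "A(t-1)", C = "A(t-2)"),
                               stimulus = "A", observable = character())
  expect_true(isTRUE(all.equal(simplify_network(fan), fan)))

  # the bundled model has no 1-in/1-out internal nodes left
  net <- builtin_nfkb_network()
  expect_true(isTRUE(all.equal(simplify_network(net), net)))

  for (seed in 1:10) {
    rn <- random_network(6, seed = seed)
    once <- simplify_network(rn)
    expect_true(isTRUE(all.equal(simplify_network(once), once)))
    # reduction preserves stimulus -> observable reachability
    d0 <- igraph::distances(network_graph(rn), v = rn$stimulus[1],
                            to = rn$observable[1], mode = "out")
    d1 <- igraph::distances(network_graph(once), v = rn$stimulus[1],
                            to = rn$observable[1], mode = "out")
    expect_equal(is.finite(d0[1, 1]), is.finite(d1[1, 1]))
  }
})

test_that("collapsing a chain preserves activation onset", {
  # delays compose additively: the observable switches on at the same
  # minute; each removed node contributed one minute of trailing
  # activity, so the off-transition of the full chain lags by the number
  # of collapsed nodes
  net <- boolean_delay_network(
    c(B = "A(t-2)", C = "B(t-3)", D = "C(t-4)"),
    stimulus = "A", observable = "D")
  simp <- simplify_network(net)
  expect_setequal(simp$nodes, c("A", "D"))
  p <- stimulus_protocol(stim_event("A", 0, 20), 60)
  iv_full <- activation_intervals(simulate_network(net, p), "D")
  iv_simp <- activation_intervals(simulate_network(simp, p), "D")
  expect_equal(iv_full$start, iv_simp$start)
  expect_equal(iv_full$end, iv_simp$end + 2L)   # two nodes removed
})

test_that("the kernel pathway is the node set all signals pass through", {
  net <- builtin_nfkb_network()
  expect_setequal(find_kernel(net, c("TNF", "IL1", "LPS"), "NFkB"),
                  c("IKK", "IkBa", "NFkB"))

  chain <- boolean_delay_network(c(B = "A(t-1)", C = "B(t-1)"),
                                 stimulus = "A", observable = "C")
  expect_setequal(find_kernel(chain, "A", "C"), c("A", "B", "C"))

  # two disjoint routes share only the endpoints
  par2 <- boolean_delay_network(
    c(B = "A(t-1)", C = "A(t-1)", D = "B(t-1) OR C(t-1)"),
    stimulus = "A", observable = "D")
  expect_setequal(find_kernel(par2, "A", "D"), c("A", "D"))

  disc <- boolean_delay_network(c(B = "A(t-1)"), nodes = c("A", "B", "Z"),
                                stimulus = c("A", "Z"), observable = "B")
  expect_warning(k <- find_kernel(disc, "Z", "B"), "no path")
  expect_length(k, 0L)
})

test_that("feedback regulators are hub targets on long cycles", {
  net <- builtin_nfkb_network()
  expect_setequal(feedback_regulators(net, "NFkB"),
                  c("TNF", "A20", "IL1"))
  expect_length(feedback_regulators(net, "NFkB"), 3L)

  acyclic <- boolean_delay_network(c(B = "A(t-1)", C = "B(t-1)"),
                                   stimulus = "A", observable = "C")
  expect_length(feedback_regulators(acyclic, "B"), 0L)

  # a pure 2-cycle partner is excluded by default, included on request
  loop <- boolean_delay_network(c(A = "B(t-1)", B = "A(t-1)"),
                                nodes = c("A", "B"))
  expect_length(feedback_regulators(loop, "A"), 0L)
  expect_equal(feedback_regulators(loop, "A", exclude_two_cycles = FALSE),
               "B")
})
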