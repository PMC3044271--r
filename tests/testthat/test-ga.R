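# Genetic-algorithm fitting: fitness, operators, the GA loop, and the
# two-stage protocol.

toy_net <- function() {
  boolean_delay_network(c(B = "A(t-2)", C = "2*B(t-3)"),
                        stimulus = "A", observable = c("B", "C"))
}

toy_experiments <- function(net, horizon = 40L) {
  p <- stimulus_protocol(stim_event("A", 0, 20), horizon)
  tr <- simulate_network(net, p, accumulator = "bounded")
  list(experiment(p, character(),
                  observed_bits(tr, c("B", "C"), 0:horizon)))
}

test_that("MSE fitness counts squared bit differences over all samples", {
  net <- toy_net()
  exps <- toy_experiments(net)
  # the generating parameters fit perfectly
  expect_equal(mse_fitness(net, NULL, exps, accumulator = "bounded"), 0)
  # complementing every observed bit gives the maximal error
  flipped <- exps
  flipped[[1]]$observations$bit <- 1L - flipped[[1]]$observations$bit
  expect_equal(mse_fitness(net, NULL, flipped, accumulator = "bounded"), 1)
  # 3 mismatches out of 10 points -> 0.3
  ten <- exps
  ten[[1]]$observations <- ten[[1]]$observations[1:10, ]
  ten[[1]]$observations$bit[c(2, 5, 9)] <-
    1L - ten[[1]]$observations$bit[c(2, 5, 9)]
  expect_equal(mse_fitness(net, NULL, ten, accumulator = "bounded"), 0.3)
  expect_error(mse_fitness(net, NULL, list()), "empty training set")
})

test_that("roulette selection weights individuals by inverse error", {
  expect_equal(unique(roulette_select(0.5, n = 50)), 1L)
  set.seed(1)
  picks <- roulette_select(c(0, 1), n = 1e4)
  expect_gt(mean(picks == 1L), 0.99)
  # equal fitness: uniform within a chi-square test
  picks <- roulette_select(rep(0.25, 4), n = 2e4)
  expect_gt(chisq.test(tabulate(picks, 4))$p.value, 1e-3)
})

test_that("crossover swaps tails once; mutation stays in range", {
  a <- rep(1L, 10); b <- rep(2L, 10)
  set.seed(3)
  for (i in 1:20) {
    kids <- ga_crossover(a, b)
    for (k in kids) {
      expect_true(all(k %in% c(1L, 2L)))
      expect_lte(sum(diff(k) != 0L), 1L)   # at most one switch point
    }
    expect_equal(sort(c(kids[[1]], kids[[2]])), sort(c(a, b)))
  }
  expect_error(ga_crossover(a, b[1:3]), "length mismatch")

  cfg <- ga_config(population_size = 10, generations = 1,
                   theta_range = c(1, 50), r_range = c(-5, 5))
  ch <- random_chromosome(4, cfg)
  cfg0 <- cfg; cfg0$mutation_rate <- 0
  expect_identical(ga_mutate(ch, cfg0), ch)
  cfg1 <- cfg; cfg1$mutation_rate <- 1
  set.seed(4)
  for (i in 1:50) {
    m <- ga_mutate(ch, cfg1)
    th <- m[seq(1, 8, 2)]; rr <- m[seq(2, 8, 2)]
    expect_true(all(th >= 1 & th <= 50))
    expect_true(all(rr != 0 & abs(rr) <= 5))
  }
  # rate-1 mutation of a single gene resamples uniformly
  set.seed(5)
  cfg1g <- ga_config(population_size = 10, generations = 1,
                     mutation_rate = 1, theta_range = c(1, 8),
                     r_range = c(1, 2))
  draws <- replicate(4000, ga_mutate(c(1L, 1L), cfg1g)[1])
  expect_gt(chisq.test(tabulate(draws, 8))$p.value, 1e-3)
})

test_that("the GA recovers a known chain exactly and deterministically", {
  net <- toy_net()
  exps <- toy_experiments(net)
  cfg <- ga_config(population_size = 100, generations = 100, seed = 7,
                   theta_range = c(1, 10), r_range = c(1, 3))
  g <- run_ga(net, free_edge_set(net, "all"), exps, cfg,
              accumulator = "bounded")
  expect_equal(g$best_mse, 0)
  expect_equal(g$parameters$theta, c(2L, 3L))
  expect_equal(g$parameters$r, c(1L, 2L))
  # elitism makes the best-so-far history non-increasing
  expect_true(all(diff(g$history) <= 0))
  expect_length(g$history, cfg$generations + 1L)
  # same seed, same answer
  g2 <- run_ga(net, free_edge_set(net, "all"), exps, cfg,
               accumulator = "bounded")
  expect_identical(g$parameters, g2$parameters)
  expect_identical(g$history, g2$history)
})

test_that("free edge sets split on the kernel and chromosomes decode", {
  net <- builtin_nfkb_network()
  kernel <- c("IKK", "IkBa", "NFkB")
  ke <- free_edge_set(net, "kernel", kernel)
  re <- free_edge_set(net, "rest", kernel)
  expect_equal(nrow(ke) + nrow(re), nrow(network_edges(net)))
  expect_setequal(paste(ke$target, ke$source),
                  c("IkBa IKK", "IkBa NFkB", "NFkB IkBa"))
  ch <- c(7L, 2L, 96L, -62L, 1L, 1L)
  net2 <- apply_chromosome(net, ke, ch)
  ed <- network_edges(net2)
  expect_equal(ed$theta[ed$target == "IkBa" & ed$source == "IKK"], 7L)
  expect_error(apply_chromosome(net, ke, ch[1:3]), "length")
})

test_that("two-stage fitting freezes the kernel and merges parameters", {
  # kernel-only network: stage 2 is a no-op, the result equals run_ga
  chain <- toy_net()
  exps <- toy_experiments(chain)
  cfg <- ga_config(population_size = 60, generations = 60, seed = 11,
                   theta_range = c(1, 10), r_range = c(1, 3))
  ts <- two_stage_fit(chain, kernel_nodes = c("A", "B", "C"),
                      training_sets = exps, config = cfg,
                      accumulator = "bounded")
  direct <- run_ga(chain, free_edge_set(chain, "all"), exps, cfg,
                   accumulator = "bounded")
  expect_null(ts$stage2)
  expect_identical(ts$parameters, direct$parameters)

  # full model: stage-1 kernel genes are frozen through stage 2
  truth <- synthetic_nfkb_truth()
  sets <- study_training_sets(truth, sigma = 0)
  fit <- two_stage_fit(builtin_nfkb_network(), c("IKK", "IkBa", "NFkB"),
                       list(stage1 = sets$wt, stage2 = sets$ext),
                       config = study_config(1), accumulator = "bounded")
  ed <- network_edges(fit$network)
  s1 <- fit$stage1$parameters
  for (i in seq_len(nrow(s1))) {
    j <- ed$target == s1$target[i] & ed$source == s1$source[i]
    expect_equal(ed$theta[j], s1$theta[i])
    expect_equal(ed$r[j], s1$r[i])
  }
  expect_true(all(diff(fit$stage1$history) <= 0))
  expect_true(all(diff(fit$stage2$history) <= 0))
  expect_error(two_stage_fit(builtin_nfkb_network(), c("IKK"),
                             list(stage1 = sets$wt, stage2 = list())),
               "stage-2")
})

test_that("delays are recovered from noisy densitometry traces", {
  # moderate noise (signal-to-noise 10), short lanes binarized with a
  # matched bin count; every seed must recover >= 80% of the
  # identifiable delays within +-2 minutes
  truth <- synthetic_nfkb_truth()
  identifiable <- study_identifiable(truth)
  for (seed in 1:3) {
    sets <- study_training_sets(truth, sigma = 10, bins = 6L, seed = seed)
    fit <- two_stage_fit(builtin_nfkb_network(), c("IKK", "IkBa", "NFkB"),
                         list(stage1 = sets$wt, stage2 = sets$ext),
                         config = study_config(seed),
                         accumulator = "bounded")
    expect_gte(study_recovery(fit, truth, identifiable), 0.8)
  }
})
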