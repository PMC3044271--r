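# Shared harness for the parameter-recovery study: ground truth with the
# bundled network's topology and exercisable synthetic parameters,
# conditions starting from the resting state (IkBa present), all regulated
# nodes observed on a 3-minute grid over 60 minutes.

study_obs_nodes <- function(truth) setdiff(truth$nodes, "LPS")
study_rest <- c(IkBa = 1L)
study_grid <- seq(0L, 60L, by = 3L)

study_conditions <- function(horizon = 60L) {
  tnf45 <- stimulus_protocol(stim_event("TNF", 0, 45), horizon)
  lps45 <- stimulus_protocol(stim_event("LPS", 0, 45), horizon)
  wt <- list(list(protocol = tnf45, knockouts = character()),
             list(protocol = lps45, knockouts = character()))
  list(wt = wt,
       ext = c(wt, list(list(protocol = tnf45, knockouts = "A20"))))
}

study_training_sets <- function(truth, sigma = 0, bins = 256L,
                                seed = NULL) {
  conds <- study_conditions()
  if (!is.null(seed)) set.seed(seed)
  wt <- synthetic_training_set(truth, conds$wt,
                               nodes = study_obs_nodes(truth),
                               grid = study_grid, sigma = sigma,
                               initial = study_rest, bins = bins,
                               accumulator = "bounded")
  ext <- synthetic_training_set(truth, conds$ext,
                                nodes = study_obs_nodes(truth),
                                grid = study_grid, sigma = sigma,
                                initial = study_rest, bins = bins,
                                accumulator = "bounded")
  list(wt = wt, ext = ext)
}

study_bits <- function(net, conds = study_conditions()$ext,
                       obs = study_obs_nodes(net)) {
  unlist(lapply(conds, function(cond) {
    tr <- simulate_network(net, cond$protocol, cond$knockouts,
                           initial = study_rest, accumulator = "bounded")
    observed_bits(tr, obs, study_grid)$bit
  }))
}

# a true delay is identifiable when every feasible +-3-minute perturbation
# of it (alone) changes the sampled training bits
study_identifiable <- function(truth) {
  ed <- network_edges(truth)
  ref <- study_bits(truth)
  vapply(seq_len(nrow(ed)), function(i) {
    changed <- vapply(c(-3L, 3L), function(d) {
      th <- ed$theta[i] + d
      if (th < 1L) return(NA)
      p <- ed[i, c("target", "source", "theta", "r")]
      p$theta <- th
      !identical(study_bits(set_edge_params(truth, p)), ref)
    }, NA)
    all(changed, na.rm = TRUE) && any(!is.na(changed))
  }, NA)
}

study_config <- function(seed) {
  ga_config(population_size = 150L, generations = 200L,
            elitism_count = 10L, seed = seed,
            theta_range = c(1L, 40L), r_range = c(1L, 3L))
}

study_recovery <- function(fit, truth, identifiable) {
  ed <- network_edges(truth)
  m <- match(paste(ed$target, ed$source),
             paste(fit$parameters$target, fit$parameters$source))
  err <- abs(fit$parameters$theta[m] - ed$theta)
  mean(err[identifiable] <= 2L)
}
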