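# Genetic-algorithm estimation of the free (theta, r) edge parameters
# against binarized experimental profiles.  Chromosomes are integer vectors
# of interleaved (theta, r) genes, one pair per free edge in the network's
# declared edge order; fitness is the mean squared error between simulated
# and observed bits at the observation grid points.

#' GA configuration
#'
#' Defaults follow the published settings: population 1000, 800
#' generations, crossover rate 1 (always applied), mutation rate 2% per
#' gene, with elitism.  Gene ranges default to theta in \[1, 400\] and
#' r in \[-100, 100\] \ {0}, generous bounds around the bundled model's
#' largest printed values.
#'
#' @param population_size individuals per generation.
#' @param generations number of generations (the GA terminates there).
#' @param crossover_rate probability a selected pair is crossed over.
#' @param mutation_rate per-gene probability of resampling.
#' @param elitism_count best individuals copied unchanged each generation.
#' @param seed RNG seed set at the start of [run_ga()] (NULL: leave RNG).
#' @param theta_range integer delayed-activation bounds, min >= 1.
#' @param r_range integer response bounds; 0 is never sampled.
#' @param epsilon roulette weight is `1 / (mse + epsilon)`.
#' @param sample_every default observation grid spacing (minutes) for
#'   experiments without an explicit grid.
#' @return list of class `ga_config`.
#' @export
ga_config <- function(population_size = 1000L, generations = 800L,
                      crossover_rate = 1, mutation_rate = 0.02,
                      elitism_count = 1L, seed = NULL,
                      theta_range = c(1L, 400L),
                      r_range = c(-100L, 100L),
                      epsilon = 1e-6, sample_every = 5L) {
  stopifnot(population_size >= 2L, generations >= 1L,
            crossover_rate >= 0, crossover_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            elitism_count >= 1L, elitism_count < population_size,
            theta_range[1] >= 1L, theta_range[2] >= theta_range[1])
  r_vals <- setdiff(seq.int(r_range[1], r_range[2]), 0L)
  if (!length(r_vals)) stop("r_range contains no nonzero integers")
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 elitism_count = as.integer(elitism_count),
                 seed = seed,
                 theta_range = as.integer(theta_range),
                 r_values = as.integer(r_vals),
                 epsilon = epsilon,
                 sample_every = as.integer(sample_every)),
            class = "ga_config")
}

#' Training experiments
#'
#' Pairs a stimulus/knockout condition with the binarized observations the
#' model is fitted to.
#'
#' @param protocol a [stimulus_protocol()].
#' @param knockouts nodes clamped off in this condition.
#' @param observations data.frame `node`, `t`, `bit` (the sampling grid).
#' @param initial optional named 0/1 vector of pre-stimulus starting
#'   states (e.g. `c(IkBa = 1)` for a resting cell).
#' @return object of class `bdn_experiment`.
#' @export
experiment <- function(protocol, knockouts = character(), observations,
                       initial = NULL) {
  stopifnot(inherits(protocol, "bdn_protocol"),
            all(c("node", "t", "bit") %in% names(observations)))
  if (any(observations$t < 0 | observations$t > protocol$horizon))
    stop("observation times outside the protocol horizon")
  if (!all(observations$bit %in% c(0L, 1L)))
    stop("observations must be 0/1 bits")
  structure(list(protocol = protocol, knockouts = knockouts,
                 observations = observations, initial = initial),
            class = "bdn_experiment")
}

#' Select free edges of a network
#'
#' @param network a `bdn`.
#' @param which `"all"` edges, `"kernel"` (both endpoints in
#'   `kernel_nodes`), or `"rest"` (the complement of the kernel edges).
#' @param kernel_nodes node set for `"kernel"`/`"rest"`.
#' @return data.frame `target`, `source` in the declared edge order.
#' @export
free_edge_set <- function(network, which = c("all", "kernel", "rest"),
                          kernel_nodes = NULL) {
  which <- match.arg(which)
  ed <- network_edges(network)[, c("target", "source")]
  if (which == "all") return(ed)
  if (is.null(kernel_nodes)) stop("kernel_nodes required for '", which, "'")
  in_kernel <- ed$target %in% kernel_nodes & ed$source %in% kernel_nodes
  out <- ed[if (which == "kernel") in_kernel else !in_kernel, ,
            drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Overwrite edge parameters of a network
#'
#' @param network a `bdn`.
#' @param params data.frame with `target`, `source`, `theta`, `r`.
#' @return the modified network.
#' @export
set_edge_params <- function(network, params) {
  rewrite <- function(expr, tgt) {
    if (expr$op == "term") {
      i <- which(params$target == tgt & params$source == expr$source)
      if (length(i) == 1L)
        edge_term(expr$source, params$theta[i], params$r[i])
      else expr
    } else if (expr$op == "not") {
      expr$arg <- rewrite(expr$arg, tgt)
      expr
    } else {
      expr$args <- lapply(expr$args, rewrite, tgt = tgt)
      expr
    }
  }
  for (tgt in unique(params$target)) {
    if (is.null(network$rules[[tgt]]))
      stop("no rule for target '", tgt, "'")
    network$rules[[tgt]]$expr <- rewrite(network$rules[[tgt]]$expr, tgt)
  }
  validate_network(network)
}

#' Random chromosome / decoding
#'
#' A chromosome interleaves (theta, r) for each free edge in the declared
#' edge order: `c(theta_1, r_1, theta_2, r_2, ...)`.
#'
#' @param n_edges number of free edges.
#' @param config a [ga_config()].
#' @return integer vector of length `2 * n_edges`.
#' @export
random_chromosome <- function(n_edges, config) {
  th <- config$theta_range[1] - 1L +
    sample.int(config$theta_range[2] - config$theta_range[1] + 1L,
               n_edges, replace = TRUE)
  rr <- config$r_values[sample.int(length(config$r_values), n_edges,
                                   replace = TRUE)]
  as.integer(rbind(th, rr))
}

#' @rdname random_chromosome
#' @param network,free_edges the network and the free-edge table the
#'   chromosome refers to.
#' @param chromosome integer vector.
#' @return `apply_chromosome` returns the network with the chromosome's
#'   parameters written onto the free edges.
#' @export
apply_chromosome <- function(network, free_edges, chromosome) {
  m <- nrow(free_edges)
  if (length(chromosome) != 2L * m)
    stop("chromosome length ", length(chromosome), " does not match ",
         m, " free edges")
  params <- data.frame(target = free_edges$target,
                       source = free_edges$source,
                       theta = chromosome[seq(1L, 2L * m, by = 2L)],
                       r = chromosome[seq(2L, 2L * m, by = 2L)])
  set_edge_params(network, params)
}

# ---- fitness --------------------------------------------------------------

# Precompiled evaluation context: simulating an experiment set reduces to
# indexing the state matrix at the observation grid.
ga_context <- function(network, free_edges, training_set, accumulator) {
  if (!length(training_set)) stop("empty training set")
  comp <- compile_bdn(network)
  key <- paste(comp$edge_df$target, comp$edge_df$source)
  idx <- match(paste(free_edges$target, free_edges$source), key)
  if (anyNA(idx))
    stop("free edge not present in the network: ",
         paste(free_edges$target[is.na(idx)], "<-",
               free_edges$source[is.na(idx)], collapse = ", "))
  exps <- lapply(training_set, function(ex) {
    stopifnot(inherits(ex, "bdn_experiment"))
    obs <- ex$observations
    node_col <- match(obs$node, comp$nodes)
    if (anyNA(node_col))
      stop("observed node '", obs$node[is.na(node_col)][1],
           "' is not in the network")
    init <- integer(length(comp$nodes))
    if (!is.null(ex$initial))
      init[match(names(ex$initial), comp$nodes)] <- as.integer(ex$initial)
    list(stim = stim_matrix(network, ex$protocol),
         ko = as.integer(comp$nodes %in% ex$knockouts),
         horizon = ex$protocol$horizon,
         at = cbind(obs$t + 1L, node_col),
         bits = as.integer(obs$bit),
         init = init)
  })
  n_obs <- sum(vapply(exps, function(e) length(e$bits), 1L))
  bounded <- accumulator == "bounded"
  list(comp = comp, idx = idx, exps = exps, n_obs = n_obs,
       bounded = bounded,
       base_theta = comp$e_theta, base_r = comp$e_r)
}

ga_eval <- function(ctx, chromosome) {
  theta <- ctx$base_theta
  r <- ctx$base_r
  if (length(ctx$idx)) {
    m <- length(ctx$idx)
    theta[ctx$idx] <- chromosome[seq(1L, 2L * m, by = 2L)]
    r[ctx$idx] <- chromosome[seq(2L, 2L * m, by = 2L)]
  }
  sq <- 0
  for (e in ctx$exps) {
    states <- sim_compiled(ctx$comp, e$stim, e$ko, e$init, e$horizon,
                           ctx$bounded, theta = theta, r = r)
    sq <- sq + sum((states[e$at] - e$bits)^2)
  }
  sq / ctx$n_obs
}

#' Mean-squared-error fitness of a parameterization
#'
#' Simulates every experiment and returns the mean of squared differences
#' between predicted and observed bits over all (experiment, node,
#' timepoint) triples.  0 iff every sampled bit matches; 1 iff every bit is
#' complemented.
#'
#' @param network a `bdn`.
#' @param chromosome integer vector for `free_edges`, or `NULL` to evaluate
#'   the network's current parameters.
#' @param training_set list of [experiment()] objects.
#' @param free_edges data.frame `target`,`source` (needed with a
#'   chromosome).
#' @param accumulator see [simulate_network()].
#' @return mse in \[0, 1\].
#' @export
mse_fitness <- function(network, chromosome, training_set,
                        free_edges = NULL,
                        accumulator = c("accumulate", "bounded")) {
  accumulator <- match.arg(accumulator)
  if (is.null(chromosome))
    free_edges <- data.frame(target = character(), source = character())
  ctx <- ga_context(network, free_edges, training_set, accumulator)
  ga_eval(ctx, chromosome)
}

# ---- genetic operators ----------------------------------------------------

#' Roulette-wheel selection
#'
#' Samples indices with probability proportional to `1 / (mse + epsilon)`:
#' lower error, higher selection probability; equal fitness is uniform.
#'
#' @param fitnesses numeric vector of MSE values.
#' @param n number of draws (with replacement).
#' @param epsilon weighting constant.
#' @return integer indices into `fitnesses`.
#' @export
roulette_select <- function(fitnesses, n = 1L, epsilon = 1e-6) {
  if (!length(fitnesses)) stop("empty population")
  w <- 1 / (fitnesses + epsilon)
  sample.int(length(fitnesses), n, replace = TRUE, prob = w)
}

#' Single-point crossover and per-gene mutation
#'
#' `ga_crossover` cuts both parents at one uniform position in `0..L` and
#' swaps the tails (a cut at 0 or L returns the parents unchanged, up to
#' order).  `ga_mutate` resamples each gene independently with probability
#' `config$mutation_rate`, uniformly within its declared range, so children
#' are always in-range.
#'
#' @param a,b equal-length integer chromosomes.
#' @return `ga_crossover`: list of two children.
#' @export
ga_crossover <- function(a, b) {
  if (length(a) != length(b)) stop("chromosome length mismatch")
  cut <- sample.int(length(a) + 1L, 1L) - 1L     # 0..L
  if (cut == 0L) return(list(b, a))
  if (cut == length(a)) return(list(a, b))
  head_idx <- seq_len(cut)
  list(c(a[head_idx], b[-head_idx]), c(b[head_idx], a[-head_idx]))
}

#' @rdname ga_crossover
#' @param chromosome integer chromosome.
#' @param config a [ga_config()].
#' @export
ga_mutate <- function(chromosome, config) {
  L <- length(chromosome)
  hit <- which(stats::runif(L) < config$mutation_rate)
  if (!length(hit)) return(chromosome)
  for (i in hit) {
    chromosome[i] <- if (i %% 2L == 1L)
      config$theta_range[1] - 1L +
        sample.int(config$theta_range[2] - config$theta_range[1] + 1L, 1L)
    else config$r_values[sample.int(length(config$r_values), 1L)]
  }
  chromosome
}

# ---- the GA loop ----------------------------------------------------------

#' Fit free edge parameters by genetic algorithm
#'
#' Random initial population; roulette-wheel parent selection; single-point
#' crossover; per-gene mutation; elitism (the `elitism_count` best
#' individuals survive unchanged).  Terminates after `config$generations`
#' generations.  With elitism the best-so-far MSE never increases.
#'
#' @param network a `bdn` (its current parameters are kept on non-free
#'   edges).
#' @param free_edges data.frame `target`, `source` of edges to fit.
#' @param training_set list of [experiment()] objects.
#' @param config a [ga_config()].
#' @param accumulator see [simulate_network()].
#' @return list with `parameters` (data.frame `target`, `source`, `theta`,
#'   `r` for the free edges), `network` (the fitted network), `best_mse`,
#'   and `history` (best MSE after the initial population and after each
#'   generation; non-increasing).
#' @export
run_ga <- function(network, free_edges, training_set, config = ga_config(),
                   accumulator = c("accumulate", "bounded")) {
  accumulator <- match.arg(accumulator)
  network <- as_network(network)
  if (!nrow(free_edges)) stop("free_edges is empty")
  if (!is.null(config$seed)) set.seed(config$seed)
  ctx <- ga_context(network, free_edges, training_set, accumulator)
  m <- nrow(free_edges)
  pop <- replicate(config$population_size, random_chromosome(m, config),
                   simplify = FALSE)
  fit <- vapply(pop, function(ch) ga_eval(ctx, ch), 0)
  best_i <- which.min(fit)
  best <- pop[[best_i]]
  best_mse <- fit[best_i]
  history <- best_mse

  for (gen in seq_len(config$generations)) {
    ord <- order(fit)
    elites <- pop[ord[seq_len(config$elitism_count)]]
    children <- vector("list", config$population_size -
                         config$elitism_count)
    k <- 0L
    while (k < length(children)) {
      par <- roulette_select(fit, 2L, config$epsilon)
      pair <- list(pop[[par[1]]], pop[[par[2]]])
      if (stats::runif(1) < config$crossover_rate)
        pair <- ga_crossover(pair[[1]], pair[[2]])
      for (child in pair) {
        if (k >= length(children)) break
        k <- k + 1L
        children[[k]] <- ga_mutate(child, config)
      }
    }
    pop <- c(elites, children)
    fit <- vapply(pop, function(ch) ga_eval(ctx, ch), 0)
    gi <- which.min(fit)
    if (fit[gi] < best_mse) {
      best_mse <- fit[gi]
      best <- pop[[gi]]
    }
    history <- c(history, best_mse)
  }
  fitted <- apply_chromosome(network, free_edges, best)
  list(parameters = data.frame(
         target = free_edges$target, source = free_edges$source,
         theta = best[seq(1L, 2L * m, by = 2L)],
         r = best[seq(2L, 2L * m, by = 2L)]),
       network = fitted, best_mse = best_mse, history = history,
       config = config)
}

#' Two-stage kernel-first fitting
#'
#' Stage 1 fits only the edges among the kernel nodes, with every other
#' edge's parameters pinned at (theta = 1, r = 1), against the wild-type
#' training set.  Stage 2 freezes the kernel parameters at their stage-1
#' values and fits all remaining edges against the extended training set.
#'
#' @param network a `bdn`.
#' @param kernel_nodes kernel node set (e.g. from [find_kernel()]).
#' @param training_sets either a list of [experiment()]s used for both
#'   stages, or `list(stage1 = ..., stage2 = ...)`.
#' @param config a [ga_config()]; its seed covers both stages.
#' @param accumulator see [simulate_network()].
#' @return list with merged `parameters` for all edges, the fitted
#'   `network`, `best_mse` (stage-2 MSE on the extended set, or stage-1 MSE
#'   if there are no non-kernel edges), and the per-stage results.
#' @export
two_stage_fit <- function(network, kernel_nodes, training_sets,
                          config = ga_config(),
                          accumulator = c("accumulate", "bounded")) {
  accumulator <- match.arg(accumulator)
  network <- as_network(network)
  if (!is.null(training_sets$stage1)) {
    set1 <- training_sets$stage1
    set2 <- training_sets$stage2
  } else {
    set1 <- training_sets
    set2 <- training_sets
  }
  if (!length(set2)) stop("stage-2 training set is empty")
  kernel_edges <- free_edge_set(network, "kernel", kernel_nodes)
  rest_edges <- free_edge_set(network, "rest", kernel_nodes)
  if (!nrow(kernel_edges))
    stop("no edges among the kernel nodes ",
         paste(kernel_nodes, collapse = ", "))

  pinned <- network
  if (nrow(rest_edges))
    pinned <- set_edge_params(
      pinned, data.frame(rest_edges, theta = 1L, r = 1L))
  stage1 <- run_ga(pinned, kernel_edges, set1, config, accumulator)

  if (!nrow(rest_edges)) {
    return(list(parameters = stage1$parameters, network = stage1$network,
                best_mse = stage1$best_mse, stage1 = stage1,
                stage2 = NULL))
  }
  stage2 <- run_ga(stage1$network, rest_edges, set2, config, accumulator)
  params <- rbind(stage1$parameters, stage2$parameters)
  list(parameters = params, network = stage2$network,
       best_mse = stage2$best_mse, stage1 = stage1, stage2 = stage2)
}
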