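# Synchronous simulation of a time-delayed Boolean network under stimulus
# protocols and in-silico knockouts.  Time base: discrete 1-minute steps,
# t = 0 is the first simulated minute; stimulus intervals are half-open
# [start, end).  Update order per minute: all edge gates from the previous
# node states, then all node rules on the gate bits (fully synchronous).

#' Stimulus protocols
#'
#' A protocol is a set of exogenous on-events for stimulus nodes over a
#' simulation horizon.  An event keeps its node at level 1 for minutes
#' `start <= t < end` (half-open); the exogenous drive is OR'd with the
#' node's endogenous rule, if any.
#'
#' @param events data.frame with columns `node`, `start`, `end` and
#'   optionally `level` (default 1); or a list of [stim_event()] rows.
#' @param horizon total minutes simulated.
#' @return object of class `bdn_protocol`.
#' @examples
#' stimulus_protocol(stim_event("TNF", 0, 45), horizon = 720)
#' @export
stimulus_protocol <- function(events = NULL, horizon) {
  if (is.null(events)) {
    events <- data.frame(node = character(), start = integer(),
                         end = integer(), level = integer())
  } else if (is.list(events) && !is.data.frame(events)) {
    events <- do.call(rbind, events)
  }
  if (is.null(events$level)) events$level <- 1L
  horizon <- as.integer(horizon)
  if (is.na(horizon) || horizon < 1L) stop("horizon must be >= 1")
  if (nrow(events)) {
    bad <- which(!(events$start >= 0 & events$start < events$end &
                     events$end <= horizon))
    if (length(bad))
      stop("event for '", events$node[bad[1]],
           "' violates 0 <= start < end <= horizon")
    if (!all(events$level %in% c(0L, 1L)))
      stop("event levels must be 0 or 1")
  }
  structure(list(events = events, horizon = horizon),
            class = "bdn_protocol")
}

#' @rdname stimulus_protocol
#' @param node stimulus node name.
#' @param start,end half-open on-interval in minutes.
#' @param level 1 (drive on) or 0 (no exogenous drive).
#' @export
stim_event <- function(node, start, end, level = 1L) {
  data.frame(node = node, start = as.integer(start), end = as.integer(end),
             level = as.integer(level))
}

stim_matrix <- function(network, protocol) {
  n <- length(network$nodes)
  h <- protocol$horizon
  m <- matrix(0L, nrow = n, ncol = h + 1L,
              dimnames = list(network$nodes, NULL))
  ev <- protocol$events
  if (nrow(ev)) {
    bad <- setdiff(unique(ev$node), network$stimulus)
    if (length(bad))
      stop("protocol drives '", bad[1],
           "', which is not a declared stimulus node")
    for (k in seq_len(nrow(ev))) {
      if (ev$level[k] == 1L)
        m[ev$node[k], seq.int(ev$start[k] + 1L, ev$end[k])] <- 1L
    }
  }
  m
}

# ---- network compilation --------------------------------------------------

# Flattens a bdn into parallel edge vectors plus one RPN program per node.
# Edge order is the declared order: rules in declaration order, terms in
# their in-rule order.  This order also defines chromosome gene order.
compile_bdn <- function(network) {
  nodes <- network$nodes
  idx <- stats::setNames(seq_along(nodes), nodes)
  e_src <- integer(0); e_theta <- integer(0); e_r <- integer(0)
  e_neg <- integer(0); e_target <- character(0); e_source <- character(0)
  rpn <- rep(list(integer(0)), length(nodes))

  emit <- function(expr, target) {
    switch(expr$op,
      term = {
        e_src <<- c(e_src, idx[[expr$source]] - 1L)
        e_theta <<- c(e_theta, expr$theta)
        e_r <<- c(e_r, expr$r)
        e_neg <<- c(e_neg, 0L)
        e_target <<- c(e_target, target)
        e_source <<- c(e_source, expr$source)
        length(e_src)                       # 1-based edge id
      },
      not = c(emit(expr$arg, target), 0L),
      {
        code <- integer(0)
        opcode <- if (expr$op == "and") -1L else -2L
        for (k in seq_along(expr$args)) {
          code <- c(code, emit(expr$args[[k]], target))
          if (k > 1L) code <- c(code, opcode)
        }
        code
      })
  }
  for (tgt in names(network$rules))
    rpn[[idx[[tgt]]]] <- as.integer(emit(network$rules[[tgt]]$expr, tgt))
  list(nodes = nodes, e_src = e_src, e_theta = e_theta, e_r = e_r,
       e_neg = e_neg,
       edge_df = data.frame(target = e_target, source = e_source,
                            theta = e_theta, r = e_r),
       rpn = rpn)
}

sim_compiled <- function(comp, stim, knockout, init, horizon, bounded,
                         theta = comp$e_theta, r = comp$e_r) {
  states <- .sim_core(length(comp$nodes), horizon,
                      comp$e_src, as.integer(theta), as.integer(r),
                      comp$e_neg, comp$rpn, stim, knockout, init, bounded)
  dimnames(states) <- list(0:horizon, comp$nodes)
  states
}

# ---- public simulation API ------------------------------------------------

#' Simulate a network under a stimulus protocol and knockouts
#'
#' Runs the synchronous minute-resolution dynamics: at each minute every
#' edge gate is updated from the previous minute's source states, then each
#' node's gate tree is evaluated on the gate bits.  All nodes start off at
#' t = 0 unless `initial` is given.  Knocked-out nodes are clamped to 0 for
#' the whole run.
#'
#' @param network a `bdn`, `"builtin:nfkb"`, or a network JSON path.
#' @param protocol a [stimulus_protocol()]; `NULL` for an unstimulated run
#'   (then `horizon` must be given).
#' @param knockouts character vector of nodes clamped off.
#' @param horizon total minutes; defaults to the protocol horizon.
#' @param initial optional named 0/1 vector of starting states.
#' @param accumulator `"accumulate"` (default): the sustain accumulator
#'   grows by `r - 1` every minute the input condition holds, so a long
#'   input earns a proportionally long sustained tail.  `"bounded"`: the
#'   accumulator is clamped at `r - 1`, making the sustain a fixed duration.
#'   See the package vignette for why both readings exist.
#' @return object of class `bdn_trace`: binary node-by-time states plus the
#'   protocol and knockout set.
#' @examples
#' net <- builtin_nfkb_network()
#' tr <- simulate_network(net, stimulus_protocol(stim_event("TNF", 0, 45), 720))
#' activation_intervals(tr, "IKK")
#' @export
simulate_network <- function(network, protocol = NULL,
                             knockouts = character(), horizon = NULL,
                             initial = NULL,
                             accumulator = c("accumulate", "bounded")) {
  network <- as_network(network)
  accumulator <- match.arg(accumulator)
  if (is.null(protocol)) {
    if (is.null(horizon)) stop("give a protocol or an explicit horizon")
    protocol <- stimulus_protocol(NULL, horizon)
  }
  if (is.null(horizon)) horizon <- protocol$horizon
  horizon <- as.integer(horizon)
  if (horizon < 1L) stop("horizon must be >= 1")
  if (horizon != protocol$horizon)
    protocol <- stimulus_protocol(protocol$events, horizon)

  bad <- setdiff(knockouts, network$nodes)
  if (length(bad)) stop("unknown knockout node '", bad[1], "'")
  driven <- unique(protocol$events$node[protocol$events$level == 1L])
  clash <- intersect(knockouts, driven)
  if (length(clash))
    stop("node '", clash[1],
         "' is both knocked out and driven by the protocol")

  comp <- compile_bdn(network)
  stim <- stim_matrix(network, protocol)
  ko <- as.integer(network$nodes %in% knockouts)
  init <- integer(length(network$nodes))
  if (!is.null(initial)) {
    bad <- setdiff(names(initial), network$nodes)
    if (length(bad)) stop("unknown node '", bad[1], "' in initial state")
    init[match(names(initial), network$nodes)] <- as.integer(initial)
  }
  states <- sim_compiled(comp, stim, ko, init, horizon,
                         bounded = (accumulator == "bounded"))
  structure(list(states = states, protocol = protocol,
                 knockouts = knockouts, accumulator = accumulator),
            class = "bdn_trace")
}

#' @export
print.bdn_trace <- function(x, ...) {
  cat("Boolean trace:", ncol(x$states), "nodes x", nrow(x$states),
      "minutes (t = 0..", nrow(x$states) - 1L, ")\n", sep = " ")
  if (length(x$knockouts))
    cat("  knockouts:", paste(x$knockouts, collapse = ", "), "\n")
  on <- colSums(x$states)
  cat("  minutes on:",
      paste(names(on), on, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' @export
as.data.frame.bdn_trace <- function(x, ...) {
  data.frame(t = as.integer(rownames(x$states)), x$states,
             check.names = FALSE)
}

#' Maximal activation intervals of one node
#'
#' @param trace a `bdn_trace` (or a plain 0/1 matrix with time rownames).
#' @param node node name.
#' @param burn_in minutes at the start excluded from the report.
#' @return data.frame with one row per maximal on-run: columns `start`,
#'   `end` (both inclusive, in minutes).  Zero rows if the node is never on.
#' @export
activation_intervals <- function(trace, node, burn_in = 0L) {
  states <- if (inherits(trace, "bdn_trace")) trace$states else trace
  if (!node %in% colnames(states)) stop("unknown node '", node, "'")
  tt <- as.integer(rownames(states))
  keep <- tt >= burn_in
  bits <- states[keep, node]
  tt <- tt[keep]
  rl <- rle(as.integer(bits))
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  on <- rl$values == 1L
  data.frame(start = tt[starts[on]], end = tt[ends[on]])
}

total_on_time <- function(trace, node) {
  iv <- activation_intervals(trace, node)
  if (!nrow(iv)) 0L else sum(iv$end - iv$start + 1L)
}

# ---- literal reference interpreter ---------------------------------------

#' One edge-gate update step
#'
#' The elementary sustained/delayed-response state machine, exposed for
#' inspection and used by [simulate_reference()].  `state` is a list with
#' accumulator `tau`, gate bit `g`, and `on_run`, the current
#' consecutive-on length of the source *including* the minute being fed in.
#'
#' @param state list with `tau`, `g`, `on_run` (start from
#'   `list(tau = 0, g = 0, on_run = 0)`).
#' @param source_on 0/1 source state for this minute.
#' @param theta delayed activation (minutes, >= 1).
#' @param r sustained (`r >= 1`) or delayed (`r <= -1`) response; nonzero.
#' @param accumulate if `FALSE`, clamp the sustain accumulator at `r - 1`.
#' @return list with the updated `state` and the emitted gate bit `g`.
#' @examples
#' s <- list(tau = 0, g = 0, on_run = 0)
#' for (t in 1:5) { up <- edge_gate_update(s, 1, theta = 2, r = 1); s <- up$state }
#' s$g  # on: source has been on for >= 2 minutes
#' @export
edge_gate_update <- function(state, source_on, theta, r,
                             accumulate = TRUE) {
  if (r == 0) stop("r must be nonzero")
  if (theta < 1) stop("theta must be >= 1")
  on_run <- if (source_on) state$on_run + 1L else 0L
  tau <- state$tau
  h <- as.integer(on_run >= theta)
  if (r >= 1) {
    if (h == 1L) {
      tau <- tau + r - 1
      if (!accumulate) tau <- min(tau, r - 1)
      g <- 1L
    } else if (tau > 0) {
      tau <- tau - 1
      g <- 1L
    } else {
      g <- 0L
    }
  } else {
    if (h == 1L) {
      tau <- min(tau + 1, -r)
      g <- as.integer(tau >= -r)
    } else {
      tau <- 0
      g <- 0L
    }
  }
  list(state = list(tau = tau, g = g, on_run = on_run), g = g)
}

eval_expr_bits <- function(expr, gate_of) {
  switch(expr$op,
    term = gate_of(expr),
    not = 1L - eval_expr_bits(expr$arg, gate_of),
    and = {
      v <- 1L
      for (a in expr$args) v <- v & eval_expr_bits(a, gate_of)
      as.integer(v)
    },
    or = {
      v <- 0L
      for (a in expr$args) v <- v | eval_expr_bits(a, gate_of)
      as.integer(v)
    })
}

#' Literal pure-R reference simulator
#'
#' A direct, unoptimized transcription of the update semantics: one
#' [edge_gate_update()] state machine per edge, rule trees evaluated
#' recursively.  Used as the independent oracle for the compiled simulator;
#' the two must produce bit-identical traces.
#'
#' @inheritParams simulate_network
#' @return a `bdn_trace`.
#' @export
simulate_reference <- function(network, protocol = NULL,
                               knockouts = character(), horizon = NULL,
                               initial = NULL,
                               accumulator = c("accumulate", "bounded")) {
  network <- as_network(network)
  accumulator <- match.arg(accumulator)
  if (is.null(protocol)) {
    if (is.null(horizon)) stop("give a protocol or an explicit horizon")
    protocol <- stimulus_protocol(NULL, horizon)
  }
  if (is.null(horizon)) horizon <- protocol$horizon
  if (horizon != protocol$horizon)
    protocol <- stimulus_protocol(protocol$events, horizon)
  stim <- stim_matrix(network, protocol)
  nodes <- network$nodes

  x <- stats::setNames(integer(length(nodes)), nodes)
  if (!is.null(initial)) x[names(initial)] <- as.integer(initial)
  x <- pmax(x, stim[, 1L])
  x[knockouts] <- 0L

  # one gate state machine per (target, source) term, keyed by rule walk
  gates <- list()
  for (tgt in names(network$rules))
    for (tm in expr_terms(network$rules[[tgt]]))
      gates[[paste(tgt, tm$source)]] <-
        list(tau = 0, g = 0L, on_run = 0L)

  states <- matrix(0L, nrow = horizon + 1L, ncol = length(nodes),
                   dimnames = list(0:horizon, nodes))
  states[1L, ] <- x
  acc <- accumulator == "accumulate"

  for (t in seq_len(horizon)) {
    xprev <- x
    gbits <- list()
    for (tgt in names(network$rules)) {
      for (tm in expr_terms(network$rules[[tgt]])) {
        key <- paste(tgt, tm$source)
        up <- edge_gate_update(gates[[key]], xprev[[tm$source]],
                               tm$theta, tm$r, accumulate = acc)
        gates[[key]] <- up$state
        gbits[[key]] <- up$g
      }
    }
    for (n in nodes) {
      rule <- network$rules[[n]]
      v <- if (is.null(rule)) 0L else
        eval_expr_bits(rule$expr,
                       function(tm) gbits[[paste(n, tm$source)]])
      if (stim[n, t + 1L]) v <- 1L
      if (n %in% knockouts) v <- 0L
      x[[n]] <- v
    }
    states[t + 1L, ] <- x
  }
  structure(list(states = states, protocol = protocol,
                 knockouts = knockouts, accumulator = accumulator),
            class = "bdn_trace")
}

# ---- trace / experiment file formats -------------------------------------

#' Read and write traces as wide CSV
#'
#' Column `t` plus one 0/1 column per node.
#'
#' @param trace a `bdn_trace`.
#' @param path file path.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @return `read_trace` returns a `bdn_trace` (states only; the protocol is
#'   not stored in the CSV).
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  states <- as.matrix(df[, setdiff(names(df), "t"), drop = FALSE])
  rownames(states) <- df$t
  structure(list(states = states, protocol = NULL,
                 knockouts = character(), accumulator = NA_character_),
            class = "bdn_trace")
}

#' Read / write experiment configurations (YAML)
#'
#' Format: `stimuli:` list of `{node, start, end}`, `knockouts:` list of
#' node names, `horizon:` minutes.
#'
#' @param path YAML file path.
#' @return list with `protocol` (a `bdn_protocol`) and `knockouts`.
#' @export
read_experiment_config <- function(path) {
  obj <- yaml::read_yaml(path)
  if (is.null(obj$horizon)) stop("experiment file lacks 'horizon'")
  events <- NULL
  if (length(obj$stimuli))
    events <- do.call(rbind, lapply(obj$stimuli, function(s)
      stim_event(s$node, s$start, s$end,
                 if (is.null(s$level)) 1L else s$level)))
  list(protocol = stimulus_protocol(events, obj$horizon),
       knockouts = as.character(unlist(obj$knockouts)))
}

#' @rdname read_experiment_config
#' @param protocol a `bdn_protocol`.
#' @param knockouts character vector.
#' @export
write_experiment_config <- function(protocol, knockouts = character(),
                                    path) {
  ev <- protocol$events
  obj <- list(
    stimuli = if (nrow(ev)) lapply(seq_len(nrow(ev)), function(i)
      list(node = ev$node[i], start = ev$start[i], end = ev$end[i])) else
        list(),
    knockouts = as.list(knockouts),
    horizon = protocol$horizon)
  yaml::write_yaml(obj, path)
  invisible(path)
}
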