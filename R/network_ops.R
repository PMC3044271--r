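# Structural analysis: linear-chain reduction, kernel-pathway
# identification, feedback-loop enumeration.  All operate on the signed
# directed graph derived from the rules.

#' Signed igraph view of a network
#'
#' One vertex per node, one directed edge per rule term, with attributes
#' `theta`, `r` and `sign` (-1 for negated terms).
#'
#' @param network a `bdn` object.
#' @return an igraph graph.
#' @export
network_graph <- function(network) {
  ed <- network_edges(network)
  igraph::graph_from_data_frame(
    data.frame(from = ed$source, to = ed$target,
               theta = ed$theta, r = ed$r, sign = ed$sign),
    directed = TRUE, vertices = network$nodes)
}

#' Collapse linear pass-through nodes
#'
#' Repeatedly removes any non-stimulus, non-observable node with exactly
#' one input and one output, replacing the path a -> b -> c by a single
#' edge a -> c with `theta = theta_ab + theta_bc` (delays compose
#' additively), `r = r_bc` (the sustain belongs to the receiving reaction)
#' and sign equal to the product of the two signs.  Branching or meeting
#' nodes are preserved, and so are nodes on directed cycles: the
#' reduction targets linear relay chains, while feedback effectors (A20,
#' IL-1, TNF in the bundled model) are dynamical units in their own
#' right and the in-silico knockout interface needs them as nodes.  The
#' result is a fixed point: applying the reduction again changes
#' nothing.
#'
#' @param network a `bdn` object.
#' @return the reduced `bdn`.
#' @examples
#' net <- boolean_delay_network(c(B = "A(t-2)", C = "B(t-3)"),
#'                              stimulus = "A", observable = "C")
#' simplify_network(net)  # C(t) = A(t-5)
#' @export
simplify_network <- function(network) {
  net <- validate_network(network)
  repeat {
    ed <- network_edges(net)
    g <- network_graph(net)
    scc <- igraph::components(g, mode = "strong")
    cyclic <- names(scc$membership)[
      scc$csize[scc$membership] > 1L]
    protected <- Reduce(union, list(net$stimulus, net$observable, cyclic))
    victim <- NULL
    for (v in setdiff(net$nodes, protected)) {
      inc <- ed[ed$target == v, , drop = FALSE]
      out <- ed[ed$source == v, , drop = FALSE]
      if (nrow(inc) != 1L || nrow(out) != 1L) next
      a <- inc$source; cc <- out$target
      if (a == v || cc == v) next                   # self-loop: keep
      # merging must not create a duplicate (target, source) edge
      if (any(ed$target == cc & ed$source == a)) next
      # the v->c term's own NOT (if any) stays in c's rewritten rule, so
      # only the a->v edge's polarity must be added; the composed sign is
      # then the product of the two signs.
      victim <- list(v = v, a = a, c = cc,
                     theta = inc$theta + out$theta,
                     negated = inc$negated)
      break
    }
    if (is.null(victim)) return(net)
    net <- drop_through_node(net, victim)
  }
}

# rewrite the rule of victim$c: its term with source v becomes a term with
# source a, composed theta, r of the v->c edge, sign composed; remove v.
drop_through_node <- function(net, victim) {
  rewrite <- function(expr) {
    if (expr$op == "term") {
      if (expr$source == victim$v) {
        tm <- edge_term(victim$a, victim$theta, expr$r)
        if (victim$negated)
          structure(list(op = "not", arg = tm), class = "bdn_expr")
        else tm
      } else expr
    } else if (expr$op == "not") {
      # NOT (NOT x) from sign composition stays as written; collapse it
      inner <- rewrite(expr$arg)
      if (inner$op == "not") inner$arg
      else structure(list(op = "not", arg = inner), class = "bdn_expr")
    } else {
      expr$args <- lapply(expr$args, rewrite)
      expr
    }
  }
  rule_c <- net$rules[[victim$c]]
  rule_c$expr <- rewrite(rule_c$expr)
  net$rules[[victim$c]] <- rule_c
  net$rules[[victim$v]] <- NULL
  net$nodes <- setdiff(net$nodes, victim$v)
  validate_network(net)
}

#' Kernel pathway: nodes every signal must pass through
#'
#' Returns the nodes lying on *every* directed simple path from each source
#' to each sink.  In the bundled NF-kB model, with the three stimulus entry
#' points as sources and NFkB as sink, this is the IKK-IkBa-NFkB core.
#'
#' @param network a `bdn` object.
#' @param sources,sinks nonempty node sets.
#' @return character vector of kernel nodes (includes the sinks themselves
#'   when reachable).  Empty, with a warning, if some source has no path to
#'   some sink.
#' @export
find_kernel <- function(network, sources, sinks) {
  if (!length(sources) || !length(sinks))
    stop("sources and sinks must be nonempty")
  bad <- setdiff(c(sources, sinks), network$nodes)
  if (length(bad)) stop("unknown node '", bad[1], "'")
  g <- network_graph(network)
  kernel <- NULL
  for (s in sources) {
    for (k in sinks) {
      paths <- igraph::all_simple_paths(g, from = s, to = k, mode = "out")
      if (!length(paths)) {
        warning("no path from '", s, "' to '", k, "'")
        return(character())
      }
      common <- Reduce(intersect, lapply(paths, function(p) names(p)))
      kernel <- if (is.null(kernel)) common else intersect(kernel, common)
    }
  }
  intersect(network$nodes, kernel)   # restore declaration order
}

#' Feedback regulators of a hub node
#'
#' Enumerates the hub's direct rule targets (nodes whose rule uses the hub
#' as a source) that sit on a directed cycle back to the hub of length at
#' least 3.  Direct two-node loops (hub -> x -> hub, the IkBa-type
#' self-regulatory pair) are excluded by default, as they describe the
#' hub's own inhibitory cycle rather than a feedback route through the
#' network.
#'
#' @param network a `bdn` object.
#' @param hub node name.
#' @param exclude_two_cycles include direct 2-cycles when `FALSE`.
#' @return character vector of regulator nodes, in declaration order.
#' @examples
#' feedback_regulators(builtin_nfkb_network(), "NFkB")  # TNF, A20, IL1
#' @export
feedback_regulators <- function(network, hub, exclude_two_cycles = TRUE) {
  if (!hub %in% network$nodes) stop("unknown hub node '", hub, "'")
  ed <- network_edges(network)
  targets <- unique(ed$target[ed$source == hub])
  g <- network_graph(network)
  keep <- vapply(targets, function(d) {
    if (d == hub) return(FALSE)
    paths <- igraph::all_simple_paths(g, from = d, to = hub, mode = "out")
    lens <- vapply(paths, length, 1L)
    if (any(lens >= 3L)) return(TRUE)          # cycle length >= 3 via d
    if (!exclude_two_cycles && any(lens == 2L)) return(TRUE)
    FALSE
  }, TRUE)
  intersect(network$nodes, targets[keep])
}
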