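# The network container: named nodes, one transfer rule per regulated node,
# declared stimulus and observable subsets.  Nodes without a rule are pure
# inputs.

#' Construct a time-delayed Boolean network
#'
#' @param rules named character vector or named list of rule strings /
#'   `bdn_rule` objects; names are the target nodes.
#' @param nodes ordered character vector of all node names.  Defaults to the
#'   rule targets plus every referenced source, in order of appearance.
#' @param stimulus nodes that accept exogenous input.  A stimulus applied to
#'   a node that also has a rule is OR'd with the rule output.
#' @param observable nodes reported against experimental data.
#' @return object of class `bdn`.
#' @examples
#' net <- boolean_delay_network(
#'   c(B = "2*A(t-1)", C = "B(t-2)"),
#'   stimulus = "A", observable = "C")
#' @export
boolean_delay_network <- function(rules, nodes = NULL,
                                  stimulus = character(),
                                  observable = character()) {
  if (is.character(rules)) rules <- as.list(rules)
  if (is.null(names(rules)) || any(!nzchar(names(rules))))
    stop("'rules' must be named by their target nodes")
  if (anyDuplicated(names(rules)))
    stop("duplicate rule for target '",
         names(rules)[duplicated(names(rules))][1], "'")
  parsed <- lapply(names(rules), function(tgt) {
    r <- rules[[tgt]]
    if (inherits(r, "bdn_rule")) {
      r$target <- tgt
      r
    } else parse_rule(r, tgt)
  })
  names(parsed) <- names(rules)
  if (is.null(nodes)) {
    srcs <- unlist(lapply(parsed, function(r)
      vapply(expr_terms(r), `[[`, "", "source")))
    nodes <- unique(c(names(parsed), srcs))
  }
  net <- structure(list(nodes = nodes, rules = parsed,
                        stimulus = stimulus, observable = observable),
                   class = "bdn")
  validate_network(net)
}

#' Validate a network, returning it invisibly
#'
#' Checks that every rule target and every term source is a declared node,
#' that stimulus/observable sets are subsets of the nodes, and that no rule
#' has duplicate edges from one source.
#'
#' @param network a `bdn` object.
#' @return the network, invisibly (errors otherwise).
#' @export
validate_network <- function(network) {
  stopifnot(inherits(network, "bdn"))
  nodes <- network$nodes
  if (anyDuplicated(nodes))
    stop("duplicate node name '", nodes[duplicated(nodes)][1], "'")
  for (tgt in names(network$rules)) {
    if (!tgt %in% nodes)
      stop("rule target '", tgt, "' is not a declared node")
    for (tm in expr_terms(network$rules[[tgt]]))
      if (!tm$source %in% nodes)
        stop("rule for '", tgt, "' references undeclared node '",
             tm$source, "'")
  }
  bad <- setdiff(network$stimulus, nodes)
  if (length(bad)) stop("stimulus node '", bad[1], "' is not a declared node")
  bad <- setdiff(network$observable, nodes)
  if (length(bad)) stop("observable node '", bad[1],
                        "' is not a declared node")
  invisible(network)
}

#' Edge table of a network
#'
#' Derives the edge set from the rules: one row per (target, source) term,
#' with its dynamic parameters and sign (`-1` for terms under NOT).
#'
#' @param network a `bdn` object.
#' @return data.frame with columns `target`, `source`, `theta`, `r`,
#'   `negated`, `sign`.
#' @export
network_edges <- function(network) {
  rows <- lapply(names(network$rules), function(tgt) {
    tms <- expr_terms(network$rules[[tgt]])
    data.frame(target = tgt,
               source = vapply(tms, `[[`, "", "source"),
               theta = vapply(tms, `[[`, 1L, "theta"),
               r = vapply(tms, `[[`, 1L, "r"),
               negated = vapply(tms, `[[`, TRUE, "negated"))
  })
  out <- do.call(rbind, rows)
  out$sign <- ifelse(out$negated, -1L, 1L)
  rownames(out) <- NULL
  out
}

#' @export
print.bdn <- function(x, ...) {
  cat("Time-delayed Boolean network:", length(x$nodes), "nodes,",
      length(x$rules), "rules\n")
  inputs <- setdiff(x$nodes, names(x$rules))
  if (length(inputs)) cat("  pure inputs: ", paste(inputs, collapse = ", "),
                          "\n", sep = "")
  if (length(x$stimulus)) cat("  stimulus:    ",
                              paste(x$stimulus, collapse = ", "), "\n",
                              sep = "")
  if (length(x$observable)) cat("  observable:  ",
                                paste(x$observable, collapse = ", "), "\n",
                                sep = "")
  for (tgt in names(x$rules))
    cat("  ", tgt, "(t) = ", format_rule(x$rules[[tgt]]), "\n", sep = "")
  invisible(x)
}

#' @export
#' @method all.equal bdn
all.equal.bdn <- function(target, current, ...) {
  t1 <- list(nodes = target$nodes,
             rules = lapply(target$rules, format_rule),
             stimulus = target$stimulus, observable = target$observable)
  t2 <- list(nodes = current$nodes,
             rules = lapply(current$rules, format_rule),
             stimulus = current$stimulus, observable = current$observable)
  all.equal(t1, t2, ...)
}

#' The bundled NF-kB inflammation model
#'
#' The fitted ten-rule model of the LPS/IL-1/TNF to NF-kB signalling
#' network.  TNF, IL1 and LPS are the stimulus entry points; TNF and IL1
#' additionally carry endogenous production rules (NF-kB induces both), so
#' an exogenous stimulus is OR'd with the rule output.  IKK, IkBa and NFkB
#' are the observable read-outs.  The composite node TAB1/TAB2/TAK1 is kept
#' as printed in the source model.
#'
#' @return a `bdn` object with 10 rules over 11 nodes.
#' @examples
#' net <- builtin_nfkb_network()
#' network_edges(net)
#' @export
builtin_nfkb_network <- function() {
  rules <- c(
    "IRAK1"          = "5*IL1(t-1) OR 3*LPS(t-87)",
    "TAB1/TAB2/TAK1" = "IRAK1(t-13) OR LPS(t-125)",
    "NIK"            = "TAB1/TAB2/TAK1(t-25) OR TNFR1(t-1)",
    "IKK"            = "TAB1/TAB2/TAK1(t-100) OR NIK(t-1)",
    "IkBa"           = "NOT 2*IKK(t-3) OR -62*NFkB(t-96)",
    "NFkB"           = "NOT IkBa(t-1)",
    "A20"            = "7*NFkB(t-107)",
    "IL1"            = "-62*NFkB(t-373)",
    "TNF"            = "-62*NFkB(t-69)",
    "TNFR1"          = "4*TNF(t-1) AND NOT A20(t-10)"
  )
  boolean_delay_network(
    rules,
    nodes = c("IRAK1", "TAB1/TAB2/TAK1", "NIK", "IKK", "IkBa", "NFkB",
              "A20", "IL1", "TNF", "TNFR1", "LPS"),
    stimulus = c("TNF", "IL1", "LPS"),
    observable = c("IKK", "IkBa", "NFkB"))
}

# ---- JSON serialization ---------------------------------------------------

#' Read / write networks as JSON
#'
#' The JSON dialect stores the node list, stimulus and observable subsets,
#' and one rule string per regulated node in the rule syntax of
#' [parse_rule()]:
#' `{"nodes": [...], "stimulus_nodes": [...], "observable_nodes": [...],
#'   "rules": {"IRAK1": "5*IL1(t-1) OR 3*LPS(t-87)", ...}}`.
#' The round trip `load_network(save_network(net, path))` is lossless.
#'
#' @param path file path.
#' @return `load_network` returns a `bdn`; `save_network` returns `path`
#'   invisibly.
#' @export
load_network <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  for (field in c("nodes", "rules"))
    if (is.null(obj[[field]]))
      stop("network file '", path, "' lacks the '", field, "' field")
  rules <- vapply(obj$rules, identity, "")
  boolean_delay_network(rules, nodes = as.character(obj$nodes),
                        stimulus = as.character(obj$stimulus_nodes),
                        observable = as.character(obj$observable_nodes))
}

#' @rdname load_network
#' @param network a `bdn` object.
#' @export
save_network <- function(network, path) {
  validate_network(network)
  obj <- list(
    nodes = network$nodes,
    stimulus_nodes = network$stimulus,
    observable_nodes = network$observable,
    rules = lapply(network$rules, format_rule))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Resolve a network reference
#'
#' Accepts a `bdn` object, the URI `"builtin:nfkb"`, or a path to a network
#' JSON file.
#'
#' @param x network, URI, or path.
#' @return a `bdn` object.
#' @export
as_network <- function(x) {
  if (inherits(x, "bdn")) return(x)
  if (is.character(x) && length(x) == 1L) {
    if (x %in% c("builtin:nfkb", "builtin")) return(builtin_nfkb_network())
    if (file.exists(x)) return(load_network(x))
    stop("unknown network reference '", x,
         "' (expected a bdn, 'builtin:nfkb', or an existing file)")
  }
  stop("cannot interpret 'network' argument")
}
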