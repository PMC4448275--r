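#' Hill regulation function
#'
#' The elementary sigmoidal regulation term
#' \deqn{h(x; \theta, \mu) = x^\mu / (x^\mu + \theta^\mu)}
#' with threshold \eqn{\theta > 0} (the concentration at which h = 0.5)
#' and steepness \eqn{\mu > 0}. Monotone non-decreasing in x, h(0) = 0,
#' h tends to 1 as x grows. Evaluated in the numerically stable form
#' \eqn{1 / (1 + (\theta/x)^\mu)} for x > 0.
#'
#' @param x concentration(s), >= 0.
#' @param theta threshold, > 0.
#' @param mu steepness, > 0.
#' @return value(s) in [0, 1].
#' @examples
#' hill(0.5, theta = 0.5, mu = 5) # 0.5 at the threshold
#' @export
hill <- function(x, theta, mu) {
  if (any(x < 0)) stop("hill(): negative concentration")
  if (any(theta <= 0) || any(mu <= 0)) stop("hill(): theta and mu must be > 0")
  ifelse(x == 0, 0, 1 / (1 + (theta / x)^mu))
}

#' Regulator-interaction combinators
#'
#' The four interaction functions that compose already-evaluated Hill
#' terms (values in [0, 1]) into a single production modulation, each
#' mapping back into [0, 1]:
#' \describe{
#'   \item{\code{coop}}{cooperation: all regulators must be high;
#'     \code{min(h_1, ..., h_n)}.}
#'   \item{\code{syn}}{synergy: any regulator suffices;
#'     \code{min(1, h_1 + ... + h_n)} (empty sum is 0).}
#'   \item{\code{inh}}{inhibition: \code{1 - h}.}
#'   \item{\code{comp}}{competition of an activator with a repressor;
#'     \code{max(0, h_act - h_rep)}.}
#' }
#'
#' @param h,h_values,h_act,h_rep Hill-term values in [0, 1].
#' @return combined value in [0, 1].
#' @name combinators
#' @examples
#' coop(c(0.2, 0.9)) # 0.2
#' syn(c(0.8, 0.8))  # 1
#' comp(0.3, 0.7)    # 0
NULL

#' @rdname combinators
#' @export
coop <- function(h_values) {
  if (!length(h_values)) stop("coop(): needs at least one input")
  min(h_values)
}

#' @rdname combinators
#' @export
syn <- function(h_values) min(1, sum(h_values))

#' @rdname combinators
#' @export
inh <- function(h) 1 - h

#' @rdname combinators
#' @export
comp <- function(h_act, h_rep) pmax(0, h_act - h_rep)

#' Kinetic parameter sampling ranges
#'
#' Ranges for the per-node and per-edge dynamical parameters.
#' Concentrations are dimensionless and live near [0, 1]: basal
#' production is sampled as \code{p = p_rel * d0} with \code{p_rel} in
#' [0.5, 1.5], so unregulated steady states p/d0 land near 1, matching
#' the default Hill thresholds theta in [0.3, 0.8]. Basal degradation
#' d0 in [0.1, 1] (1/time) keeps relaxation times O(1)-O(10), and the
#' miRNA-dependent degradation gain is \code{di = d_rel * d0} with
#' \code{d_rel} in [0.5, 2], so full miRNA repression shortens a
#' transcript's lifetime by up to 3x.
#'
#' @param theta,mu Hill threshold/steepness ranges.
#' @param d0 basal degradation rate range (1/time).
#' @param p_rel production-to-degradation ratio range.
#' @param d_rel miRNA degradation gain relative to d0.
#' @return list of ranges, class \code{dynamics_ranges}.
#' @export
dynamics_ranges <- function(theta = c(0.3, 0.8), mu = c(2, 10),
                            d0 = c(0.1, 1), p_rel = c(0.5, 1.5),
                            d_rel = c(0.5, 2)) {
  rng <- list(theta = theta, mu = mu, d0 = d0, p_rel = p_rel, d_rel = d_rel)
  for (nm in names(rng)) {
    v <- rng[[nm]]
    if (length(v) != 2L || any(!is.finite(v)) || v[1] > v[2] || v[1] <= 0)
      stop("invalid range for ", nm)
  }
  structure(rng, class = "dynamics_ranges")
}

## ---- regulation trees ----------------------------------------------------
## A node's production term is a composition tree: leaves are Hill terms
## of individual regulators (each with its own theta/mu), internal nodes
## are COOP/SYN combinators; repressive edges enter either as INH leaves
## (1 - h) or as the repressor argument of a binary COMP. Every leaf is
## in [0,1] and every combinator maps [0,1]^n -> [0,1], so the tree value
## is always a valid production modulation.

tree_const <- function() list(op = "const")
tree_hill <- function(regulator, theta, mu)
  list(op = "hill", regulator = regulator, theta = theta, mu = mu)
tree_inh <- function(regulator, theta, mu)
  list(op = "inh", regulator = regulator, theta = theta, mu = mu)
tree_comb <- function(op, a, b) list(op = op, args = list(a, b))
tree_comp <- function(act, regulator, theta, mu)
  list(op = "comp", args = list(act), regulator = regulator,
       theta = theta, mu = mu)

#' Evaluate a regulation composition tree
#'
#' Reference (pure R) evaluation of a production composition tree given
#' named regulator concentrations. Used as the readable ground truth the
#' compiled fast path is checked against.
#'
#' @param tree composition tree (see \code{\link{sample_regulation_model}}).
#' @param values named numeric vector of concentrations (state and
#'   signal values together).
#' @return scalar in [0, 1].
#' @export
eval_tree <- function(tree, values) {
  switch(tree$op,
    const = 1,
    hill = hill(values[[tree$regulator]], tree$theta, tree$mu),
    inh = inh(hill(values[[tree$regulator]], tree$theta, tree$mu)),
    coop = coop(c(eval_tree(tree$args[[1]], values),
                  eval_tree(tree$args[[2]], values))),
    syn = syn(c(eval_tree(tree$args[[1]], values),
                eval_tree(tree$args[[2]], values))),
    comp = comp(eval_tree(tree$args[[1]], values),
                hill(values[[tree$regulator]], tree$theta, tree$mu)),
    stop("unknown tree op: ", tree$op))
}

## All leaf regulators of a tree, in order (for structural audits).
tree_regulators <- function(tree) {
  switch(tree$op,
    const = character(),
    hill = tree$regulator,
    inh = tree$regulator,
    comp = c(tree_regulators(tree$args[[1]]), tree$regulator),
    c(tree_regulators(tree$args[[1]]), tree_regulators(tree$args[[2]])))
}

#' Sample a regulation model for one node
#'
#' Draws the random composition of interaction functions that turns a
#' node's in-edges into its ODE right-hand side. Gene and signal
#' regulators form the production tree: activators become Hill leaves;
#' each repressor either pairs with an existing subtree through COMP
#' (with probability 1/2, when a subtree is available) or enters as an
#' INH leaf; remaining subtrees are merged pairwise by COOP or SYN
#' chosen uniformly. Every in-edge appears exactly once. miRNA
#' regulators never enter the production term: they act through the
#' degradation rate \code{d0 + di * SYN(h(m_1), ..., h(m_q))}
#' (synergistic inhibition is the only miRNA-miRNA interaction). miRNA
#' nodes themselves are produced like genes but degrade at the constant
#' basal rate \code{d0}.
#'
#' @param node node name.
#' @param kind \code{"gene"} or \code{"mirna"}.
#' @param in_edges data frame with columns \code{from} (regulator name),
#'   \code{from_kind}, \code{sign}, \code{theta}, \code{mu}; zero rows
#'   for an unregulated node (production tree is the constant 1).
#' @param ranges a \code{\link{dynamics_ranges}} object.
#' @return object of class \code{regulation_model}: \code{production}
#'   tree, \code{mirna_regs} (regulator/theta/mu data frame),
#'   \code{kinetic} (p, d0, di).
#' @export
sample_regulation_model <- function(node, kind, in_edges,
                                    ranges = dynamics_ranges()) {
  if (is.null(in_edges) || !nrow(in_edges)) {
    in_edges <- data.frame(from = character(), from_kind = character(),
                           sign = character(), theta = numeric(),
                           mu = numeric())
  }
  is_mir_reg <- in_edges$from_kind == "mirna"
  mirna_regs <- data.frame(regulator = in_edges$from[is_mir_reg],
                           theta = in_edges$theta[is_mir_reg],
                           mu = in_edges$mu[is_mir_reg])
  prod_edges <- in_edges[!is_mir_reg, , drop = FALSE]

  acts <- which(prod_edges$sign == "activation")
  reps <- which(prod_edges$sign == "repression")
  subtrees <- lapply(acts, function(i)
    tree_hill(prod_edges$from[i], prod_edges$theta[i], prod_edges$mu[i]))
  for (i in reps[sample.int(length(reps))]) {
    if (length(subtrees) && runif(1) < 0.5) {
      j <- sample.int(length(subtrees), 1L)
      subtrees[[j]] <- tree_comp(subtrees[[j]], prod_edges$from[i],
                                 prod_edges$theta[i], prod_edges$mu[i])
    } else {
      subtrees[[length(subtrees) + 1L]] <-
        tree_inh(prod_edges$from[i], prod_edges$theta[i], prod_edges$mu[i])
    }
  }
  while (length(subtrees) > 1L) {
    ij <- sample.int(length(subtrees), 2L)
    op <- sample(c("coop", "syn"), 1L)
    merged <- tree_comb(op, subtrees[[ij[1]]], subtrees[[ij[2]]])
    subtrees[[ij[1]]] <- merged
    subtrees[[ij[2]]] <- NULL
  }
  production <- if (length(subtrees)) subtrees[[1]] else tree_const()

  d0 <- runif(1, ranges$d0[1], ranges$d0[2])
  kinetic <- list(p = runif(1, ranges$p_rel[1], ranges$p_rel[2]) * d0,
                  d0 = d0,
                  di = runif(1, ranges$d_rel[1], ranges$d_rel[2]) * d0)
  structure(list(node = node, kind = kind, production = production,
                 mirna_regs = mirna_regs, kinetic = kinetic),
            class = "regulation_model")
}

#' miRNA-dependent degradation rate
#'
#' The degradation rate of a transcript regulated by q miRNAs:
#' \code{d0} when q = 0, otherwise
#' \code{d0 + di * SYN(h(m_1), ..., h(m_q))} — miRNAs inhibit their
#' shared target synergistically, so the rate saturates at
#' \code{d0 + di}.
#'
#' @param m_values miRNA concentrations (possibly empty).
#' @param kinetic list with \code{d0} and \code{di}.
#' @param mirna_hills data frame with \code{theta}, \code{mu} per miRNA.
#' @return degradation rate (1/time).
#' @export
degradation_rate <- function(m_values, kinetic, mirna_hills = NULL) {
  if (!length(m_values)) return(kinetic$d0)
  h <- hill(m_values, mirna_hills$theta, mirna_hills$mu)
  kinetic$d0 + kinetic$di * syn(h)
}

#' Build the full ODE system model for a network
#'
#' Samples one \code{\link{sample_regulation_model}} per gene/miRNA node
#' (signals are exogenous inputs, not state). The state-vector ordering
#' is the network's non-signal node order and is fixed thereafter.
#'
#' @param network a \code{regulatory_network}.
#' @param ranges \code{\link{dynamics_ranges}}.
#' @return object of class \code{system_model} with \code{nodes} (state
#'   node table), \code{signals} (signal node names), \code{models}
#'   (named list of regulation models), \code{ranges}.
#' @export
build_system_model <- function(network, ranges = dynamics_ranges()) {
  stopifnot(inherits(network, "regulatory_network"))
  nodes <- network$nodes
  state_nodes <- nodes[nodes$kind != "signal", , drop = FALSE]
  e <- network$edges
  e$from_name <- nodes$name[match(e$from, nodes$id)]
  e$to_name <- nodes$name[match(e$to, nodes$id)]
  e$from_kind <- nodes$kind[match(e$from, nodes$id)]
  models <- vector("list", nrow(state_nodes))
  names(models) <- state_nodes$name
  for (i in seq_len(nrow(state_nodes))) {
    nm <- state_nodes$name[i]
    ie <- e[e$to_name == nm, , drop = FALSE]
    in_edges <- data.frame(from = ie$from_name, from_kind = ie$from_kind,
                           sign = ie$sign, theta = ie$theta, mu = ie$mu)
    models[[i]] <- sample_regulation_model(nm, state_nodes$kind[i],
                                           in_edges, ranges)
  }
  structure(list(nodes = state_nodes,
                 signals = nodes$name[nodes$kind == "signal"],
                 models = models, ranges = ranges),
            class = "system_model")
}

#' @export
print.system_model <- function(x, ...) {
  cat("system_model:", nrow(x$nodes), "state nodes (",
      sum(x$nodes$kind == "gene"), "genes,",
      sum(x$nodes$kind == "mirna"), "miRNAs ),",
      length(x$signals), "signals\n")
  invisible(x)
}

#' Time derivative of one node (reference path)
#'
#' Pure-R evaluation of a single node's ODE right-hand side:
#' genes follow \code{p * r(x) - (d0 + di * SYN(h(m))) * x}, miRNAs
#' \code{p * r(x) - d0 * m} (constant degradation). Used for auditing
#' the compiled system; \code{\link{integrate_system}} uses the compiled
#' evaluator.
#'
#' @param node node name.
#' @param state named non-negative state vector (genes + miRNAs).
#' @param signal_values named vector of current signal values.
#' @param model a \code{system_model}.
#' @return scalar rate.
#' @export
node_derivative <- function(node, state, signal_values, model) {
  rm_ <- model$models[[node]]
  if (is.null(rm_)) stop("unknown node id: ", node)
  values <- c(state, signal_values)
  prod <- rm_$kinetic$p * eval_tree(rm_$production, values)
  dr <- if (rm_$kind == "mirna") rm_$kinetic$d0
        else degradation_rate(unname(values[rm_$mirna_regs$regulator]),
                              rm_$kinetic, rm_$mirna_regs)
  prod - dr * state[[node]]
}

#' All state derivatives (reference path)
#'
#' @inheritParams node_derivative
#' @return named vector of rates in state order.
#' @export
system_derivatives <- function(model, state, signal_values = NULL) {
  vapply(model$nodes$name, node_derivative, numeric(1),
         state = state, signal_values = signal_values, model = model)
}
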