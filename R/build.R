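## Network growth by iterated, score-guided motif replication.
##
## Starting from an edgeless node set V_N (genes + miRNAs), each step
## scores a pool of random motif templates, selects one proportionally
## to the shifted scores, fills its slots with nodes sampled
## proportionally to their sub-scores, wires the template's edges, and
## removes the consumed nodes from V_N. The slot carrying the master
## regulator role ("x") is kept in a separate set H; when V_N empties, H
## is poured back into V_N and a new hierarchy level starts. The process
## ends when both sets are empty, which yields the hierarchically
## modular structure: modules wired at level 0, their regulators wired
## together at level 1, and so on.

new_regulatory_network <- function(nodes, edges, provenance, config) {
  structure(list(nodes = nodes, edges = edges, provenance = provenance,
                 config = config),
            class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  kinds <- table(x$nodes$kind)
  cat("regulatory_network:", nrow(x$nodes), "nodes (",
      paste(names(kinds), kinds, sep = "=", collapse = ", "), "),",
      nrow(x$edges), "edges,", length(x$provenance), "motif instances\n")
  invisible(x)
}

## Mutable growth state kept in an environment to avoid copying the edge
## arrays on every insertion.
new_builder <- function(n_nodes, theta_range, mu_range) {
  b <- new.env(parent = emptyenv())
  b$indeg <- integer(n_nodes)
  b$outdeg <- integer(n_nodes)
  cap <- 4L * n_nodes + 64L
  b$from <- integer(cap); b$to <- integer(cap)
  b$sign <- character(cap); b$theta <- numeric(cap); b$mu <- numeric(cap)
  b$n_edges <- 0L
  b$keys <- new.env(parent = emptyenv(), hash = TRUE, size = cap)
  b$theta_range <- theta_range; b$mu_range <- mu_range
  b
}

## Add one edge unless it already exists (first writer wins).
## Returns TRUE if the edge was added.
builder_add_edge <- function(b, from, to, sign) {
  key <- paste0(from, "|", to)
  if (!is.null(b$keys[[key]])) return(FALSE)
  b$keys[[key]] <- TRUE
  i <- b$n_edges + 1L
  if (i > length(b$from)) {
    grow <- function(v) c(v, v)   # double capacity
    b$from <- grow(b$from); b$to <- grow(b$to); b$sign <- grow(b$sign)
    b$theta <- grow(b$theta); b$mu <- grow(b$mu)
  }
  b$from[i] <- from; b$to[i] <- to; b$sign[i] <- sign
  b$theta[i] <- runif(1L, b$theta_range[1L], b$theta_range[2L])
  b$mu[i] <- runif(1L, b$mu_range[1L], b$mu_range[2L])
  b$n_edges <- i
  b$indeg[to] <- b$indeg[to] + 1L
  b$outdeg[from] <- b$outdeg[from] + 1L
  TRUE
}

builder_edges <- function(b) {
  i <- seq_len(b$n_edges)
  data.frame(from = b$from[i], to = b$to[i], sign = b$sign[i],
             theta = b$theta[i], mu = b$mu[i],
             interaction = rep(NA_character_, b$n_edges))
}

## Lightweight degree state built from the builder (avoids reconstructing
## data frames inside the growth loop).
builder_state <- function(b, kind, n_nm) {
  deg <- (b$indeg + b$outdeg)[seq_len(n_nm)]
  indeg <- b$indeg[seq_len(n_nm)]; outdeg <- b$outdeg[seq_len(n_nm)]
  mir <- kind[seq_len(n_nm)] == "mirna"
  m <- sum(mir)
  list(deg = deg, indeg = indeg, outdeg = outdeg,
       p = tabulate(deg[deg > 0], n_nm) / n_nm,
       p_in = if (m) tabulate(indeg[mir][indeg[mir] > 0], n_nm) / m else numeric(n_nm),
       p_out = if (m) tabulate(outdeg[mir][outdeg[mir] > 0], n_nm) / m else numeric(n_nm),
       n_nodes = n_nm, n_mirnas = m, mirna = mir)
}

#' Grow a regulatory network
#'
#' Builds a hierarchically modular gene+miRNA regulatory network by
#' score-guided motif replication and (if \code{config$n_signals > 0})
#' appends signalling nodes. The whole construction is driven by
#' \code{config$seed} and is fully reproducible.
#'
#' @param config a \code{\link{network_config}}.
#' @param registry motif registry (see \code{\link{default_motif_registry}}).
#' @param theta_range,mu_range ranges for the per-edge Hill threshold and
#'   steepness parameters sampled at wiring time.
#' @return a \code{regulatory_network}: node table (id, name, kind),
#'   edge table (from, to, sign, theta, mu), and a motif-instance
#'   provenance log carrying the hierarchy level of every instantiation.
#' @examples
#' net <- build_network(network_config(30, 5, 2, seed = 42))
#' net
#' @export
build_network <- function(config, registry = default_motif_registry(),
                          theta_range = c(0.3, 0.8), mu_range = c(2, 10)) {
  stopifnot(inherits(config, "network_config"))
  set.seed(config$seed)
  n <- config$n_genes; m <- config$n_mirnas
  n_nm <- n + m
  kind <- c(rep("gene", n), rep("mirna", m))
  name <- c(paste0("g", seq_len(n)),
            if (m) paste0("mir", seq_len(m)) else character())
  targets <- sample_degree_targets(config)
  b <- new_builder(n_nm, theta_range, mu_range)

  avail <- rep(TRUE, n_nm)
  H <- integer()
  level <- 0L
  provenance <- list()
  edges_this_level <- 0L

  repeat {
    if (!any(avail)) {
      # the hierarchy is complete once a single root regulator remains:
      # one node cannot form further motifs (its self-edge, if any, was
      # already placed), so recycling it would only pile edges on it
      if (length(H) < 2L) break
      # guard: a level that adds no edges cannot make progress
      if (edges_this_level == 0L && level > 0L) break
      avail[H] <- TRUE
      H <- integer()
      level <- level + 1L
      edges_this_level <- 0L
      next
    }
    st <- builder_state(b, kind, n_nm)
    gene_avail <- which(avail & kind == "gene")
    mirna_avail <- which(avail & kind == "mirna")
    has_mir <- m > 0L

    ## pool of random motif instances, scored against the current state;
    ## when no gene is available the template must contain a miRNA slot
    ## so that each instantiation consumes at least one available node
    only_mir <- !length(gene_avail)
    pool <- replicate(config$pool_size,
                      sample_motif_template(registry, has_mir, only_mir),
                      simplify = FALSE)
    scores <- vapply(pool, motif_score, numeric(1), state = st,
                     targets = targets, gene_candidates = gene_avail,
                     mirna_candidates = mirna_avail)
    template <- pool[[select_motif(scores)]]

    ## fill slots: x first, then template order; candidates come from
    ## V_N, falling back to already-wired nodes of the right kind when
    ## V_N runs out (connector fallback), and dropping the slot when no
    ## node of that kind exists at all.
    dl <- slot_degree_deltas(template)
    order_slots <- c(which(dl$is_x), which(!dl$is_x))
    chosen <- rep(NA_integer_, nrow(dl))
    consumed <- integer()
    tab_g <- score_term_tables(st$p * st$n_nodes, st$n_nodes, targets$d_p)
    tab_in <- tab_out <- NULL
    if (st$n_mirnas > 0L) {
      tab_in <- score_term_tables(st$p_in * st$n_mirnas, st$n_mirnas, targets$d_p)
      tab_out <- score_term_tables(st$p_out * st$n_mirnas, st$n_mirnas, targets$d_e)
    }
    for (j in order_slots) {
      kj <- dl$kind[j]
      cand <- if (kj == "gene") gene_avail else mirna_avail
      cand <- setdiff(cand, chosen)
      borrowed <- FALSE
      if (!length(cand)) {
        cand <- setdiff(which(!avail & kind == kj), chosen)
        borrowed <- TRUE
      }
      if (!length(cand)) next  # no node of this kind anywhere: drop slot
      if (borrowed) {
        # connector fallback: uniform draw. Sub-score-proportional
        # selection here would concentrate edges on whichever wired
        # node last left a sparse tail bin (the 1/d_k normalizer blows
        # up in the tail), producing runaway hubs.
        sc <- rep(0, length(cand))
      } else if (kj == "gene") {
        k_old <- st$deg[cand]
        sc <- move_score(tab_g, k_old, k_old + dl$d_tot[j])
      } else {
        ki <- st$indeg[cand]; ko <- st$outdeg[cand]
        sc <- move_score(tab_in, ki, ki + dl$d_in[j]) +
          move_score(tab_out, ko, ko + dl$d_out[j])
      }
      pick <- cand[sample.int(length(cand), 1L, prob = shift_weights(sc))]
      chosen[j] <- pick
      if (!borrowed) {
        avail[pick] <- FALSE
        consumed <- c(consumed, pick)
        if (kj == "gene") gene_avail <- setdiff(gene_avail, pick)
        else mirna_avail <- setdiff(mirna_avail, pick)
      }
    }
    if (all(is.na(chosen))) next

    added <- 0L
    edge_log <- list()
    for (r in seq_len(nrow(template$edges))) {
      ef <- chosen[template$edges$from[r]]
      et <- chosen[template$edges$to[r]]
      if (is.na(ef) || is.na(et)) next
      sg <- if (kind[ef] == "mirna") "repression" else template$edges$sign[r]
      if (builder_add_edge(b, ef, et, sg)) {
        added <- added + 1L
        edge_log[[length(edge_log) + 1L]] <- c(ef, et)
      }
    }
    edges_this_level <- edges_this_level + added

    x_node <- chosen[which(dl$is_x)]
    if (added > 0L && !is.na(x_node) && x_node %in% consumed)
      H <- c(H, x_node)

    provenance[[length(provenance) + 1L]] <- list(
      template = template$name, level = level,
      nodes = setNames(chosen, paste0("slot", seq_along(chosen))),
      consumed = consumed,
      edges = if (length(edge_log)) do.call(rbind, edge_log) else matrix(integer(), 0L, 2L))
  }

  nodes <- data.frame(id = seq_len(n_nm), name = name, kind = kind)
  net <- new_regulatory_network(nodes, builder_edges(b), provenance, config)
  if (config$n_signals > 0L)
    net <- add_signalling_nodes(net, config$n_signals)
  net
}

#' Append signalling nodes to a network
#'
#' Signalling nodes model exogenous experimental inputs (stimulation,
#' drug administration, gene knock-down). They only have outgoing edges;
#' targets are sampled with probability proportional to (out-degree + 1),
#' so hubs are preferred but leaves stay eligible. Each signal receives
#' between 1 and 3 targets.
#'
#' @param network a \code{regulatory_network}.
#' @param n_signals number of signalling nodes to add.
#' @param theta_range,mu_range Hill parameter ranges for the new edges.
#' @return the augmented \code{regulatory_network}.
#' @export
add_signalling_nodes <- function(network, n_signals,
                                 theta_range = c(0.3, 0.8),
                                 mu_range = c(2, 10)) {
  stopifnot(inherits(network, "regulatory_network"))
  n_signals <- as.integer(n_signals)
  if (n_signals == 0L) return(network)
  nodes <- network$nodes
  tgt_pool <- nodes$id[nodes$kind != "signal"]
  if (!length(tgt_pool)) stop("cannot add signals to an empty network")
  outdeg <- tabulate(network$edges$from, max(nodes$id))[tgt_pool]
  w <- outdeg + 1
  new_ids <- max(nodes$id) + seq_len(n_signals)
  n_prev_sig <- sum(nodes$kind == "signal")
  new_nodes <- data.frame(id = new_ids,
                          name = paste0("s", n_prev_sig + seq_len(n_signals)),
                          kind = "signal")
  ef <- integer(); et <- integer()
  for (s in new_ids) {
    k <- sample.int(3L, 1L)
    k <- min(k, length(tgt_pool))
    tg <- tgt_pool[sample.int(length(tgt_pool), k, prob = w)]
    ef <- c(ef, rep(s, k)); et <- c(et, tg)
  }
  new_edges <- data.frame(from = ef, to = et, sign = "activation",
                          theta = runif(length(ef), theta_range[1], theta_range[2]),
                          mu = runif(length(ef), mu_range[1], mu_range[2]),
                          interaction = NA_character_)
  network$nodes <- rbind(nodes, new_nodes)
  network$edges <- rbind(network$edges, new_edges)
  network
}

#' Convert a regulatory network to an igraph graph
#'
#' Node attribute \code{kind} and edge attributes \code{sign},
#' \code{theta}, \code{mu}, \code{interaction} are carried over; vertex
#' names are the node names.
#'
#' @param network a \code{regulatory_network}.
#' @return an \code{igraph} directed graph.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "regulatory_network"))
  nm <- network$nodes$name
  e <- network$edges
  ed <- data.frame(from = nm[match(e$from, network$nodes$id)],
                   to = nm[match(e$to, network$nodes$id)],
                   sign = e$sign, theta = e$theta, mu = e$mu,
                   interaction = e$interaction)
  v <- data.frame(name = nm, kind = network$nodes$kind)
  igraph::graph_from_data_frame(ed, directed = TRUE, vertices = v)
}
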