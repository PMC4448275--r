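## Independent oracles used across the test files. These recompute
## quantities from first principles (term-by-term definitions, explicit
## loops, hand BFS) without going through the package's optimized code
## paths.

## Term-by-term sub-score for a gene: full sum over k = 1..n_nodes of
##   sign(|d_k - p_k| - |d_k - f_k|) * |d_k - p_k| / d_k
## with p_k the current total-degree fractions and f_k the fractions
## after raising `node`'s degree by `delta`. Bins with d_k = 0 skipped.
oracle_gene_subscore <- function(network, targets, node, delta) {
  st <- degree_state(network)
  n <- st$n_nodes
  counts <- tabulate(st$deg[st$deg > 0], n)
  new_counts <- counts
  k0 <- unname(st$deg[node])
  if (k0 >= 1 && k0 <= n) new_counts[k0] <- new_counts[k0] - 1L
  k1 <- k0 + delta
  if (k1 >= 1 && k1 <= n) new_counts[k1] <- new_counts[k1] + 1L
  s <- 0
  for (k in seq_len(n)) {
    d <- targets$d_p[k]
    if (d <= 0) next
    p <- counts[k] / n
    f <- new_counts[k] / n
    s <- s + sign(abs(d - p) - abs(d - f)) * abs(d - p) / d
  }
  s
}

## In/out split for a miRNA: in-degree fractions chased against the
## power-law target, out-degree fractions against the exponential one.
oracle_mirna_subscore <- function(network, targets, node, delta_in, delta_out) {
  st <- degree_state(network)
  m <- st$n_mirnas
  if (m == 0) return(0)
  n <- st$n_nodes
  one_dir <- function(degv, delta, d_target) {
    counts <- tabulate(degv[st$mirna][degv[st$mirna] > 0], n)
    new_counts <- counts
    k0 <- unname(degv[node])
    if (k0 >= 1 && k0 <= n) new_counts[k0] <- new_counts[k0] - 1L
    k1 <- k0 + delta
    if (k1 >= 1 && k1 <= n) new_counts[k1] <- new_counts[k1] + 1L
    s <- 0
    for (k in seq_len(n)) {
      d <- d_target[k]
      if (d <= 0) next
      p <- counts[k] / m
      f <- new_counts[k] / m
      s <- s + sign(abs(d - p) - abs(d - f)) * abs(d - p) / d
    }
    s
  }
  one_dir(st$indeg, delta_in, targets$d_p) +
    one_dir(st$outdeg, delta_out, targets$d_e)
}

## Brute-force directed clustering coefficient: explicit neighbour
## enumeration and a double loop over ordered neighbour pairs.
oracle_clustering <- function(network, node_id) {
  e <- network$edges
  nb <- unique(c(e$to[e$from == node_id], e$from[e$to == node_id]))
  nb <- nb[nb != node_id]
  k <- length(nb)
  if (k < 2) return(NA_real_)
  links <- 0L
  for (a in nb) for (b in nb) {
    if (a != b && any(e$from == a & e$to == b)) links <- links + 1L
  }
  links / (k * (k - 1))
}

## Hand-rolled BFS shortest path length over the directed edge list.
oracle_bfs <- function(network, from_id, to_id) {
  if (from_id == to_id) {
    e <- network$edges
    return(if (any(e$from == from_id & e$to == to_id)) 1 else Inf)
  }
  e <- network$edges
  dist <- setNames(rep(Inf, nrow(network$nodes)), network$nodes$id)
  dist[as.character(from_id)] <- 0
  frontier <- from_id
  d <- 0
  while (length(frontier)) {
    d <- d + 1
    nxt <- unique(e$to[e$from %in% frontier])
    nxt <- nxt[is.infinite(dist[as.character(nxt)])]
    if (!length(nxt)) break
    dist[as.character(nxt)] <- d
    if (to_id %in% nxt) return(d)
    frontier <- nxt
  }
  unname(dist[as.character(to_id)])
}

## Hand-assembled regulatory_network for metric tests (bypasses the
## builder entirely).
manual_network <- function(kinds, from, to,
                           sign = rep("activation", length(from))) {
  n <- length(kinds)
  nodes <- data.frame(id = seq_len(n),
                      name = paste0(ifelse(kinds == "mirna", "mir",
                                    ifelse(kinds == "signal", "s", "g")),
                                    seq_len(n)),
                      kind = kinds)
  edges <- data.frame(from = as.integer(from), to = as.integer(to),
                      sign = sign,
                      theta = rep(0.5, length(from)),
                      mu = rep(4, length(from)),
                      interaction = NA_character_)
  structure(list(nodes = nodes, edges = edges, provenance = list(),
                 config = network_config(max(1, sum(kinds == "gene")),
                                         sum(kinds == "mirna"),
                                         sum(kinds == "signal"))),
            class = "regulatory_network")
}

## Audit of a production tree: every regulator leaf with the role it
## plays ("hill" activating leaf, "inh" leaf, "comp_rep" repressor arm).
tree_roles <- function(tree) {
  switch(tree$op,
    const = data.frame(regulator = character(), role = character()),
    hill = data.frame(regulator = tree$regulator, role = "hill"),
    inh = data.frame(regulator = tree$regulator, role = "inh"),
    comp = rbind(tree_roles(tree$args[[1]]),
                 data.frame(regulator = tree$regulator, role = "comp_rep")),
    rbind(tree_roles(tree$args[[1]]), tree_roles(tree$args[[2]])))
}
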