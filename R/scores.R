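## Score-guided growth: each candidate (node i, motif slot j) pair gets a
## sub-score measuring whether granting node i the connections of slot j
## moves the current degree distribution toward its target. Summed per
## degree bin k:
##
##   S_ijk = sign(|d_k - p_k| - |d_k - f_kij|) * |d_k - p_k| / d_k
##
## where d_k is the target fraction for degree k, p_k the current
## fraction and f_kij the fraction after the hypothetical assignment.
## Only the bins the move actually changes contribute (elsewhere
## f_kij = p_k and the sign factor is 0), which makes scoring O(1) per
## candidate once the two per-bin "leave" and "enter" term tables are
## computed.

## One bin's term for a fraction change p -> f against target d.
## Bins with zero target fraction are skipped (normalizer undefined).
score_bin_term <- function(d, p, f) {
  if (is.na(d) || d <= 0) return(0)
  sign(abs(d - p) - abs(d - f)) * abs(d - p) / d
}

## Term tables over bins 1..k_max for a single node leaving (count-1) or
## entering (count+1) each bin; denominators are the population size n.
## leave[k] is 0-padded so that degree-0 lookups contribute nothing.
score_term_tables <- function(counts, n, d) {
  k_max <- length(d)
  counts <- counts[seq_len(k_max)]
  counts[is.na(counts)] <- 0L
  p <- counts / n
  valid <- d > 0
  dd <- abs(d - p)
  leave <- ifelse(valid, sign(dd - abs(d - (p - 1 / n))) * dd / d, 0)
  enter <- ifelse(valid, sign(dd - abs(d - (p + 1 / n))) * dd / d, 0)
  list(leave = c(0, leave), enter = c(0, enter), k_max = k_max)
}

## Score for moving a node from degree k_old to degree k_new using term
## tables (vectorized over nodes). Degrees beyond k_max fall outside the
## summation range and contribute nothing.
move_score <- function(tab, k_old, k_new) {
  lo <- ifelse(k_old >= 1L & k_old <= tab$k_max, tab$leave[pmin(k_old, tab$k_max) + 1L], 0)
  hi <- ifelse(k_new >= 1L & k_new <= tab$k_max, tab$enter[pmin(k_new, tab$k_max) + 1L], 0)
  ifelse(k_old == k_new, 0, lo + hi)
}

#' Current degree-distribution state of a network
#'
#' Recomputes, from the network alone, the degree-fraction vectors the
#' construction score compares against its targets: \code{p} — fraction
#' of non-signal nodes with total degree k; \code{p_in}, \code{p_out} —
#' fractions of miRNA nodes with in-/out-degree k. Edges incident to
#' signalling nodes are excluded (they are appended after growth).
#'
#' @param network a \code{regulatory_network}.
#' @return list with per-node degree vectors (\code{deg}, \code{indeg},
#'   \code{outdeg}, named by node), fraction vectors \code{p},
#'   \code{p_in}, \code{p_out} over degrees 1..k_max, and the population
#'   sizes \code{n_nodes} (genes+miRNAs) and \code{n_mirnas}.
#' @export
degree_state <- function(network) {
  stopifnot(inherits(network, "regulatory_network"))
  nodes <- network$nodes
  ns <- nodes$id[nodes$kind != "signal"]
  k_max <- length(ns)
  e <- network$edges
  keep <- e$from %in% ns & e$to %in% ns
  ef <- e$from[keep]; et <- e$to[keep]
  nmax <- max(nodes$id)
  indeg <- tabulate(et, nmax)[ns]
  outdeg <- tabulate(ef, nmax)[ns]
  deg <- indeg + outdeg
  names(deg) <- names(indeg) <- names(outdeg) <- nodes$name[match(ns, nodes$id)]
  mir <- nodes$kind[match(ns, nodes$id)] == "mirna"
  m <- sum(mir)
  p <- tabulate(deg[deg > 0], k_max) / k_max
  p_in <- if (m > 0) tabulate(indeg[mir][indeg[mir] > 0], k_max) / m else numeric(k_max)
  p_out <- if (m > 0) tabulate(outdeg[mir][outdeg[mir] > 0], k_max) / m else numeric(k_max)
  list(ids = ns, deg = deg, indeg = indeg, outdeg = outdeg,
       p = p, p_in = p_in, p_out = p_out,
       n_nodes = k_max, n_mirnas = m, mirna = mir)
}

#' Gene sub-score for a candidate slot assignment
#'
#' Scores the hypothetical assignment of a motif slot's connections
#' (total-degree increment \code{delta}) to gene node \code{node}:
#' positive when the move brings the total-degree distribution closer to
#' its power-law target, negative when it moves it away. Terms are
#' summed over degree bins 1..k_max; bins with zero target fraction are
#' skipped.
#'
#' @param state a degree state from \code{\link{degree_state}}.
#' @param targets a \code{\link{sample_degree_targets}} object.
#' @param node node name or index into \code{state$deg}.
#' @param delta total-degree increment implied by the slot (>= 0).
#' @return scalar score.
#' @export
gene_subscore <- function(state, targets, node, delta) {
  tab <- score_term_tables(state$p * state$n_nodes, state$n_nodes, targets$d_p)
  k_old <- unname(state$deg[node])
  move_score(tab, k_old, k_old + delta)
}

#' miRNA sub-score for a candidate slot assignment
#'
#' As \code{\link{gene_subscore}} but with separate in/out accounting:
#' the miRNA in-degree distribution is chased against the power-law
#' target \code{d_p} and the out-degree distribution against the
#' exponential target \code{d_e}.
#'
#' @inheritParams gene_subscore
#' @param delta_in,delta_out in-/out-degree increments implied by the slot.
#' @return scalar score (in-term plus out-term).
#' @export
mirna_subscore <- function(state, targets, node, delta_in, delta_out) {
  m <- state$n_mirnas
  if (m == 0L) return(0)
  tab_in <- score_term_tables(state$p_in * m, m, targets$d_p)
  tab_out <- score_term_tables(state$p_out * m, m, targets$d_e)
  ki <- unname(state$indeg[node]); ko <- unname(state$outdeg[node])
  move_score(tab_in, ki, ki + delta_in) + move_score(tab_out, ko, ko + delta_out)
}

#' Score a motif template against the current network state
#'
#' The motif score is the sum of sub-scores over the cross product of
#' available candidate nodes and the template's slots of matching kind:
#' gene slots accumulate \code{\link{gene_subscore}} over candidate
#' genes, miRNA slots accumulate \code{\link{mirna_subscore}} over
#' candidate miRNAs.
#'
#' @param template a \code{motif_template}.
#' @param state degree state (see \code{\link{degree_state}}).
#' @param targets degree targets.
#' @param gene_candidates,mirna_candidates indices (into
#'   \code{state$deg}) of nodes still available for wiring; default all.
#' @return scalar score.
#' @export
motif_score <- function(template, state, targets,
                        gene_candidates = NULL, mirna_candidates = NULL) {
  if (is.null(gene_candidates))
    gene_candidates <- which(!state$mirna)
  if (is.null(mirna_candidates))
    mirna_candidates <- which(state$mirna)
  dl <- slot_degree_deltas(template)
  tab_g <- score_term_tables(state$p * state$n_nodes, state$n_nodes, targets$d_p)
  s <- 0
  for (r in which(dl$kind == "gene")) {
    if (!length(gene_candidates)) break
    k_old <- unname(state$deg[gene_candidates])
    s <- s + sum(move_score(tab_g, k_old, k_old + dl$d_tot[r]))
  }
  m <- state$n_mirnas
  if (m > 0L && length(mirna_candidates)) {
    tab_in <- score_term_tables(state$p_in * m, m, targets$d_p)
    tab_out <- score_term_tables(state$p_out * m, m, targets$d_e)
    for (r in which(dl$kind == "mirna")) {
      ki <- unname(state$indeg[mirna_candidates])
      ko <- unname(state$outdeg[mirna_candidates])
      s <- s + sum(move_score(tab_in, ki, ki + dl$d_in[r])) +
        sum(move_score(tab_out, ko, ko + dl$d_out[r]))
    }
  }
  s
}

## Proportional sampling over possibly-negative scores: when the pool
## contains negative values it is shifted by -min so all weights are
## non-negative; eps keeps them strictly positive. Non-negative pools
## are used as-is (so scores (3, 1) sample at 3/4 vs 1/4), and an
## all-equal pool (including all-zero) becomes uniform.
shift_weights <- function(scores, eps = 1e-6) {
  scores + max(0, -min(scores)) + eps
}

#' Select a motif from a scored pool
#'
#' Samples one pool index with probability proportional to the shifted
#' scores (negative pools are shifted up by their minimum, so negative
#' scores are admissible and an all-equal pool is sampled uniformly).
#'
#' @param scores numeric vector of motif scores (non-empty).
#' @return the selected index.
#' @export
select_motif <- function(scores) {
  if (!length(scores)) stop("empty motif pool")
  w <- shift_weights(scores)
  sample.int(length(scores), 1L, prob = w)
}
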