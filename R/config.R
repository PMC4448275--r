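#' Network construction configuration
#'
#' Bundles the sizes and distributional parameters that drive network
#' growth: node counts per molecular layer, the power-law exponent chased
#' by the gene degree distribution, the exponential rate chased by the
#' miRNA out-degree distribution, and the motif pool size per iteration.
#'
#' @param n_genes number of gene nodes (>= 1).
#' @param n_mirnas number of miRNA nodes (>= 0).
#' @param n_signals number of exogenous signalling nodes appended after
#'   construction (>= 0). Signalling nodes only have outgoing edges.
#' @param alpha power-law scale exponent for the target degree
#'   distribution \eqn{P(k) \propto k^{-\alpha}}; transcriptional networks
#'   typically show \eqn{2 < \alpha < 3}.
#' @param lambda rate of the exponential law targeted by miRNA
#'   out-degrees (> 0); larger values concentrate miRNA regulation on few
#'   targets.
#' @param pool_size number of random motif instances scored per growth
#'   iteration (>= 1).
#' @param seed integer random seed controlling the whole construction.
#' @return an object of class \code{network_config}.
#' @examples
#' cfg <- network_config(n_genes = 50, n_mirnas = 5, alpha = 2.2)
#' @export
network_config <- function(n_genes, n_mirnas = 0L, n_signals = 0L,
                           alpha = 2.2, lambda = 0.5, pool_size = 10L,
                           seed = 1L) {
  n_genes <- as.integer(n_genes)
  n_mirnas <- as.integer(n_mirnas)
  n_signals <- as.integer(n_signals)
  if (is.na(n_genes) || n_genes < 1L) stop("n_genes must be >= 1")
  if (is.na(n_mirnas) || n_mirnas < 0L) stop("n_mirnas must be >= 0")
  if (is.na(n_signals) || n_signals < 0L) stop("n_signals must be >= 0")
  if (!is.numeric(alpha) || alpha <= 0) stop("alpha must be > 0")
  if (!is.numeric(lambda) || lambda <= 0) stop("lambda must be > 0")
  pool_size <- as.integer(pool_size)
  if (is.na(pool_size) || pool_size < 1L) stop("pool_size must be >= 1")
  structure(
    list(n_genes = n_genes, n_mirnas = n_mirnas, n_signals = n_signals,
         alpha = alpha, lambda = lambda, pool_size = pool_size,
         seed = as.integer(seed)),
    class = "network_config")
}

#' @export
print.network_config <- function(x, ...) {
  cat("network_config:", x$n_genes, "genes,", x$n_mirnas, "miRNAs,",
      x$n_signals, "signals | alpha =", x$alpha, "lambda =", x$lambda,
      "| pool =", x$pool_size, "seed =", x$seed, "\n")
  invisible(x)
}

#' Target degree-fraction vectors
#'
#' Computes the normalized degree-fraction targets the construction score
#' chases: \code{d_p[k]} proportional to \eqn{k^{-\alpha}} (the fraction
#' of nodes that should end with total degree k, and the fraction of
#' miRNAs with in-degree k), and \code{d_e[k]} proportional to
#' \eqn{e^{-\lambda k}} (the fraction of miRNAs that should end with
#' out-degree k). Both vectors run over degrees 1..k_max where k_max is
#' the total gene+miRNA node count.
#'
#' @param config a \code{\link{network_config}}.
#' @return object of class \code{degree_targets} with fields \code{d_p},
#'   \code{d_e}, \code{k_max}.
#' @examples
#' tg <- sample_degree_targets(network_config(10, 2))
#' sum(tg$d_p) # 1
#' @export
sample_degree_targets <- function(config) {
  stopifnot(inherits(config, "network_config"))
  k_max <- config$n_genes + config$n_mirnas
  k <- seq_len(k_max)
  d_p <- k^(-config$alpha)
  d_p <- d_p / sum(d_p)
  d_e <- exp(-config$lambda * k)
  d_e <- d_e / sum(d_e)
  structure(list(d_p = d_p, d_e = d_e, k_max = k_max),
            class = "degree_targets")
}
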