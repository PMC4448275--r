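#' Clustering coefficient (directed convention)
#'
#' For a node with k distinct neighbours (union of in- and
#' out-neighbours, self excluded) and n directed edges among those
#' neighbours, \code{C = n / (k * (k - 1))}. Undefined (NA) for k < 2.
#'
#' @param network a \code{regulatory_network}.
#' @param node node name (or id); NULL computes all nodes.
#' @return named numeric vector of coefficients in [0, 1] (NA where
#'   undefined).
#' @export
clustering_coefficient <- function(network, node = NULL) {
  stopifnot(inherits(network, "regulatory_network"))
  nodes <- network$nodes
  e <- network$edges
  out_nb <- split(e$to, factor(e$from, levels = nodes$id))
  in_nb <- split(e$from, factor(e$to, levels = nodes$id))
  ekey <- paste0(e$from, "|", e$to)
  ids <- if (is.null(node)) nodes$id else {
    if (is.character(node)) nodes$id[match(node, nodes$name)] else node
  }
  if (any(is.na(ids)) || !all(ids %in% nodes$id)) stop("unknown node")
  cc <- vapply(ids, function(v) {
    nb <- setdiff(unique(c(out_nb[[as.character(v)]],
                           in_nb[[as.character(v)]])), v)
    k <- length(nb)
    if (k < 2L) return(NA_real_)
    pairs <- expand.grid(from = nb, to = nb)
    pairs <- pairs[pairs$from != pairs$to, ]
    n_links <- sum(paste0(pairs$from, "|", pairs$to) %in% ekey)
    n_links / (k * (k - 1))
  }, numeric(1))
  names(cc) <- nodes$name[match(ids, nodes$id)]
  cc
}

#' Log-log power-law line fit
#'
#' Fits a straight line to (log k, log frequency) over non-empty degree
#' bins by ordinary least squares and returns the slope magnitude (the
#' estimated scale exponent) and the coefficient of determination. Pass
#' either raw samples (degrees) or a pre-binned (k, count/value) pair —
#' the latter also fits mean-C(k) curves.
#'
#' @param samples numeric vector of raw samples (e.g., node degrees);
#'   binned by \code{table}. Ignored when \code{k} is given.
#' @param k,value pre-binned curve: bin positions and their
#'   counts/values. Zero or negative entries are dropped before the log
#'   transform.
#' @return list with \code{exponent} (slope magnitude), \code{slope}
#'   (signed), \code{r_squared}, \code{n_bins}, and the \code{lm} fit.
#' @examples
#' k <- 1:50
#' fit_power_law(k = k, value = k^-2.2)$exponent # 2.2 exactly
#' @export
fit_power_law <- function(samples = NULL, k = NULL, value = NULL) {
  if (is.null(k)) {
    if (is.null(samples)) stop("provide samples or (k, value)")
    tab <- table(samples[samples > 0])
    k <- as.numeric(names(tab))
    value <- as.numeric(tab)
  }
  keep <- k > 0 & value > 0 & is.finite(k) & is.finite(value)
  k <- k[keep]; value <- value[keep]
  if (length(unique(k)) < 2L)
    stop("degenerate input: need at least two non-empty bins")
  value <- value / sum(value)
  fit <- lm(log(value) ~ log(k))
  sl <- unname(coef(fit)[2])
  y <- log(value)
  r2 <- 1 - sum(residuals(fit)^2) / sum((y - mean(y))^2)
  list(exponent = abs(sl), slope = sl, r_squared = r2,
       n_bins = length(k), fit = fit)
}

#' C(k) scaling exponent of one network
#'
#' Mean clustering coefficient per degree bin, fitted in log-log space.
#' The binning variable is the same k that enters the coefficient's
#' definition — the number of distinct neighbours. Returns NA when
#' fewer than two usable bins exist (tiny or triangle-free networks).
#'
#' @param network a \code{regulatory_network}.
#' @return list with \code{exponent} (slope magnitude, NA if
#'   undefined), \code{r_squared}, and the binned \code{curve}.
#' @export
clustering_exponent <- function(network) {
  cc <- clustering_coefficient(network)
  nodes <- network$nodes
  e <- network$edges
  nb_count <- vapply(nodes$id, function(v) {
    nb <- unique(c(e$to[e$from == v], e$from[e$to == v]))
    length(setdiff(nb, v))
  }, integer(1))
  deg <- setNames(nb_count, nodes$name)[names(cc)]
  # zero-C nodes stay in the bin means; only bins whose mean is zero
  # are dropped before the log transform
  ok <- !is.na(cc) & deg > 0
  if (sum(ok) < 2L)
    return(list(exponent = NA_real_, r_squared = NA_real_, curve = NULL))
  mean_c <- tapply(cc[ok], deg[ok], mean)
  kk <- as.numeric(names(mean_c))
  curve <- data.frame(k = kk, c = as.numeric(mean_c))
  if (sum(curve$c > 0) < 2L || length(unique(kk[curve$c > 0])) < 2L)
    return(list(exponent = NA_real_, r_squared = NA_real_, curve = curve))
  f <- fit_power_law(k = curve$k, value = curve$c)
  list(exponent = f$exponent, r_squared = f$r_squared, curve = curve)
}

#' Scale invariance of the clustering coefficient
#'
#' Generates networks of random sizes, fits each network's C(k) scaling
#' exponent, and regresses the exponent on network size. In a
#' hierarchically modular generator the exponent should not depend on
#' size: the regression slope's confidence interval should cover 0, and
#' the exponents should sit near magnitude 1.
#'
#' @param n_networks number of networks to generate.
#' @param size_range total node count range (sizes sampled uniformly).
#' @param alpha,lambda,pool_size construction parameters.
#' @param mirna_frac fraction of nodes that are miRNAs.
#' @param seed root seed.
#' @return list with \code{table} (size, exponent per network),
#'   \code{slope}, \code{ci} (95\% CI for the size effect),
#'   \code{mean_exponent}, and the \code{lm} fit. Errors if all sizes
#'   are identical (regression undefined).
#' @export
clustering_scale_invariance <- function(n_networks = 30,
                                        size_range = c(10, 500),
                                        alpha = 2.2, lambda = 0.5,
                                        pool_size = 10, mirna_frac = 0.1,
                                        seed = 1L) {
  set.seed(seed)
  sz <- seq(size_range[1], size_range[2])
  sizes <- sz[sample.int(length(sz), n_networks, replace = TRUE)]
  seeds <- sample.int(.Machine$integer.max, n_networks)
  expo <- vapply(seq_len(n_networks), function(i) {
    m <- round(mirna_frac * sizes[i])
    cfg <- network_config(sizes[i] - m, m, 0, alpha = alpha,
                          lambda = lambda, pool_size = pool_size,
                          seed = seeds[i])
    clustering_exponent(build_network(cfg))$exponent
  }, numeric(1))
  tab <- data.frame(size = sizes, exponent = expo)
  ok <- !is.na(expo)
  if (length(unique(sizes[ok])) < 2L)
    stop("size regression undefined: all usable networks share one size")
  fit <- lm(exponent ~ size, data = tab[ok, ])
  ci <- confint(fit)["size", ]
  list(table = tab, slope = unname(coef(fit)["size"]), ci = ci,
       mean_exponent = mean(expo[ok]), fit = fit)
}

#' Path-length profile of candidate interactions
#'
#' Scores a candidate interaction list against the ground-truth network
#' by directed shortest-path length: length 1 is a direct interaction,
#' length > 1 an indirect one, and Inf no interaction (target
#' unreachable from source).
#'
#' @param network a \code{regulatory_network}.
#' @param candidates two-column matrix or data frame of (source, target)
#'   node names. A self-pair (a, a) counts as direct (length 1) when the
#'   network carries the self-edge, and as absent (Inf) otherwise.
#' @return named table of counts over observed path lengths
#'   (\code{"1"}, \code{"2"}, ..., \code{"Inf"}); total equals the
#'   number of candidate pairs.
#' @export
path_length_profile <- function(network, candidates) {
  stopifnot(inherits(network, "regulatory_network"))
  candidates <- as.matrix(candidates)
  if (ncol(candidates) != 2L) stop("candidates must have two columns")
  g <- as_igraph(network)
  src <- unique(candidates[, 1])
  d <- igraph::distances(g, v = src, mode = "out")
  len <- d[cbind(match(candidates[, 1], src),
                 match(candidates[, 2], colnames(d)))]
  self <- candidates[, 1] == candidates[, 2]
  if (any(self)) {
    nm <- network$nodes$name
    self_edges <- paste0(nm[match(network$edges$from, network$nodes$id)],
                         "|", nm[match(network$edges$to, network$nodes$id)])
    len[self] <- ifelse(paste0(candidates[self, 1], "|",
                               candidates[self, 2]) %in% self_edges, 1, Inf)
  }
  table(factor(len, levels = unique(sort(len))))
}
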