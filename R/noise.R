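#' Noise configuration
#'
#' Parameters of the two-level variability model: biological
#' variability as multiplicative-relative white-noise jitter of every
#' model parameter per subject, and technical variability as the
#' two-component measurement-error model
#' \deqn{y = c + x e^{\eta} + \epsilon,\quad
#'   \epsilon \sim N(0, \sigma_\epsilon),\ \eta \sim N(0, \sigma_\eta)}
#' whose additive term dominates at low expression and whose
#' multiplicative term dominates at high expression.
#'
#' @param sigma_bio relative standard deviation of the per-subject
#'   parameter jitter (dimensionless, >= 0).
#' @param c constant mean background level (intensity units, >= 0).
#' @param sigma_eps standard deviation of the additive error (>= 0).
#' @param sigma_eta standard deviation of the multiplicative log-error
#'   (>= 0).
#' @return object of class \code{noise_config}.
#' @export
noise_config <- function(sigma_bio = 0.05, c = 0, sigma_eps = 0.05,
                         sigma_eta = 0.1) {
  vals <- c(sigma_bio = sigma_bio, c = c, sigma_eps = sigma_eps,
            sigma_eta = sigma_eta)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("noise parameters must be finite and >= 0")
  structure(as.list(vals), class = "noise_config")
}

## Multiplicative-relative jitter factor, truncated to keep parameters
## positive.
jitter_factor <- function(n, sigma) pmax(1 + rnorm(n, 0, sigma), 1e-6)

jitter_tree <- function(tree, sigma) {
  if (!is.null(tree$theta)) {
    tree$theta <- tree$theta * jitter_factor(1L, sigma)
    tree$mu <- tree$mu * jitter_factor(1L, sigma)
  }
  if (!is.null(tree$args))
    tree$args <- lapply(tree$args, jitter_tree, sigma = sigma)
  tree
}

#' Per-subject biological parameter jitter
#'
#' Returns a copy of the system model in which every kinetic and Hill
#' parameter has been multiplied by an independent factor
#' \eqn{1 + \zeta}, \eqn{\zeta \sim N(0, \sigma_{bio})}, truncated below
#' at \eqn{10^{-6}} so positivity invariants hold. The original model is
#' untouched; \code{sigma_bio = 0} returns the model unchanged.
#'
#' @param model a \code{system_model}.
#' @param config a \code{\link{noise_config}}.
#' @return a jittered \code{system_model}.
#' @export
jitter_parameters <- function(model, config) {
  stopifnot(inherits(model, "system_model"), inherits(config, "noise_config"))
  s <- config$sigma_bio
  if (s == 0) return(model)
  model$models <- lapply(model$models, function(m) {
    m$production <- jitter_tree(m$production, s)
    q <- nrow(m$mirna_regs)
    if (q) {
      m$mirna_regs$theta <- m$mirna_regs$theta * jitter_factor(q, s)
      m$mirna_regs$mu <- m$mirna_regs$mu * jitter_factor(q, s)
    }
    m$kinetic$p <- m$kinetic$p * jitter_factor(1L, s)
    m$kinetic$d0 <- m$kinetic$d0 * jitter_factor(1L, s)
    m$kinetic$di <- m$kinetic$di * jitter_factor(1L, s)
    m
  })
  model
}

#' Apply the two-component measurement-error model
#'
#' Element-wise observed intensity \code{y = c + x * exp(eta) + eps}
#' with independent draws per element. Observed intensities may be
#' negative (the additive error is Gaussian); no clipping is applied.
#'
#' @param x true expression vector (or matrix).
#' @param config a \code{\link{noise_config}}.
#' @return observed intensities, same shape as \code{x}.
#' @export
measure_expression <- function(x, config) {
  stopifnot(inherits(config, "noise_config"))
  n <- length(x)
  eta <- rnorm(n, 0, config$sigma_eta)
  eps <- rnorm(n, 0, config$sigma_eps)
  y <- config$c + x * exp(eta) + eps
  attributes(y) <- attributes(x)
  y
}

## Matrix wrapper used by generate_dataset (keeps dimnames).
apply_measurement <- function(mat, config) {
  if (!length(mat)) return(mat)
  measure_expression(mat, config)
}
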