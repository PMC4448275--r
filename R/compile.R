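## Compilation of a system_model into flat arrays evaluated by the C++
## stack machine (src/rhs.cpp). The compiled form is a pure function of
## the model: recompiling after parameter jitter is cheap, and the
## compiled evaluator is checked against the R reference path
## (node_derivative) in the test suite.

#' Compile a system model for fast integration
#'
#' Lowers every node's regulation tree to a postfix program over a
#' shared table of Hill terms, producing the flat arrays consumed by the
#' compiled right-hand-side evaluator. Users normally do not call this
#' directly; \code{\link{integrate_system}} compiles on the fly.
#'
#' @param model a \code{system_model}.
#' @return object of class \code{compiled_system}.
#' @export
compile_system <- function(model) {
  stopifnot(inherits(model, "system_model"))
  state_names <- model$nodes$name
  signal_names <- model$signals
  idx <- setNames(seq_along(c(state_names, signal_names)) - 1L,
                  c(state_names, signal_names))
  n_state <- length(state_names)

  hsrc <- integer(); htheta <- numeric(); hmu <- numeric()
  add_term <- function(regulator, theta, mu) {
    src <- idx[[regulator]]
    if (is.null(src)) stop("regulator not in state/signals: ", regulator)
    hsrc[length(hsrc) + 1L] <<- src
    htheta[length(htheta) + 1L] <<- theta
    hmu[length(hmu) + 1L] <<- mu
    length(hsrc) - 1L   # 0-based term index
  }

  ops <- integer(); args <- integer()
  emit <- function(op, arg = 0L) {
    ops[length(ops) + 1L] <<- op
    args[length(args) + 1L] <<- arg
  }
  emit_tree <- function(tree) {
    switch(tree$op,
      const = emit(3L),
      hill = emit(1L, add_term(tree$regulator, tree$theta, tree$mu)),
      inh = emit(2L, add_term(tree$regulator, tree$theta, tree$mu)),
      coop = { emit_tree(tree$args[[1]]); emit_tree(tree$args[[2]]); emit(4L) },
      syn = { emit_tree(tree$args[[1]]); emit_tree(tree$args[[2]]); emit(5L) },
      comp = { emit_tree(tree$args[[1]])
               emit(1L, add_term(tree$regulator, tree$theta, tree$mu))
               emit(6L) },
      stop("unknown tree op: ", tree$op))
  }

  prog_ptr <- integer(n_state + 1L)
  mir_ptr <- integer(n_state + 1L)
  mir_idx <- integer()
  p <- d0 <- di <- numeric(n_state)
  for (i in seq_len(n_state)) {
    m <- model$models[[state_names[i]]]
    prog_ptr[i] <- length(ops)
    mir_ptr[i] <- length(mir_idx)
    emit_tree(m$production)
    if (m$kind != "mirna" && nrow(m$mirna_regs)) {
      for (r in seq_len(nrow(m$mirna_regs)))
        mir_idx[length(mir_idx) + 1L] <-
          add_term(m$mirna_regs$regulator[r], m$mirna_regs$theta[r],
                   m$mirna_regs$mu[r])
    }
    p[i] <- m$kinetic$p
    d0[i] <- m$kinetic$d0
    di[i] <- m$kinetic$di
  }
  prog_ptr[n_state + 1L] <- length(ops)
  mir_ptr[n_state + 1L] <- length(mir_idx)

  structure(list(state_names = state_names, signal_names = signal_names,
                 hsrc = hsrc, htheta = htheta, hmu = hmu,
                 ops = ops, args = args, prog_ptr = prog_ptr,
                 mir_ptr = mir_ptr, mir_idx = mir_idx,
                 p = p, d0 = d0, di = di, n_state = n_state),
            class = "compiled_system")
}

## Derivatives through the compiled path; xext = c(state, signal values)
## in compiled order.
compiled_derivatives <- function(cs, state, signal_values = NULL) {
  xext <- c(as.numeric(state), as.numeric(signal_values))
  rhs_eval_cpp(xext, cs$hsrc, cs$htheta, cs$hmu, cs$ops, cs$args,
               cs$prog_ptr, cs$mir_ptr, cs$mir_idx, cs$p, cs$d0, cs$di,
               cs$n_state)
}
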