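#' Integrate the regulatory ODE system
#'
#' Solves the coupled gene/miRNA concentration ODEs over a time grid
#' with an adaptive stiff-capable solver (\code{deSolve}, lsoda by
#' default; on failure the integration is retried with the implicit BDF
#' method before erroring with diagnostics). Signal nodes are exogenous
#' inputs evaluated from their programs at every solver step. Tiny
#' negative excursions produced by the solver are clipped to 0 in the
#' returned trajectory.
#'
#' @param model a \code{system_model} (or precompiled
#'   \code{compiled_system} via the \code{compiled} argument).
#' @param initial_state non-negative numeric: either one value recycled
#'   over nodes or a full named state vector in model node order.
#' @param signals signal programs (see \code{\link{signal_programs}}):
#'   NULL (all zero), one program for all signals, or a named list.
#' @param times output time grid (default 100 points over [0, 50]).
#' @param rtol,atol solver tolerances.
#' @param method primary solver method.
#' @param compiled optional precompiled system (skips compilation).
#' @return object of class \code{trajectory}: \code{time}, \code{states}
#'   (time x nodes matrix, columns named by node), \code{signals} (the
#'   resolved programs).
#' @examples
#' net <- build_network(network_config(10, 2, 1, seed = 7))
#' set.seed(7); mod <- build_system_model(net)
#' tr <- integrate_system(mod, 0.1, signal_constant(1))
#' dim(tr$states)
#' @export
integrate_system <- function(model, initial_state = 0.1, signals = NULL,
                             times = seq(0, 50, length.out = 100),
                             rtol = 1e-6, atol = 1e-8, method = "lsoda",
                             compiled = NULL) {
  cs <- if (!is.null(compiled)) compiled else compile_system(model)
  n <- cs$n_state
  y0 <- if (length(initial_state) == 1L) rep(initial_state, n)
        else as.numeric(initial_state[cs$state_names])
  if (length(y0) != n || any(!is.finite(y0)) || any(y0 < 0))
    stop("initial_state must be non-negative with one value per node")
  programs <- resolve_signal_programs(cs$signal_names, signals)
  func <- function(t, y, parms) {
    xext <- c(pmax(y, 0), signal_values_at(programs, t))
    list(rhs_eval_cpp(xext, cs$hsrc, cs$htheta, cs$hmu, cs$ops, cs$args,
                      cs$prog_ptr, cs$mir_ptr, cs$mir_idx,
                      cs$p, cs$d0, cs$di, n))
  }
  run <- function(meth) deSolve::ode(y = y0, times = times, func = func,
                                     parms = NULL, method = meth,
                                     rtol = rtol, atol = atol)
  out <- tryCatch(run(method), error = function(e) e, warning = function(w) w)
  if (inherits(out, "condition") ||
      !is.matrix(out) || nrow(out) < length(times) || any(!is.finite(out))) {
    out2 <- tryCatch(run("bdf"), error = function(e) e)
    if (inherits(out2, "condition") || nrow(out2) < length(times) ||
        any(!is.finite(out2)))
      stop("ODE integration failed (", method, " and bdf): ",
           if (inherits(out, "condition")) conditionMessage(out) else
             "non-finite or truncated solution")
    out <- out2
  }
  states <- pmax(unclass(out)[, -1L, drop = FALSE], 0)
  colnames(states) <- cs$state_names
  structure(list(time = times, states = states, signals = programs),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory:", length(x$time), "time points x", ncol(x$states),
      "nodes over [", min(x$time), ",", max(x$time), "]\n")
  invisible(x)
}

#' Steady-state expression sample from a trajectory
#'
#' Takes the expression values at the last simulated time point — the
#' convention standing in for a one-shot (e.g., microarray) measurement
#' — and splits them into the genes view and the miRNAs view.
#'
#' @param traj a \code{trajectory}.
#' @param model the \code{system_model} it was integrated from (for node
#'   kinds); if omitted, nodes named \code{mir*} form the miRNA view.
#' @return list with named vectors \code{genes} and \code{mirnas}.
#' @export
steady_state_sample <- function(traj, model = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  last <- traj$states[nrow(traj$states), ]
  is_mir <- if (!is.null(model)) {
    model$nodes$kind[match(names(last), model$nodes$name)] == "mirna"
  } else grepl("^mir", names(last))
  list(genes = last[!is_mir], mirnas = last[is_mir])
}

#' Simulation condition
#'
#' One experimental condition: a label, a number of subjects, and the
#' signal programs active while those subjects are simulated.
#'
#' @param name condition label.
#' @param n_subjects number of subjects (>= 0).
#' @param signals signal programs (NULL, one program, or named list; see
#'   \code{\link{integrate_system}}).
#' @return object of class \code{sim_condition}.
#' @export
sim_condition <- function(name, n_subjects, signals = NULL) {
  n_subjects <- as.integer(n_subjects)
  if (is.na(n_subjects) || n_subjects < 0L) stop("n_subjects must be >= 0")
  structure(list(name = as.character(name), n_subjects = n_subjects,
                 signals = signals), class = "sim_condition")
}

#' Generate a multi-view expression dataset
#'
#' For every subject of every condition: jitter the model parameters
#' (biological variability), integrate the ODE system under the
#' condition's signal programs, take the last time point as the
#' subject's true expression, and apply the two-component measurement
#' error. Returns parallel feature-by-subject matrices for the genes
#' view and the miRNAs view, plus the noiseless matrices and the full
#' ground truth.
#'
#' @param network a \code{regulatory_network}.
#' @param conditions list of \code{\link{sim_condition}}s.
#' @param noise a \code{\link{noise_config}}.
#' @param seed integer seed for the whole dataset (model sampling when
#'   \code{model} is NULL, jitter, measurement error).
#' @param model optional prebuilt \code{system_model}; built (seeded)
#'   from the network otherwise.
#' @param times simulation time grid.
#' @param initial_state initial concentrations (see
#'   \code{\link{integrate_system}}).
#' @param ranges \code{\link{dynamics_ranges}} used if the model is
#'   built here.
#' @return object of class \code{expression_dataset}: matrices
#'   \code{genes}, \code{mirnas}, \code{genes_true}, \code{mirnas_true}
#'   (features x subjects), factor \code{labels}, \code{conditions}
#'   (resolved signal programs per condition), \code{network},
#'   \code{model}, \code{seed}.
#' @examples
#' net <- build_network(network_config(12, 3, 2, seed = 3))
#' ds <- generate_dataset(net,
#'   list(sim_condition("ctrl", 2, signal_constant(0)),
#'        sim_condition("stim", 2, signal_constant(1))),
#'   noise = noise_config(), seed = 3,
#'   times = seq(0, 50, length.out = 25))
#' dim(ds$genes)
#' @export
generate_dataset <- function(network, conditions, noise = noise_config(),
                             seed = 1L, model = NULL,
                             times = seq(0, 50, length.out = 100),
                             initial_state = 0.1,
                             ranges = dynamics_ranges()) {
  stopifnot(inherits(network, "regulatory_network"))
  if (inherits(conditions, "sim_condition")) conditions <- list(conditions)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(model)) model <- build_system_model(network, ranges)
  state_names <- model$nodes$name
  is_mir <- model$nodes$kind == "mirna"
  gene_names <- state_names[!is_mir]
  mir_names <- state_names[is_mir]

  cols_true_g <- list(); cols_true_m <- list()
  labels <- character(); subject_ids <- character()
  resolved <- list()
  for (cond in conditions) {
    stopifnot(inherits(cond, "sim_condition"))
    programs <- resolve_signal_programs(model$signals, cond$signals)
    resolved[[cond$name]] <- programs
    for (s in seq_len(cond$n_subjects)) {
      jm <- jitter_parameters(model, noise)
      traj <- integrate_system(jm, initial_state, programs, times)
      ss <- steady_state_sample(traj, model)
      cols_true_g[[length(cols_true_g) + 1L]] <- ss$genes
      cols_true_m[[length(cols_true_m) + 1L]] <- ss$mirnas
      labels <- c(labels, cond$name)
      subject_ids <- c(subject_ids, paste0(cond$name, "_s", s))
    }
  }
  bindcols <- function(cols, rn) {
    m <- if (length(cols)) do.call(cbind, cols) else
      matrix(numeric(), nrow = length(rn), ncol = 0L)
    rownames(m) <- rn; colnames(m) <- subject_ids
    m
  }
  genes_true <- bindcols(cols_true_g, gene_names)
  mirnas_true <- bindcols(cols_true_m, mir_names)
  genes <- apply_measurement(genes_true, noise)
  mirnas <- apply_measurement(mirnas_true, noise)
  structure(list(genes = genes, mirnas = mirnas,
                 genes_true = genes_true, mirnas_true = mirnas_true,
                 labels = factor(labels, levels = unique(labels)),
                 subjects = subject_ids, conditions = resolved,
                 network = network, model = model, seed = seed),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("expression_dataset:", nrow(x$genes), "genes x", ncol(x$genes),
      "subjects;", nrow(x$mirnas), "miRNAs;",
      nlevels(x$labels), "condition(s):",
      paste(levels(x$labels), table(x$labels)[levels(x$labels)],
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}
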