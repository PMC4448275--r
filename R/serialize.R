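## Model serialization: the per-node composition trees plus kinetic
## parameters round-trip through JSON at full double precision, so a
## reloaded model evaluates to identical right-hand sides.

tree_to_list <- function(tree) {
  out <- list(op = tree$op)
  if (!is.null(tree$regulator)) {
    out$regulator <- tree$regulator
    out$theta <- tree$theta
    out$mu <- tree$mu
  }
  if (!is.null(tree$args)) out$args <- lapply(tree$args, tree_to_list)
  out
}

list_to_tree <- function(x) {
  out <- list(op = x$op)
  if (!is.null(x$regulator)) {
    out$regulator <- x$regulator
    out$theta <- x$theta
    out$mu <- x$mu
  }
  if (!is.null(x$args)) out$args <- lapply(x$args, list_to_tree)
  out
}

#' Serialize a system model to JSON
#'
#' @param model a \code{system_model}.
#' @param path optional file path; when NULL the JSON string is
#'   returned.
#' @return the JSON string (invisibly when written to a file).
#' @export
model_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "system_model"))
  payload <- list(
    nodes = model$nodes,
    signals = model$signals,
    ranges = unclass(model$ranges),
    models = lapply(model$models, function(m) {
      list(node = m$node, kind = m$kind,
           production = tree_to_list(m$production),
           mirna_regs = m$mirna_regs,
           kinetic = m$kinetic)
    }))
  # 17 significant digits round-trips IEEE doubles exactly
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = I(17),
                         dataframe = "columns")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Load a system model from JSON
#'
#' @param path file path or JSON string produced by
#'   \code{\link{model_to_json}}.
#' @return a \code{system_model}.
#' @export
model_from_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                          simplifyVector = FALSE)
  nodes <- data.frame(id = vapply(x$nodes$id, as.integer, integer(1)),
                      name = unlist(x$nodes$name),
                      kind = unlist(x$nodes$kind))
  models <- lapply(x$models, function(m) {
    mr <- m$mirna_regs
    mirna_regs <- data.frame(
      regulator = as.character(unlist(mr$regulator)),
      theta = as.numeric(unlist(mr$theta)),
      mu = as.numeric(unlist(mr$mu)))
    structure(list(node = m$node, kind = m$kind,
                   production = list_to_tree(m$production),
                   mirna_regs = mirna_regs,
                   kinetic = lapply(m$kinetic, as.numeric)),
              class = "regulation_model")
  })
  names(models) <- vapply(models, `[[`, character(1), "node")
  ranges <- do.call(dynamics_ranges, lapply(x$ranges, as.numeric))
  structure(list(nodes = nodes,
                 signals = as.character(unlist(x$signals)),
                 models = models, ranges = ranges),
            class = "system_model")
}
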