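## Network and dataset export. Primary outputs are written to a
## temporary file in the same directory and renamed into place, so a
## failed run never leaves a half-written artifact.

write_atomic <- function(writer, path) {
  tmp <- paste0(path, ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Export a network as GraphML
#'
#' Node attribute \code{kind} and edge attributes \code{sign},
#' \code{theta}, \code{mu}, \code{interaction} are preserved.
#'
#' @param network a \code{regulatory_network}.
#' @param path output file path.
#' @export
export_network_graphml <- function(network, path) {
  g <- as_igraph(network)
  ia <- igraph::edge_attr(g, "interaction")
  ia[is.na(ia)] <- ""
  g <- igraph::set_edge_attr(g, "interaction", value = ia)
  write_atomic(function(p) igraph::write_graph(g, p, format = "graphml"),
               path)
}

#' Export a network as a SIF-style TSV
#'
#' Three columns: source, sign, target (node names).
#'
#' @inheritParams export_network_graphml
#' @export
export_network_sif <- function(network, path) {
  nm <- network$nodes$name
  e <- network$edges
  sif <- data.frame(source = nm[match(e$from, network$nodes$id)],
                    sign = e$sign,
                    target = nm[match(e$to, network$nodes$id)])
  write_atomic(function(p)
    write.table(sif, p, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE), path)
}

#' Export motif-instance provenance as JSON
#'
#' One record per motif instantiation: template name, hierarchy level,
#' slot-to-node assignment, consumed nodes and added edges.
#'
#' @inheritParams export_network_graphml
#' @export
export_provenance_json <- function(network, path) {
  nm <- network$nodes$name
  recs <- lapply(network$provenance, function(pr) {
    list(template = pr$template, level = pr$level,
         nodes = as.list(setNames(ifelse(is.na(pr$nodes), NA, nm[pr$nodes]),
                                  names(pr$nodes))),
         consumed = nm[pr$consumed],
         edges = if (nrow(pr$edges))
           data.frame(from = nm[pr$edges[, 1]], to = nm[pr$edges[, 2]])
         else data.frame(from = character(), to = character()))
  })
  write_atomic(function(p)
    writeLines(jsonlite::toJSON(recs, auto_unbox = TRUE, null = "null",
                                dataframe = "columns"), p), path)
}

#' Export an expression view as TSV
#'
#' Rows are features (stable ids), columns subject ids, with a header
#' row; the first column is named \code{feature}.
#'
#' @param mat features x subjects matrix.
#' @param path output file path.
#' @export
export_view_tsv <- function(mat, path) {
  df <- data.frame(feature = rownames(mat), mat, check.names = FALSE)
  write_atomic(function(p)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE), path)
}

#' Export a trajectory in long format
#'
#' Columns: subject, time, feature, value.
#'
#' @param traj a \code{trajectory}.
#' @param subject subject id recorded in the first column.
#' @param path output file path.
#' @export
export_trajectory_tsv <- function(traj, subject, path) {
  long <- data.frame(
    subject = subject,
    time = rep(traj$time, times = ncol(traj$states)),
    feature = rep(colnames(traj$states), each = length(traj$time)),
    value = as.vector(traj$states))
  write_atomic(function(p)
    write.table(long, p, sep = "\t", quote = FALSE, row.names = FALSE), path)
}
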