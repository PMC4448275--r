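## Run configuration and the end-to-end pipeline: one YAML/JSON file
## (or an in-memory list) describes network sizes, dynamics ranges,
## noise, simulation settings and per-condition signal programs; a
## single seed makes the whole artifact bundle reproducible.

run_config_defaults <- function() {
  list(
    network = list(n_genes = 100L, n_mirnas = 10L, n_signals = 2L,
                   alpha = 2.2, lambda = 0.5, pool_size = 10L),
    dynamics = list(theta = c(0.3, 0.8), mu = c(2, 10), d0 = c(0.1, 1),
                    p_rel = c(0.5, 1.5), d_rel = c(0.5, 2)),
    noise = list(sigma_bio = 0.05, c = 0, sigma_eps = 0.05,
                 sigma_eta = 0.1),
    simulation = list(t_max = 50, n_points = 100L, initial_state = 0.1,
                      rtol = 1e-6, atol = 1e-8),
    conditions = list(list(name = "cond1", n_subjects = 10L,
                           signals = list(type = "constant", value = 0)),
                      list(name = "cond2", n_subjects = 10L,
                           signals = list(type = "constant", value = 1))),
    seed = 1L,
    out_prefix = "mvsim_run")
}

check_known_keys <- function(x, known, where) {
  unknown <- setdiff(names(x), known)
  if (length(unknown))
    stop("unknown configuration key(s) in ", where, ": ",
         paste(unknown, collapse = ", "))
}

parse_signal_spec <- function(spec) {
  if (inherits(spec, "signal_program")) return(spec)
  if (is.numeric(spec) && length(spec) == 1L) return(signal_constant(spec))
  if (is.character(spec) && spec == "zero") return(signal_zero())
  if (is.list(spec)) {
    type <- spec$type
    if (identical(type, "constant")) return(signal_constant(spec$value))
    if (identical(type, "zero")) return(signal_zero())
    if (identical(type, "periodic"))
      return(signal_periodic(spec$amplitude, spec$period,
                             if (is.null(spec$waveform)) "sine"
                             else spec$waveform))
    if (identical(type, "custom"))
      return(signal_custom(as.numeric(spec$time), as.numeric(spec$values)))
  }
  stop("unparseable signal specification")
}

signal_spec_of <- function(program) {
  c(list(type = program$type), program$spec)
}

#' Build a validated run configuration
#'
#' Merges a (possibly partial) configuration list over the package
#' defaults, rejecting unknown keys and validating values. The same
#' structure is accepted from YAML or JSON files via
#' \code{\link{load_run_config}}.
#'
#' @param config named list with any of the sections \code{network},
#'   \code{dynamics}, \code{noise}, \code{simulation},
#'   \code{conditions}, \code{seed}, \code{out_prefix}.
#' @return validated list of class \code{run_config}.
#' @export
run_config <- function(config = list()) {
  defaults <- run_config_defaults()
  check_known_keys(config, names(defaults), "top level")
  for (sec in c("network", "dynamics", "noise", "simulation"))
    if (!is.null(config[[sec]]))
      check_known_keys(config[[sec]], names(defaults[[sec]]), sec)
  merged <- modifyList(defaults, config)
  if (!is.null(config$conditions)) merged$conditions <- config$conditions

  net <- merged$network
  cfg_net <- network_config(net$n_genes, net$n_mirnas, net$n_signals,
                            alpha = net$alpha, lambda = net$lambda,
                            pool_size = net$pool_size,
                            seed = merged$seed)
  ranges <- do.call(dynamics_ranges,
                    lapply(merged$dynamics, function(v) as.numeric(unlist(v))))
  noise <- do.call(noise_config, merged$noise)
  sim <- merged$simulation
  if (sim$t_max <= 0 || sim$n_points < 2L) stop("invalid simulation grid")
  conditions <- lapply(merged$conditions, function(cd) {
    check_known_keys(cd, c("name", "n_subjects", "signals"), "condition")
    sig <- cd$signals
    if (!is.null(sig) && is.list(sig) && is.null(sig$type) &&
        !inherits(sig, "signal_program"))
      sig <- lapply(sig, parse_signal_spec)   # named per-signal specs
    else if (!is.null(sig))
      sig <- parse_signal_spec(sig)
    sim_condition(cd$name, cd$n_subjects, sig)
  })
  structure(list(network = cfg_net, dynamics = ranges, noise = noise,
                 simulation = sim, conditions = conditions,
                 seed = as.integer(merged$seed),
                 out_prefix = merged$out_prefix),
            class = "run_config")
}

#' Load a run configuration from YAML or JSON
#'
#' @param path file path (\code{.yaml}/\code{.yml} parsed as YAML,
#'   \code{.json} as JSON; YAML is tried first otherwise).
#' @return a validated \code{run_config}.
#' @examples
#' cfg <- load_run_config(system.file("extdata", "example_config.yaml",
#'                                    package = "mvsim"))
#' cfg$network
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                       simplifyVector = TRUE)
  else yaml::read_yaml(path)
  run_config(raw)
}

#' Save a run configuration as YAML
#'
#' The saved file reloads (via \code{\link{load_run_config}}) into an
#' equivalent configuration, so a run can be regenerated byte-for-byte
#' from its provenance.
#'
#' @param config a \code{run_config}.
#' @param path output path.
#' @export
save_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  raw <- list(
    network = config$network[c("n_genes", "n_mirnas", "n_signals",
                               "alpha", "lambda", "pool_size")],
    dynamics = unclass(config$dynamics),
    noise = unclass(config$noise),
    simulation = config$simulation,
    conditions = lapply(config$conditions, function(cd) {
      sig <- cd$signals
      list(name = cd$name, n_subjects = cd$n_subjects,
           signals = if (is.null(sig)) list(type = "zero")
                     else if (inherits(sig, "signal_program"))
                       signal_spec_of(sig)
                     else lapply(sig, signal_spec_of))
    }),
    seed = config$seed,
    out_prefix = config$out_prefix)
  write_atomic(function(p) yaml::write_yaml(raw, p), path)
}

#' Named GRN presets
#'
#' Three reference network sizes used throughout the package's worked
#' analyses: \code{grn1} (1000 genes, 100 miRNAs, 10 signals),
#' \code{grn2} (1000 genes, 300 miRNAs, 35 signals) and \code{grn3}
#' (500 genes, 100 miRNAs, 20 signals). The default design is two
#' conditions of 50 subjects with all signals held at 0 versus 1.
#'
#' @param name \code{"grn1"}, \code{"grn2"} or \code{"grn3"}.
#' @param n_subjects subjects per condition.
#' @param seed root seed.
#' @return a \code{run_config}.
#' @export
grn_preset <- function(name = c("grn1", "grn2", "grn3"), n_subjects = 50L,
                       seed = 1L) {
  name <- match.arg(name)
  sizes <- switch(name,
    grn1 = c(1000L, 100L, 10L),
    grn2 = c(1000L, 300L, 35L),
    grn3 = c(500L, 100L, 20L))
  run_config(list(
    network = list(n_genes = sizes[1], n_mirnas = sizes[2],
                   n_signals = sizes[3]),
    conditions = list(
      list(name = "cond1", n_subjects = n_subjects,
           signals = list(type = "constant", value = 0)),
      list(name = "cond2", n_subjects = n_subjects,
           signals = list(type = "constant", value = 1))),
    seed = seed,
    out_prefix = name))
}

#' Run the full pipeline and write the artifact bundle
#'
#' Builds the network, samples the ODE model, simulates every condition
#' and writes: \code{<prefix>_network.graphml}, \code{<prefix>_network.sif},
#' \code{<prefix>_motifs.json} (provenance), \code{<prefix>_model.json},
#' per-view observed and true expression TSVs, \code{<prefix>_labels.tsv}
#' and \code{<prefix>_provenance.json} (config + seed + package version +
#' stage timings). All primary outputs are written atomically
#' (write-then-rename).
#'
#' @param config a \code{run_config}.
#' @param out_dir output directory (created if missing).
#' @param quiet suppress stage messages.
#' @return (invisibly) list with the in-memory objects and output paths.
#' @export
run_end_to_end <- function(config, out_dir = ".", quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  prefix <- file.path(out_dir, config$out_prefix)
  say <- function(...) if (!quiet) message(...)
  timings <- list()
  stage <- function(what, expr) {
    t0 <- Sys.time()
    res <- force(expr)
    dt <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    timings[[what]] <<- round(dt, 3)
    say(sprintf("[mvsim] %s: %.2fs", what, dt))
    res
  }

  network <- stage("build_network", build_network(config$network))
  model <- stage("build_system_model",
                 build_system_model(network, config$dynamics))
  sim <- config$simulation
  times <- seq(0, sim$t_max, length.out = sim$n_points)
  dataset <- stage("generate_dataset",
                   generate_dataset(network, config$conditions,
                                    noise = config$noise, seed = NULL,
                                    model = model, times = times,
                                    initial_state = sim$initial_state))

  paths <- list(
    graphml = paste0(prefix, "_network.graphml"),
    sif = paste0(prefix, "_network.sif"),
    motifs = paste0(prefix, "_motifs.json"),
    model = paste0(prefix, "_model.json"),
    genes = paste0(prefix, "_genes.tsv"),
    mirnas = paste0(prefix, "_mirnas.tsv"),
    genes_true = paste0(prefix, "_genes_true.tsv"),
    mirnas_true = paste0(prefix, "_mirnas_true.tsv"),
    labels = paste0(prefix, "_labels.tsv"),
    config = paste0(prefix, "_config.yaml"),
    provenance = paste0(prefix, "_provenance.json"))
  stage("write_outputs", {
    export_network_graphml(network, paths$graphml)
    export_network_sif(network, paths$sif)
    export_provenance_json(network, paths$motifs)
    write_atomic(function(p) model_to_json(model, p), paths$model)
    export_view_tsv(dataset$genes, paths$genes)
    export_view_tsv(dataset$mirnas, paths$mirnas)
    export_view_tsv(dataset$genes_true, paths$genes_true)
    export_view_tsv(dataset$mirnas_true, paths$mirnas_true)
    write_atomic(function(p)
      write.table(data.frame(subject = dataset$subjects,
                             condition = as.character(dataset$labels)),
                  p, sep = "\t", quote = FALSE, row.names = FALSE),
      paths$labels)
    save_run_config(config, paths$config)
    prov <- list(package = "mvsim",
                 version = as.character(utils::packageVersion("mvsim")),
                 r_version = R.version.string,
                 seed = config$seed,
                 config_file = basename(paths$config),
                 timings_sec = timings)
    write_atomic(function(p)
      writeLines(jsonlite::toJSON(prov, auto_unbox = TRUE, digits = NA), p),
      paths$provenance)
    NULL
  })
  invisible(list(network = network, model = model, dataset = dataset,
                 paths = paths, timings = timings))
}
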