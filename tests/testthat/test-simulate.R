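## Hand-built one-gene model used by the closed-form tests.
one_gene_model <- function(p = 0.8, d0 = 0.4) {
  m <- structure(list(node = "g1", kind = "gene",
                      production = list(op = "const"),
                      mirna_regs = data.frame(regulator = character(),
                                              theta = numeric(),
                                              mu = numeric()),
                      kinetic = list(p = p, d0 = d0, di = 0.1)),
                 class = "regulation_model")
  structure(list(nodes = data.frame(id = 1L, name = "g1", kind = "gene"),
                 signals = character(), models = list(g1 = m),
                 ranges = dynamics_ranges()),
            class = "system_model")
}

test_that("an unregulated gene follows the closed-form saturation curve", {
  p <- 0.8; d0 <- 0.4
  model <- one_gene_model(p, d0)
  times <- seq(0, 50, length.out = 100)
  tr <- integrate_system(model, 0, times = times)
  analytic <- (p / d0) * (1 - exp(-d0 * times))
  rel_err <- abs(tr$states[-1, "g1"] - analytic[-1]) / analytic[-1]
  expect_lt(max(rel_err), 1e-4)
  expect_identical(unname(tr$states[1, "g1"]), 0)
  # steady state = p / d0 at the last time point
  ss <- steady_state_sample(tr, model)
  expect_equal(unname(ss$genes["g1"]), p / d0, tolerance = 1e-4)
  expect_identical(length(ss$mirnas), 0L)
})

test_that("trajectories stay non-negative and bounded by p/d0", {
  for (seed in c(6, 23)) {
    net <- build_network(network_config(20, 4, 2, seed = seed))
    set.seed(seed)
    model <- build_system_model(net)
    tr <- integrate_system(model, 0.1, signal_constant(1))
    expect_true(all(tr$states >= 0))
    caps <- vapply(model$models, function(m) m$kinetic$p / m$kinetic$d0,
                   numeric(1))
    # production term <= p, so concentrations settle below p/d0
    # (allow solver tolerance headroom)
    expect_true(all(t(tr$states) <= caps + 1e-6))
  }
})

test_that("a repressilator ring matches an independent reference and oscillates", {
  # 3-gene ring of repression, deterministic tree structure (a lone
  # repressor always becomes an INH leaf)
  rngs <- dynamics_ranges()
  mk <- function(self, prev) {
    ie <- data.frame(from = prev, from_kind = "gene", sign = "repression",
                     theta = 0.3, mu = 6)
    m <- sample_regulation_model(self, "gene", ie, rngs)
    m$kinetic <- list(p = 3, d0 = 1, di = 0.5)
    m
  }
  model <- structure(list(
    nodes = data.frame(id = 1:3, name = c("g1", "g2", "g3"), kind = "gene"),
    signals = character(),
    models = list(g1 = mk("g1", "g3"), g2 = mk("g2", "g1"),
                  g3 = mk("g3", "g2")), ranges = rngs),
    class = "system_model")
  times <- seq(0, 100, length.out = 400)
  tr <- integrate_system(model, c(g1 = 1, g2 = 0.1, g3 = 0.1),
                         times = times)
  # independent reference: the same ODEs written out by hand
  ref_rhs <- function(t, y, parms) {
    h <- function(x) ifelse(x <= 0, 0, x^6 / (x^6 + 0.3^6))
    list(c(3 * (1 - h(y[3])) - y[1],
           3 * (1 - h(y[1])) - y[2],
           3 * (1 - h(y[2])) - y[3]))
  }
  ref <- deSolve::ode(c(1, 0.1, 0.1), times, ref_rhs, NULL,
                      rtol = 1e-8, atol = 1e-10)
  expect_equal(unname(tr$states), unname(pmax(ref[, -1], 0)),
               tolerance = 1e-3)
  # non-constant late-time trajectory
  late <- tr$states[times > 50, "g1"]
  expect_gt(diff(range(late)), 0.5)
})

test_that("datasets have consistent views, labels and shapes", {
  net <- build_network(network_config(12, 3, 2, seed = 31))
  conds <- list(sim_condition("a", 3, signal_constant(0)),
                sim_condition("b", 2, signal_constant(1)))
  ds <- generate_dataset(net, conds, noise_config(), seed = 31,
                         times = seq(0, 30, length.out = 40))
  expect_identical(dim(ds$genes), c(12L, 5L))
  expect_identical(dim(ds$mirnas), c(3L, 5L))
  expect_identical(colnames(ds$genes), colnames(ds$mirnas))
  expect_identical(as.character(ds$labels), c("a", "a", "a", "b", "b"))
  expect_identical(colnames(ds$genes), ds$subjects)
  # zero-subject condition keeps the schema intact
  ds0 <- generate_dataset(net, sim_condition("empty", 0), noise_config(),
                          seed = 1, times = seq(0, 5, length.out = 5))
  expect_identical(dim(ds0$genes), c(12L, 0L))
  expect_identical(rownames(ds0$genes), rownames(ds$genes))
})

test_that("identical seeds reproduce datasets bit-for-bit and zero noise collapses subjects", {
  net <- build_network(network_config(10, 2, 1, seed = 13))
  conds <- list(sim_condition("c1", 2, signal_constant(0.5)))
  tm <- seq(0, 20, length.out = 30)
  d1 <- generate_dataset(net, conds, noise_config(), seed = 99, times = tm)
  d2 <- generate_dataset(net, conds, noise_config(), seed = 99, times = tm)
  expect_identical(d1$genes, d2$genes)
  expect_identical(d1$mirnas, d2$mirnas)
  # noise fully disabled: all subjects within a condition identical
  nz <- noise_config(sigma_bio = 0, c = 0, sigma_eps = 0, sigma_eta = 0)
  d3 <- generate_dataset(net, conds, nz, seed = 7, times = tm)
  expect_identical(d3$genes[, 1], d3$genes[, 2])
  expect_identical(d3$genes, d3$genes_true)
})

test_that("strong signal contrasts separate conditions beyond within-condition spread", {
  net <- build_network(network_config(25, 5, 3, seed = 41))
  conds <- list(sim_condition("off", 5, signal_constant(0)),
                sim_condition("on", 5, signal_constant(1)))
  ds <- generate_dataset(net, conds, noise_config(sigma_bio = 0.02,
                                                  sigma_eps = 0.01,
                                                  sigma_eta = 0.02),
                         seed = 41, times = seq(0, 50, length.out = 60))
  # the signal contrast only reaches nodes downstream of a signal
  g <- as_igraph(net)
  sig <- net$nodes$name[net$nodes$kind == "signal"]
  d <- igraph::distances(g, v = sig, mode = "out")
  downstream <- colnames(d)[apply(is.finite(d), 2, any)]
  x <- ds$genes[rownames(ds$genes) %in% downstream, ]
  off <- x[, ds$labels == "off"]; on <- x[, ds$labels == "on"]
  between <- sqrt(sum((rowMeans(off) - rowMeans(on))^2))
  within <- mean(c(apply(off, 2, function(v) sqrt(sum((v - rowMeans(off))^2))),
                   apply(on, 2, function(v) sqrt(sum((v - rowMeans(on))^2)))))
  expect_gt(between, within)
})

test_that("signal programs cover constant, periodic and custom shapes", {
  expect_identical(signal_constant(2)$fn(c(0, 5)), c(2, 2))
  expect_identical(signal_zero()$fn(3), 0)
  sq <- signal_periodic(1, 10, "square")
  expect_identical(sq$fn(c(0, 4.9, 5, 9.9)), c(1, 1, 0, 0))
  sn <- signal_periodic(2, 8, "sine")
  expect_true(all(sn$fn(seq(0, 40, by = 0.5)) >= 0))
  cu <- signal_custom(c(0, 10), c(0, 1))
  expect_equal(cu$fn(5), 0.5, tolerance = 1e-12)
  expect_error(signal_constant(-1), ">= 0")
  # unknown signal names rejected
  net <- build_network(network_config(5, 0, 1, seed = 2))
  set.seed(2); model <- build_system_model(net)
  expect_error(integrate_system(model, 0.1, list(bogus = signal_zero())),
               "unknown signal")
})
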