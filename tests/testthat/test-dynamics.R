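test_that("hill function satisfies its defining identities", {
  for (theta in c(0.3, 0.5, 0.8)) for (mu in c(2, 5, 10)) {
    expect_equal(hill(theta, theta, mu), 0.5, tolerance = 1e-12)
    expect_identical(hill(0, theta, mu), 0)
  }
  # closed form by direct evaluation
  expect_equal(hill(1, 0.5, 5), 1 / (1 + 0.5^5), tolerance = 1e-12)
  # monotone, and steeper mu gives larger slope at the threshold
  x <- seq(0.01, 2, by = 0.01)
  expect_true(all(diff(hill(x, 0.5, 3)) > 0))
  eps <- 1e-6
  slope <- function(mu) (hill(0.5 + eps, 0.5, mu) - hill(0.5 - eps, 0.5, mu)) / (2 * eps)
  expect_gt(slope(8), slope(2))
  expect_error(hill(-0.1, 0.5, 2), "negative")
})

test_that("combinators implement min / capped sum / complement / clamped difference", {
  expect_identical(coop(0.4), 0.4)
  expect_identical(coop(c(0.2, 0.9)), 0.2)
  expect_identical(coop(c(0.5, 0, 0.9)), 0)
  expect_identical(syn(c(0.3, 0.4)), 0.7)
  expect_identical(syn(c(0.8, 0.8)), 1)
  expect_identical(syn(numeric()), 0)
  expect_identical(inh(0), 1)
  expect_identical(inh(1), 0)
  expect_identical(comp(0.5, 0.5), 0)
  expect_identical(comp(1, 0), 1)
  expect_identical(comp(0.3, 0.7), 0)
  # all combinators map [0,1] inputs into [0,1]
  set.seed(1)
  for (i in 1:100) {
    v <- runif(sample(1:5, 1))
    expect_true(coop(v) >= 0 && coop(v) <= 1)
    expect_true(syn(v) >= 0 && syn(v) <= 1)
    expect_true(all(inh(v) >= 0 & inh(v) <= 1))
    expect_true(comp(v[1], rev(v)[1]) >= 0 && comp(v[1], rev(v)[1]) <= 1)
  }
})

test_that("degradation rate ranges from basal to saturated", {
  kin <- list(p = 1, d0 = 0.4, di = 0.6)
  expect_identical(degradation_rate(numeric(), kin), 0.4)
  hp <- data.frame(theta = 0.5, mu = 4)
  expect_equal(degradation_rate(0.5, kin, hp), 0.4 + 0.5 * 0.6,
               tolerance = 1e-12)
  hp2 <- data.frame(theta = c(0.5, 0.5), mu = c(4, 4))
  expect_equal(degradation_rate(c(100, 100), kin, hp2), 0.4 + 0.6,
               tolerance = 1e-6)
})

test_that("sampled regulation models use every in-edge exactly once with correct sign placement", {
  set.seed(10)
  rngs <- dynamics_ranges()
  # degenerate cases
  m0 <- sample_regulation_model("g1", "gene", NULL, rngs)
  expect_identical(m0$production$op, "const")
  e1 <- data.frame(from = "g2", from_kind = "gene", sign = "activation",
                   theta = 0.5, mu = 3)
  m1 <- sample_regulation_model("g1", "gene", e1, rngs)
  expect_identical(m1$production$op, "hill")
  expect_identical(m1$production$regulator, "g2")
  # structural audit over many random trees
  for (i in 1:300) {
    n_act <- sample(0:3, 1); n_rep <- sample(0:3, 1); n_mir <- sample(0:2, 1)
    lbl <- function(p, n) if (n > 0) paste0(p, seq_len(n)) else character()
    ie <- data.frame(
      from = c(lbl("a", n_act), lbl("r", n_rep), lbl("m", n_mir)),
      from_kind = c(rep("gene", n_act + n_rep), rep("mirna", n_mir)),
      sign = c(rep("activation", n_act), rep("repression", n_rep + n_mir)),
      theta = runif(n_act + n_rep + n_mir, 0.3, 0.8),
      mu = runif(n_act + n_rep + n_mir, 2, 10))
    m <- sample_regulation_model("g1", "gene", ie, rngs)
    roles <- tree_roles(m$production)
    # every non-miRNA edge appears exactly once in the tree
    expect_setequal(roles$regulator, ie$from[ie$from_kind != "mirna"])
    expect_false(any(duplicated(roles$regulator)))
    # activators as plain hill leaves, repressors as INH or COMP arms
    expect_true(all(roles$role[grepl("^a", roles$regulator)] == "hill"))
    expect_true(all(roles$role[grepl("^r", roles$regulator)] %in%
                      c("inh", "comp_rep")))
    # miRNA regulators live in the degradation term only
    expect_setequal(m$mirna_regs$regulator, ie$from[ie$from_kind == "mirna"])
    expect_true(all(c(m$kinetic$p, m$kinetic$d0, m$kinetic$di) > 0))
  }
})

test_that("node derivatives match closed forms and hand-composed expressions", {
  rngs <- dynamics_ranges()
  # unregulated gene at its steady state p/d0 has zero derivative
  set.seed(2)
  m <- sample_regulation_model("g1", "gene", NULL, rngs)
  model <- structure(list(
    nodes = data.frame(id = 1L, name = "g1", kind = "gene"),
    signals = character(), models = list(g1 = m), ranges = rngs),
    class = "system_model")
  xss <- m$kinetic$p / m$kinetic$d0
  expect_equal(node_derivative("g1", c(g1 = xss), NULL, model), 0,
               tolerance = 1e-12)
  expect_error(node_derivative("nope", c(g1 = 1), NULL, model), "unknown")

  # one activator at its threshold, no miRNA: 0.5 p - d0 x
  act <- data.frame(from = "g2", from_kind = "gene", sign = "activation",
                    theta = 0.4, mu = 6)
  m2 <- sample_regulation_model("g1", "gene", act, rngs)
  model2 <- structure(list(
    nodes = data.frame(id = 1:2, name = c("g1", "g2"), kind = "gene"),
    signals = character(),
    models = list(g1 = m2,
                  g2 = sample_regulation_model("g2", "gene", NULL, rngs)),
    ranges = rngs), class = "system_model")
  st <- c(g1 = 0.7, g2 = 0.4)
  expect_equal(node_derivative("g1", st, NULL, model2),
               0.5 * m2$kinetic$p - m2$kinetic$d0 * 0.7, tolerance = 1e-12)

  # full miRNA feed-forward loop: hand-composed right-hand side
  # tf -> gene (activation), tf -> mir (activation), mir -| gene
  tf_e <- data.frame(from = "g2", from_kind = "gene", sign = "activation",
                     theta = 0.5, mu = 4)
  mir_e <- data.frame(from = c("g2", "mir1"), from_kind = c("gene", "mirna"),
                      sign = c("activation", "repression"),
                      theta = c(0.5, 0.6), mu = c(4, 3))
  set.seed(5)
  mg <- sample_regulation_model("g1", "gene", mir_e, rngs)
  mm <- sample_regulation_model("mir1", "mirna", tf_e, rngs)
  mt <- sample_regulation_model("g2", "gene", NULL, rngs)
  model3 <- structure(list(
    nodes = data.frame(id = 1:3, name = c("g1", "mir1", "g2"),
                       kind = c("gene", "mirna", "gene")),
    signals = character(), models = list(g1 = mg, mir1 = mm, g2 = mt),
    ranges = rngs), class = "system_model")
  st3 <- c(g1 = 0.9, mir1 = 0.3, g2 = 0.6)
  h <- function(x, th, mu) x^mu / (x^mu + th^mu)
  by_hand <- c(
    g1 = mg$kinetic$p * h(0.6, 0.5, 4) -
      (mg$kinetic$d0 + mg$kinetic$di * min(1, h(0.3, 0.6, 3))) * 0.9,
    mir1 = mm$kinetic$p * h(0.6, 0.5, 4) - mm$kinetic$d0 * 0.3,
    g2 = mt$kinetic$p - mt$kinetic$d0 * 0.6)
  expect_equal(system_derivatives(model3, st3), by_hand, tolerance = 1e-12)
  # compiled evaluator agrees with the R reference
  cs <- compile_system(model3)
  expect_equal(as.numeric(mvsim:::compiled_derivatives(cs, st3)),
               unname(by_hand), tolerance = 1e-12)
})

test_that("compiled RHS agrees with the R reference on random networks", {
  for (seed in c(4, 17)) {
    net <- build_network(network_config(25, 5, 3, seed = seed))
    set.seed(seed)
    model <- build_system_model(net)
    cs <- compile_system(model)
    set.seed(seed + 1)
    for (i in 1:5) {
      st <- setNames(runif(nrow(model$nodes), 0, 1.5), model$nodes$name)
      sv <- setNames(runif(length(model$signals)), model$signals)
      expect_equal(as.numeric(mvsim:::compiled_derivatives(cs, st, sv)),
                   unname(system_derivatives(model, st, sv)),
                   tolerance = 1e-10)
    }
  }
})

test_that("model JSON serialization round-trips to identical dynamics", {
  net <- build_network(network_config(15, 4, 2, seed = 8))
  set.seed(8)
  model <- build_system_model(net)
  js <- model_to_json(model)
  model2 <- model_from_json(js)
  st <- setNames(runif(nrow(model$nodes)), model$nodes$name)
  sv <- setNames(runif(length(model$signals)), model$signals)
  expect_identical(system_derivatives(model, st, sv),
                   system_derivatives(model2, st, sv))
  # file round-trip
  f <- tempfile(fileext = ".json")
  model_to_json(model, f)
  model3 <- model_from_json(f)
  expect_identical(system_derivatives(model, st, sv),
                   system_derivatives(model3, st, sv))
})
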