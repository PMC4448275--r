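test_that("degree targets are normalized discrete laws", {
  cfg <- network_config(3, 1, alpha = 2.2, lambda = 0.5)
  tg <- sample_degree_targets(cfg)
  # brute-force normalization: Z by direct summation over k = 1..4
  z <- sum((1:4)^-2.2)
  expect_equal(tg$d_p, (1:4)^-2.2 / z, tolerance = 1e-12)
  expect_equal(sum(tg$d_p), 1, tolerance = 1e-12)
  expect_equal(sum(tg$d_e), 1, tolerance = 1e-12)
  expect_true(all(tg$d_p >= 0) && all(tg$d_e >= 0))
  # large lambda concentrates the exponential mass on degree 1
  tg2 <- sample_degree_targets(network_config(50, 0, lambda = 50))
  expect_gt(tg2$d_e[1], 1 - 1e-12)
  expect_error(network_config(10, alpha = -1), "alpha")
  expect_error(network_config(10, lambda = 0), "lambda")
  expect_error(network_config(0), "n_genes")
})

test_that("sub-scores match term-by-term recomputation on small networks", {
  for (seed in 1:8) {
    cfg <- network_config(sample(3:6, 1), sample(0:2, 1), 0,
                          seed = seed)
    net <- build_network(cfg)
    tg <- sample_degree_targets(cfg)
    st <- degree_state(net)
    for (nd in seq_len(st$n_nodes)) {
      for (delta in 0:3) {
        expect_equal(gene_subscore(st, tg, nd, delta),
                     oracle_gene_subscore(net, tg, nd, delta),
                     tolerance = 1e-12,
                     info = paste("seed", seed, "node", nd, "delta", delta))
      }
      if (st$mirna[nd]) {
        for (di in 0:2) for (do in 0:2) {
          expect_equal(mirna_subscore(st, tg, nd, di, do),
                       oracle_mirna_subscore(net, tg, nd, di, do),
                       tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("zero-discrepancy states score zero and improving moves score positive", {
  # hand state: all fractions already at target -> any degree-preserving
  # move scores 0
  cfg <- network_config(4, 0)
  tg <- sample_degree_targets(cfg)
  st <- list(deg = c(1L, 1L, 1L, 1L), indeg = integer(4), outdeg = integer(4),
             p = tg$d_p * 0, p_in = numeric(4), p_out = numeric(4),
             n_nodes = 4L, n_mirnas = 0L, mirna = rep(FALSE, 4))
  st$p <- tg$d_p                      # exactly at target
  expect_equal(gene_subscore(st, tg, 1, 0), 0)
  # a move landing every bin on target from off-target is positive
  st2 <- st
  st2$p <- c(1, 0, 0, 0)              # everyone at degree 1, target is not
  st2$deg <- c(1L, 1L, 1L, 1L)
  expect_gt(gene_subscore(st2, tg, 1, 1), 0)
})

test_that("motif scores reduce to sub-score sums in degenerate cases", {
  cfg <- network_config(6, 0, seed = 5)
  net <- build_network(cfg)
  tg <- sample_degree_targets(cfg)
  st <- degree_state(net)
  reg <- default_motif_registry()
  set.seed(1)
  tmpl <- reg$autoregulation$make()   # single gene slot, self-loop (delta 2)
  cand <- which(!st$mirna)
  expected <- sum(vapply(cand, function(i) gene_subscore(st, tg, i, 2L),
                         numeric(1)))
  expect_equal(motif_score(tmpl, st, tg), expected, tolerance = 1e-12)
})

test_that("motif selection is proportional to shifted scores", {
  set.seed(42)
  # all-zero pool: uniform over 3
  draws <- replicate(6000, select_motif(c(0, 0, 0)))
  expect_gt(chisq.test(table(factor(draws, 1:3)))$p.value, 1e-4)
  # non-negative pool used as-is: scores (3, 1) -> 3/4 vs 1/4
  draws2 <- replicate(8000, select_motif(c(3, 1)))
  expect_equal(mean(draws2 == 1L), 0.75, tolerance = 0.025)
  # single-motif pool: always selected
  expect_identical(select_motif(5), 1L)
  # negative scores admissible
  expect_true(select_motif(c(-2, -1)) %in% 1:2)
})

test_that("motif templates are well-formed", {
  reg <- default_motif_registry()
  set.seed(7)
  for (i in 1:200) {
    nm <- sample(names(reg), 1)
    tmpl <- reg[[nm]]$make()
    expect_identical(sum(tmpl$slots$is_x), 1L, info = nm)
    expect_true(all(tmpl$edges$sign %in% c("activation", "repression")))
    mir_src <- tmpl$slots$kind[tmpl$edges$from] == "mirna"
    expect_true(all(tmpl$edges$sign[mir_src] == "repression"), info = nm)
    if (nm == "single_input_module")
      expect_true(nrow(tmpl$slots) %in% 3:6)
    if (nm == "dense_overlapping_regulons") {
      # every slot participates in at least one edge
      expect_setequal(union(tmpl$edges$from, tmpl$edges$to),
                      tmpl$slots$slot)
    }
  }
})

test_that("built networks satisfy the structural invariants", {
  for (seed in c(2, 11)) {
    cfg <- network_config(50, 8, 4, seed = seed)
    net <- build_network(cfg)
    # conservation
    expect_identical(nrow(net$nodes), 50L + 8L + 4L)
    # signal purity: in-degree exactly 0
    sig <- net$nodes$id[net$nodes$kind == "signal"]
    expect_true(all(!net$edges$to %in% sig))
    expect_true(all(vapply(sig, function(s) any(net$edges$from == s),
                           logical(1))))
    # miRNA-source edges always repressive
    mir <- net$nodes$id[net$nodes$kind == "mirna"]
    expect_true(all(net$edges$sign[net$edges$from %in% mir] == "repression"))
    # no duplicate edges
    expect_false(any(duplicated(net$edges[c("from", "to")])))
    # every non-signal node appears in >= 1 motif instance
    touched <- unique(unlist(lapply(net$provenance, function(p)
      p$nodes[!is.na(p$nodes)])))
    expect_true(all(setdiff(net$nodes$id, sig) %in% touched))
    # self-loops only from autoregulation
    selfs <- net$edges$from[net$edges$from == net$edges$to]
    auto_nodes <- unlist(lapply(net$provenance, function(p)
      if (p$template == "autoregulation") p$nodes else NULL))
    expect_true(all(selfs %in% auto_nodes))
  }
})

test_that("construction terminates across sizes, including degenerate ones", {
  for (n in c(1, 2, 3, 5, 13, 60)) {
    cfg <- network_config(n, max(0, round(n / 10)), 0, seed = n)
    net <- build_network(cfg)
    expect_identical(nrow(net$nodes), as.integer(n + max(0, round(n / 10))))
  }
  # a single gene terminates as a self-regulating gene or lone root
  net1 <- build_network(network_config(1, 0, 0, seed = 3))
  expect_identical(nrow(net1$nodes), 1L)
  expect_lte(nrow(net1$edges), 1L)
  # larger sweep point
  net2k <- build_network(network_config(1800, 200, 0, seed = 1))
  expect_identical(nrow(net2k$nodes), 2000L)
})

test_that("hierarchy levels are recorded and recycling is bounded", {
  net <- build_network(network_config(200, 20, 0, seed = 9))
  levels <- vapply(net$provenance, function(p) p$level, numeric(1))
  expect_gte(max(levels), 1)          # at least one recycling round
  counts <- table(levels)
  expect_gt(counts[["0"]], counts[[length(counts)]])  # shrinking hierarchy
})

test_that("signal targets are sampled with out-degree-plus-one smoothing", {
  # star: hub (node 1) with out-degree 9, nine leaves with out-degree 0
  star <- manual_network(rep("gene", 10), from = rep(1L, 9), to = 2:10)
  set.seed(21)
  aug <- add_signalling_nodes(star, 10000)
  sig_edges <- aug$edges[aug$edges$from > 10, ]
  # restrict to signals with exactly one target: single weighted draw,
  # hub probability = 10 / (10 + 9 * 1) = 10/19
  k_per_sig <- table(sig_edges$from)
  singles <- as.integer(names(k_per_sig)[k_per_sig == 1])
  hub_freq <- mean(sig_edges$to[sig_edges$from %in% singles] == 1L)
  expect_equal(hub_freq, 10 / 19, tolerance = 0.03)
  # unchanged when n_signals = 0
  expect_identical(add_signalling_nodes(star, 0), star)
})
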