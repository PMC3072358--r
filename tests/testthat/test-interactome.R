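mk_ev <- function(a, b, db = "biogrid", exp = "E1", prov = "direct") {
  data.frame(gene_a = a, gene_b = b, source_db = db, experiment_id = exp,
             provenance_class = prov, stringsAsFactors = FALSE)
}

test_that("integration merges parallel evidence and drops dirty records", {
  t1 <- mk_ev("A", "B", "biogrid", "E1")
  t2 <- rbind(mk_ev("B", "A", "intact", "E2"),     # same pair, other order
              mk_ev("A", "A", "intact", "E2"),     # self-interaction
              mk_ev("C", "D", "mint", "E3", "orthology_inferred"),
              mk_ev("A", "B", "mint", "E1"))       # duplicate (pair, exp)
  net <- integrate_evidence(list(t1, t2))
  expect_identical(nrow(net$edges), 1L)
  expect_identical(nrow(net$evidence), 2L)
  expect_identical(unname(net$log),
                   c(1L, 1L, 1L))                  # orth, self, duplicate
  expect_identical(interactome_nodes(net), c("A", "B"))
})

test_that("hand-enumerated counts on three overlapping sources", {
  s1 <- rbind(mk_ev("A", "B", "biogrid", "E1"), mk_ev("B", "C", "biogrid", "E1"))
  s2 <- rbind(mk_ev("C", "B", "intact", "E2"), mk_ev("A", "C", "intact", "E2"))
  s3 <- rbind(mk_ev("B", "A", "mint", "E3"), mk_ev("D", "A", "mint", "E3"))
  net <- integrate_evidence(list(s1, s2, s3))
  # edges: AB(E1,E3) BC(E1,E2) AC(E2) AD(E3) -> 4 edges, 6 evidence records
  expect_identical(nrow(net$edges), 4L)
  expect_identical(nrow(net$evidence), 6L)
  per_edge <- table(net$evidence$edge)
  expect_identical(sort(unname(c(per_edge))), c(1L, 1L, 2L, 2L))
})

test_that("experiment scale threshold is strict", {
  ev99 <- do.call(rbind, lapply(1:99, function(i)
    mk_ev(sprintf("a%03d", i), sprintf("b%03d", i), exp = "SMALL")))
  ev100 <- do.call(rbind, lapply(1:100, function(i)
    mk_ev(sprintf("c%03d", i), sprintf("d%03d", i), exp = "BIG")))
  net <- classify_experiment_scale(integrate_evidence(list(ev99, ev100)))
  expect_identical(unname(net$experiment_scale["SMALL"]), "single_gene")
  expect_identical(unname(net$experiment_scale["BIG"]), "high_throughput")
})

test_that("gold filter equals its defining predicate, and is idempotent", {
  set.seed(41)
  n_exp_ht <- 3
  rows <- list()
  for (i in 1:120) {
    a <- sprintf("g%02d", sample.int(30, 1)); b <- sprintf("g%02d", sample.int(30, 1))
    if (a == b) next
    exp <- if (runif(1) < 0.3) sprintf("SG%02d", sample.int(20, 1))
           else sprintf("HT%d", sample.int(n_exp_ht, 1))
    rows[[length(rows) + 1]] <- mk_ev(a, b, exp = exp)
  }
  net <- classify_experiment_scale(integrate_evidence(do.call(rbind, rows)))
  # by construction SG experiments are tiny and HT experiments are large
  # relative to a threshold of 10 used here
  net <- classify_experiment_scale(net, threshold = 10)
  gold <- gold_filter(net)

  # brute-force predicate over all input edges
  ev <- net$evidence
  for (e in unique(ev$edge)) {
    cls <- ev$scale_class[ev$edge == e]
    ids <- ev$experiment_id[ev$edge == e]
    keep <- any(cls == "single_gene") ||
      length(unique(ids[cls == "high_throughput"])) >= 2
    expect_identical(e %in% gold$edges$edge, keep)
  }
  # subgraph property and idempotence
  expect_true(all(gold$edges$edge %in% net$edges$edge))
  gold2 <- gold_filter(gold)
  expect_identical(gold2$edges, gold$edges)
  expect_identical(gold2$evidence, gold$evidence)
  # an edge supported by exactly one high-throughput record is dropped
  one_ht <- classify_experiment_scale(
    integrate_evidence(do.call(rbind, lapply(1:30, function(i)
      mk_ev(sprintf("x%02d", i), sprintf("y%02d", i), exp = "HTBIG")))),
    threshold = 10)
  expect_identical(nrow(gold_filter(one_ht)$edges), 0L)
  expect_error(gold_filter(integrate_evidence(mk_ev("A", "B"))),
               "classify_experiment_scale")
})

test_that("degree and betweenness match hand values on canonical graphs", {
  # path a-b-c
  net <- integrate_evidence(rbind(mk_ev("a", "b"), mk_ev("b", "c")))
  m <- compute_metrics(net)
  expect_identical(m$degree[match(c("a", "b", "c"), m$gene_id)], c(1, 2, 1))
  expect_identical(m$betweenness[match(c("a", "b", "c"), m$gene_id)],
                   c(0, 1, 0))
  # star with 4 leaves: center lies on C(4,2) = 6 leaf pairs
  star <- integrate_evidence(do.call(rbind, lapply(1:4, function(i)
    mk_ev("hub", paste0("leaf", i)))))
  ms <- compute_metrics(star)
  expect_identical(ms$betweenness[ms$gene_id == "hub"], 6)
  expect_true(all(ms$degree[ms$gene_id != "hub"] == 1))
})

test_that("betweenness equals the brute-force oracle on random graphs", {
  for (seed in 1:50) {
    g <- random_graph_evidence(n = sample(5:25, 1), p_edge = runif(1, 0.1, 0.5),
                               seed = seed)
    if (is.null(g$evidence)) next
    net <- integrate_evidence(g$evidence)
    m <- compute_metrics(net)
    oracle <- brute_betweenness(g$n, g$edges)
    idx <- as.integer(sub("v", "", m$gene_id))
    expect_equal(m$betweenness, oracle[idx], tolerance = 1e-10)
    # handshake identity
    expect_identical(sum(m$degree), 2 * nrow(net$edges))
    # degree-0/1 nodes have zero betweenness
    expect_true(all(m$betweenness[m$degree <= 1] == 0))
  }
})

test_that("hub threshold satisfies its defining inequality", {
  m <- data.frame(gene_id = sprintf("g%03d", 1:100), degree = 1:100,
                  betweenness = 0)
  h <- call_hubs(m, 0.25)
  expect_identical(h$threshold, 75L)
  expect_identical(length(h$hubs), 25L)

  # heavy ties at the threshold: all tied nodes excluded
  m2 <- data.frame(gene_id = sprintf("g%03d", 1:100),
                   degree = c(rep(1, 50), rep(10, 40), 11:20), betweenness = 0)
  h2 <- call_hubs(m2, 0.25)
  deg <- m2$degree
  # defining inequality: smallest d with |{degree > d}| <= 0.25 n
  expect_true(sum(deg > h2$threshold) <= 25)
  expect_true(h2$threshold == 0 || sum(deg > h2$threshold - 1) > 25)
  expect_lte(h2$realized_fraction, 0.25)
  expect_true(all(m2$degree[match(h2$hubs, m2$gene_id)] > h2$threshold))

  # all degrees equal: no separating threshold
  m3 <- data.frame(gene_id = c("a", "b", "c"), degree = 5, betweenness = 0)
  expect_warning(h3 <- call_hubs(m3, 0.25), "empty")
  expect_identical(length(h3$hubs), 0L)
  expect_error(call_hubs(m, 1.2), "fraction")
})

test_that("hub sets are downward-closed in the fraction", {
  set.seed(7)
  m <- data.frame(gene_id = sprintf("g%03d", 1:200),
                  degree = rpois(200, 6), betweenness = 0)
  prev <- character(0)
  for (f in c(0.1, 0.2, 0.3, 0.5)) {
    h <- suppressWarnings(call_hubs(m, f))
    expect_true(all(prev %in% h$hubs))    # raising fraction never removes
    prev <- h$hubs
  }
})

test_that("power-law fit recovers a planted exponent", {
  # exact grid frequencies proportional to k^-2
  ks <- 11:60
  cnt <- round(1e6 * ks^(-2))
  m <- data.frame(gene_id = seq_len(sum(cnt)), degree = rep(ks, cnt),
                  betweenness = 0)
  fit <- fit_power_law(m, xmin = 10)
  expect_equal(fit$gamma, 2, tolerance = 0.05)

  # sampling oracle: exact discrete power law, gamma = 2.2, n = 5000
  set.seed(1)
  kk <- 1:100000
  pk <- kk^(-2.2); pk <- pk / sum(pk)
  d <- sample(kk, 5000, replace = TRUE, prob = pk)
  fit2 <- fit_power_law(data.frame(gene_id = 1:5000, degree = d,
                                   betweenness = 0), xmin = 10)
  expect_lt(abs(fit2$gamma - 2.2), fit2$gamma_ci)

  expect_error(fit_power_law(data.frame(gene_id = 1:10, degree = rep(2, 10),
                                        betweenness = 0), xmin = 10),
               "distinct degree values")
})

test_that("network summary reports Table-2 style quantities", {
  tri <- classify_experiment_scale(integrate_evidence(
    rbind(mk_ev("a", "b"), mk_ev("b", "c"), mk_ev("a", "c"))))
  s <- summarize_network(tri)
  val <- function(f) s$value[s$feature == f]
  expect_identical(val("proteins"), 3)
  expect_identical(val("interactions"), 3)
  expect_identical(val("degree_mean"), 2)
  expect_identical(val("degree_median"), 2)
  # handshake: mean degree = 2 edges / nodes on a random fixture
  g <- random_graph_evidence(15, 0.3, seed = 99)
  net <- integrate_evidence(g$evidence)
  s2 <- summarize_network(classify_experiment_scale(net))
  expect_equal(s2$value[s2$feature == "degree_mean"],
               2 * nrow(net$edges) / length(interactome_nodes(net)))
})
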