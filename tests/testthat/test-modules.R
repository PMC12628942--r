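test_that("fast-greedy modularity attains the exhaustive optimum on oracle graphs", {
  two_tri <- igraph::graph_from_edgelist(rbind(
    c("a", "b"), c("b", "c"), c("c", "a"),
    c("d", "e"), c("e", "f"), c("f", "d")), directed = FALSE)
  best <- exhaustive_best_modularity(two_tri)
  part <- fast_greedy_partition(two_tri)
  expect_equal(best, 0.5)
  expect_equal(part$Q, best)
  expect_equal(length(part$sizes), 2)

  k5 <- igraph::make_full_graph(5)
  igraph::V(k5)$name <- paste0("v", 1:5)
  part5 <- fast_greedy_partition(k5)
  expect_equal(part5$Q, exhaustive_best_modularity(k5))
  expect_equal(part5$Q, 0)
  expect_equal(length(part5$sizes), 1)
})

test_that("fast-greedy Q never exceeds the exhaustive optimum on small graphs", {
  set.seed(14)
  for (i in 1:4) {
    g <- igraph::sample_gnp(7, 0.4)
    if (igraph::ecount(g) < 1) next
    igraph::V(g)$name <- paste0("n", 1:7)
    comps <- igraph::components(g)
    expect_lte(fast_greedy_partition(g)$Q,
               exhaustive_best_modularity(g) + 1e-12)
  }
  expect_error(fast_greedy_partition(igraph::make_empty_graph(0, directed = FALSE)),
               "at least")
})

test_that("Zi and Pi match the brute-force kappa-counting oracle", {
  fx <- two_module_graph()
  roles <- zi_pi_roles(fx$graph, as_partition(fx$membership))
  oracle <- brute_zipi(fx$edges, fx$membership)
  expect_equal(setNames(roles$Zi, roles$node), oracle$Zi[roles$node])
  expect_equal(setNames(roles$Pi, roles$node), oracle$Pi[roles$node])
  expect_equal(setNames(roles$degree, roles$node), oracle$k[roles$node])
  # link conservation: sum_s kappa_is = k_i is implicit in the oracle equality
  expect_error(zi_pi_roles(fx$graph, as_partition(fx$membership[-1])),
               "absent.*a1")
})

test_that("participation coefficient follows its closed form", {
  # star node with 4 links spread evenly over 4 modules: Pi = 1 - 4*(1/4)^2
  edges <- rbind(c("hub", "m1"), c("hub", "m2"), c("hub", "m3"), c("hub", "m4"),
                 c("m1", "m1b"), c("m2", "m2b"), c("m3", "m3b"), c("m4", "m4b"))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  mem <- setNames(c(1L, 1L, 2L, 3L, 4L, 1L, 2L, 3L, 4L),
                  c("hub", "m1", "m2", "m3", "m4", "m1b", "m2b", "m3b", "m4b"))
  roles <- zi_pi_roles(g, as_partition(mem))
  expect_equal(roles$Pi[roles$node == "hub"], 0.75)
  # all links inside the own module: Pi = 0
  expect_equal(roles$Pi[roles$node == "m1b"], 0)
})

test_that("role categories use strict hub thresholds (boundaries stay low)", {
  classify <- function(Zi, Pi) {
    ifelse(Zi > 2.5, ifelse(Pi > 0.62, "network hub", "module hub"),
           ifelse(Pi > 0.62, "connector", "peripheral"))
  }
  expect_equal(classify(3.0, 0.5), "module hub")
  expect_equal(classify(2.5, 0.62), "peripheral")   # boundary is not a hub
  expect_equal(classify(1.0, 0.70), "connector")
  expect_equal(classify(2.6, 0.70), "network hub")
  fx <- two_module_graph()
  roles <- zi_pi_roles(fx$graph, as_partition(fx$membership))
  expect_equal(roles$role, classify(roles$Zi, roles$Pi))
  # monotone: raising Pi can never send a connector back to peripheral
  con <- roles[roles$role == "connector", ]
  if (nrow(con) > 0) expect_true(all(con$Pi > 0.62))
})

test_that("module eigengenes summarize rank-1 modules exactly", {
  prof <- rnorm(10)
  X <- rbind(t1 = prof, t2 = 2 * prof + 3, t3 = -prof, t4 = prof + rnorm(10, 0, 1e-9),
             t5 = 0.5 * prof)
  colnames(X) <- paste0("S", 1:10)
  part <- as_partition(setNames(rep(1L, 5), rownames(X)))
  eig <- module_eigengenes(X, part, min_size = 5)
  expect_equal(unname(eig$var_explained["M1"]), 1, tolerance = 1e-6)
  expect_equal(abs(cor(eig$eigengenes[, "M1"], prof)), 1, tolerance = 1e-6)
  expect_equal(sum(eig$eigengenes[, "M1"]^2), 1)     # unit norm
  # orientation: summed member correlations are non-negative
  expect_gte(sum(cor(eig$eigengenes[, "M1"], t(X))), 0)

  # a 4-node module is excluded at min_size 5
  part2 <- as_partition(setNames(c(rep(1L, 4), 2L), rownames(X)))
  eig2 <- module_eigengenes(X, part2, min_size = 5)
  expect_equal(ncol(eig2$eigengenes), 0)
  expect_error(module_eigengenes(X[1:3, ], part, min_size = 2), "missing")
})

test_that("module-environment correlations behave like Pearson on eigengenes", {
  set.seed(21)
  prof <- rnorm(12)
  X <- rbind(t1 = prof, t2 = prof * 1.5, t3 = prof + rnorm(12, 0, 1e-6),
             t4 = 2 * prof, t5 = prof - 1)
  colnames(X) <- paste0("S", 1:12)
  part <- as_partition(setNames(rep(1L, 5), rownames(X)))
  eig <- module_eigengenes(X, part, 5)
  frame <- data.frame(sample_id = colnames(X),
                      MAP = as.numeric(eig$eigengenes[, "M1"]),
                      pH = rnorm(12))
  out <- module_env_correlation(eig, frame, env_vars = c("MAP", "pH"))
  expect_equal(out$r[out$variable == "MAP"], 1, tolerance = 1e-9)
  expect_true(out$significant[out$variable == "MAP"])
  expect_true(all(abs(out$r) <= 1))

  # consistent sample reordering leaves r unchanged
  o <- sample(12)
  eig2 <- eig; eig2$eigengenes <- eig$eigengenes[o, , drop = FALSE]
  out2 <- module_env_correlation(eig2, frame[o, ], env_vars = c("MAP", "pH"))
  expect_equal(out2$r, out$r, tolerance = 1e-12)

  frame$bad <- letters[1:12]
  expect_error(module_env_correlation(eig, frame, env_vars = "bad"),
               "non-numeric.*bad")
})
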